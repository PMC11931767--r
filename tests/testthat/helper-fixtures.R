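# Shared fixture builders. Everything is generated in code; no files.

tiny_config <- function(n_segments = 6, n_intersections = 4,
                        annual_counts = c("2007" = 20, "2008" = 20),
                        year_start = 2007, year_end = NULL,
                        hot_fraction = 0, hot_weight0 = 1,
                        weight_decay = 1, seed = 1L) {
  year_end <- year_end %||% (max(as.integer(names(annual_counts))) + 1)
  synthetic_config(
    n_segments = n_segments, n_intersections = n_intersections,
    year_start = year_start, year_end = year_end,
    annual_counts = annual_counts,
    hot_fraction = hot_fraction, hot_weight0 = hot_weight0,
    weight_decay = weight_decay, seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-positioned two-segment / two-intersection network for geometric
# assignment tests: segments along y = 0 and y = 10, intersections at the
# left endpoints.
toy_network <- function() {
  out <- tibble::tibble(
    id = c("seg-a", "seg-b", "int-a", "int-b"),
    kind = c("segment", "segment", "intersection", "intersection"),
    label = c("Main St blk 1", "South St blk 1",
              "Main St & First Ave", "South St & First Ave"),
    geometry = list(
      rbind(c(0, 0), c(10, 0)),
      rbind(c(0, 10), c(10, 10)),
      matrix(c(0, 0), nrow = 1),
      matrix(c(0, 10), nrow = 1)
    )
  )
  class(out) <- c("microplace_network", class(out))
  out
}

# Case series with given microplace ids, dated across years round-robin.
cases_with_ids <- function(ids, years = 2007) {
  n <- length(ids)
  yrs <- rep_len(years, n)
  tibble::tibble(
    event_id = sprintf("ev-%04d", seq_len(n)),
    date = as.Date(sprintf("%d-06-15", yrs)),
    microplace_id = ids
  )
}

# Mid-sized spatial series with a genuinely declining concentration:
# 5,000 microplaces, 10 years x 100 expected events, hot set decaying.
generate_case_series_fixture <- function(seed = 1L, weight_decay = 0.85,
                                         n_years = 10) {
  counts <- setNames(rep(100, n_years), 2007 + seq_len(n_years) - 1)
  cfg <- synthetic_config(
    n_segments = 3000, n_intersections = 2000,
    year_start = 2007, year_end = 2007 + n_years,
    annual_counts = counts,
    hot_fraction = 0.02, hot_weight0 = 50, weight_decay = weight_decay,
    seed = seed
  )
  generate_case_series(generate_network(cfg), cfg)
}

# O(n^2) pairwise oracle for the repeat indicator.
brute_force_repeat <- function(ids) {
  vapply(seq_along(ids), function(i) {
    as.integer(any(ids[-i] == ids[i]))
  }, integer(1))
}
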