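#' Simulate a case series on a microplace network
#'
#' Draws, for each study year, a Poisson number of events (expected count
#' from `config$annual_counts`, scaled by the fraction of the year inside the
#' study window), with dates uniform over the available part of the year.
#' Each event's microplace is sampled with probability proportional to its
#' routing weight: hot microplaces carry weight
#' `hot_weight0 * weight_decay^(year - first_year)`, all others weight 1.
#' The hot set is a fixed random subset of `round(hot_fraction * M)`
#' microplaces drawn once per series. Each year uses its own child RNG
#' stream, so changing one year's count does not perturb another year's
#' draws; the whole series is deterministic given `config$seed`.
#'
#' @param network A microplace network tibble from [generate_network()].
#' @param config A [synthetic_config()].
#' @return A case-series tibble, ordered by date then event id, with columns
#'   `event_id`, `date` (class `Date`), `microplace_id`, and
#'   `assignment_distance` (0: simulated events are pre-assigned).
#' @export
generate_case_series <- function(network, config) {
  validate_synthetic_config(config)
  validate_network(network)
  m <- nrow(network)

  set.seed(child_seed(config$seed, "hot-set"))
  n_hot <- round(config$hot_fraction * m)
  hot <- rep(FALSE, m)
  if (n_hot > 0) hot[sample.int(m, n_hot)] <- TRUE

  lam <- expected_annual_counts(config)
  yrs <- as.integer(names(lam))
  first_year <- floor(config$year_start)

  per_year <- purrr::map(yrs, function(y) {
    set.seed(child_seed(config$seed, paste0("year-", y)))
    n <- rpois(1L, lam[[as.character(y)]])
    if (n == 0) return(NULL)
    lo <- pmax(0, config$year_start - y)
    hi <- pmin(1, config$year_end - y)
    origin <- as.Date(sprintf("%d-01-01", y))
    ndays <- as.integer(as.Date(sprintf("%d-01-01", y + 1)) - origin)
    dates <- origin + floor(runif(n, lo, hi) * ndays)
    w <- rep(1, m)
    w[hot] <- config$hot_weight0 * config$weight_decay^(y - first_year)
    tibble::tibble(
      date = dates,
      microplace_id = network$id[sample.int(m, n, replace = TRUE, prob = w)]
    )
  })

  out <- dplyr::bind_rows(per_year)
  if (nrow(out) == 0) {
    return(tibble::tibble(event_id = character(), date = as.Date(character()),
                          microplace_id = character(),
                          assignment_distance = numeric()))
  }
  out <- dplyr::arrange(out, .data$date, .data$microplace_id)
  out$event_id <- sprintf("ev-%06d", seq_len(nrow(out)))
  out$assignment_distance <- 0
  dplyr::select(out, "event_id", "date", "microplace_id",
                "assignment_distance")
}

#' Simulate repeat labels directly from a log-linear trend
#'
#' Bypasses the spatial allocation entirely: for year index
#' `t = 0, ..., n_years - 1` it emits `n_per_year` cases whose repeat label
#' is an independent Bernoulli draw with probability `p0 * rr^t`. Used for
#' parameter-recovery studies of the trend model, where the generative
#' relative risk is known exactly.
#'
#' @param p0 Repeat probability in the first year, in (0, 1].
#' @param rr Per-year relative risk (> 0).
#' @param n_years Number of study years.
#' @param n_per_year Cases per year.
#' @param seed Integer seed.
#' @param first_year Calendar year of index 0 (default 2007).
#' @return A case-series tibble with columns `event_id`, `date` (July 1 of
#'   each year), `microplace_id` (`NA`), and `is_repeat` (0/1).
#' @export
generate_bernoulli_series <- function(p0, rr, n_years, n_per_year, seed,
                                      first_year = 2007L) {
  stopifnot(rr > 0, n_years >= 1, n_per_year >= 1)
  t <- seq_len(n_years) - 1L
  p <- p0 * rr^t
  bad <- which(p <= 0 | p > 1)
  if (length(bad)) {
    stop(sprintf("repeat probability %.4g out of (0, 1] in year index %d",
                 p[bad[1]], bad[1] - 1L), call. = FALSE)
  }
  set.seed(seed)
  out <- tibble::tibble(
    date = rep(as.Date(sprintf("%d-07-01", first_year + t)), each = n_per_year),
    is_repeat = as.integer(rbinom(n_years * n_per_year, 1L, rep(p, each = n_per_year)))
  )
  out$event_id <- sprintf("ev-%06d", seq_len(nrow(out)))
  out$microplace_id <- NA_character_
  dplyr::select(out, "event_id", "date", "microplace_id", "is_repeat")
}

#' Write or read an event table as CSV
#'
#' The on-disk schema has columns `event_id`, `date` (ISO-8601), and the
#' optional location columns `microplace_id`, `x`, `y`, `cross_street_a`,
#' `cross_street_b`, `address_ref`; absent optional columns are omitted when
#' writing and restored as missing when reading.
#'
#' @param events An event tibble.
#' @param path File path.
#' @return The reader returns the event tibble; the writer returns `path`
#'   invisibly.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(all(c("event_id", "date") %in% names(events)))
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           date = readr::col_date(),
                           .default = readr::col_guess()
                         ))
  for (col in c("event_id", "microplace_id", "cross_street_a",
                "cross_street_b", "address_ref")) {
    if (col %in% names(out)) out[[col]] <- as.character(out[[col]])
  }
  tibble::as_tibble(out)
}
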