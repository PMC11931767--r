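#' Compute the binary repeat-location indicator
#'
#' Labels every case by whether its microplace hosts at least one other case
#' anywhere in the series — past or future. All cases at a microplace with
#' two or more cases get `is_repeat = 1`; cases at single-case microplaces
#' get 0. This binary operationalization is the concentration statistic at
#' the heart of the case-only design: the share of repeat cases is the
#' probability that a given event's location recurs in the data.
#'
#' @param cases Case-series tibble with `event_id` and `microplace_id`.
#' @return The input with an `is_repeat` integer column.
#' @export
#' @examples
#' cases <- tibble::tibble(
#'   event_id = c("a", "b", "c"),
#'   date = as.Date("2020-01-01") + 0:2,
#'   microplace_id = c("m1", "m1", "m2")
#' )
#' compute_repeat_indicators(cases)$is_repeat  # 1 1 0
compute_repeat_indicators <- function(cases) {
  cases <- tibble::as_tibble(cases)
  if (anyNA(cases$microplace_id)) {
    bad <- cases$event_id[is.na(cases$microplace_id)]
    stop(sprintf("unassigned case(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  cases$is_repeat <- repeat_flags(cases$microplace_id)
  cases
}

# Fast path shared with the permutation loop.
repeat_flags <- function(microplace_id) {
  idx <- match(microplace_id, unique(microplace_id))
  as.integer(tabulate(idx)[idx] >= 2L)
}

#' Annual spatial-concentration series
#'
#' Groups cases by calendar year and reports, per year, the number of events,
#' the number of repeat events, and the concentration `n_repeat / n_events`.
#' Repeat membership is always evaluated against the full series, so a
#' microplace with one case in the first year and one in the last contributes
#' a repeat case to both years.
#'
#' @param cases Case series with `is_repeat` populated (see
#'   [compute_repeat_indicators()]).
#' @param study_end Optional fractional year marking the end of the study
#'   window (e.g. `2021.75`); the final year is flagged `partial` when it is
#'   not fully covered.
#' @return A tibble with class `annual_series` and columns `year`,
#'   `n_events`, `n_repeat`, `concentration`, `partial`.
#' @export
annual_concentration <- function(cases, study_end = NULL) {
  stopifnot("is_repeat" %in% names(cases))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cases), year = year_of(.data$date)),
    n_events = dplyr::n(),
    n_repeat = sum(.data$is_repeat),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$year)
  out$concentration <- ifelse(out$n_events > 0,
                              out$n_repeat / out$n_events, NA_real_)
  out$partial <- if (is.null(study_end)) {
    FALSE
  } else {
    study_end - out$year < 1
  }
  class(out) <- c("annual_series", class(out))
  out
}

#' Summary table of microplaces and events
#'
#' A compact descriptive table in the style of a study's "Table 1": counts
#' of microplaces by kind and of events by repeat status, with shares
#' rounded half-up to one decimal. Raw proportions are kept at full
#' precision in the `prop` column; `pct` is the display value.
#'
#' @param cases Case series with `is_repeat` populated. May be empty, in
#'   which case event percentages are undefined (`NA`).
#' @param network Microplace network tibble; `NULL` to omit the microplace
#'   block.
#' @return A tibble with columns `group`, `item`, `n`, `prop`, `pct`.
#' @export
summary_table <- function(cases, network = NULL) {
  stopifnot("is_repeat" %in% names(cases))
  rows <- list()
  if (!is.null(network)) {
    kk <- dplyr::count(tibble::as_tibble(network), .data$kind)
    m <- sum(kk$n)
    rows$places <- tibble::tibble(
      group = "microplaces",
      item = c("total", paste0(kk$kind, "s")),
      n = c(m, kk$n),
      prop = c(NA, if (m > 0) kk$n / m else rep(NA_real_, nrow(kk)))
    )
  }
  n_total <- nrow(cases)
  n_rep <- sum(cases$is_repeat)
  ev_prop <- if (n_total > 0) c(n_rep, n_total - n_rep) / n_total
             else c(NA_real_, NA_real_)
  rows$events <- tibble::tibble(
    group = "events",
    item = c("total", "repeat locations", "non-repeat locations"),
    n = c(n_total, n_rep, n_total - n_rep),
    prop = c(NA, ev_prop)
  )
  out <- dplyr::bind_rows(rows)
  out$pct <- round_half_up(100 * out$prop, 1)
  out
}
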