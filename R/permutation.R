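#' Reshuffle date-location pairs
#'
#' Randomly permutes the observed microplace labels across cases while
#' leaving every case's date untouched. The multiset of locations and the
#' vector of dates are both preserved exactly, so the pooled repeat
#' proportion is invariant; only the association between location and time
#' is destroyed. Any existing `is_repeat` column is dropped so it must be
#' recomputed on the shuffled series.
#'
#' @param cases Assigned case series.
#' @return The series with `microplace_id` permuted and `is_repeat` removed.
#' @export
permute_locations <- function(cases) {
  cases <- tibble::as_tibble(cases)
  n <- nrow(cases)
  if (n > 1) {
    cases$microplace_id <- cases$microplace_id[sample.int(n)]
  }
  cases$is_repeat <- NULL
  cases
}

#' Monte Carlo permutation null for the concentration trend
#'
#' Tests whether the observed time trend in the repeat indicator could have
#' been produced by the study design or exogenous time trends alone. Each
#' trial reshuffles date-location pairs (or, with `null_mode = "uniform"`,
#' redraws every location uniformly from the network), recomputes the repeat
#' indicator against the shuffled series, and refits the trend model with
#' settings identical to the observed fit. Extremity is two-sided on the
#' magnitude of the log relative risk: a trial is as extreme as the data
#' when `|log RR_null| >= |log RR_obs|`.
#'
#' The empirical p-value is `n_as_extreme / n_valid_trials`; when no trial
#' is as extreme it is reported as the upper bound `1 / n_valid_trials`
#' (flagged by `p_is_upper_bound`). The add-one estimator
#' `(n_as_extreme + 1) / (n_valid_trials + 1)` is also returned. Trials
#' whose fit fails are recorded as `NA` and excluded from the denominator;
#' more than 50% failures aborts with a diagnostic. Each trial draws from a
#' child RNG stream derived from `seed` and the trial index, so the null
#' distribution is reproducible trial-by-trial.
#'
#' @param cases Case series with `is_repeat` populated.
#' @param n_trials Number of permutation trials (>= 1).
#' @param seed Integer root seed for the trial streams.
#' @param null_mode `"permute"` (default: reshuffle observed locations) or
#'   `"uniform"` (redraw locations uniformly over the network).
#' @param network Required for `null_mode = "uniform"`.
#' @param year_coding Passed to [fit_log_linear_trend()].
#' @return An object of class `permutation_result` with fields
#'   `observed_log_rr`, `null_log_rrs` (length `n_trials`, `NA` for failed
#'   fits), `n_as_extreme`, `empirical_p`, `p_is_upper_bound`, `p_add_one`,
#'   `n_trials`, `n_failed`, `seed`, `null_mode`.
#' @export
#' @examples
#' net <- generate_network(config_boston_2007_2021(scale = 100))
#' cfg <- config_boston_2007_2021(seed = 3, scale = 100)
#' cases <- compute_repeat_indicators(generate_case_series(net, cfg))
#' monte_carlo_null(cases, n_trials = 49, seed = 9)
monte_carlo_null <- function(cases, n_trials, seed,
                             null_mode = c("permute", "uniform"),
                             network = NULL,
                             year_coding = c("integer", "fractional")) {
  null_mode <- match.arg(null_mode)
  year_coding <- match.arg(year_coding)
  stopifnot(n_trials >= 1)
  if (null_mode == "uniform" && is.null(network)) {
    stop("null_mode = \"uniform\" requires the network", call. = FALSE)
  }
  cases <- compute_repeat_indicators(tibble::as_tibble(cases))
  observed <- fit_log_linear_trend(cases, year_coding)

  # Precompute the centered year covariate once; trials only change labels.
  yrc <- if (year_coding == "integer") {
    year_of(cases$date) - observed$year_origin
  } else {
    fractional_year(cases$date) - observed$year_origin
  }
  ids <- cases$microplace_id
  n <- length(ids)
  pool <- if (null_mode == "uniform") network$id else NULL

  null_log_rrs <- vapply(seq_len(n_trials), function(trial) {
    set.seed(child_seed(seed, paste0("trial-", trial)))
    shuffled <- if (null_mode == "permute") {
      ids[sample.int(n)]
    } else {
      pool[sample.int(length(pool), n, replace = TRUE)]
    }
    y <- repeat_flags(shuffled)
    if (all(y == y[1])) return(NA_real_)
    fit <- tryCatch(fit_log_bernoulli(y, yrc), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) NA_real_ else fit$coef[[2]]
  }, numeric(1))

  n_failed <- sum(is.na(null_log_rrs))
  if (n_failed > n_trials / 2) {
    stop(sprintf("%d of %d null-trial fits failed; null distribution unusable",
                 n_failed, n_trials), call. = FALSE)
  }
  n_valid <- n_trials - n_failed
  k <- sum(abs(null_log_rrs) >= abs(observed$log_rr), na.rm = TRUE)
  structure(
    list(
      observed_log_rr = observed$log_rr,
      observed_fit = observed,
      null_log_rrs = null_log_rrs,
      n_as_extreme = k,
      empirical_p = if (k == 0) 1 / n_valid else k / n_valid,
      p_is_upper_bound = k == 0,
      p_add_one = (k + 1) / (n_valid + 1),
      n_trials = n_trials,
      n_failed = n_failed,
      seed = seed,
      null_mode = null_mode
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> Monte Carlo null for the concentration trend\n")
  cat(sprintf("  observed log RR: %.4f  (RR %.3f)\n",
              x$observed_log_rr, exp(x$observed_log_rr)))
  p_txt <- if (x$p_is_upper_bound) sprintf("< %.4g", x$empirical_p)
  else sprintf("= %.4g", x$empirical_p)
  cat(sprintf("  %d/%d trials as extreme; empirical p %s (%s null)\n",
              x$n_as_extreme, x$n_trials - x$n_failed, p_txt, x$null_mode))
  if (x$n_failed > 0) cat(sprintf("  %d trial fits failed\n", x$n_failed))
  invisible(x)
}

#' @rdname tidy.trend_fit
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(trial = seq_len(x$n_trials), null_log_rr = x$null_log_rrs)
}

#' @rdname tidy.trend_fit
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed_log_rr = x$observed_log_rr,
    n_trials = x$n_trials,
    n_failed = x$n_failed,
    n_as_extreme = x$n_as_extreme,
    empirical_p = x$empirical_p,
    p_is_upper_bound = x$p_is_upper_bound,
    p_add_one = x$p_add_one,
    null_mode = x$null_mode
  )
}
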