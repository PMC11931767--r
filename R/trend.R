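#' Fit the log-linear trend in repeat probability
#'
#' Models the probability that a case is a repeat as
#' `P(repeat = 1) = exp(b0 + b1 * year)` — a Bernoulli outcome with a log
#' link (log-binomial regression), fit by maximum likelihood. The
#' exponentiated slope `exp(b1)` is the relative risk per year: the
#' multiplicative annual change in spatial concentration. Year is coded, by
#' default, as the integer calendar year centered at the first study year;
#' `"fractional"` coding uses `year + (day of year - 1)/365.25` instead.
#'
#' Log-binomial likelihoods are not always well behaved (fitted
#' probabilities can run against the `p <= 1` boundary). When the primary
#' fit fails to converge, the model is refit as a Poisson working model with
#' robust (HC0 sandwich) standard errors, a standard device for estimating
#' relative risks from binary outcomes, and `family_used` records the switch.
#'
#' @param cases Case series with `is_repeat` populated; at least two
#'   distinct years and both outcome values must be present.
#' @param year_coding `"integer"` (default) or `"fractional"`.
#' @return An object of class `trend_fit`; see [tidy.trend_fit()] and
#'   [glance.trend_fit()] for tabular views. Key fields: `rr_per_year`,
#'   `log_rr`, `se_log_rr`, `ci95` (RR scale), `p_value` (two-sided Wald),
#'   `family_used`, `converged`, `n_cases`, `baseline` (fitted repeat
#'   probability at the first study year).
#' @export
#' @examples
#' series <- generate_bernoulli_series(0.6, 0.98, 10, 400, seed = 42)
#' fit <- fit_log_linear_trend(series)
#' tidy(fit)
fit_log_linear_trend <- function(cases, year_coding = c("integer", "fractional")) {
  year_coding <- match.arg(year_coding)
  cases <- tibble::as_tibble(cases)
  stopifnot(all(c("date", "is_repeat") %in% names(cases)))
  yr_int <- year_of(cases$date)
  if (length(unique(yr_int)) < 2) {
    stop("insufficient variation: at least two distinct study years required",
         call. = FALSE)
  }
  y <- cases$is_repeat
  if (all(y == 1L) || all(y == 0L)) {
    stop("degenerate fit: all repeat indicators identical", call. = FALSE)
  }
  origin <- min(yr_int)
  yrc <- if (year_coding == "integer") {
    yr_int - origin
  } else {
    fractional_year(cases$date) - origin
  }

  fit <- fit_log_bernoulli(y, yrc)
  est <- fit$coef
  se <- sqrt(diag(fit$vcov))
  z <- qnorm(0.975)
  structure(
    list(
      rr_per_year = exp(est[[2]]),
      log_rr = est[[2]],
      se_log_rr = se[[2]],
      ci95 = c(lower = exp(est[[2]] - z * se[[2]]),
               upper = exp(est[[2]] + z * se[[2]])),
      p_value = 2 * pnorm(-abs(est[[2]] / se[[2]])),
      baseline = exp(est[[1]]),
      se_log_baseline = se[[1]],
      family_used = fit$family_used,
      converged = fit$converged,
      n_cases = length(y),
      n_years = length(unique(yr_int)),
      year_origin = origin,
      year_coding = year_coding
    ),
    class = "trend_fit"
  )
}

# Core fitter on a Bernoulli outcome with log link. Aggregates to
# per-year-value binomial totals when the covariate is discrete (identical
# MLE and observed information, much faster), falls back to a robust-SE
# Poisson working model when the log-binomial fit does not converge.
fit_log_bernoulli <- function(y, yrc) {
  p0 <- max(min(mean(y), 0.999), 1e-6)
  agg <- rowsum(cbind(k = y, n = 1L), group = yrc)
  uy <- as.numeric(rownames(agg))
  lb <- tryCatch(
    suppressWarnings(
      glm(cbind(agg[, "k"], agg[, "n"] - agg[, "k"]) ~ uy,
          family = binomial(link = "log"),
          start = c(log(p0), 0))
    ),
    error = function(e) NULL
  )
  ok <- !is.null(lb) && lb$converged &&
    all(is.finite(coef(lb))) && all(fitted(lb) <= 1 + 1e-8)
  if (ok) {
    return(list(coef = coef(lb), vcov = vcov(lb),
                family_used = "log_binomial", converged = TRUE))
  }
  po <- glm(y ~ yrc, family = poisson())
  list(coef = coef(po), vcov = sandwich::vcovHC(po, type = "HC0"),
       family_used = "poisson_robust", converged = po$converged)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> log-linear (log-binomial) repeat-probability trend\n")
  cat(sprintf("  RR per year: %.3f  (95%% CI %.3f, %.3f)  p = %.3g\n",
              x$rr_per_year, x$ci95[["lower"]], x$ci95[["upper"]], x$p_value))
  cat(sprintf("  family: %s  converged: %s  cases: %d over %d years\n",
              x$family_used, x$converged, x$n_cases, x$n_years))
  invisible(x)
}

#' Tidy a fitted repeat-probability trend
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per model term with the estimate on the RR
#'   scale and a Wald 95% CI; `glance()` gives a one-row model summary.
#' @export
tidy.trend_fit <- function(x, ...) {
  z <- qnorm(0.975)
  tibble::tibble(
    term = c("(baseline)", "year"),
    estimate = c(x$baseline, x$rr_per_year),
    std.error = c(x$se_log_baseline, x$se_log_rr),
    statistic = log(c(x$baseline, x$rr_per_year)) /
      c(x$se_log_baseline, x$se_log_rr),
    p.value = 2 * pnorm(-abs(log(c(x$baseline, x$rr_per_year)) /
                               c(x$se_log_baseline, x$se_log_rr))),
    conf.low = exp(log(c(x$baseline, x$rr_per_year)) -
                     z * c(x$se_log_baseline, x$se_log_rr)),
    conf.high = exp(log(c(x$baseline, x$rr_per_year)) +
                      z * c(x$se_log_baseline, x$se_log_rr))
  )
}

#' @rdname tidy.trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    rr_per_year = x$rr_per_year,
    conf.low = x$ci95[["lower"]],
    conf.high = x$ci95[["upper"]],
    p.value = x$p_value,
    family_used = x$family_used,
    converged = x$converged,
    n_cases = x$n_cases,
    n_years = x$n_years
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Derived summaries of a fitted trend
#'
#' Translates the per-year relative risk into the quantities usually quoted
#' alongside it: the annual percent change `100 * (rr - 1)`; the aggregate
#' relative reduction over a span, `100 * (1 - rr^span)`; the absolute
#' percentage-point reduction, `100 * baseline * (1 - rr^span)`; and the
#' number of events shifted from repeat to non-repeat locations in an
#' average year, `baseline * (1 - rr^span) * mean_annual_events`.
#'
#' @param fit A converged `trend_fit`.
#' @param span_years Span over which to aggregate the annual change
#'   (e.g. 14 for a 2007-to-2021 study).
#' @param baseline_concentration Concentration at the start of the span;
#'   defaults to the fitted first-year repeat probability.
#' @param mean_annual_events Average events per year used to scale the
#'   events-shifted quantity (e.g. total events / elapsed fractional years);
#'   `NA` if not supplied.
#' @return A one-row tibble: `annual_pct_change`,
#'   `aggregate_relative_reduction`, `absolute_pp_reduction`,
#'   `events_shifted`.
#' @export
#' @examples
#' fit <- fit_log_linear_trend(generate_bernoulli_series(0.6, 0.98, 10, 400, 1))
#' derive_quantities(fit, span_years = 9, mean_annual_events = 400)
derive_quantities <- function(fit, span_years,
                              baseline_concentration = NULL,
                              mean_annual_events = NULL) {
  stopifnot(inherits(fit, "trend_fit"), span_years >= 0)
  if (!fit$converged) stop("trend fit did not converge", call. = FALSE)
  rr <- fit$rr_per_year
  base <- baseline_concentration %||% fit$baseline
  drop <- 1 - rr^span_years
  tibble::tibble(
    annual_pct_change = 100 * (rr - 1),
    aggregate_relative_reduction = 100 * drop,
    absolute_pp_reduction = 100 * base * drop,
    events_shifted = if (is.null(mean_annual_events)) NA_real_
    else base * drop * mean_annual_events
  )
}
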