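test_that("case series conserves counts and references only network ids", {
  cfg <- tiny_config(n_segments = 40, n_intersections = 20,
                     annual_counts = c("2007" = 50, "2008" = 30, "2009" = 10),
                     hot_fraction = 0.1, hot_weight0 = 8, weight_decay = 0.9,
                     seed = 5)
  net <- generate_network(cfg)
  cases <- generate_case_series(net, cfg)
  expect_true(all(cases$microplace_id %in% net$id))
  expect_false(anyDuplicated(cases$event_id) > 0)
  expect_false(is.unsorted(cases$date))
  expect_true(all(year_part <- format(cases$date, "%Y") %in% c("2007", "2008", "2009")))
})

test_that("case series is deterministic and years use independent streams", {
  cfg <- tiny_config(annual_counts = c("2007" = 30, "2008" = 30), seed = 9)
  net <- generate_network(cfg)
  a <- generate_case_series(net, cfg)
  b <- generate_case_series(net, cfg)
  expect_identical(a, b)

  # dropping 2008 leaves 2007's draws untouched
  cfg2 <- tiny_config(annual_counts = c("2007" = 30), year_end = 2009, seed = 9)
  only07 <- generate_case_series(net, cfg2)
  in07 <- dplyr::filter(a, format(date, "%Y") == "2007")
  expect_equal(only07$date, in07$date)
  expect_equal(only07$microplace_id, in07$microplace_id)
})

test_that("all-zero annual counts yield an empty series", {
  cfg <- tiny_config(annual_counts = c("2007" = 0, "2008" = 0))
  net <- generate_network(cfg)
  cases <- generate_case_series(net, cfg)
  expect_equal(nrow(cases), 0)
  expect_named(cases, c("event_id", "date", "microplace_id",
                        "assignment_distance"))
})

test_that("fractional end year truncates dates and scales the expected count", {
  cfg <- tiny_config(annual_counts = c("2020" = 400), year_start = 2020,
                     year_end = 2020.75, seed = 4)
  net <- generate_network(cfg)
  cases <- generate_case_series(net, cfg)
  expect_true(all(cases$date <= as.Date("2020-09-30")))
  # expected 300 after the 0.75 scaling; Poisson(300) stays within 5 sd
  expect_gt(nrow(cases), 300 - 5 * sqrt(300))
  expect_lt(nrow(cases), 300 + 5 * sqrt(300))
})

test_that("uniform allocation matches the birthday-problem closed form", {
  # with hot_weight0 = 1 allocation is uniform over M microplaces, so a
  # given event repeats with probability 1 - (1 - 1/M)^(n-1)
  obs <- exp_p <- numeric(0)
  for (seed in 1:8) {
    cfg <- tiny_config(n_segments = 1200, n_intersections = 800,
                       annual_counts = c("2007" = 300, "2008" = 300),
                       hot_fraction = 0.1, hot_weight0 = 1, seed = seed)
    net <- generate_network(cfg)
    cases <- compute_repeat_indicators(generate_case_series(net, cfg))
    n <- nrow(cases)
    obs <- c(obs, mean(cases$is_repeat))
    exp_p <- c(exp_p, 1 - (1 - 1 / nrow(net))^(n - 1))
  }
  expect_lt(abs(mean(obs) - mean(exp_p)), 0.02)
})

test_that("bernoulli outcome simulator hits its target probabilities", {
  flat <- generate_bernoulli_series(p0 = 0.576, rr = 1, n_years = 5,
                                    n_per_year = 4000, seed = 2)
  expect_equal(nrow(flat), 20000)
  expect_lt(abs(mean(flat$is_repeat) - 0.576),
            4 * sqrt(0.576 * (1 - 0.576) / 20000))

  declining <- generate_bernoulli_series(0.8, 0.9, n_years = 3,
                                         n_per_year = 5000, seed = 3)
  by_year <- tapply(declining$is_repeat, format(declining$date, "%Y"), mean)
  expect_lt(abs(by_year[[1]] - 0.8), 0.03)
  expect_lt(abs(by_year[[3]] - 0.8 * 0.9^2), 0.03)
})

test_that("bernoulli simulator rejects probabilities leaving (0, 1]", {
  expect_error(
    generate_bernoulli_series(p0 = 0.9, rr = 1.2, n_years = 5,
                              n_per_year = 10, seed = 1),
    "year index"
  )
  # boundary p = 1 is allowed but produces a degenerate, flagged fit
  all_ones <- generate_bernoulli_series(1, 1, n_years = 3, n_per_year = 10,
                                        seed = 1)
  expect_true(all(all_ones$is_repeat == 1L))
  expect_error(fit_log_linear_trend(all_ones), "degenerate")
})

test_that("event tables round-trip through CSV", {
  cfg <- tiny_config(annual_counts = c("2007" = 25), seed = 6)
  net <- generate_network(cfg)
  cases <- generate_case_series(net, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(cases, f)
  back <- read_events_csv(f)
  expect_equal(back$event_id, cases$event_id)
  expect_equal(back$date, cases$date)
  expect_equal(back$microplace_id, cases$microplace_id)
})
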