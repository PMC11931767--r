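test_that("location parsing follows the documented mode precedence", {
  events <- tibble::tibble(
    event_id = c("e1", "e2", "e3", "e4", "e5"),
    date = as.Date("2010-01-01") + 0:4,
    cross_street_a = c("South St.", NA, NA, NA, "South St."),
    cross_street_b = c("Main St.", NA, NA, NA, "Main St."),
    address_ref = c(NA, "Main St blk 1", NA, NA, "Main St blk 1"),
    x = c(NA, NA, 3, NA, 1),
    y = c(NA, NA, 0, NA, 1),
    microplace_id = c(NA, NA, NA, "seg-17", "seg-17")
  )
  parsed <- parse_location(events)
  expect_equal(parsed$location_mode,
               c("cross_streets", "address_ref", "coordinates", "preassigned",
                 "cross_streets"))
})

test_that("a row with no location fields errors naming the event", {
  events <- tibble::tibble(event_id = c("good", "lost"),
                           date = as.Date("2010-01-01") + 0:1,
                           microplace_id = c("seg-a", NA))
  expect_error(parse_location(events), "lost")
})

test_that("cross streets match intersections as an unordered, normalized pair", {
  net <- toy_network()
  ev <- function(a, b) {
    parse_location(tibble::tibble(event_id = "e", date = as.Date("2010-01-01"),
                                  cross_street_a = a, cross_street_b = b))
  }
  hit <- assign_to_microplace(ev("main st", "FIRST AVE."), net)
  expect_equal(hit$microplace_id, "int-a")
  # order of the pair does not matter
  hit2 <- assign_to_microplace(ev("First Ave", "Main St."), net)
  expect_equal(hit2$microplace_id, "int-a")
  expect_error(assign_to_microplace(ev("Main St", "Nowhere Rd"), net),
               "unresolvable cross streets")
})

test_that("address references match segment labels after normalization", {
  net <- toy_network()
  loc <- parse_location(tibble::tibble(
    event_id = "e", date = as.Date("2010-01-01"),
    address_ref = "  SOUTH st. BLK 1 "
  ))
  expect_equal(assign_to_microplace(loc, net)$microplace_id, "seg-b")
})

test_that("coordinate snapping picks the nearest microplace with id tie-break", {
  net <- toy_network()
  pt <- function(x, y) {
    parse_location(tibble::tibble(event_id = "e", date = as.Date("2010-01-01"),
                                  x = x, y = y))
  }
  on_seg <- assign_to_microplace(pt(5, 0), net)
  expect_equal(on_seg$microplace_id, "seg-a")
  expect_equal(on_seg$assignment_distance, 0)

  # (5, 5) is exactly equidistant from seg-a and seg-b: smallest id wins
  tied <- assign_to_microplace(pt(5, 5), net)
  expect_equal(tied$microplace_id, "seg-a")

  expect_error(assign_to_microplace(pt(5, 500), net, snap_threshold = 100),
               "snap threshold")
})

test_that("nearest assignment agrees with an exhaustive distance scan", {
  cfg <- tiny_config(n_segments = 25, n_intersections = 10, seed = 13)
  net <- generate_network(cfg)
  xs <- range(unlist(lapply(net$geometry, function(g) g[, 1])))
  ys <- range(unlist(lapply(net$geometry, function(g) g[, 2])))
  set.seed(99)
  pts <- tibble::tibble(
    event_id = sprintf("p%03d", 1:100),
    date = as.Date("2010-01-01"),
    x = runif(100, xs[1], xs[2]), y = runif(100, ys[1], ys[2])
  )
  got <- assign_to_microplace(parse_location(pts), net, snap_threshold = Inf)

  # brute force: point-to-piece distance over every microplace, min by id
  dist_pt_seg <- function(px, py, a, b) {
    d <- b - a
    len2 <- sum(d^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((c(px, py) - a) * d) / len2))
    sqrt(sum((c(px, py) - (a + t * d))^2))
  }
  for (i in seq_len(nrow(pts))) {
    dmin <- vapply(net$geometry, function(g) {
      if (nrow(g) == 1) {
        sqrt((pts$x[i] - g[1, 1])^2 + (pts$y[i] - g[1, 2])^2)
      } else {
        min(vapply(seq_len(nrow(g) - 1), function(j) {
          dist_pt_seg(pts$x[i], pts$y[i], g[j, ], g[j + 1, ])
        }, numeric(1)))
      }
    }, numeric(1))
    best <- min(net$id[dmin <= min(dmin) + 1e-9])
    expect_equal(got$microplace_id[i], best)
  }
})

test_that("build_case_series splits input into assigned plus excluded", {
  net <- toy_network()
  events <- tibble::tibble(
    event_id = c("e1", "e2", "e3", "e4", "e5"),
    date = as.Date("2012-03-01") + 0:4,
    x = c(5, 1, NA, NA, 2000),
    y = c(0, 10, NA, NA, 2000),
    microplace_id = c(NA, NA, "seg-a", NA, NA),
    cross_street_a = c(NA, NA, NA, "Main St", NA),
    cross_street_b = c(NA, NA, NA, "First Ave", NA)
  )
  cases <- build_case_series(events, net, snap_threshold = 100)
  excl <- exclusion_log(cases)
  expect_equal(nrow(cases) + nrow(excl), nrow(events))
  expect_equal(nrow(cases), 4)
  expect_equal(excl$event_id, "e5")
  expect_match(excl$reason, "snap threshold")
  expect_false(is.unsorted(cases$date))
})

test_that("unknown-location rows land in the exclusion log, not an error", {
  net <- toy_network()
  events <- tibble::tibble(
    event_id = c("known", "unknown"),
    date = as.Date("2012-01-01") + 0:1,
    microplace_id = c("seg-a", NA)
  )
  cases <- build_case_series(events, net)
  expect_equal(cases$event_id, "known")
  expect_equal(exclusion_log(cases),
               tibble::tibble(event_id = "unknown",
                              reason = "unknown location"))
})

test_that("assignment is idempotent on an already-assigned series", {
  cfg <- tiny_config(annual_counts = c("2007" = 40), seed = 21)
  net <- generate_network(cfg)
  cases <- generate_case_series(net, cfg)
  again <- build_case_series(cases, net)
  expect_equal(again$event_id, cases$event_id)
  expect_equal(again$microplace_id, cases$microplace_id)
  expect_equal(nrow(exclusion_log(again)), 0)
})

test_that("empty input yields an empty series, not an error", {
  cases <- build_case_series(tibble::tibble(event_id = character(),
                                            date = as.Date(character())),
                             toy_network())
  expect_equal(nrow(cases), 0)
  expect_equal(nrow(exclusion_log(cases)), 0)
})
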