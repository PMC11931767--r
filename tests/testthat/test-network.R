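test_that("generated network has exactly the requested composition", {
  cfg <- tiny_config(n_segments = 30, n_intersections = 12, seed = 3)
  net <- generate_network(cfg)
  expect_s3_class(net, "microplace_network")
  expect_equal(sum(net$kind == "segment"), 30)
  expect_equal(sum(net$kind == "intersection"), 12)
  expect_false(anyDuplicated(net$id) > 0)
  # kind determines geometry arity
  expect_true(all(purrr::map2_lgl(net$kind, net$geometry, function(k, g) {
    if (k == "segment") nrow(g) >= 2 else nrow(g) == 1
  })))
  tallies <- counts_by_kind(net)
  expect_equal(sum(tallies$n), nrow(net))
})

test_that("minimal and degenerate networks behave", {
  net <- generate_network(tiny_config(n_segments = 1, n_intersections = 0))
  expect_equal(nrow(net), 1)
  expect_equal(net$kind, "segment")

  net2 <- generate_network(tiny_config(n_segments = 0, n_intersections = 3))
  expect_equal(sum(net2$kind == "intersection"), 3)

  expect_error(
    generate_network(tiny_config(n_segments = 0, n_intersections = 0)),
    "at least one microplace"
  )
})

test_that("intersections sit at endpoints shared by >= 2 segments when possible", {
  net <- generate_network(tiny_config(n_segments = 20, n_intersections = 5,
                                      seed = 11))
  seg_ends <- do.call(rbind, lapply(net$geometry[net$kind == "segment"],
                                    function(g) g[c(1, nrow(g)), ]))
  pts <- do.call(rbind, net$geometry[net$kind == "intersection"])
  shared <- apply(pts, 1, function(p) {
    sum(abs(seg_ends[, 1] - p[1]) < 1e-9 & abs(seg_ends[, 2] - p[2]) < 1e-9)
  })
  expect_true(all(shared >= 2))
})

test_that("network generation is deterministic: identical GeoJSON bytes", {
  cfg <- tiny_config(n_segments = 3, n_intersections = 2, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".geojson")
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_network_geojson(generate_network(cfg), f1)
  write_network_geojson(generate_network(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed moves the jitter
  cfg2 <- tiny_config(n_segments = 3, n_intersections = 2, seed = 8)
  f3 <- withr::local_tempfile(fileext = ".geojson")
  write_network_geojson(generate_network(cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("network round-trips through GeoJSON and WKT CSV", {
  net <- generate_network(tiny_config(n_segments = 8, n_intersections = 4,
                                      seed = 2))
  gj <- withr::local_tempfile(fileext = ".geojson")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_network_geojson(net, gj)
  write_network_csv(net, cs)
  for (back in list(read_network_geojson(gj), read_network_csv(cs))) {
    expect_equal(back$id, net$id)
    expect_equal(back$kind, net$kind)
    expect_equal(back$label, net$label)
    for (i in seq_len(nrow(net))) {
      expect_equal(back$geometry[[i]], net$geometry[[i]], tolerance = 1e-5)
    }
  }
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(tiny_config(hot_fraction = 1.5), "hot_fraction")
  expect_error(tiny_config(weight_decay = 0), "weight_decay")
  expect_error(tiny_config(annual_counts = c("2007" = -1)), "non-negative")
  expect_error(
    synthetic_config(1, 1, year_start = 2010, year_end = 2009,
                     annual_counts = c("2008" = 5)),
    "year_end"
  )
})

test_that("synthetic config round-trips through JSON", {
  cfg <- config_boston_2007_2021(seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  write_synthetic_config(cfg, f)
  back <- read_synthetic_config(f)
  expect_equal(back$annual_counts, cfg$annual_counts)
  expect_equal(back$hot_weight0, cfg$hot_weight0)
  expect_equal(back$seed, cfg$seed)
})
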