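test_that("the standardized grid is 11 samples every 30 min from tB", {
  ts <- metric_timeseries("zp_T", seq(108, 140, by = 1 / 6),
                          rep(10, length(seq(108, 140, by = 1 / 6))))
  qs <- sample_qsea(ts, tB = 110)
  expect_length(qs$values, 11)
  expect_equal(qs$offsets_min, seq(0, 300, 30))
  expect_equal(qs$tB + qs$offsets_min / 60, seq(110, 115, by = 0.5))
  expect_true(all(qs$values == 10))
  expect_true(attr(qs, "standard_grid"))
  qs2 <- sample_qsea(ts, tB = 110, offsets_min = seq(0, 600, 120))
  expect_false(attr(qs2, "standard_grid"))
})

test_that("linear interpolation is exact on a ramp and on affine series", {
  tt <- seq(110, 116, by = 1 / 6)  # 10-min frames
  ramp <- metric_timeseries("m", tt, (tt - 110) * 60)  # minutes since tB
  qs <- sample_qsea(ramp, tB = 110)
  expect_equal(qs$values, seq(0, 300, 30), tolerance = 1e-9)
  aff <- metric_timeseries("m", tt, 5 + 3.7 * tt)
  qa <- sample_qsea(aff, tB = 110)
  expect_equal(qa$values, 5 + 3.7 * (110 + seq(0, 300, 30) / 60),
               tolerance = 1e-9)
})

test_that("short trajectories error in strict mode and pad in lenient mode", {
  short <- metric_timeseries("m", c(110, 112), c(1, 2))
  expect_error(sample_qsea(short, tB = 110), "assay window")
  qs <- sample_qsea(short, tB = 110, strict = FALSE)
  expect_equal(sum(is.na(qs$values)), 6)  # offsets 150..300 uncovered
  expect_equal(qs$values[1:5], seq(1, 2, by = 0.25), tolerance = 1e-9)
})

test_that("milestone metrics interpolate the annotated timings", {
  ts <- sample_trajectory(c(16.4, 12.9, 8.1), c(113, 120.9, 136),
                          metric = "zp_T")
  mm <- milestone_metrics(ts, list(tSB = 102.5, tB = 113, tEB = 120.9,
                                   t_biopsy = 136))
  expect_equal(mm$value_tB, 16.4, tolerance = 1e-9)
  expect_equal(mm$value_tEB, 12.9, tolerance = 1e-9)
  expect_equal(mm$value_tbiopsy, 8.1, tolerance = 1e-9)
  expect_true(mm$pre_tB)  # series starts at tB, tSB reported from tB frame
  expect_equal(mm$value_tSB, 16.4)
  # overall thinning percent change from the point values
  expect_equal(mm$pc_tbiopsy_tB, (8.1 - 16.4) / 16.4 * 100,
               tolerance = 1e-9)
  expect_equal(round(mm$pc_tbiopsy_tB, 1), -50.6)
  # boundary: milestone equal to the last sample returns the last value
  last <- milestone_metrics(ts, list(tSB = 113, tB = 113, tEB = 120.9,
                                     t_biopsy = max(ts$times)))
  expect_equal(last$value_tbiopsy, ts$values[length(ts$values)])
  expect_error(milestone_metrics(ts, list(tSB = 100, tB = 105, tEB = 120,
                                          t_biopsy = 150)),
               "outside")
})

test_that("percent change follows its definition and exchange identity", {
  expect_equal(percent_change(100, 150), 50)
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(14288, 24082),
               (24082 - 14288) / 14288 * 100)  # +68.5, Table rounds to +69
  expect_error(percent_change(0, 5), "> 0")
  # exchange identity: pc(a, b) = -pc(b, a) * b / a
  set.seed(11)
  a <- runif(50, 1, 100); b <- runif(50, 1, 100)
  expect_equal(percent_change(a, b),
               -percent_change(b, a) * b / a, tolerance = 1e-12)
})

test_that("expansion maps summarize and test each offset", {
  set.seed(5)
  a <- matrix(rnorm(30 * 11, 10), 30, dimnames = list(NULL, paste0("offset_", seq(0, 300, 30))))
  b <- matrix(rnorm(25 * 11, 10), 25, dimnames = list(NULL, paste0("offset_", seq(0, 300, 30))))
  map <- build_expansion_map(a, b)
  expect_s3_class(map, "expansion_map")
  expect_equal(map$offset_min, seq(0, 300, 30))
  expect_equal(map$n_a, rep(30, 11))
  expect_true(all(map$p >= 0 & map$p <= 1))
  expect_true(all(map$p_holm >= map$p - 1e-12))
  expect_true(is.na(earliest_significant_offset(map)) ||
                mean(map$p < 0.05) <= 3 / 11)  # null data: no sustained onset
  expect_error(build_expansion_map(a[1, , drop = FALSE], b), "at least 2")
})

test_that("a configured divergence onset is detected at 150 min", {
  sc <- qsea_divergence_scenario(n_per_group = 200, onset_min = 150,
                                 seed = 77)
  map <- build_expansion_map(sc$a, sc$b, labels = c("euploid", "aneuploid"))
  expect_equal(earliest_significant_offset(map), 150)
  # means recover the configured baseline within 3 SE at each offset
  base <- 16.2 * exp(log(12.6 / 16.2) / 6.2 * seq(0, 300, 30) / 60)
  se <- map$sd_a / sqrt(map$n_a)
  expect_true(all(abs(map$mean_a - base) < 3 * se))
})
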