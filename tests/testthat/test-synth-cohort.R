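test_that("cohort generation is deterministic and respects the seed", {
  cfg <- cohort_config(n_cycles = 40, seed = 5)
  a <- sample_cohorts(cfg)
  b <- sample_cohorts(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- sample_cohorts(cohort_config(n_cycles = 40, seed = 6))
  expect_false(identical(a$embryos, c2$embryos))
})

test_that("realized euploid fraction matches the configured prevalence", {
  cfg <- cohort_config(n_cycles = 786, seed = 21)
  cs <- sample_cohorts(cfg, trajectories = FALSE)
  n <- nrow(cs$embryos)
  p0 <- 886 / 2184
  phat <- mean(cs$embryos$ploidy == "euploid")
  # 99% binomial interval around the configured prevalence
  half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(phat - p0), half)
})

test_that("degenerate or incomplete configurations are rejected", {
  expect_error(cohort_config(n_cycles = 0), "empty cohort")
  cfg <- cohort_config(n_cycles = 5, seed = 1)
  expect_error(sample_cohorts(cfg, calibrations = calibration_presets()["euploid"]),
               "missing calibration")
})

test_that("embryo records satisfy the generator contracts", {
  cs <- small_cohort()
  e <- cs$embryos
  expect_true(all(e$tSB <= e$tB & e$tB <= e$tEB & e$tEB <= e$t_biopsy))
  expect_true(all(e$t_biopsy - e$tB >= 5))
  # only euploids transferred; live birth recorded only for transfers
  expect_true(all(e$ploidy[e$transferred] == "euploid"))
  expect_true(all(is.na(e$live_birth) | e$transferred))
  expect_true(all(!e$transferred | !is.na(e$live_birth)))
  # each embryo in exactly one cycle; anchors nested
  expect_equal(anyDuplicated(e$embryo_id), 0L)
  for (ms in c("tB", "tEB", "tbiopsy")) {
    expect_true(all(e[[paste0("zp_A_", ms)]] >= e[[paste0("emb_A_", ms)]]))
    expect_true(all(e[[paste0("emb_A_", ms)]] >= e[[paste0("ICM_A_", ms)]]))
  }
  # trajectory values at the milestones equal the drawn anchors
  tr <- cs$trajectories
  for (i in sample(nrow(e), 10)) {
    row <- e[i, ]
    tz <- tr[tr$embryo_id == row$embryo_id & tr$metric == "zp_T", ]
    v <- approx(tz$time_hpi, tz$value,
                xout = c(row$tB, row$tEB, row$t_biopsy))$y
    expect_equal(v, c(row$zp_T_tB, row$zp_T_tEB, row$zp_T_tbiopsy),
                 tolerance = 1e-9)
    expect_true(all(diff(tz$value[order(tz$time_hpi)]) <= 1e-9))
  }
})

test_that("group anchor means are recovered at n = 500", {
  cfg <- cohort_config(n_cycles = 500, embryos_per_cycle = 1,
                       p_euploid = 0, seed = 31)
  e <- sample_cohorts(cfg, trajectories = FALSE)$embryos
  cal <- calibration_presets()$aneuploid
  for (chk in list(c("zp_T_tbiopsy", "zp_T", 3),
                   c("zp_A_tB", "zp_A", 1),
                   c("emb_A_tbiopsy", "emb_A", 3),
                   c("ICM_A_tB", "ICM_A", 1))) {
    x <- e[[chk[1]]]
    m0 <- cal$anchors[[chk[2]]][as.integer(chk[3]), "mean"]
    expect_lt(abs(mean(x) - m0), 3 * sd(x) / sqrt(length(x)),
              label = paste("anchor recovery", chk[1]))
  }
  # timing means too
  expect_lt(abs(mean(e$tB) - 113.0), 3 * sd(e$tB) / sqrt(nrow(e)))
})

test_that("trajectory interpolation is exponential through the anchors", {
  ts <- sample_trajectory(c(14288, 17435, 24082), c(113, 120.9, 136))
  at <- function(x) approx(ts$times, ts$values, xout = x)$y
  expect_equal(at(113), 14288, tolerance = 1e-12)
  expect_equal(at(120.9), 17435, tolerance = 1e-12)
  expect_equal(at(136), 24082, tolerance = 1e-12)
  # log-space midpoint of a segment is the geometric mean of its anchors
  grid_mid <- exp((log(14288) + log(17435)) / 2)
  i <- which.min(abs(ts$times - (113 + 120.9) / 2))
  expect_equal(exp(approx(ts$times, log(ts$values),
                          xout = (113 + 120.9) / 2)$y),
               grid_mid, tolerance = 1e-6)
  expect_true(all(diff(ts$values) >= 0))
  # constant anchors give a constant series
  flat <- sample_trajectory(c(7, 7, 7), c(110, 114, 120))
  expect_true(all(abs(flat$values - 7) < 1e-12))
  expect_error(sample_trajectory(c(0, 1, 2), c(1, 2, 3)), "> 0")
  expect_error(sample_trajectory(c(1, 2, 3), c(3, 2, 1)), "ordered")
})

test_that("grade assignment spans independence to strict dominance", {
  set.seed(7)
  comp <- rep(c(TRUE, FALSE), each = 4000)
  g0 <- assign_grade(comp, strength = 0)
  tab <- table(g0, comp)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  g1 <- assign_grade(comp, strength = 1)
  expect_gte(min(as.integer(g1[comp])), max(as.integer(g1[!comp])))
  expect_gte(min(as.integer(g1[comp])), 3)  # competent at least "good"
  expect_identical(as.character(gardner_tier("BA")), "good")
  expect_error(gardner_tier("ZZ"), "unknown")
})
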