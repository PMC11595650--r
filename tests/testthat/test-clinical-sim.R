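make_cycle <- function(ploidy, grade, zp300, cycle = "C1",
                       transferred = NULL, order = NULL, lb = NULL) {
  n <- length(ploidy)
  ids <- sprintf("E%02d", seq_len(n))
  emb <- data.frame(embryo_id = ids, cycle_id = cycle, ploidy = ploidy,
                    grade = grade,
                    transferred = if (is.null(transferred)) FALSE else transferred,
                    transfer_order = if (is.null(order)) NA_integer_ else order,
                    live_birth = if (is.null(lb)) NA else lb,
                    stringsAsFactors = FALSE)
  qs <- data.frame(embryo_id = ids, offset_0 = rep(16, n),
                   offset_300 = zp300, stringsAsFactors = FALSE)
  list(embryos = emb, qsea = qs)
}

test_that("embryologist ranking returns the maximal-tier set", {
  cx <- make_cycle(c("euploid", "aneuploid", "aneuploid"),
                   c("AA", "BB", "CC"), c(8, 9, 10))
  expect_equal(rank_by_embryologist(cx$embryos), "E01")
  tie <- make_cycle(c("euploid", "aneuploid", "aneuploid"),
                    c("AB", "BA", "CC"), c(8, 9, 10))
  expect_setequal(rank_by_embryologist(tie$embryos), c("E01", "E02"))
  single <- make_cycle("euploid", "BB", 8)
  expect_equal(rank_by_embryologist(single$embryos), "E01")
  nog <- single$embryos; nog$grade <- NA_character_; nog$grade_tier <- NULL
  expect_error(rank_by_embryologist(nog), "grade")
})

test_that("qSEA ranking is a deterministic strict order", {
  cx <- make_cycle(rep("euploid", 3), rep("AA", 3), c(6.0, 9.0, 7.5))
  expect_equal(rank_by_qsea(cx$qsea), c("E01", "E03", "E02"))
  # descending for area metrics: larger expansion ranked higher
  area <- data.frame(embryo_id = c("E01", "E02"),
                     offset_0 = c(14000, 14000),
                     offset_300 = c(20000, 25000))
  expect_equal(rank_by_qsea(area, direction = "descending"),
               c("E02", "E01"))
  # exact score tie broken by steeper thinning, then id
  tie <- data.frame(embryo_id = c("E01", "E02", "E03"),
                    offset_0 = c(16, 18, 18),
                    offset_300 = c(8, 8, 8))
  expect_equal(rank_by_qsea(tie), c("E02", "E03", "E01"))
  expect_equal(rank_by_qsea(tie), rank_by_qsea(tie))
  expect_error(rank_by_qsea(tie[, -3]), "offset_300")
})

test_that("euploidy-ranking cycles are classified per the category rules", {
  r <- classify_sim_one(
    make_cycle(c("euploid", "aneuploid"), c("AA", "BB"), c(6, 9))$embryos,
    make_cycle(c("euploid", "aneuploid"), c("AA", "BB"), c(6, 9))$qsea)
  expect_equal(r$concordance, "agree")
  expect_equal(r$effectiveness, "both_right")
  cx <- make_cycle(c("euploid", "aneuploid"), c("AA", "AA"), c(6, 9))
  r2 <- classify_sim_one(cx$embryos, cx$qsea)
  expect_equal(r2$concordance, "embryologist_multi_top")
  expect_equal(r2$emb_top_ploidy, "mixed")
  expect_equal(r2$effectiveness, "qsea_right_vs_mixed")
  cx3 <- make_cycle(c("aneuploid", "euploid"), c("AA", "BB"), c(9, 6))
  r3 <- classify_sim_one(cx3$embryos, cx3$qsea)
  expect_equal(r3$effectiveness, "qsea_better")
  expect_equal(r3$concordance, "disagree")
  # all-euploid tie counts as an embryologist "right" verdict
  cx4 <- make_cycle(c("euploid", "euploid", "aneuploid"),
                    c("AA", "AA", "BB"), c(6, 7, 9))
  expect_equal(classify_sim_one(cx4$embryos, cx4$qsea)$effectiveness,
               "both_right")
  mono <- make_cycle(c("euploid", "euploid"), c("AA", "BB"), c(6, 9))
  expect_error(classify_sim_one(mono$embryos, mono$qsea), "ineligible")
})

test_that("transfer-priority cycles are classified per the category rules", {
  agree <- make_cycle(c("euploid", "euploid"), c("AA", "AA"), c(6, 9),
                      transferred = c(TRUE, FALSE), order = c(1L, NA),
                      lb = c(TRUE, NA))
  r <- classify_sim_two(agree$embryos, agree$qsea)
  expect_equal(r$agreement, "agree")
  expect_true(r$embryologist_correct)
  expect_equal(r$qsea_status, "correct")
  unt <- make_cycle(c("euploid", "euploid"), c("AA", "AA"), c(9, 6),
                    transferred = c(TRUE, FALSE), order = c(1L, NA),
                    lb = c(FALSE, NA))
  r2 <- classify_sim_two(unt$embryos, unt$qsea)
  expect_equal(r2$agreement, "disagree")
  expect_false(r2$embryologist_correct)
  expect_equal(r2$qsea_status, "top_untransferred")
  swap <- make_cycle(c("euploid", "euploid"), c("AA", "AA"), c(9, 6),
                     transferred = c(TRUE, TRUE), order = c(1L, 2L),
                     lb = c(FALSE, TRUE))
  r3 <- classify_sim_two(swap$embryos, swap$qsea)
  expect_false(r3$embryologist_correct)
  expect_equal(r3$qsea_status, "correct")
  none <- make_cycle(c("euploid", "euploid"), c("AA", "AA"), c(6, 9))
  expect_error(classify_sim_two(none$embryos, none$qsea), "no transfer")
})

test_that("simulation outcomes partition eligible cycles deterministically", {
  cs <- small_cohort()
  qs <- cohort_qsea(cs, "zp_T")
  emb <- cs$embryos
  for (ty in c("sim1", "sim2")) {
    elig <- if (ty == "sim1") eligible_sim_one(emb) else eligible_sim_two(emb)
    out <- run_simulation(emb, qs, type = ty)
    expect_setequal(out$cycle_id, elig)
    expect_equal(anyDuplicated(out$cycle_id), 0L)
    out2 <- run_simulation(emb, qs, type = ty)
    expect_identical(out, out2)
  }
  s1 <- run_simulation(emb, qs, type = "sim1")
  # agreement implies a singleton verdict pair: both right or both wrong
  expect_true(all(s1$effectiveness[s1$concordance == "agree"] %in%
                    c("both_right", "both_wrong")))
  summ <- summarize_simulation(s1)
  expect_equal(sum(summ$counts$concordance), summ$n)
  expect_equal(sum(summ$counts$effectiveness), summ$n)
  expect_error(summarize_simulation(s1[0, ]), "empty")
})

test_that("percentages round half away from zero to integers", {
  expect_equal(qseamorph:::round_half_away(42.9), 43)
  expect_equal(qseamorph:::round_half_away(29.5), 30)
  expect_equal(qseamorph:::round_half_away(-50.5), -51)
  expect_equal(qseamorph:::round_half_away(56.49), 56)
})
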