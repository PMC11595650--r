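# integer percent, rounding half away from zero (57.5 -> 58, matching the
# clinical presentation of simulation percentages)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.pct <- function(n, total) round_half_away(n / total * 100)

#' Embryologist top-quality set of a cohort
#'
#' All embryos at the maximal Gardner tier (excellent > good > average >
#' low); ties are allowed, so the set can contain more than one embryo.
#'
#' @param embryos Data frame for one cycle with `embryo_id` and either a
#'   `grade_tier` or a two-letter `grade` column.
#' @return Character vector of top embryo ids.
#' @export
rank_by_embryologist <- function(embryos) {
  if (nrow(embryos) == 0L) stop("empty cohort")
  tier <- if ("grade_tier" %in% names(embryos)) {
    factor(embryos$grade_tier,
           levels = c("low", "average", "good", "excellent"), ordered = TRUE)
  } else if ("grade" %in% names(embryos)) {
    gardner_tier(embryos$grade)
  } else stop("missing grade")
  if (anyNA(tier)) stop("missing grade")
  embryos$embryo_id[tier == max(tier)]
}

#' Strict qSEA ranking of a cohort
#'
#' Ranks embryos by their standardized assay value at one offset. For zona
#' thickness the direction is ascending (thinner ranked higher); for area
#' metrics descending (larger expansion ranked higher). Exact score ties are
#' broken by the steeper change over the assay window (offset 300 minus
#' offset 0, favouring stronger thinning or expansion), then by embryo id,
#' so the order is a deterministic strict total order.
#'
#' @param qsea Wide assay data frame (`embryo_id` + `offset_*` columns)
#'   covering every embryo of the cohort.
#' @param ids Embryo ids to rank (default: all rows of `qsea`).
#' @param offset Scoring offset in minutes (default 300, the end of the
#'   standardized window).
#' @param direction `"ascending"` or `"descending"`.
#' @return Character vector: embryo ids in rank order (best first).
#' @export
rank_by_qsea <- function(qsea, ids = qsea$embryo_id, offset = 300,
                         direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  col <- paste0("offset_", offset)
  if (!col %in% names(qsea)) stop("no assay column ", col)
  rows <- match(ids, qsea$embryo_id)
  if (anyNA(rows)) stop("missing qSEA record for: ",
                        paste(ids[is.na(rows)], collapse = ", "))
  score <- qsea[[col]][rows]
  if (anyNA(score)) stop("missing qSEA value at offset ", offset)
  slope <- if ("offset_0" %in% names(qsea))
    qsea[[col]][rows] - qsea[["offset_0"]][rows] else rep(0, length(rows))
  sgn <- if (direction == "ascending") 1 else -1
  ids[order(sgn * score, sgn * slope, ids)]
}

#' Classify one cycle of the euploidy-ranking simulation
#'
#' Compares the embryologist's grade-based top set with the qSEA top pick in
#' a cycle containing both euploid and aneuploid blastocysts. Concordance is
#' `agree` when the embryologist top set is a singleton equal to the qSEA
#' top, `embryologist_multi_top` when the grade ranking is tied across more
#' than one embryo, and `disagree` otherwise. The effectiveness label
#' compares the ploidy verdicts: the embryologist verdict is right when all
#' top-set embryos are euploid, wrong when all are aneuploid, and mixed
#' otherwise (so an all-euploid tie counts as right); the qSEA verdict is
#' the ploidy of its single top.
#'
#' @param embryos One cycle's embryo table (needs `embryo_id`, `cycle_id`,
#'   `ploidy`, grade columns).
#' @param qsea Wide assay table covering the cycle.
#' @param offset,direction Passed to [rank_by_qsea()].
#' @return One-row data frame: `cycle_id`, `concordance`, `emb_top_ploidy`,
#'   `qsea_top_ploidy`, `effectiveness`.
#' @export
classify_sim_one <- function(embryos, qsea, offset = 300,
                             direction = "ascending") {
  if (nrow(embryos) < 2L || length(unique(embryos$ploidy)) < 2L)
    stop("ineligible cohort: needs >= 2 embryos with both ploidies")
  top_e <- rank_by_embryologist(embryos)
  order_q <- rank_by_qsea(qsea, embryos$embryo_id, offset, direction)
  top_q <- order_q[1]
  concordance <- if (length(top_e) > 1L) "embryologist_multi_top"
    else if (top_e == top_q) "agree" else "disagree"
  plo <- stats::setNames(embryos$ploidy, embryos$embryo_id)
  e_plo <- unique(plo[top_e])
  emb_top_ploidy <- if (length(e_plo) > 1L) "mixed" else e_plo
  qsea_top_ploidy <- unname(plo[top_q])
  e_right <- emb_top_ploidy == "euploid"
  e_mixed <- emb_top_ploidy == "mixed"
  q_right <- qsea_top_ploidy == "euploid"
  effectiveness <-
    if (e_mixed) { if (q_right) "qsea_right_vs_mixed" else "qsea_wrong_vs_mixed"
    } else if (e_right && q_right) "both_right"
    else if (!e_right && !q_right) "both_wrong"
    else if (e_right) "embryologist_better"
    else "qsea_better"
  data.frame(cycle_id = embryos$cycle_id[1], concordance = concordance,
             emb_top_ploidy = emb_top_ploidy,
             qsea_top_ploidy = qsea_top_ploidy,
             effectiveness = effectiveness, stringsAsFactors = FALSE)
}

#' Classify one cycle of the transfer-priority simulation
#'
#' Within a cycle holding at least two euploid blastocysts of which at least
#' one was transferred, the embryologist's priority pick is the historically
#' first-transferred embryo. Agreement holds when the qSEA-top euploid is
#' that same embryo. The embryologist was correct when the first transfer
#' produced a live birth. The qSEA pick is `correct` when its top euploid
#' was transferred and produced a live birth, `incorrect` when transferred
#' without one (miscarriages count as no live birth), and
#' `top_untransferred` when it has no transfer record.
#'
#' @inheritParams classify_sim_one
#' @return One-row data frame: `cycle_id`, `agreement`,
#'   `embryologist_correct`, `qsea_status`.
#' @export
classify_sim_two <- function(embryos, qsea, offset = 300,
                             direction = "ascending") {
  eu <- embryos[embryos$ploidy == "euploid", , drop = FALSE]
  if (nrow(eu) < 2L)
    stop("ineligible cohort: needs >= 2 euploid blastocysts")
  if (!any(eu$transferred)) stop("no transfer record in cohort")
  first <- eu$embryo_id[which(eu$transfer_order == 1L)]
  if (length(first) != 1L) stop("no unique first-transfer record")
  order_q <- rank_by_qsea(qsea, eu$embryo_id, offset, direction)
  top_q <- order_q[1]
  agreement <- if (top_q == first) "agree" else "disagree"
  lb <- stats::setNames(eu$live_birth, eu$embryo_id)
  trans <- stats::setNames(eu$transferred, eu$embryo_id)
  qsea_status <- if (!isTRUE(trans[[top_q]])) "top_untransferred"
    else if (isTRUE(lb[[top_q]])) "correct" else "incorrect"
  data.frame(cycle_id = embryos$cycle_id[1], agreement = agreement,
             embryologist_correct = isTRUE(lb[[first]]),
             qsea_status = qsea_status, stringsAsFactors = FALSE)
}

#' Run a ranking simulation over every eligible cycle
#'
#' Applies [classify_sim_one()] or [classify_sim_two()] to all cycles that
#' pass the corresponding eligibility filter ([eligible_sim_one()] /
#' [eligible_sim_two()]).
#'
#' @param embryos Full embryo table (all cycles).
#' @param qsea Wide assay table covering all embryos.
#' @param type `"sim1"` (euploidy ranking) or `"sim2"` (transfer priority).
#' @param offset,direction Passed to [rank_by_qsea()].
#' @return Data frame of per-cycle outcomes with attribute `type`.
#' @export
run_simulation <- function(embryos, qsea, type = c("sim1", "sim2"),
                           offset = 300, direction = "ascending") {
  type <- match.arg(type)
  cyc <- if (type == "sim1") eligible_sim_one(embryos)
         else eligible_sim_two(embryos)
  if (length(cyc) == 0L) stop("no eligible cycles")
  f <- if (type == "sim1") classify_sim_one else classify_sim_two
  out <- do.call(rbind, lapply(cyc, function(cid)
    f(embryos[embryos$cycle_id == cid, , drop = FALSE], qsea,
      offset, direction)))
  attr(out, "type") <- type
  out
}

#' Summarize per-cycle simulation outcomes
#'
#' Tallies the outcome categories of one simulation with integer
#' percentages (rounded half away from zero, the clinical presentation) and
#' the derived aggregates: for the euploidy-ranking simulation,
#' `equally_effective` (both right or both wrong) and `equal_or_better`
#' (every category in which the qSEA verdict was at least as good as the
#' embryologists'); for the transfer-priority simulation the upper bound on
#' correct prioritization, counting top-ranked euploids never yet
#' transferred as potential successes.
#'
#' @param outcomes Data frame from [run_simulation()] (or assembled in its
#'   schema); its `type` attribute, or the column set, decides the summary.
#' @return List of class `sim_summary` with `n`, per-category `counts` and
#'   `percent`, and the aggregates.
#' @export
summarize_simulation <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) stop("empty outcome list")
  type <- attr(outcomes, "type")
  if (is.null(type)) {
    type <- if ("effectiveness" %in% names(outcomes)) "sim1"
            else if ("qsea_status" %in% names(outcomes)) "sim2"
            else stop("unrecognized outcome schema")
  }
  n <- nrow(outcomes)
  cnt <- function(v, levels) {
    x <- table(factor(v, levels = levels))
    stats::setNames(as.integer(x), levels)
  }
  if (type == "sim1") {
    conc <- cnt(outcomes$concordance,
                c("agree", "disagree", "embryologist_multi_top"))
    eff <- cnt(outcomes$effectiveness,
               c("both_right", "both_wrong", "embryologist_better",
                 "qsea_better", "qsea_right_vs_mixed", "qsea_wrong_vs_mixed"))
    emb_top <- cnt(outcomes$emb_top_ploidy,
                   c("euploid", "aneuploid", "mixed"))
    qsea_top <- cnt(outcomes$qsea_top_ploidy, c("euploid", "aneuploid"))
    equally <- eff[["both_right"]] + eff[["both_wrong"]]
    eq_or_better <- equally + eff[["qsea_better"]] +
      eff[["qsea_right_vs_mixed"]]
    res <- list(type = "sim1", n = n,
                counts = list(concordance = conc, effectiveness = eff,
                              emb_top_ploidy = emb_top,
                              qsea_top_ploidy = qsea_top),
                percent = list(concordance = .pct(conc, n),
                               effectiveness = .pct(eff, n),
                               emb_top_ploidy = .pct(emb_top, n),
                               qsea_top_ploidy = .pct(qsea_top, n)),
                equally_effective = c(n = equally, pct = .pct(equally, n)),
                equal_or_better = c(n = eq_or_better,
                                    pct = .pct(eq_or_better, n)))
  } else {
    agr <- cnt(outcomes$agreement, c("agree", "disagree"))
    qs <- cnt(outcomes$qsea_status,
              c("correct", "incorrect", "top_untransferred"))
    emb_ok <- sum(outcomes$embryologist_correct)
    upper <- qs[["correct"]] + qs[["top_untransferred"]]
    res <- list(type = "sim2", n = n,
                counts = list(agreement = agr, qsea_status = qs,
                              embryologist_correct = emb_ok),
                percent = list(agreement = .pct(agr, n),
                               qsea_status = .pct(qs, n),
                               embryologist_correct = .pct(emb_ok, n)),
                improve_upper_bound = c(n = upper, pct = .pct(upper, n)))
  }
  structure(res, class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("Simulation", if (x$type == "sim1") "1 (euploidy ranking)"
      else "2 (transfer priority)", "-", x$n, "eligible cycles\n")
  for (nm in names(x$counts)) {
    cat(" ", nm, ":\n")
    v <- x$counts[[nm]]
    if (length(v) == 1L) {
      cat("    ", v, " (", x$percent[[nm]], "%)\n", sep = "")
    } else {
      for (k in names(v))
        cat(sprintf("    %-22s %4d (%d%%)\n", k, v[[k]],
                    x$percent[[nm]][[k]]))
    }
  }
  if (x$type == "sim1") {
    cat(sprintf("  equally effective: %d (%d%%); equal or better: %d (%d%%)\n",
                x$equally_effective[["n"]], x$equally_effective[["pct"]],
                x$equal_or_better[["n"]], x$equal_or_better[["pct"]]))
  } else {
    cat(sprintf("  correct may improve up to: %d (%d%%)\n",
                x$improve_upper_bound[["n"]], x$improve_upper_bound[["pct"]]))
  }
  invisible(x)
}
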