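#' Percent change between two metric values
#'
#' `(v_to - v_from) / v_from * 100`, the convention used for expansion
#' ratios between milestones (+50 means a 50 percent increase).
#'
#' @param v_from Reference value(s), strictly positive.
#' @param v_to Target value(s).
#' @return Percent change, vectorized.
#' @export
#' @examples
#' percent_change(14288, 24082)  # +68.6 for the aneuploid zona area
percent_change <- function(v_from, v_to) {
  if (any(v_from <= 0)) stop("v_from must be > 0")
  (v_to - v_from) / v_from * 100
}

#' Standardized expansion sampling of one trajectory
#'
#' Resamples a metric trajectory on the standardized assay grid: every 30
#' minutes over the 5 hours following full blastulation, 11 samples
#' including the tB frame itself. Values are linearly interpolated between
#' frames.
#'
#' @param ts A [metric_timeseries()].
#' @param tB Reference time (full blastulation) in hpi.
#' @param offsets_min Sampling offsets in minutes. Departing from the
#'   standard `seq(0, 300, 30)` grid marks the result non-standard.
#' @param strict If `TRUE` (default), error when the trajectory does not
#'   cover the full window; if `FALSE`, missing offsets become `NA`.
#' @param embryo_id Optional id carried on the result.
#' @return An object of class `qsea_series` with fields `metric`, `tB`,
#'   `offsets_min`, `values`, and attribute `standard_grid`.
#' @export
sample_qsea <- function(ts, tB, offsets_min = seq(0, 300, by = 30),
                        strict = TRUE, embryo_id = NA_character_) {
  stopifnot(inherits(ts, "metric_timeseries"))
  target <- tB + offsets_min / 60
  lo <- min(ts$times); hi <- max(ts$times)
  covered <- target >= lo - 1e-9 & target <= hi + 1e-9
  if (!all(covered)) {
    if (strict)
      stop("trajectory covers [", round(lo, 2), ", ", round(hi, 2),
           "] hpi but the assay window needs [", round(min(target), 2),
           ", ", round(max(target), 2), "]")
  }
  vals <- rep(NA_real_, length(target))
  if (any(covered))
    vals[covered] <- stats::approx(ts$times, ts$values,
                                   xout = target[covered])$y
  structure(list(embryo_id = embryo_id, metric = ts$metric, tB = tB,
                 offsets_min = offsets_min, values = vals),
            standard_grid = identical(as.numeric(offsets_min),
                                      as.numeric(seq(0, 300, by = 30))),
            class = "qsea_series")
}

#' Milestone values and expansion ratios for one trajectory
#'
#' Interpolates a trajectory at the four annotated timings and derives the
#' percent changes tEB/tB, t-biopsy/tEB and t-biopsy/tB. Trajectories start
#' at tB, so the tSB value is reported as the earliest available frame value
#' and flagged `pre_tB`.
#'
#' @param ts A [metric_timeseries()].
#' @param timings Named list or vector with `tSB`, `tB`, `tEB`, `t_biopsy`
#'   (hpi), ordered.
#' @param strict Error if tB..t-biopsy fall outside the trajectory span.
#' @return One-row data frame: metric, values at the four timings, a
#'   `pre_tB` flag for the tSB value, and the three percent changes.
#' @export
milestone_metrics <- function(ts, timings, strict = TRUE) {
  stopifnot(inherits(ts, "metric_timeseries"))
  tt <- unlist(timings)[c("tSB", "tB", "tEB", "t_biopsy")]
  if (anyNA(tt)) stop("timings must contain tSB, tB, tEB, t_biopsy")
  if (is.unsorted(tt)) stop("timings must be ordered")
  lo <- min(ts$times); hi <- max(ts$times)
  if (strict && (tt["tB"] < lo - 1e-9 || tt["t_biopsy"] > hi + 1e-9))
    stop("milestone outside trajectory span")
  at <- function(x) stats::approx(ts$times, ts$values, xout = x, rule = 2)$y
  pre_tB <- tt["tSB"] < lo - 1e-9
  v <- c(at(max(tt["tSB"], lo)), at(tt["tB"]), at(tt["tEB"]),
         at(tt["t_biopsy"]))
  data.frame(metric = ts$metric,
             value_tSB = v[1], value_tB = v[2], value_tEB = v[3],
             value_tbiopsy = v[4], pre_tB = unname(pre_tB),
             pc_tEB_tB = percent_change(v[2], v[3]),
             pc_tbiopsy_tEB = percent_change(v[3], v[4]),
             pc_tbiopsy_tB = percent_change(v[2], v[4]))
}

#' Standardized assay values for every embryo of a cohort
#'
#' @param cohort A `cohort_set` from [sample_cohorts()] (with trajectories).
#' @param metric Which metric to sample (`"zp_T"`, `"zp_A"` or `"emb_A"`).
#' @param offsets_min Assay offsets in minutes.
#' @return Wide data frame: `embryo_id` plus one `offset_<min>` column per
#'   offset.
#' @export
cohort_qsea <- function(cohort, metric = "zp_T",
                        offsets_min = seq(0, 300, by = 30)) {
  stopifnot(inherits(cohort, "cohort_set"))
  if (is.null(cohort$trajectories))
    stop("cohort_set was generated without trajectories")
  tr <- cohort$trajectories[cohort$trajectories$metric == metric, ,
                            drop = FALSE]
  if (nrow(tr) == 0L) stop("no trajectories for metric ", metric)
  tBs <- stats::setNames(cohort$embryos$tB, cohort$embryos$embryo_id)
  sp <- split(tr, tr$embryo_id)
  rows <- lapply(names(sp), function(id) {
    ts <- metric_timeseries(metric, sp[[id]]$time_hpi, sp[[id]]$value)
    sample_qsea(ts, tBs[[id]], offsets_min = offsets_min,
                embryo_id = id)$values
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("offset_", offsets_min)
  cbind(data.frame(embryo_id = names(sp), stringsAsFactors = FALSE), out)
}

#' Group expansion map with per-timepoint tests
#'
#' Summarizes two groups of standardized assay series offset by offset
#' (mean, SD, n) and tests the group difference at every offset with the
#' normality-gated two-group test of [compare_groups()]. Per-offset p-values
#' are reported unadjusted, as in the clinical presentation; because 11
#' correlated tests are performed a Holm-adjusted column is also emitted.
#' No correction is applied for embryos clustered within cycles.
#'
#' @param a,b Numeric matrices or wide data frames (rows = embryos, one
#'   column per offset; an `embryo_id` column is dropped if present). Both
#'   groups need at least 2 embryos.
#' @param alpha Two-sided significance level for the per-offset flag.
#' @param labels Length-2 character: group labels.
#' @return Data frame of class `expansion_map`: offset_min, mean/sd/n per
#'   group, `p`, `p_holm`, `significant`.
#' @export
build_expansion_map <- function(a, b, alpha = 0.05, labels = c("A", "B")) {
  strip <- function(x) {
    x <- as.data.frame(x)
    x$embryo_id <- NULL
    as.matrix(x)
  }
  a <- strip(a); b <- strip(b)
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each group needs at least 2 embryos")
  if (ncol(a) != ncol(b)) stop("offset grids differ between groups")
  offs <- sub("^offset_", "", colnames(a))
  offs <- suppressWarnings(as.numeric(offs))
  if (anyNA(offs)) offs <- seq(0, by = 30, length.out = ncol(a))
  res <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    tst <- compare_groups(x, y, continuous = TRUE)
    data.frame(offset_min = offs[j],
               mean_a = mean(x), sd_a = stats::sd(x), n_a = length(x),
               mean_b = mean(y), sd_b = stats::sd(y), n_b = length(y),
               test = tst$test, p = tst$p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "labels") <- labels
  attr(out, "clustering_adjusted") <- FALSE
  class(out) <- c("expansion_map", class(out))
  out
}

#' Earliest offset of sustained group divergence
#'
#' The onset of significance in an expansion map: the smallest offset at
#' which the group difference is significant and remains significant at
#' every later offset. Isolated early significances (expected at rate alpha
#' under the null) are therefore not counted as an onset.
#'
#' @param map An `expansion_map` from [build_expansion_map()].
#' @param adjusted Use the Holm-adjusted p-values instead of the raw ones.
#' @param alpha Significance level; defaults to the map's own alpha.
#' @return Offset in minutes, or `NA` if the groups never sustainedly
#'   diverge.
#' @export
earliest_significant_offset <- function(map, adjusted = FALSE,
                                        alpha = attr(map, "alpha")) {
  p <- if (adjusted) map$p_holm else map$p
  sig <- p < alpha
  tail_ok <- rev(cumprod(rev(sig))) == 1
  if (!any(tail_ok)) return(NA_real_)
  map$offset_min[which(tail_ok)[1]]
}

#' Two-group assay scenario with a configured divergence onset
#'
#' Generates standardized zona-thickness assay matrices for two groups whose
#' mean curves coincide before a configured offset and separate from it
#' onwards: group A thins along the calibrated euploid pace while group B
#' (the slower-thinning group) is shifted upward by `step` micrometres at
#' the onset offset, growing by `slope` per 30 minutes thereafter.
#' Between-embryo heterogeneity enters as a random intercept.
#'
#' @param n_per_group Embryos per group.
#' @param onset_min Divergence onset offset in minutes.
#' @param step Mean separation (um) at the onset offset.
#' @param slope Additional separation per 30 min after onset.
#' @param sd_embryo Between-embryo SD of the random intercept (um).
#' @param sd_noise Within-embryo measurement SD per offset (um).
#' @param seed Optional seed.
#' @return List with matrices `a`, `b` (rows = embryos, 11 offset columns)
#'   and `offsets_min`.
#' @export
qsea_divergence_scenario <- function(n_per_group = 200, onset_min = 150,
                                     step = 0.9, slope = 0.35,
                                     sd_embryo = 2.0, sd_noise = 1.5,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offs <- seq(0, 300, by = 30)
  baseline <- 16.2 * exp(log(12.6 / 16.2) / 6.2 * offs / 60)
  shift <- ifelse(offs < onset_min, 0,
                  step + slope * (offs - onset_min) / 30)
  draw <- function(mu) {
    re <- stats::rnorm(n_per_group, 0, sd_embryo)
    m <- matrix(rep(mu, each = n_per_group), n_per_group) + re +
      matrix(stats::rnorm(n_per_group * length(offs), 0, sd_noise),
             n_per_group)
    m[m < 0.1] <- 0.1
    colnames(m) <- paste0("offset_", offs)
    m
  }
  list(a = draw(baseline), b = draw(baseline + shift), offsets_min = offs)
}
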