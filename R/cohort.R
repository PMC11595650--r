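#' A single-metric trajectory for one embryo
#'
#' @param metric Metric name (e.g. `"zp_T"`).
#' @param times Sample times in hpi, strictly increasing.
#' @param values Non-negative metric values (um^2 for areas, um for zp_T).
#' @return An object of class `metric_timeseries`.
#' @export
metric_timeseries <- function(metric, times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("values must be >= 0")
  structure(list(metric = metric, times = as.numeric(times),
                 values = as.numeric(values)),
            class = "metric_timeseries")
}

#' Interpolate a metric trajectory through its milestone anchors
#'
#' Builds a trajectory on a uniform frame grid from tB to t-biopsy that
#' passes exactly through the three milestone anchors (tB, tEB, t-biopsy).
#' Interpolation is exponential (linear in log value), so the series is
#' positive, monotone between anchors, and percent change accumulates
#' multiplicatively — matching how expansion is reported as ratios between
#' milestones. The grid always contains the milestone times themselves, so
#' linear resampling downstream recovers the anchors exactly.
#'
#' @param anchors Numeric length-3: metric values at tB, tEB, t-biopsy. Must
#'   be strictly positive (log interpolation).
#' @param timings Numeric length-3: tB, tEB, t-biopsy in hpi, ordered.
#' @param spacing_min Frame spacing in minutes.
#' @param metric Metric name attached to the result.
#' @return A [metric_timeseries()].
#' @export
#' @examples
#' ts <- sample_trajectory(c(14288, 17435, 24082), c(113, 120.9, 136))
#' ts$values[1]  # 14288, exactly the tB anchor
sample_trajectory <- function(anchors, timings, spacing_min = 10,
                              metric = "metric") {
  stopifnot(length(anchors) == 3L, length(timings) == 3L)
  if (any(anchors <= 0)) stop("anchors must be > 0 for log interpolation")
  if (is.unsorted(timings, strictly = FALSE) || any(diff(timings) < 0))
    stop("timings must be ordered tB <= tEB <= t_biopsy")
  grid <- seq(timings[1], timings[3], by = spacing_min / 60)
  grid <- sort(unique(c(grid, timings)))
  # collapse coincident milestones (tEB == t_biopsy is legal in the limit)
  key_t <- timings[!duplicated(timings)]
  key_v <- anchors[!duplicated(timings)]
  if (length(key_t) == 1L) {
    vals <- rep(key_v, length(grid))
  } else {
    vals <- exp(stats::approx(key_t, log(key_v), xout = grid, rule = 2)$y)
  }
  metric_timeseries(metric, grid, vals)
}

#' Map a Gardner letter grade to its quality tier
#'
#' Tiers collapse the ICM/TE letter pairs: excellent = AA; good = AB or BA;
#' average = BB, AC or CA; low = CC, BC or CB.
#'
#' @param grade Character vector of two-letter Gardner grades.
#' @return Ordered factor with levels `low < average < good < excellent`.
#' @export
#' @examples
#' gardner_tier(c("AA", "BA", "CA", "CB"))
gardner_tier <- function(grade) {
  map <- c(AA = "excellent", AB = "good", BA = "good",
           BB = "average", AC = "average", CA = "average",
           CC = "low", BC = "low", CB = "low")
  tier <- map[toupper(grade)]
  if (anyNA(tier)) stop("unknown Gardner grade: ",
                        paste(unique(grade[is.na(tier)]), collapse = ", "))
  factor(tier, levels = c("low", "average", "good", "excellent"),
         ordered = TRUE)
}

#' Assign Gardner grade tiers with a tunable competence association
#'
#' The virtual embryologist assigns a morphology tier from a latent quality
#' quantile. At association strength 0 the tier is independent of competence;
#' at strength 1 competent embryos draw from the upper half of the quality
#' scale and incompetent from the lower half, so competent tiers strictly
#' dominate (ties allowed).
#'
#' @param competent Logical vector: latent competence (euploid and
#'   implantation-capable).
#' @param strength Association strength in `[0, 1]`.
#' @param base_probs Marginal tier probabilities at strength 0, ordered
#'   low, average, good, excellent.
#' @return Ordered factor of tiers, same length as `competent`.
#' @export
assign_grade <- function(competent, strength = 0.5,
                         base_probs = c(0.15, 0.30, 0.30, 0.25)) {
  stopifnot(strength >= 0, strength <= 1, length(base_probs) == 4L)
  base_probs <- base_probs / sum(base_probs)
  n <- length(competent)
  u <- stats::runif(n)
  half <- ifelse(competent, 0.5 + 0.5 * stats::runif(n), 0.5 * stats::runif(n))
  q <- (1 - strength) * u + strength * half
  breaks <- c(0, cumsum(base_probs))
  breaks[length(breaks)] <- 1 + 1e-9
  tiers <- c("low", "average", "good", "excellent")
  factor(tiers[findInterval(q, breaks, rightmost.closed = TRUE)],
         levels = tiers, ordered = TRUE)
}

# random letter pair consistent with a tier (presentation only; ranking uses
# the tier)
.gardner_letters <- function(tier) {
  pool <- list(excellent = "AA", good = c("AB", "BA"),
               average = c("BB", "AC", "CA"), low = c("CC", "BC", "CB"))
  vapply(as.character(tier), function(tt) {
    p <- pool[[tt]]
    p[sample.int(length(p), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

# redraw rows of draw_fn(k) (a k-row matrix) until ok_fn(row-matrix) is TRUE
# for every row; bounded attempts
.resample_rows <- function(n, draw_fn, ok_fn, max_attempts = 100L,
                           what = "draws") {
  out <- draw_fn(n)
  bad <- which(!ok_fn(out))
  attempt <- 0L
  while (length(bad) > 0L) {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("could not satisfy constraints for ", what, " after ",
           max_attempts, " attempts")
    repl <- draw_fn(length(bad))
    out[bad, ] <- repl
    bad <- bad[!ok_fn(out[bad, , drop = FALSE])]
  }
  out
}

# correlated standard normals: n x k with equicorrelation rho
.equicorr_normals <- function(n, k, rho) {
  shared <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * k), n, k)
  sqrt(rho) * shared + sqrt(1 - rho) * eps
}

# timings for n embryos of one group: n x 4 (tSB, tB, tEB, t_biopsy),
# ordered, with at least 5.5 h between tB and biopsy so the standardized
# 5-h assay window is always covered
.sample_timings <- function(n, cal) {
  draw <- function(k) {
    z <- .equicorr_normals(k, 4L, cal$timing_cor)
    sweep(sweep(z, 2, cal$timing_sd, `*`), 2, cal$timing_mean, `+`)
  }
  ok <- function(m) {
    m[, 1] <= m[, 2] & m[, 2] <= m[, 3] & m[, 3] <= m[, 4] &
      m[, 4] - m[, 2] >= 5.5 & m[, 1] > 0
  }
  tm <- .resample_rows(n, draw, ok, what = "timing ordering")
  colnames(tm) <- c("tSB", "tB", "tEB", "t_biopsy")
  tm
}

# milestone anchors for n embryos of one group. zp_A and emb_A share the
# same standardized deviations (the outer contour tracks the embryo it
# wraps), which keeps the thin annulus positive almost surely; zp_T and
# ICM_A are separately calibrated observables. Only the zona thickness
# carries a monotonicity contract (non-increasing across milestones) and is
# rejection-resampled accordingly; its violation rate is ~2% so the
# truncation leaves the calibrated means intact. Area anchors are left
# unconstrained across milestones: forcing them ordered would truncate the
# wide t-biopsy marginals and shift their means by far more than a standard
# error.
.sample_anchors <- function(n, cal) {
  rho <- cal$anchor_cor
  an <- cal$anchors
  val <- function(a, z) sweep(sweep(z, 2, a[, "sd"], `*`), 2, a[, "mean"], `+`)
  draw <- function(k) {
    z_area <- .equicorr_normals(k, 3L, rho)
    z_zpt <- .equicorr_normals(k, 3L, rho)
    z_icm <- .equicorr_normals(k, 3L, rho)
    cbind(val(an$zp_A, z_area), val(an$emb_A, z_area),
          val(an$zp_T, z_zpt), val(an$ICM_A, z_icm))
  }
  ok <- function(m) {
    zp <- m[, 1:3, drop = FALSE]; em <- m[, 4:6, drop = FALSE]
    zt <- m[, 7:9, drop = FALSE]; ic <- m[, 10:12, drop = FALSE]
    apply(zt, 1, function(r) all(diff(r) <= 0)) &
      apply(zp > 0, 1, all) & apply(em > 0, 1, all) &
      zt[, 3] > 0 & apply(ic > 0, 1, all)
  }
  m <- .resample_rows(n, draw, ok, what = "anchor ordering")
  colnames(m) <- paste(rep(c("zp_A", "emb_A", "zp_T", "ICM_A"), each = 3),
                       rep(c("tB", "tEB", "tbiopsy"), 4), sep = "_")
  # enforce strict nesting at each milestone (clips are rare and small)
  for (ms in 1:3) {
    m[, 3 + ms] <- pmin(m[, 3 + ms], m[, ms] - 1)          # emb_A <= zp_A - 1
    m[, 9 + ms] <- pmin(m[, 9 + ms], 0.9 * m[, 3 + ms])     # ICM_A <= 0.9 emb_A
  }
  m
}

#' Generate a synthetic cohort set
#'
#' Draws cycles of biopsied blastocysts with group-calibrated blastulation
#' timings, milestone morphometric anchors, exponentially interpolated
#' metric trajectories, Gardner grade tiers from a virtual embryologist, and
#' retrospective transfer/live-birth records. Only euploid blastocysts are
#' transferred (single vitrified-warmed transfers, in embryologist priority
#' order, until a live birth or drop-out).
#'
#' @param config A [cohort_config()]; its `seed` fixes every draw.
#' @param calibrations Named list of [group_calibration()] objects covering
#'   every group the configuration can draw (see [calibration_presets()]).
#' @param trajectories If `TRUE` (default) build per-embryo trajectories for
#'   the assay metrics (`zp_A`, `emb_A`, `zp_T`); set `FALSE` to generate
#'   only the embryo table (faster for large cohorts).
#' @return An object of class `cohort_set`: a list with `embryos` (one row
#'   per blastocyst), `trajectories` (long data frame: embryo_id, metric,
#'   time_hpi, value) and the `config`.
#' @export
#' @examples
#' cs <- sample_cohorts(cohort_config(n_cycles = 20, seed = 42))
#' table(cs$embryos$ploidy)
sample_cohorts <- function(config, calibrations = calibration_presets(),
                           trajectories = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_cycles < 1) stop("empty cohort")
  set.seed(config$seed)

  k_max <- length(config$embryos_per_cycle)
  n_per_cycle <- sample.int(k_max, config$n_cycles, replace = TRUE,
                            prob = config$embryos_per_cycle)
  n <- sum(n_per_cycle)
  cycle_id <- rep(sprintf("C%04d", seq_len(config$n_cycles)), n_per_cycle)
  embryo_id <- sprintf("E%05d", seq_len(n))

  euploid <- stats::runif(n) < config$p_euploid
  lb_potential <- stats::runif(n) < config$p_lb
  group <- ifelse(!euploid, "aneuploid",
                  if (config$stratify_euploid_by_lb)
                    ifelse(lb_potential, "euploid_LB", "euploid_noLB")
                  else "euploid")
  missing_cal <- setdiff(unique(group), names(calibrations))
  if (length(missing_cal) > 0)
    stop("missing calibration for group(s): ",
         paste(missing_cal, collapse = ", "))

  tm <- matrix(NA_real_, n, 4,
               dimnames = list(NULL, c("tSB", "tB", "tEB", "t_biopsy")))
  anc <- NULL
  for (g in unique(group)) {
    idx <- which(group == g)
    cal <- calibrations[[g]]
    tm[idx, ] <- .sample_timings(length(idx), cal)
    a <- .sample_anchors(length(idx), cal)
    if (is.null(anc)) anc <- matrix(NA_real_, n, ncol(a),
                                    dimnames = list(NULL, colnames(a)))
    anc[idx, ] <- a
  }

  tier <- assign_grade(euploid & lb_potential, config$grade_assoc)
  grade <- .gardner_letters(tier)

  # retrospective transfer records: euploids in embryologist priority order
  # (tier, then a latent priority draw), transferred one at a time until the
  # first live birth or drop-out
  transferred <- logical(n)
  transfer_order <- rep(NA_integer_, n)
  live_birth <- rep(NA, n)
  prio_noise <- stats::runif(n)
  dropout <- stats::runif(n)  # per-embryo continuation draw after a failure
  for (cid in unique(cycle_id)) {
    idx <- which(cycle_id == cid & euploid)
    if (length(idx) == 0L) next
    ord <- idx[order(-as.integer(tier[idx]), prio_noise[idx], idx)]
    k <- 0L
    for (i in ord) {
      k <- k + 1L
      transferred[i] <- TRUE
      transfer_order[i] <- k
      live_birth[i] <- lb_potential[i]
      if (live_birth[i]) break
      if (dropout[i] > 0.7) break  # couple discontinues after a failure
    }
  }

  embryos <- data.frame(embryo_id = embryo_id, cycle_id = cycle_id,
                        ploidy = ifelse(euploid, "euploid", "aneuploid"),
                        grade = grade,
                        grade_tier = as.character(tier),
                        tm, transferred = transferred,
                        transfer_order = transfer_order,
                        live_birth = live_birth,
                        anc, stringsAsFactors = FALSE)

  traj <- NULL
  if (trajectories) {
    metrics <- c("zp_A", "emb_A", "zp_T")
    pieces <- vector("list", n * length(metrics))
    jj <- 0L
    for (i in seq_len(n)) {
      tt <- c(tm[i, "tB"], tm[i, "tEB"], tm[i, "t_biopsy"])
      for (m in metrics) {
        ts <- sample_trajectory(anc[i, paste(m, c("tB", "tEB", "tbiopsy"),
                                             sep = "_")],
                                tt, config$frame_spacing_min, metric = m)
        jj <- jj + 1L
        pieces[[jj]] <- data.frame(embryo_id = embryo_id[i], metric = m,
                                   time_hpi = ts$times, value = ts$values,
                                   stringsAsFactors = FALSE)
      }
    }
    traj <- do.call(rbind, pieces)
    rownames(traj) <- NULL
  }

  structure(list(config = config, embryos = embryos, trajectories = traj),
            class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("cohort_set:", nrow(x$embryos), "embryos in",
      length(unique(x$embryos$cycle_id)), "cycles;",
      sum(x$embryos$ploidy == "euploid"), "euploid,",
      sum(x$embryos$transferred), "transferred\n")
  invisible(x)
}

#' Cycle filters for the two clinical ranking simulations
#'
#' `eligible_sim_one()` selects cycles with more than one biopsied blastocyst
#' containing both euploid and aneuploid embryos (euploidy-ranking
#' simulation). `eligible_sim_two()` selects cycles with at least two euploid
#' blastocysts of which at least one was transferred (transfer-priority
#' simulation). Both are reproducible from the embryo table alone.
#'
#' @param embryos Embryo table from a [sample_cohorts()] `cohort_set` (or any
#'   table with the same columns).
#' @return Character vector of eligible cycle ids.
#' @export
eligible_sim_one <- function(embryos) {
  sp <- split(embryos$ploidy, embryos$cycle_id)
  names(sp)[vapply(sp, function(p)
    length(p) >= 2 && any(p == "euploid") && any(p == "aneuploid"),
    logical(1))]
}

#' @rdname eligible_sim_one
#' @export
eligible_sim_two <- function(embryos) {
  sp <- split(embryos, embryos$cycle_id)
  names(sp)[vapply(sp, function(d) {
    eu <- d[d$ploidy == "euploid", , drop = FALSE]
    nrow(eu) >= 2 && any(eu$transferred)
  }, logical(1))]
}
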