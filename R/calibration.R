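#' Group calibration for the synthetic cohort generator
#'
#' A calibration describes one clinical group (euploid, aneuploid, or
#' transferred euploids split by live-birth outcome) by the means and SDs of
#' its blastulation timings and of its morphometric anchors at the three
#' expansion milestones: full blastulation (tB), expanding blastocyst (tEB)
#' and trophectoderm biopsy (t-biopsy).
#'
#' @param group Group label, one of `"euploid"`, `"aneuploid"`,
#'   `"euploid_LB"`, `"euploid_noLB"`.
#' @param timings Named list with elements `tSB`, `tB`, `tEB`, `t_biopsy`,
#'   each a numeric `c(mean, sd)` in hours post insemination (hpi).
#' @param anchors Named list with elements `zp_A`, `emb_A`, `zp_T`, `ICM_A`;
#'   each a 3 x 2 matrix (rows tB, tEB, t_biopsy; columns mean, sd). Areas in
#'   square micrometres, thickness in micrometres.
#' @param anchor_cor Within-embryo correlation of the standardized anchor
#'   deviations across the three milestones, in `[0, 1]`.
#' @param timing_cor Within-embryo correlation of timing deviations (a shared
#'   developmental "pace" factor), in `[0, 1]`.
#' @return An object of class `group_calibration`.
#' @export
group_calibration <- function(group, timings, anchors,
                              anchor_cor = 0.7, timing_cor = 0.6) {
  stopifnot(is.character(group), length(group) == 1L)
  need_t <- c("tSB", "tB", "tEB", "t_biopsy")
  if (!all(need_t %in% names(timings)))
    stop("timings must contain ", paste(need_t, collapse = ", "))
  tm <- vapply(timings, function(x) x[1], numeric(1))[need_t]
  ts <- vapply(timings, function(x) x[2], numeric(1))[need_t]
  if (any(ts < 0)) stop("timing SDs must be >= 0")
  if (is.unsorted(tm)) stop("mean timings must be ordered tSB <= tB <= tEB <= t_biopsy")
  need_m <- c("zp_A", "emb_A", "zp_T", "ICM_A")
  if (!all(need_m %in% names(anchors)))
    stop("anchors must contain ", paste(need_m, collapse = ", "))
  anchors <- lapply(anchors[need_m], function(a) {
    a <- as.matrix(a)
    stopifnot(nrow(a) == 3L, ncol(a) == 2L)
    dimnames(a) <- list(c("tB", "tEB", "t_biopsy"), c("mean", "sd"))
    if (any(a[, "sd"] < 0)) stop("anchor SDs must be >= 0")
    a
  })
  # areas must nest at every milestone: zona-inclusive >= embryo proper >= ICM
  for (ms in 1:3) {
    if (!(anchors$zp_A[ms, 1] >= anchors$emb_A[ms, 1] &&
          anchors$emb_A[ms, 1] >= anchors$ICM_A[ms, 1]))
      stop("anchor means must satisfy zp_A >= emb_A >= ICM_A at each milestone")
  }
  stopifnot(anchor_cor >= 0, anchor_cor <= 1, timing_cor >= 0, timing_cor <= 1)
  structure(list(group = group,
                 timing_mean = tm, timing_sd = ts,
                 anchors = anchors,
                 anchor_cor = anchor_cor, timing_cor = timing_cor),
            class = "group_calibration")
}

#' Calibration presets for the four clinical study groups
#'
#' Returns the generator calibrations reproducing the published group-wise
#' morphometric summary of 2184 biopsied blastocysts: aneuploid versus
#' euploid, and transferred euploids that did or did not result in a live
#' birth. Timings are in hpi; areas in square micrometres; zona thickness in
#' micrometres.
#'
#' @return Named list of [group_calibration()] objects with elements
#'   `aneuploid`, `euploid`, `euploid_noLB`, `euploid_LB`.
#' @export
#' @examples
#' cal <- calibration_presets()
#' cal$aneuploid$anchors$zp_T  # 16.4 -> 12.9 -> 8.1 um thinning
calibration_presets <- function() {
  a3 <- function(m1, s1, m2, s2, m3, s3)
    matrix(c(m1, m2, m3, s1, s2, s3), nrow = 3,
           dimnames = list(c("tB", "tEB", "t_biopsy"), c("mean", "sd")))
  list(
    aneuploid = group_calibration(
      "aneuploid",
      timings = list(tSB = c(102.5, 10.5), tB = c(113.0, 12.7),
                     tEB = c(120.9, 14.5), t_biopsy = c(136.0, 15.2)),
      anchors = list(
        zp_A  = a3(14288, 1257, 17435, 1828, 24082, 5763),
        emb_A = a3(13349, 1196, 16900, 1867, 23612, 5960),
        zp_T  = a3(16.4, 2.9, 12.9, 2.4, 8.1, 3.2),
        ICM_A = a3(3458, 905, 3497, 1047, 3804, 1471))),
    euploid = group_calibration(
      "euploid",
      timings = list(tSB = c(100.5, 9.6), tB = c(109.7, 11.1),
                     tEB = c(115.9, 12.0), t_biopsy = c(131.6, 13.7)),
      anchors = list(
        zp_A  = a3(14168, 1119, 17417, 1955, 25438, 5968),
        emb_A = a3(13249, 1121, 16922, 1986, 25058, 6212),
        zp_T  = a3(16.2, 2.9, 12.6, 2.5, 7.1, 2.7),
        ICM_A = a3(3414, 902, 3460, 1066, 3727, 1469))),
    euploid_noLB = group_calibration(
      "euploid_noLB",
      timings = list(tSB = c(100.3, 9.7), tB = c(109.9, 11.2),
                     tEB = c(116.7, 12.4), t_biopsy = c(132.4, 13.9)),
      anchors = list(
        zp_A  = a3(14124, 1071, 17482, 2234, 25141, 5873),
        emb_A = a3(13235, 1107, 16996, 2274, 24694, 6169),
        zp_T  = a3(16.5, 3.0, 12.9, 2.5, 7.3, 2.9),
        ICM_A = a3(3425, 953, 3414, 1078, 3800, 1547))),
    euploid_LB = group_calibration(
      "euploid_LB",
      timings = list(tSB = c(99.0, 9.8), tB = c(107.5, 10.9),
                     tEB = c(112.6, 11.2), t_biopsy = c(127.1, 12.5)),
      anchors = list(
        zp_A  = a3(14263, 1231, 17542, 1835, 25790, 6159),
        emb_A = a3(13309, 1121, 17030, 1757, 25512, 6299),
        zp_T  = a3(16.3, 3.1, 12.8, 2.5, 6.9, 2.5),
        ICM_A = a3(3434, 852, 3541, 1212, 3468, 984))))
}

#' Configuration for synthetic cohort generation
#'
#' @param n_cycles Number of PGT-A cycles (oocyte retrievals) to simulate.
#' @param embryos_per_cycle Probability vector for the number of biopsied
#'   blastocysts per cycle (`embryos_per_cycle[k]` is the probability of `k`
#'   embryos). The default averages ~2.8 embryos per cycle, matching a cohort
#'   of ~2184 blastocysts over 786 cycles.
#' @param p_euploid Probability that a blastocyst is euploid (default
#'   886/2184 = 0.4056, the study prevalence).
#' @param p_lb Live-birth probability for a transferred competent-draw
#'   euploid (default 233/548, the study LB rate per transfer).
#' @param grade_assoc Strength in `[0, 1]` of the association between latent
#'   competence (euploid and implantation-capable) and the Gardner grade tier
#'   assigned by the virtual embryologist. 0 = independent, 1 = competent
#'   embryos strictly dominate the tier order.
#' @param stratify_euploid_by_lb If `TRUE` (default), euploid embryos draw
#'   their trajectories from the `euploid_LB` / `euploid_noLB` calibrations
#'   according to latent competence; if `FALSE` all euploids use the pooled
#'   `euploid` calibration.
#' @param frame_spacing_min Spacing of the simulated time-lapse frame grid in
#'   minutes (default 10; the standardized assay later resamples at 30).
#' @param scale_um_per_px Spatial scale used when rendering masks.
#' @param side_px Mask frame side length in pixels, or `NA` to auto-size each
#'   frame to its outer contour.
#' @param seed Integer seed fixing every draw of the generator.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cycles,
                          embryos_per_cycle = c(0.20, 0.26, 0.23, 0.15, 0.10, 0.06),
                          p_euploid = 886 / 2184,
                          p_lb = 233 / 548,
                          grade_assoc = 0.5,
                          stratify_euploid_by_lb = TRUE,
                          frame_spacing_min = 10,
                          scale_um_per_px = 1,
                          side_px = NA_integer_,
                          seed = 1L) {
  if (n_cycles < 1) stop("empty cohort: n_cycles must be >= 1")
  embryos_per_cycle <- embryos_per_cycle / sum(embryos_per_cycle)
  stopifnot(all(embryos_per_cycle >= 0),
            p_euploid >= 0, p_euploid <= 1,
            p_lb >= 0, p_lb <= 1,
            grade_assoc >= 0, grade_assoc <= 1,
            frame_spacing_min > 0)
  structure(list(n_cycles = as.integer(n_cycles),
                 embryos_per_cycle = embryos_per_cycle,
                 p_euploid = p_euploid, p_lb = p_lb,
                 grade_assoc = grade_assoc,
                 stratify_euploid_by_lb = isTRUE(stratify_euploid_by_lb),
                 frame_spacing_min = frame_spacing_min,
                 scale_um_per_px = scale_um_per_px,
                 side_px = side_px,
                 seed = as.integer(seed)),
            class = "cohort_config")
}
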