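---
title: "Quantitative standardized expansion assay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative standardized expansion assay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qseamorph)
```

## The scientific problem

After the embryonic genome activates, a human blastocyst expands: fluid is
pumped into the blastocoel, the trophectoderm (TE) stretches, and the
surrounding zona pellucida (zp) — a glycoprotein shell — thins under the
hydrostatic pressure until the embryo can hatch. How fast and how
consistently this happens carries information about the embryo's
chromosomal constitution (euploidy) and its chance of producing a live
birth (LB) after transfer. `qseamorph` implements a quantitative,
operator-independent way to extract this information from labeled
time-lapse segmentation masks, and the simulation machinery needed to ask
whether ranking embryos by these measurements could compete with the
embryologist's Gardner-grade morphology assessment within a cohort.

## Morphometric features

Each time-lapse frame is reduced to a labeled mask at the median focal
plane (0 background, 1 zona, 2 embryo proper, 3 inner cell mass). From it
we compute, in micrometre units via the declared per-pixel scale:

* **zp-A** — area of the embryo *including* the zona: all non-background
  pixels times scale².
* **emb-A** — area of the embryo proper (everything enclosed by the inner
  zona surface: blastocoel, TE and ICM), labels 2 ∪ 3.
* **ICM-A** — inner-cell-mass area, label 3.
* **ICM/TE ratio** — `ICM_A / (emb_A − ICM_A)`. The TE denominator is
  taken in the same focal plane as the ICM numerator; nothing else is
  well-defined from a single-plane annotation.
* **zp-T** — zona thickness, defined as the *largest* distance between the
  embryo-proper edge and the outer zona edge.

### The thickness estimator

zp-T is a directed Hausdorff distance: for every point of the embryo edge,
take the distance to the nearest point of the outer contour, then take the
maximum over the embryo edge. For nested circles with inner radius
$R_{in}$, outer radius $R_{out}$ and inner-center offset $d$ this equals
$R_{out} - R_{in} + d$, which is the closed form the test suite checks
against on randomized eccentric annuli.

Two numerical choices matter. First, edges are localized at subpixel
precision as the midpoints of in/out 4-neighbour pixel pairs (the
half-level marching-squares contour); raw boundary *pixel centers* sit up
to a pixel inside their region and would bias distances. Second, the
maximum of a rasterization-jittered, nearly flat distance profile is
biased upward by the jitter's extreme value (about +0.3 px for typical
blastocyst geometries), so the profile is smoothed along the contour with
a circular moving average (default 15 edge points, about 7 px of arc
against a curvature sagitta below 0.01 px) before the maximum is taken.
The residual bias is below 0.05 µm at 1 µm/px. `smooth = 1` restores the
raw pointwise maximum, and a radial-ray variant (`method = "radial"`) is
available; both readings coincide for nested near-circular contours.

## The standardized expansion assay

Expansion is compared across embryos on a standardized clock: each metric
is sampled by linear interpolation every 30 minutes over the 5 hours
following full blastulation (tB), 11 samples including the tB frame
itself. Starting the grid at tB anchors every embryo at its own
blastulation state regardless of developmental pace, which is what makes
the assay cohort-comparable. Milestone values at tB, tEB (expanding
blastocyst) and t-biopsy, and percent changes between them
(`(v_to − v_from)/v_from × 100`), summarize each trajectory.

Group **expansion maps** aggregate two sets of assay series offset by
offset (mean, SD, n) and test the group difference at every offset with a
normality-gated two-group test: Shapiro–Wilk on each sample at α = 0.05,
Welch t-test if both pass, Mann–Whitney U otherwise (a mixed pair takes
the nonparametric path — the conservative choice, and Welch rather than a
pooled t-test for the same reason). Per-offset p-values are reported
unadjusted, matching the clinical presentation; because 11 correlated
tests are run, a Holm-adjusted column is also emitted. No correction is
applied for embryos clustered within cycles — the source analyses report
none — and the map metadata says so.

The *onset of divergence* is the earliest offset at which the difference
is significant **and stays significant at every later offset**. Under the
null, each offset has an α chance of an isolated significance, so a
pointwise "first p < α" definition would report spurious early onsets at a
rate near `1 − (1 − α)^k`; sustained significance is robust to this while
agreeing with the intended reading of "became significant from X minutes
on".

## Statistical utilities

* `fit_logistic()` — maximum-likelihood logistic regression (IRLS via
  `glm`), odds ratios with Wald 95% CIs; complete separation is detected
  and flagged non-converged.
* `roc_auc()` — AUC as the rank (Mann–Whitney concordance) statistic with
  midrank tie handling; CIs by a seeded percentile bootstrap (default
  2000 resamples) stratified by class. The default of 2000 resamples
  balances CI stability (~0.005 Monte-Carlo jitter) against runtime.
* `composite_score()` — linear predictor of a fitted model, the score
  input for covariate-adjusted AUCs. Morphology enters adjustments as the
  ordinal tier coded numerically (1–4); indicator coding changes nothing
  for the binary contrasts exercised here and is available by passing
  factor columns.

## The synthetic cohort generator

No clinical images or tables ship with the package; a calibrated generator
stands in for them so every stage is testable. `calibration_presets()`
encodes, for the four clinical groups (aneuploid, euploid, and transferred
euploids with/without LB), the published group means and SDs of the four
blastulation timings and of the four metric anchors at tB, tEB and
t-biopsy — e.g. aneuploid zp-T thins 16.4 ± 2.9 → 12.9 ± 2.4 → 8.1 ± 3.2
µm, euploid zp-A grows 14,168 → 17,417 → 25,438 µm².

Design choices, made once:

* **Timings** are drawn as correlated Gaussians sharing a per-embryo
  "pace" factor (correlation 0.6), rejection-resampled (max 100 attempts)
  until ordered tSB ≤ tB ≤ tEB ≤ t-biopsy with at least 5.5 h from tB to
  biopsy, since more than 5 h always elapse between blastulation and
  biopsy in the clinical workflow the assay presumes.
* **Anchors** are drawn with a configurable within-embryo correlation
  (default 0.7) across milestones. zp-A and emb-A share the same
  standardized deviations — the outer contour tracks the embryo it wraps —
  which keeps the thin annulus positive; the drawn emb-A is additionally
  clipped a hair below zp-A, and ICM-A below 0.9 emb-A (both clips move
  group means by ≪ 1 SE). Only zona thickness carries a monotonicity
  contract (non-increasing), enforced by rejection; its ~2% violation rate
  shifts the calibrated mean by ~0.05 µm. Area anchors are *not* forced
  into cross-milestone order: their t-biopsy marginals are wide (SD ≈
  6000 µm² against a 7000 µm² mean gap), so rejection would truncate them
  and shift group means by roughly 900 µm² — several standard errors —
  destroying calibration recovery. The rare non-monotone area trajectory
  is accepted instead.
* **Trajectories** interpolate the anchors exponentially (linear in log
  value) on a 10-minute frame grid that always contains the milestone
  times, so anchors are recovered exactly and percent change accumulates
  multiplicatively; the interpolant is positive and monotone between
  anchors. Before tB, metrics are held at their tB anchor (the assay never
  samples earlier). Spontaneous collapses are **not** simulated:
  generated trajectories are smooth, a documented limitation below.
* **Ploidy** is Bernoulli with the study prevalence 886/2184; latent LB
  competence is Bernoulli 233/548. Euploid embryos draw trajectories from
  the LB / no-LB calibrations according to competence (disable with
  `stratify_euploid_by_lb = FALSE` to use the pooled euploid preset).
* **Grades**: a virtual embryologist assigns Gardner tiers from a latent
  quality quantile mixing a uniform with a competence-separated uniform;
  the mixing weight is the association strength (0 = independent, 1 =
  competent embryos strictly dominate). The default 0.5 puts the virtual
  embryologist between chance and perfection, in line with clinical
  top-ranking accuracy. Marginal tier frequencies default to
  15/30/30/25% (low/average/good/excellent).
* **Transfers**: only euploids, single transfers in embryologist priority
  order (tier, then a latent preference), continuing after a failed
  transfer with probability 0.7 until a live birth or drop-out. The
  continuation probability is invented plumbing; it only shapes how many
  cycles have untransferred euploids.
* **Mask rendering**: each embryo-frame is two nested circles plus an ICM
  sector. The outer radius reproduces the drawn zp-A exactly. The drawn
  zp-T is realized by offsetting the inner circle
  (`d = zp_T − (R_out − R_in)`); when thickness and the area pair are
  geometrically incompatible — which the clinical calibration makes the
  rule, since the published mean annulus is ~1–2 µm against zp-T values of
  8–16 µm — the inner radius is shrunk to `R_out − (zp_T + margin)/2`, the
  largest inner circle that can still realize the thickness while keeping
  a minimum zona clearance (2 µm) everywhere. zp-A and zp-T therefore
  round-trip exactly; emb-A round-trips only when geometry permits. This
  mirrors the treatment of zp-T and the areas as separately calibrated
  observables rather than forcing a joint consistency the published
  summary statistics themselves do not have.

What the generator does *not* emulate: spontaneous collapse/re-expansion
cycles, hatching and herniation after zona breach, irregular (non-convex)
contours, multi-focal-plane structure, segmentation noise, and any
per-aneuploidy-class structure. Tests passing on generated data therefore
validate the measurement and analysis machinery, not the biological claims
on real images.

## Clinical ranking simulations

Two retrospective simulations ask what would have happened had the assay
ranked embryos instead of (or beside) the embryologist.

**Simulation 1 — euploidy ranking.** Eligible cycles have > 1 biopsied
blastocyst with both euploid and aneuploid embryos. The embryologist's top
set is every embryo at the maximal Gardner tier (ties allowed); the assay
ranking is a strict order — by default zp-T at tB + 300 min, thinner
first, ties broken by steeper thinning then id, so ties are effectively
impossible. Each cycle gets a concordance label (agree / disagree /
multi-top) and a six-way effectiveness label comparing the ploidy verdicts
(both right, both wrong, embryologist better, qSEA better, and qSEA
right/wrong against a mixed-ploidy tie). An all-euploid tie counts as an
embryologist "right": only ploidy-mixed top sets are "mixed".

**Simulation 2 — transfer priority.** Eligible cycles have ≥ 2 euploid
blastocysts, ≥ 1 transferred. The embryologist's pick is operationalized
as the historically first-transferred embryo (the retrospective reading;
grade ties make the grade-based set unusable here). The assay pick is
correct if it was transferred and produced a live birth (miscarriage
counts as no live birth), incorrect if transferred without one, and
`top_untransferred` when its top euploid has no transfer record — the
category that defines the "may improve up to" upper bound.

Percentages are reported as integers, rounded half away from zero,
matching the clinical presentation. The ranking score choice (final-offset
value; alternatives: thinning slope, percent change over the window) is
recorded in the output metadata.

`fixture_sim_one_concordance()`, `fixture_sim_one_effectiveness()` and
`fixture_sim_two()` construct synthetic cohorts whose category counts
equal the published ones, as an end-to-end arithmetic check of the
ranking, classification and aggregation paths. The concordance and
effectiveness surfaces are encoded by *separate* cohorts because the
published aggregate tallies are not jointly realizable by one embryo-level
dataset: the effectiveness split forces 104 + 26 + 66 = 196 qSEA euploid
tops, while the concordance analysis tallies 199.

```{r fixtures}
fx <- fixture_sim_one_effectiveness()
summarize_simulation(run_simulation(fx$embryos, fx$qsea, "sim1"))
```

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks have the power they claim while completing in minutes:
500 embryos per group for calibration-recovery checks (3-standard-error
acceptance bands), 20–25 random annulus specs for geometry oracles (areas
within 2% of πR², thickness within 2 px of the closed form), 2000
replicates for the type-I calibration of the gated test (acceptance band
0.039–0.061 at α = 0.05), 10 seeded replicates of the 150-minute
divergence scenario (n = 200 per group, ≥ 8 must localize the onset), and
5000 subjects for the null-AUC check (|AUC − 0.5| < 0.03). Anchor
recovery through trajectories is exact to 1e−9 relative; interpolation
reproduces affine series to the same tolerance.

## Known limitations

* Single focal plane only; no 3-D fusion, no multi-plane consistency.
* The generator's circular geometry cannot probe the thickness estimator
  on irregular or locally breached zonae (the estimator itself handles
  them; an enclosure warning is raised when the zona does not wrap the
  embryo).
* Per-offset tests ignore within-cycle clustering, faithfully to the
  source analysis; map metadata flags it.
* The effectiveness and concordance fixture surfaces cannot be unified
  (see above), so cross-surface identities should not be expected from
  fixture output.
* Between-milestone interpolation is smooth and monotone; collapse
  dynamics, and any metric before tB, are out of scope.
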