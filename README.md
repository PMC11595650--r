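# qseamorph

Quantitative analysis of blastocyst expansion dynamics from labeled
time-lapse segmentation masks, for embryologists and researchers studying
embryo selection in IVF/PGT-A settings.

As a blastocyst expands, fluid pressure stretches the trophectoderm and
thins the zona pellucida. `qseamorph` measures this process and asks
whether it can rank embryos. It provides:

* **Morphometry** — from a labeled mask at the median focal plane: the
  zona-inclusive area (zp-A, µm²), the embryo-proper area (emb-A), the
  inner-cell-mass area (ICM-A), the ICM/TE ratio
  `ICM_A / (emb_A − ICM_A)`, and the maximum zona thickness

  `zp-T = max over embryo-edge points of the distance to the nearest
  outer-zona-edge point`  (a directed Hausdorff distance; for nested
  circles with inner offset *d* it equals `R_out − R_in + d`).

* **The standardized expansion assay (qSEA)** — every metric resampled at
  tB + 0, 30, …, 300 min (11 samples over the 5 h following full
  blastulation), milestone values at tB/tEB/t-biopsy with percent changes,
  and group *expansion maps*: per-offset mean ± SD with a
  Shapiro–Wilk-gated Welch-t / Mann–Whitney test, Holm-adjusted column,
  and the earliest offset of sustained divergence.

* **Statistics** — logistic odds ratios with Wald CIs, composite risk
  scores, and rank-statistic ROC AUC with seeded stratified-bootstrap
  percentile CIs.

* **Clinical ranking simulations** — within-cohort comparisons of
  qSEA-based ranking against Gardner-grade morphology: euploidy ranking
  (agree/disagree/multi-top concordance plus a six-way effectiveness
  classification) and euploid transfer priority (correct / incorrect /
  top-not-yet-transferred, with the "may improve up to" upper bound).

* **A calibrated synthetic generator** — cohorts, timings, metric
  trajectories, Gardner grades, transfer records and rendered labeled
  masks, calibrated to the published group-wise summary statistics of
  2184 biopsied blastocysts, so the whole pipeline is testable without
  clinical data.

## Worked example

```r
library(qseamorph)

# a synthetic cohort of 300 PGT-A cycles, fully seeded
cs <- sample_cohorts(cohort_config(n_cycles = 300, seed = 7))
cs
#> cohort_set: 884 embryos in 300 cycles; 370 euploid, 262 transferred

# standardized zona-thickness assay and the euploid/aneuploid expansion map
qs <- cohort_qsea(cs, metric = "zp_T")
eu <- cs$embryos$embryo_id[cs$embryos$ploidy == "euploid"]
map <- build_expansion_map(qs[qs$embryo_id %in% eu, ],
                           qs[!qs$embryo_id %in% eu, ],
                           labels = c("euploid", "aneuploid"))
round(map[c(1, 6, 11), c("offset_min", "mean_a", "mean_b", "p")], 3)
#>    offset_min mean_a mean_b     p
#> 1           0 16.431 16.435 0.984
#> 6         150 14.734 14.950 0.275
#> 11        300 13.634 14.015 0.064
```

Euploid blastocysts (group *a*) thin faster: by tB + 300 min their mean
zona is 0.38 µm thinner than the aneuploid mean. At 300 cycles this
difference does not reach per-offset significance — the calibrated group
separation is subtle and the source finding rests on a much larger cohort;
`qsea_divergence_scenario()` generates groups with a configured onset when
a detectable effect is needed.

```r
# euploidy-ranking simulation on the same cohort
s1 <- summarize_simulation(run_simulation(cs$embryos, qs, "sim1"))
s1
#> Simulation 1 (euploidy ranking) - 182 eligible cycles
#>   concordance :
#>     agree                    28 (15%)
#>     disagree                 64 (35%)
#>     embryologist_multi_top   90 (49%)
#>   ...
#>   equally effective: 54 (30%); equal or better: 107 (59%)
```

In 59% of eligible synthetic cycles the zona-thickness ranking is at least
as effective as the virtual embryologist at putting a euploid embryo on
top (the published clinical figure is 69%; the synthetic cohort's
grade–competence association and group separation are configurable, not
fitted).

```r
# single-frame morphometry on a rendered mask
m <- render_mask(frame_spec(R_out = 80, R_in = 60, d = 10, icm_frac = 0.2),
                 scale = 1)
measure_frame(m)
#>   time  zp_A emb_A    zp_T ICM_A ICM_TE_ratio
#> 1   NA 20081 11289 29.8461  2290    0.2544727
```

`zp_A ≈ π·80² = 20106`, `zp_T ≈ 80 − 60 + 10 = 30`: the estimators track
the analytic geometry to sub-percent / sub-pixel accuracy.

A thin CLI ships in `inst/cli/qsea-morph`
(`qsea-morph simulate --out run1 --seed 7`), wrapping `run_pipeline()`,
which writes versioned CSV/JSON outputs and a manifest with per-file
content hashes.

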