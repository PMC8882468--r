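# grscreen

Growth-rate-corrected scoring and statistics for 3D organoid drug
screens, with companion in vivo and clinical-benefit analyses and fully
seeded synthetic-data generators.

## The problem

Endpoint viability screens on patient-derived organoids (PDxOs) read a
luminescence signal once, after ~96 h of drug exposure. Organoid lines
double anywhere between 3 and 8 days, so in that window a fast line
grows several-fold while a slow line barely doubles -- and traditional
endpoint metrics (IC50, GI50, EC50) silently mix growth rate into
apparent potency, making slow-growing lines look drug-resistant. Anyone
comparing drug sensitivity *across* patient-derived models (for drug
repurposing, subtype pharmacology, or functional precision oncology)
needs metrics that remove this confound.

`grscreen` implements the growth-rate (GR) correction for plate-based
organoid screens. With `T` the treated endpoint reading, `T0` the day-0
seeding-control reading and `C` the vehicle (DMSO) endpoint reading,

    GR(c) = 2^( log2(T/T0) / log2(C/T0) ) − 1

is the ratio of treated to untreated growth rate at dose `c`: 1 means
uninhibited growth, 0 cytostasis, −1 complete kill. Sigmoid fits on the
GR scale yield **GR50** (dose where GR crosses 0.5), **GEC50**,
**GR_inf**, the **cytostatic dose** (GR = 0), and **GR_aoc** -- the
normalized area over the GR curve, which is defined for *every* curve,
including non-responders where all the threshold metrics go missing.
Traditional EC50/IC50/GI50 are computed alongside for comparison.

On top of the scoring engine sit the cross-screen statistics used in
organoid-pharmacology studies: model and drug ranking, hierarchical
clustering of the GR_aoc matrix, exact Mann-Whitney / Hodges-Lehmann
group comparisons (subtype and drug-class effects), GR50-GI50
concordance with fast/slow-grower residual analysis, replicate
reproducibility, Loewe-additivity synergy matrices for two-drug
combinations, tumor-volume AUC / growth-rate / log-rank recurrence
statistics for xenograft validation, Spearman organoid-to-xenograft
concordance, and PFS/TTNT clinical benefit ratios against the 1.3
precision-oncology benchmark.

Everything is driven by tibbles and returns tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Two simulated lines with *identical* true drug response
(GR_inf = −0.8, GEC50 = 0.1 µM, Hill 1.5) but doubling times of 3 vs 8
days, screened with the default design (8-point half-log dilution,
4 technical × 3 biological replicates, 16 day-0 wells, 96 h exposure)
at default noise:

```r
library(grscreen)
lines <- tibble::tibble(model_id = c("ORG-fast", "ORG-slow"),
                        doubling_days = c(3, 8), subtype = "TNBC")
truth <- tibble::tibble(model_id = lines$model_id, drug_id = "drugA",
                        inert = FALSE, gr_inf = -0.8,
                        gec50_uM = 0.1, hill = 1.5)
sim <- simulate_screen(lines, truth, screen_config(), seed = 7)
score_screen(sim)
```

```
  model_id drug_id   GR50  GEC50 GR_inf GR_aoc cytostatic_uM   IC50   GI50
1 ORG-fast   drugA 0.0517 0.0998 -0.811   1.03         0.115 0.0867 0.0487
2 ORG-slow   drugA 0.0523 0.1008 -0.803   1.03         0.117 0.2920 0.0561
```

The GR-scale metrics agree across the two lines (GR50 0.0517 vs
0.0523 µM; GR_aoc 1.03 for both) and recover the simulated truth, while
the endpoint IC50 differs 3.4-fold (0.087 vs 0.292 µM) purely because
the slow line grows less in 96 h -- the artifact the GR correction
exists to remove.

The clinical-benefit calculator reproduces the case-study arithmetic
directly from therapy durations:

```r
clinical_benefit_ratio(list(pfs_days = 138, ttnt_days = 197),
                       list(pfs_days = 41,  ttnt_days = 41))
#>   pfs_ratio ttnt_ratio benchmark meets_benchmark
#> 1       3.4        4.8       1.3            TRUE
```

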