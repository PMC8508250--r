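# edrisk

Preoperative risk modeling of **early distant recurrence** (EDR, distant
metastatic relapse within 12 months of surgery) after upfront
pancreaticoduodenectomy for resectable pancreatic adenocarcinoma.

Roughly 40% of patients judged technically resectable relapse at distance
within a year of a Whipple-type resection, which argues for neoadjuvant
chemotherapy rather than upfront surgery in a subgroup that anatomy alone
cannot identify. `edrisk` implements, as a tested and reusable R pipeline,
a preoperative modeling strategy for that problem:

1. **CT radiomics** — isotropic resampling (1 mm, tri-linear), 64-bin
   fixed-bin-number intensity discretization, and a fixed catalogue of
   167 IBSI-style features in ten families: mesh-based morphology
   (including the surface-to-volume ratio A/V, minimized by a sphere at
   3/r), first-order statistics, intensity histogram, grey-level
   co-occurrence (13-direction 3D, averaged and merged), run length
   (averaged and merged), size zone, neighbourhood grey-tone difference,
   and distance zone matrices.
2. **Three-stage variable selection** — an ICC(2,1) delineation-robustness
   screen across readers' contours (features with ICC < 0.80 are dropped),
   a |Spearman| > 0.70 redundancy filter keeping one representative per
   correlated cluster (best univariate-logistic p), and a 1000-resample
   bootstrap ranking that keeps variables with p < 0.05 in more than half
   of the resamples.
3. **A compact prognostic model** — backward multivariable logistic
   regression (retention at p < 0.20, at most three variables), yielding a
   per-patient prognostic index

   P = 1 / (1 + exp(−(B₀ + Σᵢ Bᵢ Xᵢ)))

   dichotomized at the Youden-optimal cutoff of the training ROC curve.
4. **Survival evaluation** — Kaplan–Meier curves of the high- vs low-risk
   groups, the log-rank test, and the Cox hazard ratio of the dichotomized
   index, with the cutoff frozen before it ever sees validation data.

Because no patient cohort ships with the package, a first-class synthetic
module generates voxelized tumor phantoms (spheres, ellipsoids, lobulated
solids with optional hypodense necrotic core, controllable noise),
multi-reader contour variants, and simulated cohorts whose EDR outcomes are
drawn from a logistic model with known coefficients — so every stage is
testable end to end against analytic and brute-force oracles.

## Worked example

```r
library(edrisk)

# one synthetic tumor, extracted through the full radiomics workflow
ph  <- make_phantom(phantom_spec(shape_kind = "lobulated", radius_mm = 12,
                                 lobulation_amplitude = 0.2,
                                 necrotic_core = TRUE, noise_sd = 4, seed = 7))
row <- extract_all(ph$volume, ph$mask, id = "pt001")
row[, c("case", "morph.surf_to_vol_ratio", "morph.sphericity", "ih.entropy")]
#> 1 pt001                   0.269            0.929       4.29

# a simulated cohort with the published combined-model coefficients as truth
feats  <- tibble::tibble(morph.surf_to_vol_ratio = runif(300, 0.2, 0.5))
cohort <- simulate_cohort(cohort_sim_spec(n_patients = 300, seed = 42),
                          feature_values = feats)
model  <- fit_backward_logistic(cohort, outcome = "edr",
                                candidates = c("ca199_u_ml", "necrosis",
                                               "morph.surf_to_vol_ratio"))
model  <- calibrate_cutoff(model, cohort, "edr")
model
#> <edr_logistic> 3 variable(s), n = 300, training AUC = 0.688
#>                      term coefficient       se   p_value      or or_low or_high
#> 1             (Intercept)    0.018751 0.534451 9.720e-01 1.01893 0.3575  2.9045
#> 2              ca199_u_ml    0.002188 0.001049 3.702e-02 1.00219 1.0001  1.0043
#> 3                necrosis    1.408005 0.312124 6.451e-06 4.08779 2.2172  7.5365
#> 4 morph.surf_to_vol_ratio   -3.738597 1.523729 1.414e-02 0.02379 0.0012  0.4714
#> risk cutoff (Youden): 0.3166

risk  <- classify_risk(model, cohort)
strat <- evaluate_stratification(dplyr::bind_cols(cohort, risk))
strat
#> <edr_stratification> n = 300
#> log-rank chi-sq = 18.372, p = 1.82e-05
#> HR (high vs low) = 1.724 [1.34, 2.218]
#>   S(12m | high) = 0.454
#>   S(12m | low) = 0.807
```

Read: all three planted predictors are recovered with the expected signs
(a *low* surface-to-volume ratio — a compact, rounded tumor — raises EDR
risk, as do necrosis and higher CA19.9), and the dichotomized index
separates the 12-month recurrence-free fractions (45% vs 81%).
`autoplot()` methods draw the KM curves, ROC curve, bootstrap ranking and
ICC report; `tidy()`/`glance()` return broom-style tables.

`run_pipeline(edr_config(...))` chains everything — phantom population,
extraction, robustness screen, cohort simulation, stratified split,
selection cascade, model fit, frozen-cutoff evaluation — deterministically
from one seed, and writes a run directory with the feature table, cohort,
model JSON, metrics and a JSON-lines log.

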