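---
title: "Methods: radiomic prognostic modeling of early distant recurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic prognostic modeling of early distant recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrisk)
```

## The modeling problem

Early distant recurrence (EDR) — distant metastatic relapse within 12
months of an upfront pancreaticoduodenectomy — marks patients whose
"technically resectable" tumors were biologically unresectable, and who
would plausibly have been better served by neoadjuvant chemotherapy.
`edrisk` implements a fully preoperative modeling strategy for this
endpoint: quantitative CT features of the delineated tumor, one serum
marker (CA19.9, U/mL, continuous), and one radiological reading (necrosis,
binary) feed a heavily regularized selection cascade and a deliberately
small logistic model whose probability-scale output (the prognostic index)
is dichotomized into high- and low-risk groups.

The package ships no patient data. Instead a synthetic module generates
the study conditions — voxelized tumor phantoms, emulated multi-reader
contours, and cohorts with known generative coefficients — so that every
stage can be validated against analytic and brute-force oracles. What such
validation does and does not establish about real CT data is discussed at
the end.

## Image preprocessing

Extraction runs in a fixed order: resample, then discretize, then compute
features.

* **Resampling** (`resample_isotropic()`): tri-linear interpolation onto
  cubic voxels, 1 mm by default. The corresponding 2D term ("bilinear") is
  sometimes used loosely for this step; in 3D, with cubic target voxels,
  tri-linear interpolation is the only consistent reading. The mask is
  interpolated with the same kernel and re-thresholded at 0.5. Output grid
  centers are aligned with the input grid center; mask volume is preserved
  to within about 3% for lesions at least ten voxels across, which the
  test suite asserts.
* **Discretization** (`discretize()`): fixed-bin-number rebinning, 64 bins
  over the in-mask min–max range. Bin labels are invariant to any constant
  intensity shift of the region; a constant region maps to bin 1. No
  resegmentation or outlier windowing is applied before binning; the
  extraction provenance records this.

## The feature catalogue

`extract_all()` produces a fixed catalogue of 167 features in ten families
(`feature_catalogue()` enumerates them): morphology (16), first-order
statistics (17), intensity histogram (19), co-occurrence matrix features
in averaged and merged 3D aggregations (23 each), run-length features in
both aggregations (16 each), size-zone (16), neighbourhood grey-tone
difference (5), and distance-zone (16) features. Texture matrices use
distance-1 symmetric co-occurrence over the 13 unique 3D directions,
26-connected zones, and city-block distance to the region border (border
voxels at distance 1). "Averaged" computes a feature per direction and
averages; "merged" sums the directional matrices first. Degenerate inputs
take documented limits rather than NaN: a constant region has joint
entropy 0, correlation 1, a single full-size zone, and coarseness capped
at 10^6.

### Mesh morphology and a numerical choice

Surface area and volume come from a closed triangulated mesh of the mask.
The mesh is built by marching tetrahedra (each grid cell split into the
six tetrahedra sharing its main diagonal) over a *lightly smoothed* copy
of the binary mask (Gaussian, σ = 0.7 voxels), with linear interpolation
of the 0.5 iso-crossings. The smoothing is essential: meshing the raw
binary field quantizes facet orientations and overestimates the area of a
digitized sphere by ~27%, while the smoothed mesh is within ~3% for both a
sphere (A/V = 3/r) and a cube (A/V = 6/a). The width trades staircase
inflation on curved surfaces (dominant at small σ) against rounding of
genuinely sharp edges (dominant at large σ); σ = 0.7 voxels keeps both
analytic references within a few percent, and the tetrahedral
decomposition avoids any precomputed triangulation table. Mesh volume is
the divergence-theorem sum over the same oriented surface, so area and
volume refer to one consistent surface.

## The selection cascade

1. **Robustness screen** (`icc_screen()`): two-way random-effects,
   absolute-agreement, single-rater ICC — ICC(2,1) — per feature across
   readers' contours of the same cases; features below 0.80 are excluded.
   This form charges systematic reader offsets to disagreement, which is
   the conservative choice for contour robustness. Zero between-case
   variance makes the ICC undefined; such features are excluded with a
   recorded reason. Clinical and radiological variables bypass this stage:
   it applies only to contour-derived features.
2. **Redundancy filter** (`redundancy_filter()`): connected components of
   the |Spearman| > 0.70 graph; each cluster keeps the member with the
   best univariate-logistic p against the outcome (ties: smaller p, then
   name). The absolute value is deliberate — anti-correlated duplicates
   carry the same information. The filter runs over the pooled candidate
   set (robust radiomic features plus clinical variables), and constant
   columns are excluded with a reason since rank correlation is undefined
   for them.
3. **Bootstrap ranking** (`bootstrap_rank()`): B = 1000 resamples with
   replacement; in each, every candidate is tested in its own univariate
   logistic regression, scoring a hit at p < 0.05; variables with hits in
   more than B/2 resamples are selected. Resamples with a single outcome
   class are redrawn (and counted); separated fits fall back to a
   Firth-type penalized likelihood with a penalized likelihood-ratio p.
   Ranking ties break by smaller median p, then name.

### What the bootstrap hit count actually measures

For a null covariate the hit count is *not* Binomial(B, α). Conditional
on the observed data, the resampled z-statistic fluctuates around the
dataset's realized z, so the per-resample hit probability is approximately
Φ(z−1.96) + Φ(−z−1.96); averaging over z ~ N(0,1) gives ≈ 0.166, and the
count is Binomial(B, π(data)) with π highly variable between datasets.
Simulation (40 independent null datasets, n = 150) reproduces this: mean
hit fraction 0.16, SD 0.14, with occasional datasets where a pure-noise
variable clears the B/2 majority. The majority-vote rule is therefore the
load-bearing part of the procedure — it requires the dataset's own
evidence (roughly |z| > 2.6), not just resampling noise — but users should
know that the ranking's raw frequencies are inflated relative to α and
that the procedure has a real, if small, false-positive mode. The test
suite asserts the derived 0.166 expectation, not the naive α.

## The prognostic model

`fit_backward_logistic()` removes the worst-p variable until all Wald
p-values are below 0.20, then continues until at most three variables
remain — the events-per-variable cap of a cohort with ~25 training events.
Covariates are standardized internally for numerical stability (feature
scales span nine orders of magnitude) and estimates are mapped back, which
leaves slope p-values unchanged. If nothing survives, an intercept-only
model is returned with a warning; with several null candidates this is
expected roughly half the time at p_retain = 0.20, not rarely — the
retention threshold is deliberately permissive. Overall fit is the
likelihood-ratio test against the intercept-only model. Separation falls
back to the in-package Firth-type fit.

The prognostic index is the exact logistic transform
P = 1/(1 + exp(−(B₀ + Σ Bᵢ Xᵢ))); missing model variables raise an error
rather than being imputed. `youden_cutoff()` scans midpoints between
consecutive distinct scores (plus ±∞), maximizes sensitivity +
specificity − 1, and breaks ties toward higher specificity — the
clinically conservative direction, since the high-risk label routes
patients away from upfront surgery. AUC is the rank-based concordance
statistic with ties counted 1/2.

## Survival evaluation

Risk groups use the cutoff frozen on the training cohort. Kaplan–Meier
estimation, the log-rank test and the Cox hazard ratio of the binary
indicator (Efron tie handling, Wald intervals) come from the `survival`
package behind the module's interface; 12-month survival is read from the
KM curve with the right-continuous convention. If one group has no events
the Cox likelihood is monotone and a ridge-penalized fit is used, flagged
in the result.

## The synthetic study conditions

* **Phantoms**: spheres, ellipsoids, and lobulated solids whose radius is
  modulated by three low-order trigonometric surface modes with total
  amplitude `lobulation_amplitude`; intensity 80 inside, 30 in a
  concentric necrotic core scaled to the requested volume fraction, 0
  outside, plus Gaussian noise. The values are arbitrary CT-like units,
  fixed so histogram features are predictable.
* **Reader variants**: reader 1 keeps the contour; others cycle through
  dilation, erosion and random boundary jitter, realized by thresholding
  a Gaussian-smoothed mask so the boundary moves about `perturb_mm` along
  its normal. Zero perturbation returns exact copies; perturbations that
  erase the mask raise an error.
* **Cohorts**: CA19.9 is log-normal (meanlog 3.7, sdlog 1.3; median
  ≈ 40 U/mL, matching published cohort tables — the published evidence
  gives only medians and IQRs, so log-normality is this package's
  assumption, not an established fact); necrosis prevalence 0.18. EDR is
  Bernoulli with logistic probability; the default coefficients are the
  published combined-model values and the intercept is calibrated by
  Monte Carlo so the marginal EDR rate hits 26.5%. Event times are
  exponential conditional on the EDR label — truncated below 12 months
  (mean 6) for EDR, shifted past 12 months and truncated at the follow-up
  maximum otherwise — since the generative literature gives no
  survival-time mechanism.
* **Seeds**: one master seed expands into labeled 31-bit child seeds
  (`edrisk:::child_seed`), so each stage has an independent reproducible
  stream and identical configurations are bit-identical.

The demo pipeline (`edr_config()`) plants its radiomic signal with a
surface-to-volume coefficient of −18 per mm⁻¹ — about 1.5 log-odds per
population SD of the phantom cohort — rather than the published −2.9: at
demo cohort sizes (tens of patients) the published effect size is
undetectable by any method, and an end-to-end demonstration needs a signal
the cascade can plausibly find. Reader perturbation defaults to 0.5 mm
(sub-voxel disagreement between experienced readers on a conspicuous
late-arterial lesion), and per-case noise SD is drawn from U(2, 7) to give
the phantom population the between-patient texture heterogeneity a real
cohort has.

## What the phantom studies do not show

The phantoms have a sharp tumor/background edge (background 0), so
boundary-sensitive intensity and texture features are *less* contour-robust
here than on real contrast CT, where lesion-to-background contrast is a
few tens of HU: in the demo, morphology passes the ICC screen broadly
while most texture families fail, and the screen's overall pass rate
(~13%) is below what is reported for real pancreatic cohorts (~49%). The
phantoms also contain no acquisition physics — no beam hardening, partial
volume beyond the voxelization itself, or scanner-dependent noise
texture — so passing tests demonstrate correctness of the computations and
of the statistical machinery, not clinical transportability of any
particular feature. Validation-side metrics from the demo pipeline
(AUC, HR) are computed on a few dozen simulated patients and are
accordingly unstable; they are outputs to inspect, not benchmarks.

## Problem sizes

The test suite and acceptance script keep simulations at sizes chosen for
tight Monte-Carlo behavior at interactive runtimes: brute-force texture
oracles on ROIs up to 5×5×5 with ≤ 4 grey levels; ICC calibration at 29
cases × 3 readers × 200 replicates; bootstrap calibration at n = 150 with
B up to 1000; coefficient-recovery coverage at n = 1000 × 200 replicates;
Cox recovery at 100–1000 subjects per arm; and end-to-end pipeline runs of
30–60 synthetic patients with B = 60–200. The package itself has no such
limits; `edr_config()` scales all of them.
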