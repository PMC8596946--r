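---
title: "Normative difference-map scoring and task PLS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative difference-map scoring and task PLS: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Longitudinal imaging studies of sport concussion compare each injured
athlete's scalar brain parameter maps — cerebral blood flow (CBF, ml/100
g/min), fractional anisotropy (FA) and mean diffusivity (MD, mm²/s) — against
uninjured controls, at acute injury (ACU), medical clearance to return to
play (RTP), and one year later (YR1). Raw male–female or athlete–control
differences mix baseline physiology (sex, age, concussion history) with the
injury response. `normpls` implements a normative-scoring pipeline that
isolates the injury response and quantifies how it evolves over sessions,
together with everything needed to validate the machinery on synthetic
cohorts with planted ground truth.

## Model and procedure

**Difference scoring.** For each concussed athlete $s$, all controls of the
same sex and history-of-concussion (HOC) status within ≤ 2 years of age are
matched (inclusive bound on fractional ages — `match_criteria()`). At every
in-mask voxel, a robust control mean $m_s$ is computed with the Huber
location M-estimator (tuning $k = 1.35$, scale $1.4826\,\mathrm{MAD}$,
IRLS from the median), and the athlete's maps become difference scores
$\Delta x_s = x_s - m_s$. The same matched subgroup is reused for all of the
athlete's sessions, so longitudinal change is referenced to a fixed
normative baseline. The M-estimator scale is not stated in the approach this
follows; $1.4826\,\mathrm{MAD}$ is the standard companion, consistent at the
normal.

**Task PLS.** Two 3 × V summary matrices per modality: (a) the session means
of $\Delta x_s$, and (b) the session-wise point-biserial correlations of
$\Delta x_s$ with sex (0 = male, 1 = female). Each is decomposed by an
*uncentered* SVD — no row or column centering, the task-PLS convention for
condition summaries, so the component reflects overall deviation from zero
rather than deviation from the grand mean. The first component's voxel
salience, session saliences and covariance fraction
$100\, s_1^2 / \sum_i s_i^2$ are reported. The two analyses are separate
SVDs, not one stacked six-row problem, because main-effect and sex-effect
components are reported with separate covariance percentages. Sign
convention: the largest-magnitude session salience is made positive; this is
arbitrary but fixed, and bootstrap replicates are sign-aligned to the point
estimate by the inner product of voxel saliences.

**Bootstrap inference.** Athletes are resampled with replacement, each
athlete's ACU/RTP/YR1 maps moving as one unit (repeated-measures bootstrap,
1,000 iterations by default). Bootstrap ratios are bootstrap mean divided by
bootstrap SE, referred to the standard normal for p-values. A salience with
zero bootstrap variance is reported as a signed-infinity sentinel with
p = 0 and counted in `n_degenerate`.

**Missing sessions.** The point estimate omits missing entries from the
summary-matrix cost (a session mean or correlation is taken over the
athletes who have that session). Inside the bootstrap, each replicate's
subject × (session, voxel) matrix is completed by SOFT-IMPUTE — iterated
soft-thresholded SVD, $Z \leftarrow \mathrm{SVT}_\lambda(P_{obs}(X) +
P_{miss}(Z))$ — so that resampled athletes contribute whole triplets. The
threshold $\lambda$ minimizes the held-out MSE over a 15-point logarithmic
grid, estimated from 200 random holdouts of 5% of the observed entries.
A fresh completion per replicate realizes the multiple-imputation idea: the
imputation uncertainty enters through the resampling. $\lambda$ is fixed at
the cross-validated value across replicates (re-selection per replicate is
possible but adds nothing at these sizes and is much slower).

**Cluster-extent correction.** Voxelwise |BSR| is thresholded two-sided at
p = .005; surviving voxels form clusters under faces-only (6-neighbor)
connectivity by default. Map smoothness is estimated from athlete-level
residual maps (session means removed) with the first-neighbor variance-ratio
estimator $\mathrm{FWHM} = \Delta x \sqrt{-2\ln 2 / \ln(1 -
s^2_{diff}/2s^2)}$ per axis. Monte-Carlo simulation of smooth unit-variance
Gaussian null fields in the same mask (2,000 fields by default) yields the
minimum cluster size whose familywise null probability is below α = .05.
Cluster tables report |BSR|-weighted centres of mass in mm, volumes in mm³,
and peak signed BSR.

**ROI statistics.** Averaging $\Delta x$ over the significant voxels gives
per-session effect estimates for all, male, and female athletes, with
bootstrap percentile 95% CIs, BSRs, normal p-values, and Benjamini–Hochberg
FDR flags across the three sessions of each block; the female−male contrast
is pooled over the sessions flagged significant in the sex-effect analysis
(all three when none are flagged).

**Clinical battery.** SCAT symptom tables (22 items, 0–6) are scored into
totals and somatic/cognitive/sleep/mood domain sums (9 + 6 + 3 + 4 items).
Elevation at ACU and RTP relative to baseline uses one-sided paired Wilcoxon
tests; male–female comparisons use two-sample Wilcoxon tests; both use
mid-ranks with tie-corrected normal variance, switching to the exact null
distribution for untied samples with n ≤ 25. FDR is controlled at 0.05.
Attrition is checked by Spearman correlations of retention indicators
against demographics and clinical scores.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `huber_k` | 1.35 | Huber tuning; ≈95% efficiency at the normal |
| `max_age_gap` | 2 | years, inclusive, control matching |
| `n_boot` | 1000 | bootstrap iterations |
| `voxel_p` | 0.005 | two-sided voxel threshold |
| `cluster_alpha` | 0.05 | cluster-level familywise rate |
| `n_sim` | 2000 | null fields for the cluster threshold |
| `cv_n_iter`, `cv_holdout` | 200, 0.05 | SOFT-IMPUTE cross-validation |
| `impute_max_rank` | 10 | rank cap for the completion |
| `fdr_q` | 0.05 | FDR level (sessions, clinical tests) |
| `connectivity` | 6 | cluster neighborhood (6/18/26) |

The rank cap deserves a note: a subject × (session, voxel) matrix of ~61
rows cannot support more than a handful of stable components, and capping
the soft-thresholded SVD at rank 10 leaves the CV-selected solutions
untouched while keeping the completion well-posed and fast. The soft_impute
convergence criterion is the squared relative Frobenius change of the fit
(the reference algorithm's criterion); the CV and bootstrap loops use a
looser tolerance (1e-3) than final fits (1e-5) because holdout ordering and
replicate statistics are insensitive at that scale.

## What the synthetic cohorts emulate — and what they do not

`sim_config()` defaults describe the cohort the pipeline targets: 167
controls and 61 concussed athletes on a 24 × 28 × 24 grid of 3 mm voxels
with a ~950-voxel ellipsoidal analysis mask; session dropout
8/61, 10/61, 29/61 (missing completely at random, matching the finding that
attrition was unrelated to demographics); spatially smooth Gaussian noise
(6 mm FWHM — the scale real maps are smoothed to); additive sex, age and
HOC baseline offsets; subject-level random intercepts (1 noise-SD); a
session-varying concussion main effect in one compact region; and a
session-varying sex-by-concussion effect in a second, disjoint region. Ages
are integer truncated normal (mean 20.3, SD 2, range 17–28); sex and HOC
are Bernoulli(0.5). The sex effect is planted with its sign tied to the sex
code (+a for females, −a for males) in the concussed group only, so the
female−male contrast equals `2a` while the concussed group mean is
unshifted in expectation; controls carry only the baseline sex offset,
mirroring the control-referenced design of the difference scores.
`truth_report()` returns the `2a` contrast so recovery checks always score
against the realized generative truth.

Not emulated: biophysical forward models for CBF/FA/MD, scanner artifacts,
registration error, non-Gaussian or spatially varying noise, informative
attrition. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under the stated generative model, not
that any particular real-data finding is reproduced — the underlying MRI
data are not public, so printed effect sizes from real cohorts are not
reproduction targets.

## Numerical choices and degenerate inputs

* Smooth fields use circular convolution with an L2-normalized separable
  kernel — stationary with exactly unit marginal variance, so the
  Monte-Carlo cluster null needs no empirical renormalization.
* Zero-variance voxels in the sex-correlation maps get correlation 0 (and
  are counted); a zero-MAD voxel in the Huber estimator returns the median.
* A bootstrap resample with fewer than two distinct athletes (or, for the
  sex analysis, fewer than two of either sex) is redrawn and logged.
* FWHM estimation returns 0 with a warning for maps rougher than white
  noise or with zero variance; the cluster threshold is well-defined at
  FWHM 0.
* The minimum cluster size is the (1−α) order statistic of per-field
  maximum null cluster sizes, plus one voxel.
* Athletes with no imaging session at all (possible under dropout) are
  dropped from scoring with a warning.
* Ties in Wilcoxon tests use mid-ranks with variance correction; zero
  differences are dropped; exact p-values are used only for untied samples.

## Open design points, resolved

* **"200 iterations" in the imputation CV** is read as 200 cross-validation
  repeats (it parenthesizes the holdout statement); both the repeat count
  and the sweep cap are exposed.
* **Matrix orientation** for completion is subjects × (session-concatenated
  voxels); the per-voxel 61 × 3 orientation is available for the small ROI
  matrices, where it is the natural shape.
* **Multivariate QC screen**: the published supplementary description is
  not available in the source text; the implemented screen (principal
  components of the control set at 90% variance, median/MAD-standardized
  scores, chi-square flags with Bonferroni correction) is the package's own
  specified, testable stand-in, and is configurable.
* **Cluster connectivity and sidedness** are unstated upstream; defaults
  are faces-only and two-sided, both exposed.
* **Manual ventricle / brain-stem edits** cannot be reproduced
  algorithmically; masks accept an optional user-supplied exclusion volume.

## Problem sizes used in the test-suite and validation runs

The packaged validation suite exercises: oracle equivalences at n = 5–50
(Huber), 3 × 200 (PLS), 200 × 30 (SOFT-IMPUTE, signal-to-noise amplitude
ratio 20); null calibration on 50 voxel-level cohorts (30 athletes,
~2,000-voxel mask, 100 bootstrap iterations) and 200 cluster-level cohorts
(reduced to a ~500-voxel mask; cluster thresholds from 500 null fields,
memoized on the rounded smoothness estimate); effect recovery on 20 cohorts
at the standard cohort sizes and contrast coverage on 100 cohorts at
30/31 athletes per sex; and a full default-configuration run executed twice
to confirm byte-identical reproducibility. These sizes were chosen as the
smallest at which the binomial tolerances of the calibration checks are
meaningful. The null-calibration checks are expected to expose — not
hide — the first-component BSR anticonservatism described under known
limitations.

## Known limitations

* **First-component salience BSRs are anticonservative under the null.**
  The reported component is *selected* to maximize covariance, which scales
  its saliences (and hence their bootstrap ratios) by roughly
  $\sqrt{3\,\mathrm{pct}_1/100}$ relative to a fixed direction; worse, any
  athlete-constant structure in the difference maps — subject-level
  intercepts, or the shared error of the finite matched-control reference —
  forms a genuine rank-one pattern across the three session rows that the
  uncentered first component locks onto even when no effect is planted.
  Plain per-voxel z-scores of the session means are calibrated under the
  same simulations, so this is a property of component-1 inference itself,
  not of the scoring or resampling machinery. Cluster-extent correction
  inherits the inflation because its Monte-Carlo null assumes unit-variance
  fields. In practice this means voxel/cluster findings from the PLS
  analyses should be read as pattern descriptions with approximate error
  control, and effects near threshold deserve skepticism. The packaged
  null-calibration checks in the test suite document this behavior rather
  than hide it.
* **The athlete-only bootstrap understates reference uncertainty.** The
  resampling unit is the athlete's session triplet; variability of the
  matched-control robust means is invisible to it, so ROI confidence
  intervals are modestly anticonservative at realistic control:athlete
  ratios.
* Cluster-level calibration uses the classic Gaussian-autocorrelation null;
  heavy-tailed spatial correlation in real data would make it anticonservative
  (the modern ACF-based null is out of scope).
* The normal reference for BSRs is an approximation; with 61 athletes it is
  adequate, but small cohorts should interpret |BSR| thresholds cautiously.
* MCAR imputation is assumed; informative dropout would bias session
  contrasts.
* The pipeline assumes maps are pre-aligned to a common template; no
  registration is performed.
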