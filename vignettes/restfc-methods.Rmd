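---
title: "Methods: seed-based resting-state connectivity and its link to behavior"
author: "restfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based resting-state connectivity and its link to behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

`restfc` implements a seed-based resting-state functional-connectivity
analysis and its behavioral correlation layer, of the kind used to ask
whether the coupling between two language-network nodes (e.g. left anterior
inferior frontal gyrus, aIFG, and posterior middle temporal gyrus, pMTG) at
rest predicts performance in a semantic task, and whether an intervention
(e.g. inhibitory theta-burst stimulation) changes that brain-behavior
association. The pipeline starts from spatially normalized BOLD runs and
runs entirely on synthetic data with known ground truth, so every stage is
testable without any subject data:

1. **Denoising.** Nuisance variance is removed from the voxel time series
   by multiple regression; the series are then band-pass filtered and
   finally motion-scrubbed.
2. **Connectivity.** Spherical grey-matter ROIs are summarized by their
   first eigenvariate; functional connectivity is the Fisher-transformed
   Pearson correlation between ROI series (ROI-to-ROI) or between an ROI
   series and every brain voxel (seed maps), the latter summarized by a
   hemispheric laterality index.
3. **Behavior.** Trial-level lexical-decision reaction times are cleaned
   (incorrect trials, then a 2 SD outlier cut) and normalized per subject
   by the expected-condition mean, isolating semantic-control cost from
   general speed.
4. **Inference.** Across-subject correlations between connectivity and
   normalized RTs (t-based p, Lilliefors normality gate, Bonferroni
   control), repeated-measures ANOVA with Greenhouse-Geisser correction,
   signed-rank tests for error rates, and a permutation test for condition
   differences in correlation strength.

# Denoising model and its parameters

The nuisance design contains, per frame: the 6 rigid-body motion
parameters and their first temporal derivatives (backward differences with
a leading zero row), each entered linearly and squared — 24 columns — plus
the mean white-matter and CSF signals (linear only) and an intercept, 27
columns in total. Grey-matter signal is never included, to avoid biasing
grey-matter correlations. Compartment means are taken over voxels with
tissue probability strictly above 0.75; that cut is standard for white
matter, and CSF uses the same default with a separate argument
(`csfProb`) because no separate convention is established. The phrase
"first and second order terms" admits a narrower reading in which only the
derivatives are squared; `buildNuisanceDesign(expansion = "derivsq")`
provides that 21-column variant, but the 24-column expansion is the
default as the standard Friston-style set.

Filtering is a zero-phase (forward-backward) Butterworth band-pass, order
2 per pass, passband 0.01-0.08 Hz (`bandpassFilter`). The contract is
stated in frequency-response terms — a 0.05 Hz tone keeps at least 90% of
its amplitude, a 0.2 Hz tone keeps at most 10% — rather than in terms of
the filter family. Channels are demeaned before filtering and residual
edge-transient means are removed, so constants map to zero exactly.

Scrubbing uses framewise displacement defined as the **maximum
frame-to-frame displacement of any point within a 50 mm sphere** centered
at the isocenter. Writing the rigid transform difference as `A p + b`,
the objective `|A p + b|` is convex, so its maximum over the ball sits on
the sphere surface; `framewiseDisplacement` solves the resulting secular
equation in the eigenbasis of `A'A` exactly (with the trust-region "hard
case" handled), rather than sampling points. The common
sum-of-absolute-values variant is available as `mode = "power"` but is not
the default, because the max-over-sphere definition is the one the
pipeline is built around. Frames with FD strictly above 0.5 mm are
discarded (a frame exactly at threshold is kept), and a run fails quality
control when the surviving frames cover less than 300 s — with the default
180-frame, TR 2 s acquisition (6 minutes), that is the "less than 5
minutes" exclusion rule.

Stage order is fixed: drop the first 4 frames (field saturation), regress,
filter, then censor. Scrubbing-before-filtering is a defensible
alternative, but filter-then-scrub is the order the narrative of such
pipelines describes and is what `denoiseRun` enforces; censoring after
zero-phase filtering also avoids re-introducing spectral leakage through
gaps.

# Connectivity conventions

ROI spheres (default radius 7 mm) include every voxel whose center lies
within the radius (inclusive) and inside the grey-matter mask; the
center-in-sphere rule is grid-independent and deterministic, and is
documented because other toolkits' inclusion conventions differ. The ROI
signal is the first eigenvariate: the first left singular vector of the
column-demeaned frames-by-voxels matrix, scaled by its singular value, with
the sign fixed so the summed correlation with the voxel series is positive;
a one-voxel ROI reduces to the demeaned voxel series.

Correlations are clipped to ±(1 − 1e−12) before `atanh`, so degenerate
identical series produce a finite, flagged record instead of infinity.
Seed maps treat the seed's own voxels as ordinary voxels; zero-variance
voxels get z = 0 and are counted in a QC field.

The laterality index is `LI = (LH − RH)/(LH + RH)` over suprathreshold
voxel counts, with voxelwise p from the two-tailed t of the underlying
correlation (`t = r√df/√(1−r²)`), threshold p < .001. Three conventions
had to be fixed where none is universal: hemispheres are assigned by the
sign of the mm x-coordinate under the affine (not the voxel index), the
midline column x = 0 is excluded, and only positively correlated voxels
are counted by default (positive-connectivity renderings; a
`positiveOnly = FALSE` switch enables two-sided counting). An LI with no
suprathreshold voxels is reported as missing, never as 0.

# Behavioral cleaning

Incorrect or unanswered trials are removed first; then, within each
subject-session-condition cell, correct trials with RT strictly greater
than the cell mean plus 2 SD are removed in a **single pass** — the cutoff
is not recomputed after removal, since iterative trimming changes results
and is not part of the procedure being modeled. The outlier scope is the
cell by default (the common convention when condition means are the unit
of analysis); `outlierScope = "session"` pools conditions. Error rates are
computed on the raw table — a cell's error denominator is everything
presented, so cleaning never flatters accuracy. Normalized RTs divide each
non-expected condition mean by the same subject-session's expected mean,
which cancels multiplicative subject speed exactly (a tested invariant).

# Inference layer

* `correlationPValue(r, n)` uses the exact t relation
  `t = r√(n−2)/√(1−r²)` on n−2 df, two-tailed; Spearman's rho uses the
  same approximation on ranks (adequate in the n≈18 regime this targets).
* The Lilliefors normality test estimates mean and SD from the sample and
  therefore cannot use the plain Kolmogorov-Smirnov null; the p-value
  comes from a seeded Monte-Carlo null (default 100,000 standard-normal
  samples of the same size). A correlation family in which any variable
  fails the gate at α = .05 is analyzed with Spearman instead of Pearson.
* Bonferroni control multiplies p by the family size m and caps at 1. For
  the connectivity-behavior family the default m is 6 (3 ROI pairs × 2
  normalized-RT measures) — the only family size consistent with an
  adjusted-significant p = .005 next to an adjusted-non-significant
  p = .010 — and is configurable.
* The permutation test for a condition difference in correlation strength
  uses the statistic `Δ = atanh(r₁) − atanh(r₂)` and builds the null by
  independently swapping each subject's condition pair with probability
  ½ — the literal reading of "random assignment of condition to individual
  data"; a constrained half/half relabeling would be an alternative but is
  not what that description says. The Monte-Carlo p uses add-one smoothing
  `(1 + #{|Δ*| ≥ |Δ|})/(nperm + 1)`, avoiding p = 0; when 2ⁿ ≤ nperm the
  test switches to exhaustive enumeration of all 2ⁿ assignments and
  reports the exact unsmoothed proportion. Degenerate permuted samples
  (zero variance) contribute Δ* = 0 and are counted in QC.
* The repeated-measures ANOVA is computed from orthonormal within-subject
  contrasts; per effect, Mauchly's W (with the second-order chi-square
  correction term) gates the Greenhouse-Geisser epsilon
  `tr(S)²/(q·tr(S²))` at p < .05. Huynh-Feldt is deliberately not
  implemented. Two-level factors have ε = 1 by construction; an effect
  whose between-condition variation vanishes entirely reports F = 0,
  p = 1 rather than 0/0. The F statistics are cross-checked against
  `aov()` and the ε/Mauchly values against `car::Anova` in the test suite.
* The Wilcoxon signed-rank test drops zero differences, uses an exact
  null for up to 25 non-zero differences — computed by convolution over
  (doubled) ranks, so tied ranks are handled exactly — and the
  continuity-corrected normal approximation beyond that.

# The synthetic-data generators

**Phantom** (`makePhantom`): a 20×24×20 grid of 3 mm voxels with
concentric ellipsoidal tissue compartments (WM core, GM shell carrying the
ROIs, CSF rim), 180 frames at TR 2 s. ROI signals are sums of cosines at
the Fourier frequencies inside 0.01-0.08 Hz with uniform random phases —
so the analysis band-pass is near-transparent to signal and filter effects
can be tested in isolation. The signal set is demeaned, orthonormalized
and mixed with the Cholesky factor of the target correlation matrix, which
plants the ROI correlation structure **exactly** in the sample; recovery
error downstream therefore measures the pipeline, not the draw. Every
voxel adds AR(1) noise (default marginal SD 1, coefficient 0.3 — i.e.
voxel-level SNR 1, a realistic resting-state regime); WM and CSF carry
their own shared AR(1) signals (gain 1) which also leak, attenuated by 0.3,
into grey matter — this leak is what nuisance regression is there to
remove. Motion is a low-amplitude random-walk drift (0.02 mm per frame;
rotational drift scaled to comparable surface displacement on a 50 mm
sphere) with optional planted spikes whose frame-to-frame jump equals the
requested magnitude exactly.

What the phantom does **not** emulate: hemodynamic convolution,
scanner drift and spike artifacts beyond AR(1), spatial autocorrelation of
noise, susceptibility dropout, or any physiological effect of stimulation.
Passing recovery tests therefore shows the pipeline's algebra and
calibration are right under idealized signal structure, not that real
acquisitions meet these assumptions.

**Cohort** (`makeCohort`): trial-level RTs per subject, session and
condition, `rt = speed_s · (μ_cond + ε)` with a log-normal subject speed
factor (sdlog 0.08) and within-cell noise (SD 90 ms); condition means
default to 850/910/960/1020 ms (expected < unexpected < anomalous <
pseudoword, the monotone ordering such tasks produce), 52/52/52/104 trials
per session, Bernoulli errors at 1.7%. Per session, ROI-pair Fisher-z
values are drawn with mean 0.5 and SD 0.2; the coupled pair's z is drawn
conditionally on the standardized realized normalized-RT measure,
`z = μ_z + σ_z(ρ·s + √(1−ρ²)·ε)`, which has population correlation exactly
ρ with the measure and leaves the RT marginals untouched (RTs are
generated first and never modified). A rank-based Gaussian copula was
considered for this coupling and rejected: the rank-to-normal-score step
attenuates the realized Pearson correlation measurably at n = 18, whereas
the conditional-Gaussian construction leaves only the unavoidable
small-sample Pearson bias (E[r̂] ≈ ρ(1 − (1−ρ²)/2n), about −0.62 realized
for ρ = −0.63 at n = 18). Default per-session couplings are −0.63 (sham),
−0.17 (aIFG stimulation) and −0.42 (pMTG stimulation).

# Reproducibility and problem sizes

All randomness flows from explicit integer seeds; a pipeline seed fans out
to per-stage, per-subject child seeds through a deterministic string hash
(`childSeed`), so stages own independent streams and identical configs
yield byte-identical result bundles (a tested invariant, including NIfTI
and TSV checksums).

The test suite validates calibration at the study's native sizes: planted
behavioral couplings are checked over 1,000 cohorts of 18 subjects;
permutation-test size over 1,000 null cohorts with 999 draws each; imaging
recovery over 200 default phantoms (with |E[ẑ] − z_true| < 0.05 as the
recovery envelope — the residual bias, about −0.03 at worst, comes from
eigenvariate noise attenuation plus the projection of band-limited signal
onto the 27-column nuisance span); the FD solver against 10,000-point
dense sphere sampling. The bundled demo pipeline uses a reduced 14×16×14
grid with two ROIs purely to keep the worked example quick; all analysis
defaults are unchanged there.

# Known limitations

* The semantic-control ROI coordinates of the motivating literature are
  not published as printed triplets; `dmnRoiSpecs()` ships the four
  default-mode-network nodes that are, and the phantom's aIFG/aMTG/pMTG
  labels are desk-scale synthetic stand-ins, not anatomical coordinates.
  Real-data use requires user-supplied ROI peaks.
* Group-level voxelwise GLM inference (random-field cluster statistics,
  conjunction analysis) is out of scope; seed maps and laterality indices
  are computed per subject only.
* Spatial preprocessing (realignment, segmentation, normalization,
  smoothing) is assumed done upstream; the phantom is born in common
  space.
* The Lilliefors Monte-Carlo null and the permutation test are seeded
  simulations; their p-values carry Monte-Carlo error of order
  1/√nsim.
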