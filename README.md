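# restfc

Seed-based resting-state functional connectivity and its link to behavior,
as a tested, reproducible R pipeline.

## What problem this addresses

In resting-state fMRI, slow (0.01–0.08 Hz) BOLD fluctuations that are
temporally similar between brain regions are taken as evidence of
functional connectivity. A recurring study design in the language domain
asks whether the resting coupling between fronto-temporal nodes — e.g.
left anterior inferior frontal gyrus (aIFG) and posterior middle temporal
gyrus (pMTG) — predicts performance in a semantic task across subjects,
and whether an intervention (such as inhibitory theta-burst stimulation)
weakens that brain–behavior association. `restfc` implements the full
analysis for that design, for methodologists and students who want every
stage explicit, testable, and runnable without any subject data:

* **Denoising** — nuisance regression with the 27-column motion expansion
  (6 parameters + 6 derivatives, each linear and squared, plus WM and CSF
  means and an intercept), zero-phase Butterworth band-pass (0.01–0.08 Hz),
  and motion scrubbing by framewise displacement (FD), where FD is the
  *exact* maximum frame-to-frame displacement of any point in a 50 mm
  sphere (solved analytically, not sampled). Frames with FD > 0.5 mm are
  censored; runs with under 5 minutes of surviving data are excluded.
* **Connectivity** — 7 mm spherical grey-matter ROIs summarized by their
  first eigenvariate; ROI-to-ROI and seed-to-voxel Fisher-z
  (`z = atanh(r)`) connectivity; hemispheric laterality index
  `LI = (LH − RH)/(LH + RH)` over suprathreshold (p < .001) voxel counts.
* **Behavior** — lexical-decision reaction-time cleaning (incorrect trials,
  then a single-pass mean + 2 SD outlier cut per cell) and normalized RTs
  (condition mean ÷ expected-condition mean).
* **Inference** — correlation tests with the exact t relation
  `t = r√(n−2)/√(1−r²)`, a Monte-Carlo Lilliefors normality gate that
  switches families to Spearman, Bonferroni control, repeated-measures
  ANOVA with Mauchly-gated Greenhouse-Geisser correction, exact signed-rank
  tests, and a permutation test for condition differences in correlation
  strength, `Δ = atanh(r₁) − atanh(r₂)`, with per-subject condition swaps
  (exhaustive enumeration when 2ⁿ is small enough).
* **Synthetic data** — seeded BOLD phantoms (planted band-limited ROI
  signals with exact sample correlations, AR(1) noise, WM/CSF nuisance,
  motion spikes) and behavioral cohorts with a configurable true
  connectivity–behavior correlation, so every claim above is tested
  against known ground truth.

## Worked example

Simulate a 6-minute phantom run, denoise it, and compute ROI-to-ROI
connectivity:

```r
library(restfc)

cfg <- phantomConfig(seed = 7)       # 180 frames @ TR 2 s, 3 mm voxels
ph  <- makePhantom(cfg)
ph$run
#> BoldRun: 20 x 24 x 20 voxels, 180 frames, TR 2 s (6.0 min)

gm    <- ph$tissue@gm > 0.5
masks <- lapply(cfg@roiSpecs, roiMask, gmMask = gm,
                affine = spatialAffine(ph$run))
vox   <- sort(unique(unlist(masks)))
den   <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = vox)
rois  <- lapply(seq_along(masks), function(j)
    roiTimeseries(den$clean, vox, masks[[j]], roiLabel(cfg@roiSpecs[[j]])))
fcMatrix(rois)
#>   roi_a roi_b         r         z clamped
#> 1  aIFG  aMTG 0.4336948 0.4644385   FALSE
#> 2  aIFG  pMTG 0.5661994 0.6419111   FALSE
#> 3  aMTG  pMTG 0.1611284 0.1625450   FALSE
```

The recovered correlations sit near the planted values (0.45, 0.60, 0.30):
one 180-frame run estimates each pairwise `r` with a sampling SD of about
0.06, and averaged over 200 seeds the pipeline's bias in `z` stays below
0.05 (a tested invariant). The analytic correlation test reproduces
published-table arithmetic exactly:

```r
round(correlationPValue(-0.63, 18), 3)
#> 0.005
```

A complete simulate → preprocess → connect → behavior → stats run is one
call, driven by a YAML config (see `inst/extdata/demo-config.yaml`):

```r
bundle <- runPipeline(system.file("extdata", "demo-config.yaml",
                                  package = "restfc"))
writeResultsBundle(bundle, "demo-results")
```

or from a shell via the thin wrapper
`inst/scripts/restfc-pipeline.R --config run.yaml --out results/`.
The bundle contains the connectivity and behavior tables, the stats report
(correlations with Bonferroni adjustment, permutation tests), a QC report
naming every excluded subject-session and its triggering rule, and
provenance (seed, config hash, package version). Identical config + seed
reproduces every output file byte for byte.

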