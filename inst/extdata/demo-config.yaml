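# Demonstration pipeline run: 6 simulated subjects, 3 sessions, 2 ROIs.
# Phantom geometry is scaled down from the defaults; acquisition length
# (180 frames at TR 2 s = 6 min) and all analysis thresholds keep the
# study defaults.
seed: 1
subjects: 6
sessions: [sham, aifg, pmtg]
imaging: true
rois:
  - {label: roi_l, center: [-13.5, 7.5, 0], radius: 7}
  - {label: roi_r, center: [13.5, -7.5, 0], radius: 7}
phantom:
  gridShape: [14, 16, 14]
  roiR: 0.5
cohort:
  nSubjects: 6
stats:
  n_perm: 2000
  bonferroni_m: 2
  lilliefors_sims: 500
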