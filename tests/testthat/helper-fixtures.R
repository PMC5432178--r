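# Shared fixtures: desk-scale phantom configurations and independent
# oracles used across test files.

# Small phantom: 12x14x12 grid, 160 frames (320 s, clears the 5-minute
# rule), two ROIs in opposite hemispheres of the GM shell.
smallRois <- function(radius = 5)
    list(roiSpec("L", c(-10.5, 6, 0), radius),
         roiSpec("R", c(10.5, -6, 0), radius))

smallPhantomConfig <- function(seed, r = 0.5, ...) {
    args <- list(nFrames = 160L, gridShape = c(12L, 14L, 12L),
                 roiSpecs = smallRois(),
                 roiCovariance = matrix(c(1, r, r, 1), 2, 2),
                 seed = seed)
    override <- list(...)
    args[names(override)] <- override
    do.call(phantomConfig, args)
}

# Full small-phantom recovery: phantom -> denoise -> filter -> scrub ->
# eigenvariate -> Fisher z, returning the z of every ROI pair.
recoverPhantomZ <- function(config, ...) {
    ph <- makePhantom(config)
    gmMask <- ph$tissue@gm > 0.5
    masks <- lapply(config@roiSpecs, roiMask, gmMask = gmMask,
                    affine = spatialAffine(ph$run))
    voxels <- sort(unique(unlist(masks)))
    den <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = voxels, ...)
    rts <- lapply(seq_along(masks), function(j)
        roiTimeseries(den$clean, voxels, masks[[j]],
                      roiLabel(config@roiSpecs[[j]])))
    fcMatrix(rts)
}

# Independent FD oracle: dense Fibonacci-lattice sampling of the sphere
# surface, displacing each point by the two frames' rigid transforms.
fdDenseOracle <- function(prev, cur, radius = 50, npts = 10000) {
    i <- seq_len(npts) - 0.5
    phi <- acos(1 - 2 * i / npts)
    theta <- pi * (1 + sqrt(5)) * i
    pts <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                          cos(phi))
    tp <- rigidMotionTransform(prev)
    tc <- rigidMotionTransform(cur)
    dp <- pts %*% t(tc$R - tp$R)
    dp <- sweep(dp, 2L, tc$t - tp$t, "+")
    max(sqrt(rowSums(dp^2)))
}

# Tiny trial-table builder for behavior tests.
makeTrials <- function(rts, condition = "expected", subject = "S01",
                       session = "sham", correct = TRUE) {
    n <- length(rts)
    data.frame(subject = subject, session = session, trial = seq_len(n),
               condition = condition, rt_ms = rts,
               correct = rep_len(correct, n), stringsAsFactors = FALSE)
}

fullTrialSet <- function(subject = "S01", session = "sham",
                         means = c(expected = 600, unexpected = 660,
                                   anomalous = 700, pseudoword = 750)) {
    do.call(rbind, lapply(names(means), function(cond)
        makeTrials(rep(means[[cond]], 8), cond, subject, session)))
}
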