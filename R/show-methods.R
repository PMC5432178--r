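#' @include AllClasses.R
NULL

setMethod("show", "BoldRun", function(object) {
    d <- dim(object@data)
    cat(sprintf("BoldRun: %d x %d x %d voxels, %d frames, TR %.3g s (%.1f min)\n",
                d[1], d[2], d[3], d[4], object@tr, d[4] * object@tr / 60))
})

setMethod("show", "TissueMaps", function(object) {
    d <- dim(object@gm)
    cat(sprintf("TissueMaps: %d x %d x %d grid; mean p(GM)=%.2f p(WM)=%.2f p(CSF)=%.2f\n",
                d[1], d[2], d[3], mean(object@gm), mean(object@wm),
                mean(object@csf)))
})

setMethod("show", "MotionTrace", function(object) {
    cat(sprintf("MotionTrace: %d frames; max |translation| %.3g mm, max |rotation| %.3g rad\n",
                nrow(object@params), max(abs(object@params[, 1:3])),
                max(abs(object@params[, 4:6]))))
})

setMethod("show", "CleanSeries", function(object) {
    cat(sprintf("CleanSeries: %d kept frames x %d channels, TR %.3g s\n",
                nrow(object@series), ncol(object@series), object@tr))
})

setMethod("show", "RoiSpec", function(object) {
    cat(sprintf("RoiSpec '%s': center (%g, %g, %g) mm, radius %g mm\n",
                object@label, object@center[1], object@center[2],
                object@center[3], object@radius))
})

setMethod("show", "RoiTimeseries", function(object) {
    cat(sprintf("RoiTimeseries '%s': %d frames, first eigenvariate of %d voxels\n",
                object@label, length(object@eig), object@nVoxels))
})

setMethod("show", "SeedMapStats", function(object) {
    cat(sprintf("SeedMapStats '%s': %s grid; LI = %s (LH %d, RH %d suprathreshold voxels)\n",
                object@seedLabel, paste(dim(object@zmap), collapse = " x "),
                ifelse(is.na(object@li), "NA", sprintf("%.3f", object@li)),
                object@lhCount, object@rhCount))
})

setMethod("show", "PhantomConfig", function(object) {
    cat(sprintf("PhantomConfig: %d frames @ TR %g s, grid %s @ %g mm, %d ROIs, noise SD %g (AR1 %g), seed %d\n",
                object@nFrames, object@tr,
                paste(object@gridShape, collapse = "x"), object@voxelSize,
                length(object@roiSpecs), object@noiseSd, object@ar1Coef,
                object@seed))
})

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf("CohortConfig: %d subjects x sessions {%s}, %d trials/session, seed %d\n",
                object@nSubjects, paste(object@sessions, collapse = ", "),
                sum(object@trialCounts), object@seed))
    r <- object@behaviorConnectivityR
    if (length(r))
        cat("  target behavior-connectivity r:",
            paste(sprintf("%s=%.2f", names(r), r), collapse = ", "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:\n")
    if (nrow(object@trueRoiCorrelations))
        cat(sprintf("  planted ROI correlations (%d x %d)\n",
                    nrow(object@trueRoiCorrelations),
                    ncol(object@trueRoiCorrelations)))
    r <- object@trueBehaviorEffect
    if (length(r) && any(!is.na(r)))
        cat("  behavior effect:",
            paste(sprintf("%s=%.2f", names(r), r), collapse = ", "), "\n")
    if (length(object@spikeFrames))
        cat("  motion spikes at frames:",
            paste(object@spikeFrames, collapse = ", "), "\n")
})

setMethod("show", "StatResult", function(object) {
    cat(sprintf("%s: estimate = %.4g, statistic = %.4g, df = %.4g, n = %g\n",
                object@method, object@estimate, object@statistic, object@df,
                object@n))
    cat(sprintf("  p = %.4g%s\n", object@p,
                if (!is.na(object@adjustedP))
                    sprintf(" (adjusted p = %.4g, m = %g)", object@adjustedP,
                            object@mTests) else ""))
})
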