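#' @import methods
NULL

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' BoldRun: a 4D BOLD acquisition in a common space
#'
#' Container for a single resting-state run: a 4D signal array (x, y, z,
#' frame) together with the voxel-to-mm affine and the repetition time.
#' Spatial preprocessing (realignment, normalization, smoothing) is assumed
#' to have happened upstream; synthetic phantoms are born in common space.
#'
#' @slot data 4D numeric array, dimensions (x, y, z, frame), arbitrary units.
#' @slot affine 4x4 voxel-to-mm map (RAS convention; 0-based voxel indices).
#' @slot tr repetition time in seconds.
#' @export
setClass("BoldRun",
    representation(data = "array", affine = "matrix", tr = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@data)) != 4L)
            msg <- c(msg, "data must be a 4D array (x, y, z, frame)")
        else if (dim(object@data)[4] < 2L)
            msg <- c(msg, "a run needs at least 2 frames")
        if (!identical(dim(object@affine), c(4L, 4L)))
            msg <- c(msg, "affine must be a 4x4 matrix")
        else if (abs(det(object@affine)) < 1e-12)
            msg <- c(msg, "affine must be invertible")
        if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
            msg <- c(msg, "tr must be a single positive number (seconds)")
        if (is.null(msg)) TRUE else msg
    })

#' TissueMaps: grey-matter / white-matter / CSF probability volumes
#'
#' @slot gm,wm,csf 3D probability volumes in [0, 1], on the same grid.
#' @slot affine 4x4 voxel-to-mm map shared with the paired [BoldRun-class].
#' @export
setClass("TissueMaps",
    representation(gm = "array", wm = "array", csf = "array",
                   affine = "matrix"),
    validity = function(object) {
        msg <- NULL
        dims <- list(dim(object@gm), dim(object@wm), dim(object@csf))
        if (!all(vapply(dims, length, 1L) == 3L))
            msg <- c(msg, "tissue maps must be 3D arrays")
        else if (!all(vapply(dims, identical, TRUE, y = dims[[1]])))
            msg <- c(msg, "gm, wm and csf must share one grid")
        for (tis in c("gm", "wm", "csf")) {
            v <- slot(object, tis)
            if (any(v < -1e-9 | v > 1 + 1e-9))
                msg <- c(msg, sprintf("%s probabilities must lie in [0, 1]", tis))
        }
        if (is.null(msg)) TRUE else msg
    })

#' MotionTrace: per-frame rigid-body realignment parameters
#'
#' One row per frame; columns tx, ty, tz (mm) and rx, ry, rz (radians).
#' The rigid transform of frame t maps a point p (mm, relative to the
#' isocenter) to `R(rx, ry, rz) %*% p + c(tx, ty, tz)` with
#' `R = Rz %*% Ry %*% Rx` (see [rigidMotionTransform()]).
#'
#' @slot params numeric matrix, frames x 6.
#' @export
setClass("MotionTrace",
    representation(params = "matrix"),
    validity = function(object) {
        msg <- NULL
        if (ncol(object@params) != 6L)
            msg <- c(msg, "params must have 6 columns (tx ty tz rx ry rz)")
        if (nrow(object@params) < 1L)
            msg <- c(msg, "params must have at least one frame")
        if (!is.numeric(object@params) || any(!is.finite(object@params)))
            msg <- c(msg, "params must be finite numeric")
        if (is.null(msg)) TRUE else msg
    })

#' CleanSeries: denoised, filtered, frame-censored time series
#'
#' Rows are surviving frames (after motion scrubbing), columns are channels
#' (voxels or tissue compartments). `keptFrames` indexes the surviving
#' frames in the series that entered censoring (1-based).
#'
#' @slot series numeric matrix, |keptFrames| x channels.
#' @slot keptFrames strictly increasing integer vector of surviving frames.
#' @slot tr repetition time in seconds.
#' @export
setClass("CleanSeries",
    representation(series = "matrix", keptFrames = "integer", tr = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@series) != length(object@keptFrames))
            msg <- c(msg, "series must have one row per kept frame")
        k <- object@keptFrames
        if (length(k) && (any(k < 1L) || any(diff(k) <= 0L)))
            msg <- c(msg, "keptFrames must be strictly increasing positive indices")
        if (length(object@tr) != 1L || object@tr <= 0)
            msg <- c(msg, "tr must be a single positive number")
        if (is.null(msg)) TRUE else msg
    })

## ---------------------------------------------------------------------------
## ROI machinery
## ---------------------------------------------------------------------------

#' RoiSpec: a spherical region of interest
#'
#' @slot label ROI name.
#' @slot center MNI-style mm coordinates (x, y, z).
#' @slot radius sphere radius in mm (default 7).
#' @export
setClass("RoiSpec",
    representation(label = "character", center = "numeric", radius = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@label) != 1L || !nzchar(object@label))
            msg <- c(msg, "label must be a non-empty string")
        if (length(object@center) != 3L || any(!is.finite(object@center)))
            msg <- c(msg, "center must be a finite mm triplet")
        if (length(object@radius) != 1L || !is.finite(object@radius) ||
            object@radius <= 0)
            msg <- c(msg, "radius must be a single positive number (mm)")
        if (is.null(msg)) TRUE else msg
    })

#' RoiTimeseries: an ROI's representative time series
#'
#' The ROI signal is the first eigenvariate of the frames x voxels matrix of
#' all grey-matter voxels inside the sphere (see [firstEigenvariate()]).
#'
#' @slot label ROI name.
#' @slot eig per-frame eigenvariate series.
#' @slot nVoxels number of voxels that entered the decomposition.
#' @export
setClass("RoiTimeseries",
    representation(label = "character", eig = "numeric", nVoxels = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@nVoxels < 1L)
            msg <- c(msg, "an ROI needs at least one voxel")
        if (length(object@eig) < 2L)
            msg <- c(msg, "eigenvariate series needs at least 2 frames")
        if (is.null(msg)) TRUE else msg
    })

#' SeedMapStats: seed-to-voxel Fisher-z map with laterality summary
#'
#' @slot seedLabel seed ROI name.
#' @slot zmap 3D volume of Fisher-z correlations (NA outside the brain mask).
#' @slot affine 4x4 voxel-to-mm map.
#' @slot li laterality index (LH - RH)/(LH + RH) over suprathreshold voxel
#'   counts; NA until [lateralityIndex()] is applied, and NA when no voxel
#'   survives the threshold.
#' @slot lhCount,rhCount suprathreshold voxel counts per hemisphere.
#' @slot qc list of quality-control counters (e.g. zero-variance voxels).
#' @export
setClass("SeedMapStats",
    representation(seedLabel = "character", zmap = "array", affine = "matrix",
                   li = "numeric", lhCount = "integer", rhCount = "integer",
                   qc = "list"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@zmap)) != 3L)
            msg <- c(msg, "zmap must be a 3D volume")
        if (!is.na(object@li) && (object@li < -1 - 1e-9 || object@li > 1 + 1e-9))
            msg <- c(msg, "laterality index must lie in [-1, 1]")
        tot <- object@lhCount + object@rhCount
        if (!is.na(object@li) && tot > 0L) {
            want <- (object@lhCount - object@rhCount) / tot
            if (abs(object@li - want) > 1e-9)
                msg <- c(msg, "li must equal (LH - RH)/(LH + RH)")
        }
        if (is.null(msg)) TRUE else msg
    })

## ---------------------------------------------------------------------------
## Synthetic-data configuration and ground truth
## ---------------------------------------------------------------------------

#' PhantomConfig: parameters of the synthetic BOLD phantom
#'
#' Defaults mirror the emulated acquisition: 180 frames at TR 2 s (6
#' minutes), 3 mm isotropic voxels, and a desk-scale 20 x 24 x 20 grid that
#' still supports 50 mm-sphere framewise-displacement geometry and
#' left/right hemisphere splits.
#'
#' @slot nFrames number of frames (default 180).
#' @slot tr repetition time in seconds (default 2).
#' @slot voxelSize isotropic voxel size in mm (default 3).
#' @slot gridShape voxel counts per axis (default c(20, 24, 20)).
#' @slot roiSpecs list of [RoiSpec-class] with planted signals.
#' @slot roiCovariance positive-semidefinite covariance of the planted ROI
#'   signals; its correlation structure is the ground truth.
#' @slot noiseSd marginal standard deviation of the AR(1) voxel noise.
#' @slot ar1Coef AR(1) coefficient in [0, 1).
#' @slot nuisanceGain amplitude of the shared WM/CSF compartment signals.
#' @slot gmLeak fraction of the WM+CSF signal leaking into grey matter
#'   (what nuisance regression is there to remove).
#' @slot baseline additive signal offset (arbitrary units).
#' @slot driftSd per-frame standard deviation of the motion drift (mm).
#' @slot spikes list of c(frame, magnitude-mm) planted motion spikes.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomConfig",
    representation(nFrames = "integer", tr = "numeric", voxelSize = "numeric",
                   gridShape = "integer", roiSpecs = "list",
                   roiCovariance = "matrix", noiseSd = "numeric",
                   ar1Coef = "numeric", nuisanceGain = "numeric",
                   gmLeak = "numeric", baseline = "numeric",
                   driftSd = "numeric", spikes = "list", seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@nFrames < 2L)
            msg <- c(msg, "nFrames must be at least 2")
        if (object@tr <= 0) msg <- c(msg, "tr must be positive")
        if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
            msg <- c(msg, "gridShape must be 3 counts, each >= 4")
        k <- length(object@roiSpecs)
        if (k < 1L) msg <- c(msg, "at least one ROI is required")
        if (!all(vapply(object@roiSpecs, is, TRUE, class2 = "RoiSpec")))
            msg <- c(msg, "roiSpecs must be a list of RoiSpec objects")
        C <- object@roiCovariance
        if (!identical(dim(C), c(k, k)))
            msg <- c(msg, "roiCovariance must be k x k for k ROIs")
        else {
            if (max(abs(C - t(C))) > 1e-8)
                msg <- c(msg, "roiCovariance must be symmetric")
            else if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <
                     -1e-8 * max(1, max(abs(C))))
                msg <- c(msg, "roiCovariance must be positive semi-definite")
        }
        if (object@ar1Coef < 0 || object@ar1Coef >= 1)
            msg <- c(msg, "ar1Coef must lie in [0, 1)")
        if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
        if (is.null(msg)) TRUE else msg
    })

#' CohortConfig: parameters of the synthetic behavioral cohort
#'
#' Emulates the study conditions: three sessions (sham and two real
#' stimulation sites), 260 lexical-decision trials per session (52 expected,
#' 52 unexpected, 52 anomalous, 104 pseudoword), and an across-subject
#' coupling between one ROI-pair Fisher-z and one normalized-RT measure at a
#' configurable true correlation (one value per session).
#'
#' @slot nSubjects cohort size (>= 4).
#' @slot sessions session labels; the first is treated as the reference
#'   (sham) condition by downstream helpers.
#' @slot conditionMeanRts named mean RTs (ms) for expected, unexpected,
#'   anomalous, pseudoword.
#' @slot trialCounts named trial counts per condition.
#' @slot rtSd within-cell RT standard deviation (ms).
#' @slot errorRate Bernoulli probability of an incorrect response.
#' @slot speedSdLog sdlog of the multiplicative per-subject speed factor.
#' @slot behaviorConnectivityR named (per session) target across-subject
#'   Pearson correlation between the coupled ROI-pair z and the coupled
#'   normalized-RT measure.
#' @slot roiLabels ROI labels whose pairwise z values are generated.
#' @slot coupledPair two ROI labels whose z carries the behavioral coupling.
#' @slot coupledMeasure condition whose normalized RT is coupled.
#' @slot zMean,zSd mean and SD of the across-subject Fisher-z distribution.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
    representation(nSubjects = "integer", sessions = "character",
                   conditionMeanRts = "numeric", trialCounts = "integer",
                   rtSd = "numeric", errorRate = "numeric",
                   speedSdLog = "numeric", behaviorConnectivityR = "numeric",
                   roiLabels = "character", coupledPair = "character",
                   coupledMeasure = "character", zMean = "numeric",
                   zSd = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@nSubjects < 4L)
            msg <- c(msg, "nSubjects must be at least 4 (correlations are degenerate below that)")
        conds <- c("expected", "unexpected", "anomalous", "pseudoword")
        if (!all(conds %in% names(object@conditionMeanRts)))
            msg <- c(msg, "conditionMeanRts must name expected, unexpected, anomalous, pseudoword")
        else if (any(object@conditionMeanRts[conds] <= 0))
            msg <- c(msg, "condition mean RTs must be positive")
        if (!all(conds %in% names(object@trialCounts)))
            msg <- c(msg, "trialCounts must name all four conditions")
        if (object@errorRate < 0 || object@errorRate >= 1)
            msg <- c(msg, "errorRate must lie in [0, 1)")
        r <- object@behaviorConnectivityR
        if (any(abs(r) > 1))
            msg <- c(msg, "behaviorConnectivityR must lie in [-1, 1]")
        if (!all(names(r) %in% object@sessions))
            msg <- c(msg, "behaviorConnectivityR names must be session labels")
        if (length(object@coupledPair) != 2L ||
            !all(object@coupledPair %in% object@roiLabels))
            msg <- c(msg, "coupledPair must name two of roiLabels")
        if (!object@coupledMeasure %in% c("unexpected", "anomalous", "pseudoword"))
            msg <- c(msg, "coupledMeasure must be a non-expected condition")
        if (is.null(msg)) TRUE else msg
    })

#' SyntheticTruth: planted ground truth of a synthetic dataset
#'
#' @slot trueRoiCorrelations planted ROI signal correlation matrix (0 x 0
#'   for behavioral cohorts, which plant no imaging signal).
#' @slot trueBehaviorEffect named per-session target connectivity-behavior
#'   correlation (NA for phantoms).
#' @slot spikeFrames frames with planted motion spikes.
#' @export
setClass("SyntheticTruth",
    representation(trueRoiCorrelations = "matrix",
                   trueBehaviorEffect = "numeric",
                   spikeFrames = "integer"),
    validity = function(object) {
        msg <- NULL
        C <- object@trueRoiCorrelations
        if (nrow(C) > 0L && max(abs(diag(C) - 1)) > 1e-8)
            msg <- c(msg, "trueRoiCorrelations must have unit diagonal")
        if (is.null(msg)) TRUE else msg
    })

## ---------------------------------------------------------------------------
## Statistics
## ---------------------------------------------------------------------------

#' StatResult: a single inferential result
#'
#' Lightweight container used by the inferential layer; every test returns
#' one, so that multiplicity control ([bonferroniAdjust()]) and reporting
#' are uniform.
#'
#' @slot method test name.
#' @slot estimate effect estimate (r, rho, mean difference, ...).
#' @slot statistic test statistic (t, D, V, observed z-difference, ...).
#' @slot df degrees of freedom (possibly fractional; NA where undefined).
#' @slot p two-tailed p-value.
#' @slot n sample size.
#' @slot adjustedP multiplicity-adjusted p (NA until adjusted).
#' @slot mTests family size used for the adjustment (NA until adjusted).
#' @slot details free-form list (permutation counts, QC flags, ...).
#' @export
setClass("StatResult",
    representation(method = "character", estimate = "numeric",
                   statistic = "numeric", df = "numeric", p = "numeric",
                   n = "numeric", adjustedP = "numeric", mTests = "numeric",
                   details = "list"),
    validity = function(object) {
        msg <- NULL
        if (!is.na(object@p) && (object@p < 0 || object@p > 1))
            msg <- c(msg, "p must lie in [0, 1]")
        if (!is.na(object@adjustedP)) {
            if (object@adjustedP < 0 || object@adjustedP > 1)
                msg <- c(msg, "adjustedP must lie in [0, 1]")
            if (!is.na(object@mTests) &&
                abs(object@adjustedP - min(1, object@p * object@mTests)) > 1e-12)
                msg <- c(msg, "adjustedP must equal min(1, p * mTests)")
        }
        if (is.null(msg)) TRUE else msg
    })

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Construct a BoldRun
#'
#' @param data 4D array (x, y, z, frame).
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel indices).
#' @param tr repetition time in seconds.
#' @return A [BoldRun-class] object.
#' @export
boldRun <- function(data, affine, tr)
    new("BoldRun", data = data, affine = affine, tr = as.numeric(tr))

#' Construct a TissueMaps object
#'
#' @param gm,wm,csf 3D probability volumes.
#' @param affine shared 4x4 voxel-to-mm matrix.
#' @return A [TissueMaps-class] object.
#' @export
tissueMaps <- function(gm, wm, csf, affine)
    new("TissueMaps", gm = gm, wm = wm, csf = csf, affine = affine)

#' Construct a MotionTrace
#'
#' @param params frames x 6 matrix: tx, ty, tz (mm), rx, ry, rz (rad).
#' @return A [MotionTrace-class] object.
#' @export
motionTrace <- function(params) {
    params <- as.matrix(params)
    colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    new("MotionTrace", params = params)
}

#' Construct a spherical ROI specification
#'
#' @param label ROI name.
#' @param center mm coordinate triplet.
#' @param radius sphere radius in mm; the study convention is 7 mm.
#' @return A [RoiSpec-class] object.
#' @export
roiSpec <- function(label, center, radius = 7)
    new("RoiSpec", label = as.character(label), center = as.numeric(center),
        radius = as.numeric(radius))

#' The four default-mode-network ROI centers shipped with the package
#'
#' MNI coordinates of medial frontal gyrus, posterior cingulate, and
#' left/right angular gyri, used as a negative-control ROI set. The
#' semantic-control ROI peaks (left aIFG, aMTG, pMTG) are not published as
#' coordinate triplets and must be user-supplied; the synthetic phantom
#' instead plants its own desk-scale stand-ins (see [phantomConfig()]).
#'
#' @param radius sphere radius in mm.
#' @return List of four [RoiSpec-class] objects.
#' @export
dmnRoiSpecs <- function(radius = 7)
    list(roiSpec("MFG",  c(6, 58, 4),    radius),
         roiSpec("PCC",  c(4, -52, 24),  radius),
         roiSpec("lANG", c(-50, -64, 30), radius),
         roiSpec("rANG", c(52, -64, 36), radius))

.defaultPhantomRois <- function(radius = 7)
    list(roiSpec("aIFG", c(-19.5, 16.5, 4.5),  radius),
         roiSpec("aMTG", c(-22.5, 0, 0),       radius),
         roiSpec("pMTG", c(-19.5, -16.5, -4.5), radius))

.defaultRoiCovariance <- function() {
    C <- matrix(c(1, 0.45, 0.60,
                  0.45, 1, 0.30,
                  0.60, 0.30, 1), 3, 3)
    dimnames(C) <- list(c("aIFG", "aMTG", "pMTG"), c("aIFG", "aMTG", "pMTG"))
    C
}

#' Configure a synthetic BOLD phantom
#'
#' Defaults encode the emulated study conditions: 180 frames at TR 2 s,
#' 3 mm isotropic voxels, three left-hemisphere ROIs carrying band-limited
#' (0.01-0.08 Hz) signals with a planted correlation structure, AR(1) voxel
#' noise at SNR 1, shared WM/CSF nuisance signals that leak into grey
#' matter, and a low-amplitude motion drift.
#'
#' @param nFrames,tr,voxelSize,gridShape acquisition geometry.
#' @param roiSpecs list of [RoiSpec-class]; defaults to three synthetic
#'   left-hemisphere stand-ins labelled aIFG/aMTG/pMTG.
#' @param roiCovariance planted signal covariance (PSD); its correlation
#'   structure is the recovery ground truth.
#' @param noiseSd,ar1Coef AR(1) voxel noise parameters.
#' @param nuisanceGain,gmLeak compartment-signal amplitude and its
#'   grey-matter leakage fraction.
#' @param baseline additive offset.
#' @param driftSd per-frame motion drift SD in mm.
#' @param spikes list of c(frame, magnitude-mm) motion spikes.
#' @param seed integer RNG seed.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(nFrames = 180, tr = 2, voxelSize = 3,
                          gridShape = c(20L, 24L, 20L),
                          roiSpecs = .defaultPhantomRois(),
                          roiCovariance = .defaultRoiCovariance(),
                          noiseSd = 1, ar1Coef = 0.3, nuisanceGain = 1,
                          gmLeak = 0.3, baseline = 100, driftSd = 0.02,
                          spikes = list(), seed = 1L)
    new("PhantomConfig", nFrames = as.integer(nFrames), tr = as.numeric(tr),
        voxelSize = as.numeric(voxelSize), gridShape = as.integer(gridShape),
        roiSpecs = roiSpecs, roiCovariance = as.matrix(roiCovariance),
        noiseSd = as.numeric(noiseSd), ar1Coef = as.numeric(ar1Coef),
        nuisanceGain = as.numeric(nuisanceGain), gmLeak = as.numeric(gmLeak),
        baseline = as.numeric(baseline), driftSd = as.numeric(driftSd),
        spikes = spikes, seed = as.integer(seed))

#' Configure a synthetic behavioral cohort
#'
#' Defaults encode the study conditions: a 20-subject cohort, three
#' sessions, 260 trials per session (52/52/52/104), an overall error rate of
#' 1.7%, and per-session connectivity-behavior couplings of -0.63 (sham),
#' -0.17 (aIFG stimulation) and -0.42 (pMTG stimulation) between the
#' aIFG-pMTG Fisher-z and the normalized unexpected RT.
#'
#' @param nSubjects cohort size.
#' @param sessions session labels (first = reference/sham).
#' @param conditionMeanRts named mean RTs in ms; defaults give the
#'   monotone ordering expected < unexpected < anomalous < pseudoword.
#' @param trialCounts named trials per condition.
#' @param rtSd within-cell RT standard deviation (ms).
#' @param errorRate Bernoulli error probability.
#' @param speedSdLog sdlog of the multiplicative subject speed factor.
#' @param behaviorConnectivityR named per-session target correlation; a
#'   single unnamed value applies to the first (sham) session only.
#' @param roiLabels ROI labels.
#' @param coupledPair ROI pair carrying the coupling.
#' @param coupledMeasure normalized-RT condition carrying the coupling.
#' @param zMean,zSd across-subject Fisher-z distribution.
#' @param seed integer RNG seed.
#' @return A [CohortConfig-class] object.
#' @export
cohortConfig <- function(nSubjects = 20,
                         sessions = c("sham", "aifg", "pmtg"),
                         conditionMeanRts = c(expected = 850, unexpected = 910,
                                              anomalous = 960, pseudoword = 1020),
                         trialCounts = c(expected = 52L, unexpected = 52L,
                                         anomalous = 52L, pseudoword = 104L),
                         rtSd = 90, errorRate = 0.017, speedSdLog = 0.08,
                         behaviorConnectivityR = c(sham = -0.63, aifg = -0.17,
                                                   pmtg = -0.42),
                         roiLabels = c("aIFG", "aMTG", "pMTG"),
                         coupledPair = c("aIFG", "pMTG"),
                         coupledMeasure = "unexpected",
                         zMean = 0.5, zSd = 0.2, seed = 1L) {
    if (is.null(names(behaviorConnectivityR)) &&
        length(behaviorConnectivityR) == 1L)
        names(behaviorConnectivityR) <- sessions[1L]
    ## couplings for sessions not in this design are silently dropped, so
    ## the defaults remain valid for reduced session sets
    behaviorConnectivityR <-
        behaviorConnectivityR[names(behaviorConnectivityR) %in% sessions]
    new("CohortConfig", nSubjects = as.integer(nSubjects),
        sessions = as.character(sessions),
        conditionMeanRts = conditionMeanRts,
        trialCounts = setNames(as.integer(trialCounts), names(trialCounts)),
        rtSd = as.numeric(rtSd), errorRate = as.numeric(errorRate),
        speedSdLog = as.numeric(speedSdLog),
        behaviorConnectivityR = behaviorConnectivityR,
        roiLabels = as.character(roiLabels),
        coupledPair = as.character(coupledPair),
        coupledMeasure = as.character(coupledMeasure),
        zMean = as.numeric(zMean), zSd = as.numeric(zSd),
        seed = as.integer(seed))
}

statResult <- function(method, estimate = NA_real_, statistic = NA_real_,
                       df = NA_real_, p = NA_real_, n = NA_real_,
                       details = list())
    new("StatResult", method = method, estimate = as.numeric(estimate),
        statistic = as.numeric(statistic), df = as.numeric(df),
        p = as.numeric(p), n = as.numeric(n), adjustedP = NA_real_,
        mTests = NA_real_, details = details)
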