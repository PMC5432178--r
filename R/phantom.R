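#' @include AllClasses.R AllGenerics.R
NULL

## Evaluate expr under a temporary RNG state; NULL seed = use current stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Derive a reproducible child seed from a run seed and a stage label
#'
#' One pipeline seed fans out to per-stage (and per-subject, per-session)
#' child seeds through a small deterministic string hash, so that each stage
#' owns an independent, reproducible stream and no stage reuses another's.
#'
#' @param seed integer parent seed.
#' @param ... labels (coerced to character) identifying the consumer, e.g.
#'   `childSeed(42, "phantom", subject, session)`.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(seed, ...) {
    lab <- paste(vapply(list(...), as.character, ""), collapse = "/")
    h <- as.double(seed) %% 2147483647
    for (k in utf8ToInt(lab)) h <- (h * 131 + k) %% 2147483647
    as.integer(h)
}

#' Generate a rigid-body motion trace with planted spikes
#'
#' Motion is a smooth low-amplitude random-walk drift in all six rigid-body
#' parameters; at each planted spike the frame-to-frame increment is
#' replaced by a pure translation of exactly the requested magnitude (and
#' zero rotation), so the planted framewise displacement at that transition
#' equals the magnitude under any FD convention.
#'
#' @param nFrames number of frames.
#' @param spikes list of `c(frame, magnitude)` pairs; `frame` is 1-based
#'   and must lie in `[2, nFrames]` (a spike is a jump from the previous
#'   frame), magnitude in mm.
#' @param driftSd per-frame standard deviation of the translation drift in
#'   mm (rotational drift uses `driftSd / 50` rad, i.e. comparable surface
#'   displacement on a 50 mm sphere).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [MotionTrace-class] with `nFrames` rows.
#' @examples
#' fd <- framewiseDisplacement(makeMotionTrace(180, list(c(50, 3)), seed = 1))
#' which(fd > 0.5)  # the planted spike
#' @export
makeMotionTrace <- function(nFrames, spikes = list(), driftSd = 0.02,
                            seed = NULL) {
    nFrames <- as.integer(nFrames)
    stopifnot(nFrames >= 2L, driftSd >= 0)
    for (s in spikes) {
        if (length(s) != 2L || !is.numeric(s))
            stop("each spike must be c(frame, magnitude)")
        if (s[1] < 2 || s[1] > nFrames)
            stop(sprintf("spike frame %d out of range [2, %d]",
                         as.integer(s[1]), nFrames))
    }
    .withSeed(seed, {
        incr <- cbind(matrix(stats::rnorm(3L * (nFrames - 1L), 0, driftSd),
                             nFrames - 1L, 3L),
                      matrix(stats::rnorm(3L * (nFrames - 1L), 0, driftSd / 50),
                             nFrames - 1L, 3L))
        for (s in spikes)
            incr[as.integer(s[1]) - 1L, ] <- c(s[2], 0, 0, 0, 0, 0)
        params <- rbind(rep(0, 6L), apply(incr, 2L, cumsum))
        motionTrace(params)
    })
}

## Concentric ellipsoidal tissue compartments: WM core, GM shell (holding
## the ROIs), CSF rim. Deterministic, affine-consistent, trivially maskable.
.ellipsoidTissue <- function(gridShape, affine) {
    idx <- as.matrix(expand.grid(x = 0:(gridShape[1] - 1L),
                                 y = 0:(gridShape[2] - 1L),
                                 z = 0:(gridShape[3] - 1L)))
    mm <- idx %*% t(affine[1:3, 1:3]) +
        matrix(affine[1:3, 4], nrow(idx), 3L, byrow = TRUE)
    half <- gridShape * abs(diag(affine)[1:3]) / 2
    rho <- sqrt((mm[, 1] / half[1])^2 + (mm[, 2] / half[2])^2 +
                (mm[, 3] / half[3])^2)
    shape3 <- function(v) array(v, gridShape)
    list(wm = shape3(as.numeric(rho <= 0.45)),
         gm = shape3(as.numeric(rho > 0.45 & rho <= 0.85)),
         csf = shape3(as.numeric(rho > 0.85 & rho <= 1.0)),
         mm = mm)
}

.phantomAffine <- function(gridShape, voxelSize) {
    aff <- diag(c(voxelSize, voxelSize, voxelSize, 1))
    aff[1:3, 4] <- -(gridShape - 1) / 2 * voxelSize
    aff
}

## Band-limited unit signals: sums of cosines with uniform random phase over
## the passband, demeaned and orthonormalized so that mixing with the
## Cholesky factor of the target correlation plants that correlation in the
## sample exactly.
.bandLimitedBasis <- function(nFrames, tr, k, fLo = 0.01, fHi = 0.08) {
    tsec <- (seq_len(nFrames) - 1) * tr
    freqs <- seq_len(floor(nFrames / 2)) / (nFrames * tr)
    freqs <- freqs[freqs >= fLo & freqs <= fHi]
    if (length(freqs) < 1L)
        stop("no Fourier frequency falls inside the passband; run too short")
    raw <- vapply(seq_len(k), function(j) {
        ph <- stats::runif(length(freqs), 0, 2 * pi)
        rowSums(vapply(seq_along(freqs),
                       function(i) cos(2 * pi * freqs[i] * tsec + ph[i]),
                       numeric(nFrames)))
    }, numeric(nFrames))
    raw <- sweep(raw, 2L, colMeans(raw))
    qr.Q(qr(raw))    # orthonormal, still band-limited and mean-zero
}

## AR(1) noise with unit marginal variance, frames x channels.
.ar1Noise <- function(nFrames, nChannels, phi) {
    x <- matrix(stats::rnorm(nFrames * nChannels), nFrames, nChannels)
    if (phi > 0) {
        x <- x * sqrt(1 - phi^2)
        x[1L, ] <- x[1L, ] / sqrt(1 - phi^2)   # stationary start
        for (t in 2:nFrames) x[t, ] <- phi * x[t - 1L, ] + x[t, ]
    }
    x
}

#' Generate a synthetic BOLD phantom with known ground truth
#'
#' Builds a 4D run in which grey-matter ROI voxels carry band-limited
#' (0.01-0.08 Hz) signals drawn with the planted covariance, every voxel
#' carries AR(1) noise, and WM/CSF compartments carry their own shared
#' nuisance signals (which also leak, attenuated, into grey matter). The
#' planted signals are orthonormalized before covariance mixing, so the
#' sample correlation between ROI signal components equals the planted
#' correlation exactly; recovery error downstream therefore measures the
#' pipeline, not the draw.
#'
#' @param config a [PhantomConfig-class].
#' @return List with components `run` ([BoldRun-class]), `tissue`
#'   ([TissueMaps-class]), `motion` ([MotionTrace-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' ph <- makePhantom(phantomConfig(seed = 7))
#' ph$run
#' @export
makePhantom <- function(config) {
    stopifnot(is(config, "PhantomConfig"))
    validObject(config)
    g <- config@gridShape
    nvox <- prod(g)
    n <- config@nFrames
    k <- length(config@roiSpecs)
    aff <- .phantomAffine(g, config@voxelSize)
    tis <- .ellipsoidTissue(g, aff)

    Ccor <- stats::cov2cor(config@roiCovariance)
    .withSeed(config@seed, {
        ## planted ROI signals, unit variance, exact planted correlation
        Q <- .bandLimitedBasis(n, config@tr, k)
        sig <- Q %*% chol(Ccor + diag(1e-10, k)) * sqrt(n - 1)

        ## compartment signals drawn before the (optional) voxel noise so
        ## that a given seed plants the same nuisance regardless of noiseSd
        wmSig <- as.vector(.ar1Noise(n, 1L, 0.9))
        csfSig <- as.vector(.ar1Noise(n, 1L, 0.9))

        vol <- matrix(0, n, nvox)
        if (config@noiseSd > 0)
            vol <- .ar1Noise(n, nvox, config@ar1Coef) * config@noiseSd

        gmMask <- tis$gm > 0.5
        roiIdx <- lapply(config@roiSpecs, function(spec) {
            d2 <- (tis$mm[, 1] - spec@center[1])^2 +
                  (tis$mm[, 2] - spec@center[2])^2 +
                  (tis$mm[, 3] - spec@center[3])^2
            which(d2 <= spec@radius^2 & as.vector(gmMask))
        })
        for (j in seq_len(k)) {
            if (!length(roiIdx[[j]]))
                stop(sprintf("ROI '%s' covers no grey-matter voxel of the phantom",
                             config@roiSpecs[[j]]@label))
            vol[, roiIdx[[j]]] <- vol[, roiIdx[[j]]] + sig[, j]
        }

        if (config@nuisanceGain > 0) {
            wmIdx <- which(as.vector(tis$wm) > 0.5)
            csfIdx <- which(as.vector(tis$csf) > 0.5)
            gmIdx <- which(as.vector(gmMask))
            vol[, wmIdx] <- vol[, wmIdx] + config@nuisanceGain * wmSig
            vol[, csfIdx] <- vol[, csfIdx] + config@nuisanceGain * csfSig
            vol[, gmIdx] <- vol[, gmIdx] +
                config@nuisanceGain * config@gmLeak * (wmSig + csfSig)
        }
        vol <- vol + config@baseline

        run <- boldRun(array(t(vol), c(g, n)), aff, config@tr)
        motion <- makeMotionTrace(n, config@spikes, config@driftSd,
                                  seed = NULL)
        truth <- new("SyntheticTruth",
                     trueRoiCorrelations = Ccor,
                     trueBehaviorEffect = NA_real_,
                     spikeFrames = as.integer(vapply(config@spikes,
                                                     `[`, 0, 1)))
        list(run = run,
             tissue = tissueMaps(tis$gm, tis$wm, tis$csf, aff),
             motion = motion,
             truth = truth)
    })
}
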