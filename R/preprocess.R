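#' @include AllClasses.R AllGenerics.R
NULL

#' Mean time series over a high-probability tissue compartment
#'
#' Averages the run over all voxels whose tissue probability strictly
#' exceeds `threshold`. The 0.75 cut is the study convention for the
#' white-matter compartment; CSF uses the same default (configurable).
#'
#' @param run a [BoldRun-class].
#' @param probMap 3D probability volume on the run's grid.
#' @param threshold probability cut in (0, 1); voxels with
#'   `prob > threshold` enter the mean.
#' @param tissue compartment name, used in error messages.
#' @return Numeric per-frame mean series.
#' @export
extractTissueMean <- function(run, probMap, threshold = 0.75,
                              tissue = "tissue") {
    stopifnot(is(run, "BoldRun"), threshold > 0, threshold < 1)
    d <- dim(run@data)
    if (!identical(dim(probMap), d[1:3]))
        stop(sprintf("%s probability map is not on the run's grid", tissue))
    idx <- which(as.vector(probMap) > threshold)
    if (!length(idx))
        stop(sprintf("no %s voxel has probability > %g", tissue, threshold))
    flat <- matrix(run@data, prod(d[1:3]), d[4])
    colMeans(flat[idx, , drop = FALSE])
}

#' Build the 27-column nuisance design matrix
#'
#' The default denoising recipe: the 6 rigid-body motion parameters and
#' their first temporal derivatives, each entered linearly and squared
#' (24 columns), plus the mean white-matter and CSF signals (linear only)
#' and an intercept. The derivative is the backward difference with a
#' leading zero row, preserving the frame count. An 18-column variant
#' (squares of the derivatives only) is available via
#' `expansion = "derivsq"`.
#'
#' @param motion a [MotionTrace-class] (or frames x 6 matrix).
#' @param wm,csf per-frame compartment mean series.
#' @param expansion `"full"` (default; params and derivatives squared, 27
#'   columns) or `"derivsq"` (only derivatives squared, 21 columns).
#' @return Numeric matrix with named columns, intercept last.
#' @export
buildNuisanceDesign <- function(motion, wm, csf,
                                expansion = c("full", "derivsq")) {
    expansion <- match.arg(expansion)
    m <- if (is(motion, "MotionTrace")) motion@params else as.matrix(motion)
    n <- nrow(m)
    if (length(wm) != n || length(csf) != n)
        stop("motion, wm and csf must cover the same frames")
    d <- rbind(rep(0, 6L), diff(m))
    nm <- c("tx", "ty", "tz", "rx", "ry", "rz")
    X <- cbind(m, d, if (expansion == "full") m^2, d^2, wm, csf, 1)
    colnames(X) <- c(nm, paste0("d_", nm),
                     if (expansion == "full") paste0(nm, "_sq"),
                     paste0("d_", nm, "_sq"), "wm", "csf", "intercept")
    X
}

## Drop zero/constant columns (keeping the intercept) so least squares stays
## well-posed when motion is absent.
.pruneDesign <- function(design) {
    keep <- apply(design, 2L, function(col) max(col) - min(col) > 1e-12)
    keep[colnames(design) == "intercept"] <- TRUE
    design[, keep, drop = FALSE]
}

#' Remove nuisance variance by multiple regression
#'
#' Projects each channel onto the orthogonal complement of the design's
#' column span. Zero/constant columns are pruned first; a design that is
#' still rank-deficient is rejected with the offending columns named.
#'
#' @param series frames x channels matrix (or vector).
#' @param design nuisance design matrix from [buildNuisanceDesign()] (any
#'   full-column-rank matrix works).
#' @return Residual matrix of the same shape; residuals are orthogonal to
#'   every design column.
#' @export
regressOut <- function(series, design) {
    series <- as.matrix(series)
    design <- .pruneDesign(as.matrix(design))
    if (nrow(series) != nrow(design))
        stop("series and design must cover the same frames")
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
        bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
        stop("nuisance design is rank deficient; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    qr.resid(qrd, series)
}

#' Band-pass filter BOLD time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass, order 2 per pass,
#' preserving only the resting-state band (default 0.01-0.08 Hz). Each
#' channel is demeaned before filtering, so a constant series maps to zero
#' exactly and the output mean is ~0.
#'
#' @param series frames x channels matrix (or vector).
#' @param tr repetition time in seconds.
#' @param fLo,fHi passband edges in Hz; `fHi` must lie below the Nyquist
#'   frequency `1/(2 tr)`.
#' @return Filtered matrix of the same shape.
#' @export
bandpassFilter <- function(series, tr, fLo = 0.01, fHi = 0.08) {
    stopifnot(tr > 0, fLo > 0, fLo < fHi)
    nyq <- 1 / (2 * tr)
    if (fHi >= nyq)
        stop(sprintf("upper band edge %g Hz must lie below Nyquist %g Hz",
                     fHi, nyq))
    vec <- is.null(dim(series))
    series <- as.matrix(series)
    series <- sweep(series, 2L, colMeans(series))
    bf <- signal::butter(2, c(fLo, fHi) / nyq, type = "pass")
    out <- apply(series, 2L, function(x) signal::filtfilt(bf, x))
    out <- matrix(out, nrow(series), ncol(series),
                  dimnames = dimnames(series))
    ## the passband excludes DC; remove the residual edge-transient mean
    out <- sweep(out, 2L, colMeans(out))
    if (vec) as.vector(out) else out
}

#' Rigid-body transform of one motion-parameter frame
#'
#' Maps a point p (mm, relative to the isocenter) to `R p + t` with
#' rotation `R = Rz(rz) Ry(ry) Rx(rx)` and translation `t = (tx, ty, tz)`.
#' Exposed so that independent checks (e.g. dense sphere sampling) can share
#' the package's angle convention.
#'
#' @param params length-6 numeric: tx, ty, tz (mm), rx, ry, rz (rad).
#' @return List with `R` (3x3 rotation) and `t` (length-3 translation).
#' @export
rigidMotionTransform <- function(params) {
    stopifnot(length(params) == 6L)
    cx <- cos(params[4]); sx <- sin(params[4])
    cy <- cos(params[5]); sy <- sin(params[5])
    cz <- cos(params[6]); sz <- sin(params[6])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    list(R = Rz %*% Ry %*% Rx, t = as.numeric(params[1:3]))
}

## Maximize ||A p + b|| over ||p|| <= r. The objective is convex, so the
## maximum sits on the sphere boundary; in the eigenbasis of A'A the
## stationarity condition reduces to a one-dimensional secular equation in
## the multiplier, solved by safeguarded root finding (with the usual
## trust-region "hard case" when the gradient has no component along the
## top eigenvector).
.maxSphereDisplacement <- function(A, b, r) {
    if (max(abs(A)) < 1e-14) return(sqrt(sum(b^2)))
    M <- crossprod(A)
    e <- eigen(M, symmetric = TRUE)
    lam <- e$values
    ct <- as.vector(crossprod(e$vectors, crossprod(A, b)))
    val <- function(p) {
        q <- A %*% (e$vectors %*% p) + b
        sum(q^2)
    }
    normAt <- function(mu) sqrt(sum((ct / (mu - lam))^2))
    top <- abs(lam[1] - lam) < 1e-12 * max(lam[1], 1e-300)
    if (sqrt(sum(ct[top]^2)) > 1e-14 * max(1, sqrt(sum(ct^2)))) {
        lo <- lam[1] + max(lam[1], 1) * 1e-14
        hi <- lam[1] + sqrt(sum(ct^2)) / r + 1e-12
        while (normAt(lo) < r) lo <- lam[1] + (lo - lam[1]) / 10
        mu <- stats::uniroot(function(m) normAt(m) - r, c(lo, hi),
                             tol = 1e-15)$root
        p <- ct / (mu - lam)
        sqrt(val(p * (r / sqrt(sum(p^2)))))
    } else {
        ## hard case: no gradient along the top eigenspace
        p0 <- ifelse(top, 0, ct / (lam[1] - lam))
        n0 <- sum(p0^2)
        if (n0 >= r^2) {
            mu <- stats::uniroot(function(m) normAt(m) - r,
                                 c(lam[1] + max(lam[1], 1) * 1e-14,
                                   lam[1] + sqrt(sum(ct^2)) / r + 1),
                                 tol = 1e-15)$root
            p <- ct / (mu - lam)
            sqrt(val(p * (r / sqrt(sum(p^2)))))
        } else {
            p <- p0
            p[which(top)[1]] <- sqrt(r^2 - n0)
            sqrt(val(p))
        }
    }
}

#' Framewise displacement of a motion trace
#'
#' The default (`mode = "sphere"`) is the exact maximum frame-to-frame
#' displacement of any point within a sphere of the given radius centered
#' at the isocenter: `FD[t] = max_{|p| <= r} |T_t(p) - T_{t-1}(p)|` with
#' `T` the frame's rigid transform. The maximum of this convex objective is
#' attained on the sphere surface and is computed analytically (secular
#' equation in the eigenbasis of the transform difference), not by
#' sampling. `mode = "power"` gives the common sum-of-absolute-values
#' variant (translations plus radius-scaled rotations) for comparison.
#'
#' @param motion a [MotionTrace-class] (or frames x 6 matrix).
#' @param sphereRadius sphere radius in mm (default 50).
#' @param mode `"sphere"` (exact max-over-sphere, default) or `"power"`.
#' @return Numeric FD series in mm; `FD[1] = 0`.
#' @export
framewiseDisplacement <- function(motion, sphereRadius = 50,
                                  mode = c("sphere", "power")) {
    mode <- match.arg(mode)
    m <- if (is(motion, "MotionTrace")) motion@params else as.matrix(motion)
    n <- nrow(m)
    if (n < 2L) stop("framewise displacement needs at least 2 frames")
    fd <- numeric(n)
    if (mode == "power") {
        dm <- abs(diff(m))
        fd[-1L] <- rowSums(dm[, 1:3, drop = FALSE]) +
            sphereRadius * rowSums(dm[, 4:6, drop = FALSE])
        return(fd)
    }
    prev <- rigidMotionTransform(m[1L, ])
    for (t in 2:n) {
        cur <- rigidMotionTransform(m[t, ])
        fd[t] <- .maxSphereDisplacement(cur$R - prev$R, cur$t - prev$t,
                                        sphereRadius)
        prev <- cur
    }
    fd
}

#' Censor high-motion frames (scrubbing) with a minimum-duration rule
#'
#' Frames with FD strictly greater than `threshold` are discarded; a frame
#' at exactly the threshold is kept. The run fails quality control when the
#' surviving data cover less than `minSeconds` (the 5-minute rule under the
#' study defaults), in which case the subject-session is meant to be
#' excluded by the caller.
#'
#' @param series frames x channels matrix (typically filtered residuals).
#' @param fd FD series from [framewiseDisplacement()], same length.
#' @param threshold FD censoring threshold in mm (default 0.5).
#' @param minSeconds minimum surviving duration in seconds (default 300).
#' @param tr repetition time in seconds.
#' @return List with `clean` ([CleanSeries-class]), `pass` (logical),
#'   `keptFraction`, `nCensored` and `keptSeconds`.
#' @export
censorFrames <- function(series, fd, threshold = 0.5, minSeconds = 300, tr) {
    series <- as.matrix(series)
    if (nrow(series) != length(fd))
        stop("series and fd must cover the same frames")
    keep <- which(!(fd > threshold))
    clean <- new("CleanSeries", series = series[keep, , drop = FALSE],
                 keptFrames = as.integer(keep), tr = as.numeric(tr))
    keptSeconds <- length(keep) * tr
    list(clean = clean,
         pass = keptSeconds >= minSeconds,
         keptFraction = length(keep) / length(fd),
         nCensored = length(fd) - length(keep),
         keptSeconds = keptSeconds)
}

#' Denoise one run: nuisance regression, band-pass, scrubbing
#'
#' The fixed stage order of the denoising recipe: drop initial frames,
#' extract WM/CSF compartment means, regress the nuisance design out of the
#' selected voxel channels, band-pass filter the residuals, then censor
#' high-motion frames of the filtered series. Grey-matter signal is never
#' included as a regressor.
#'
#' @param run a [BoldRun-class].
#' @param tissue a [TissueMaps-class] on the same grid.
#' @param motion a [MotionTrace-class] paired with the run.
#' @param voxels integer (linear) voxel indices to carry through; `NULL`
#'   processes every voxel.
#' @param dropInitial leading frames to discard (default 4).
#' @param wmProb,csfProb tissue-probability cuts for the compartment means.
#' @param band passband in Hz.
#' @param fdThreshold,minSeconds scrubbing parameters (mm, seconds).
#' @param fdRadius FD sphere radius in mm.
#' @param expansion nuisance expansion passed to [buildNuisanceDesign()].
#' @return List with `clean` ([CleanSeries-class] of the selected
#'   channels), `voxels` (the channel order), `fd`, `pass`, and `qc`
#'   (censored counts and surviving seconds).
#' @export
denoiseRun <- function(run, tissue, motion, voxels = NULL, dropInitial = 4L,
                       wmProb = 0.75, csfProb = 0.75, band = c(0.01, 0.08),
                       fdThreshold = 0.5, minSeconds = 300, fdRadius = 50,
                       expansion = "full") {
    stopifnot(is(run, "BoldRun"), is(tissue, "TissueMaps"),
              is(motion, "MotionTrace"))
    if (nFrames(motion) != nFrames(run))
        stop("motion trace and run must have the same frame count")
    run <- dropInitialFrames(run, dropInitial)
    motion <- dropInitialFrames(motion, dropInitial)

    d <- dim(run@data)
    flat <- matrix(run@data, prod(d[1:3]), d[4])
    if (is.null(voxels)) voxels <- seq_len(prod(d[1:3]))
    wm <- extractTissueMean(run, tissue@wm, wmProb, "white matter")
    csf <- extractTissueMean(run, tissue@csf, csfProb, "CSF")
    design <- buildNuisanceDesign(motion, wm, csf, expansion = expansion)

    resid <- regressOut(t(flat[voxels, , drop = FALSE]), design)
    filtered <- bandpassFilter(resid, run@tr, band[1], band[2])
    fd <- framewiseDisplacement(motion, fdRadius)
    cens <- censorFrames(filtered, fd, fdThreshold, minSeconds, run@tr)
    list(clean = cens$clean, voxels = voxels, fd = fd, pass = cens$pass,
         qc = list(nFrames = d[4], nCensored = cens$nCensored,
                   keptFraction = cens$keptFraction,
                   keptSeconds = cens$keptSeconds,
                   droppedInitial = as.integer(dropInitial)))
}
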