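#' @include AllClasses.R AllGenerics.R
NULL

#' Voxel indices of a spherical ROI restricted to grey matter
#'
#' A voxel belongs to the ROI when its center lies within `radius` mm
#' (Euclidean, inclusive) of the ROI center AND inside the grey-matter
#' mask. The center-in-sphere rule is deterministic and grid-independent;
#' note that other toolkits use different voxel-inclusion conventions.
#'
#' @param spec a [RoiSpec-class].
#' @param gmMask 3D binary (or probability > 0.5) grey-matter mask.
#' @param affine 4x4 voxel-to-mm map (0-based voxel indices).
#' @return Sorted integer vector of linear voxel indices into the grid.
#' @export
roiMask <- function(spec, gmMask, affine) {
    stopifnot(is(spec, "RoiSpec"), abs(det(affine)) > 1e-12)
    g <- dim(gmMask)
    idx <- as.matrix(expand.grid(x = 0:(g[1] - 1L), y = 0:(g[2] - 1L),
                                 z = 0:(g[3] - 1L)))
    mm <- idx %*% t(affine[1:3, 1:3]) +
        matrix(affine[1:3, 4], nrow(idx), 3L, byrow = TRUE)
    d2 <- (mm[, 1] - spec@center[1])^2 + (mm[, 2] - spec@center[2])^2 +
        (mm[, 3] - spec@center[3])^2
    out <- which(d2 <= spec@radius^2 & as.vector(gmMask) > 0.5)
    if (!length(out))
        stop(sprintf("ROI '%s' contains no grey-matter voxel", spec@label))
    out
}

#' First eigenvariate of an ROI's voxel time series
#'
#' The representative ROI signal: the first left singular vector of the
#' column-demeaned frames x voxels matrix, scaled by its singular value
#' (so its variance equals the first squared singular value divided by
#' frames - 1), with the sign fixed so that the sum of its correlations
#' with the voxel series is positive. For a single voxel this is exactly
#' the demeaned voxel series.
#'
#' @param x frames x voxels numeric matrix (a vector is treated as one
#'   voxel).
#' @return Numeric per-frame series.
#' @export
firstEigenvariate <- function(x) {
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("eigenvariate needs at least 2 frames")
    x <- sweep(x, 2L, colMeans(x))
    if (max(abs(x)) < 1e-12)
        stop("all ROI voxel series are constant; eigenvariate undefined")
    sv <- svd(x, nu = 1L, nv = 0L)
    eig <- sv$u[, 1L] * sv$d[1L]
    s <- sum(crossprod(x, eig))   # sign of summed covariances = correlations
    if (s < 0) eig <- -eig
    eig
}

#' Extract an ROI's eigenvariate from a denoised series
#'
#' @param clean a [CleanSeries-class] whose channels are voxels (in the
#'   order given by `voxels`).
#' @param voxels linear voxel indices corresponding to the channels.
#' @param mask linear voxel indices of the ROI (from [roiMask()]).
#' @param label ROI name.
#' @return A [RoiTimeseries-class].
#' @export
roiTimeseries <- function(clean, voxels, mask, label) {
    stopifnot(is(clean, "CleanSeries"))
    cols <- match(mask, voxels)
    if (anyNA(cols))
        stop(sprintf("ROI '%s' uses voxels absent from the denoised series",
                     label))
    new("RoiTimeseries", label = label,
        eig = firstEigenvariate(clean@series[, cols, drop = FALSE]),
        nVoxels = length(cols))
}

#' Fisher z-transform with clamping
#'
#' `atanh(r)` after clipping r to +/-(1 - 1e-12) so that degenerate
#' (identical) series yield a finite, flaggable record instead of
#' infinity.
#'
#' @param r correlation value(s).
#' @return Fisher-z value(s).
#' @export
fisherZ <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' ROI-to-ROI Fisher-z connectivity
#'
#' Pearson correlation between every unordered pair of ROI eigenvariates,
#' Fisher transformed. Correlations at the clamp boundary are flagged in
#' the `clamped` column.
#'
#' @param rois list of [RoiTimeseries-class] with equal frame counts >= 3.
#' @return data.frame with columns roi_a, roi_b, r, z, clamped;
#'   `k(k-1)/2` rows for k ROIs.
#' @export
fcMatrix <- function(rois) {
    stopifnot(length(rois) >= 2L,
              all(vapply(rois, is, TRUE, class2 = "RoiTimeseries")))
    lens <- vapply(rois, function(r) length(r@eig), 1L)
    if (length(unique(lens)) != 1L || lens[1] < 3L)
        stop("all ROI series must share one length >= 3")
    for (r in rois)
        if (stats::sd(r@eig) < 1e-12)
            stop(sprintf("ROI '%s' has a zero-variance series", r@label))
    pairs <- utils::combn(length(rois), 2L)
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        a <- rois[[pairs[1L, j]]]; b <- rois[[pairs[2L, j]]]
        r <- stats::cor(a@eig, b@eig)
        data.frame(roi_a = a@label, roi_b = b@label, r = r, z = fisherZ(r),
                   clamped = abs(r) >= 1 - 1e-12, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Voxelwise Fisher z of the Pearson correlation between the seed series
#' and every in-mask voxel series; the seed's own voxels are ordinary
#' voxels. Zero-variance voxels get z = 0 and are counted in the QC slot.
#'
#' @param seed a [RoiTimeseries-class] (or numeric seed series).
#' @param clean a [CleanSeries-class] whose channels are the in-mask
#'   voxels, in the order of `voxels`.
#' @param voxels linear voxel indices of the channels.
#' @param brainMask 3D mask defining the map support.
#' @param affine 4x4 voxel-to-mm map.
#' @param label seed name (defaults to the [RoiTimeseries-class] label).
#' @return A [SeedMapStats-class] with the z-map filled (LI slots NA until
#'   [lateralityIndex()] is applied).
#' @export
seedMap <- function(seed, clean, voxels, brainMask, affine, label = NULL) {
    s <- if (is(seed, "RoiTimeseries")) seed@eig else as.numeric(seed)
    if (is.null(label))
        label <- if (is(seed, "RoiTimeseries")) seed@label else "seed"
    stopifnot(is(clean, "CleanSeries"))
    Y <- clean@series
    if (length(s) != nrow(Y))
        stop("seed series and voxel series must share the frame count")
    sds <- apply(Y, 2L, stats::sd)
    degenerate <- sds < 1e-12
    r <- rep(0, ncol(Y))
    if (any(!degenerate))
        r[!degenerate] <- as.vector(stats::cor(s, Y[, !degenerate,
                                                    drop = FALSE]))
    z <- fisherZ(r)
    z[degenerate] <- 0
    zmap <- array(NA_real_, dim(brainMask))
    zmap[voxels] <- z
    new("SeedMapStats", seedLabel = label, zmap = zmap, affine = affine,
        li = NA_real_, lhCount = 0L, rhCount = 0L,
        qc = list(nZeroVariance = sum(degenerate), df = nrow(Y) - 2L))
}

#' Laterality index from suprathreshold voxel counts
#'
#' Voxelwise p-values come from the two-tailed t-statistic of the
#' underlying correlation, `t = r sqrt(df) / sqrt(1 - r^2)`. Suprathreshold
#' voxels (`p < pThreshold`, by default restricted to positive
#' correlations) are counted per hemisphere by the sign of their mm
#' x-coordinate under the affine (midline `x = 0` excluded), and
#' `LI = (LH - RH)/(LH + RH)`; +1 is fully left-lateralized. When no voxel
#' survives, the LI is reported as missing, not 0.
#'
#' @param stats a [SeedMapStats-class] with a filled z-map.
#' @param df degrees of freedom of the voxelwise correlation (frames - 2).
#' @param pThreshold voxelwise threshold (default .001).
#' @param positiveOnly count only positively correlated voxels (default
#'   TRUE, following positive-connectivity renderings); set FALSE for
#'   two-sided counting.
#' @return The input [SeedMapStats-class] with `li`, `lhCount`, `rhCount`
#'   filled.
#' @export
lateralityIndex <- function(stats, df, pThreshold = 0.001,
                            positiveOnly = TRUE) {
    stopifnot(is(stats, "SeedMapStats"), df >= 1)
    g <- dim(stats@zmap)
    idx <- which(!is.na(stats@zmap))
    z <- stats@zmap[idx]
    r <- tanh(z)
    tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df)
    supra <- p < pThreshold & (if (positiveOnly) z > 0 else TRUE)

    ijk <- arrayInd(idx, g) - 1L
    xmm <- ijk %*% stats@affine[1, 1:3] + stats@affine[1, 4]
    lh <- sum(supra & xmm < -1e-9)
    rh <- sum(supra & xmm > 1e-9)
    stats@lhCount <- as.integer(lh)
    stats@rhCount <- as.integer(rh)
    stats@li <- if (lh + rh > 0) (lh - rh) / (lh + rh) else NA_real_
    validObject(stats)
    stats
}
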