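# ROI masks, eigenvariates, Fisher-z connectivity, seed maps, laterality.

test_that("roiMask matches brute-force enumeration and masks by GM", {
    g <- c(9L, 9L, 9L)
    aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- -12   # centers -12..12 mm
    gm <- array(1, g)
    spec <- roiSpec("center", c(0, 0, 0), 7)
    got <- roiMask(spec, gm, aff)

    brute <- integer(0)
    for (k in 0:8) for (j in 0:8) for (i in 0:8) {
        mm <- c(3 * i - 12, 3 * j - 12, 3 * k - 12)
        if (sum((mm - spec@center)^2) <= 49)
            brute <- c(brute, 1L + i + 9L * j + 81L * k)
    }
    expect_identical(got, sort(brute))
    expect_identical(length(got), 57L)   # 3 mm lattice points within 7 mm

    # GM restriction removes voxels
    gm2 <- gm; gm2[5, 5, 5] <- 0
    expect_identical(length(roiMask(spec, gm2, aff)), 56L)
    expect_error(roiMask(spec, array(0, g), aff), "center")

    # radius below half a voxel catches only the center voxel
    tiny <- roiSpec("tiny", c(0, 0, 0), 1)
    expect_identical(length(roiMask(tiny, gm, aff)), 1L)
})

test_that("first eigenvariate reduces correctly in closed-form cases", {
    s <- sin(seq(0, 6, length.out = 50))
    # rank-1: all voxels identical -> demeaned series up to positive scale
    X <- cbind(s, s, s)
    eig <- firstEigenvariate(X)
    expect_equal(eig, sqrt(3) * (s - mean(s)), tolerance = 1e-10)
    expect_equal(cor(eig, s), 1)

    # single voxel: demeaned voxel series
    expect_equal(firstEigenvariate(matrix(s)), s - mean(s),
                 tolerance = 1e-10)

    # anti-correlated 60/40 split: aligns with the majority group
    X2 <- cbind(s, s, s, -s + 0.1 * cos(seq_len(50)), -s)
    X2 <- X2 + matrix(rnorm(250, 0, 0.01), 50)
    expect_gt(cor(firstEigenvariate(X2), s), 0.9)

    # scaling contract: var(eig) = d1^2 / (frames - 1)
    set.seed(8)
    X3 <- matrix(rnorm(200), 40, 5)
    sv <- svd(scale(X3, scale = FALSE))
    expect_equal(var(firstEigenvariate(X3)), sv$d[1]^2 / 39,
                 tolerance = 1e-10)

    # sign convention independently on a 4-voxel toy matrix
    X4 <- cbind(s, 2 * s, s + 0.05, -0.2 * s)
    eig4 <- firstEigenvariate(X4)
    expect_gt(sum(cor(eig4, X4)), 0)

    expect_error(firstEigenvariate(matrix(1, 10, 3)), "constant")
})

test_that("fcMatrix produces Fisher z per unordered pair with clamping", {
    s <- sin(seq(0, 10, length.out = 100))
    mk <- function(label, x) new("RoiTimeseries", label = label, eig = x,
                                 nVoxels = 1L)
    set.seed(3)
    a <- s + rnorm(100, 0, 0.5); b <- rnorm(100); c <- rnorm(100)
    fc <- fcMatrix(list(mk("A", a), mk("B", b), mk("C", c)))
    expect_identical(nrow(fc), 3L)                   # k(k-1)/2
    expect_equal(fc$z, atanh(fc$r))

    # closed form: r = 0.5 -> z = 0.5493
    expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)

    # identical series: clamped finite record, flagged
    fc2 <- fcMatrix(list(mk("A", a), mk("A2", a)))
    expect_true(is.finite(fc2$z) && fc2$clamped)

    # independent long series: z near zero
    expect_lt(abs(fc$z[fc$roi_a == "B" & fc$roi_b == "C"]), 0.3)

    # invariance to positive rescaling and mean shift
    fc3 <- fcMatrix(list(mk("A", 5 + 2.7 * a), mk("B", -3 + 0.4 * b),
                         mk("C", c)))
    expect_equal(fc3$z, fc$z, tolerance = 1e-12)

    expect_error(fcMatrix(list(mk("A", rep(0, 100)), mk("B", b))), "A")
})

test_that("eigenvariate and mean paths agree on homogeneous ROIs", {
    cfg <- smallPhantomConfig(seed = 31, r = 0.6)
    ph <- makePhantom(cfg)
    masks <- lapply(cfg@roiSpecs, roiMask, gmMask = ph$tissue@gm > 0.5,
                    affine = spatialAffine(ph$run))
    voxels <- sort(unique(unlist(masks)))
    den <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = voxels)
    eigs <- lapply(masks, function(m)
        firstEigenvariate(seriesMatrix(den$clean)[, match(m, voxels)]))
    means <- lapply(masks, function(m)
        rowMeans(seriesMatrix(den$clean)[, match(m, voxels)]))
    rEig <- cor(eigs[[1]], eigs[[2]])
    rMean <- cor(means[[1]], means[[2]])
    expect_lt(abs(rEig - rMean), 0.01)
})

test_that("seed maps localize planted regions and keep the Fisher variance law", {
    cfg <- smallPhantomConfig(seed = 41, r = 0.8, noiseSd = 0.6)
    ph <- makePhantom(cfg)
    gmMask <- ph$tissue@gm > 0.5
    masks <- lapply(cfg@roiSpecs, roiMask, gmMask = gmMask,
                    affine = spatialAffine(ph$run))
    brain <- (ph$tissue@gm + ph$tissue@wm + ph$tissue@csf) > 0.5
    voxels <- which(brain)
    den <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = voxels)
    seed <- roiTimeseries(den$clean, voxels, masks[[1]], "L")
    sm <- seedMap(seed, den$clean, voxels, brain, spatialAffine(ph$run))

    # top-|z| voxels (excluding the seed itself) coincide with the
    # planted partner region
    z <- zMap(sm)
    z[masks[[1]]] <- NA
    ord <- order(abs(z), decreasing = TRUE, na.last = NA)
    top <- ord[seq_along(masks[[2]])]
    jac <- length(intersect(top, masks[[2]])) /
        length(union(top, masks[[2]]))
    expect_gte(jac, 0.8)

    # seed against its own ROI: near-maximal z
    expect_gt(max(zMap(sm)[masks[[1]]], na.rm = TRUE), 1)

    # pure-noise phantom: mean z ~ 0, sd ~ 1/sqrt(n - 3)
    cfg0 <- smallPhantomConfig(seed = 42, r = 0, noiseSd = 1,
                               nuisanceGain = 0, ar1Coef = 0)
    ph0 <- makePhantom(cfg0)
    n <- nFrames(ph0$run)
    flat <- t(matrix(boldData(ph0$run), prod(dim(ph0$tissue@gm)), n))
    vox0 <- setdiff(which(brain), unlist(
        lapply(cfg0@roiSpecs, roiMask, gmMask = ph0$tissue@gm > 0.5,
               affine = spatialAffine(ph0$run))))
    clean0 <- new("CleanSeries", series = flat[, vox0],
                  keptFrames = seq_len(n), tr = 2)
    sm0 <- seedMap(rnorm(n), clean0, vox0, brain, spatialAffine(ph0$run))
    zs <- zMap(sm0)[vox0]
    expect_lt(abs(mean(zs)), 0.03)
    expect_equal(sd(zs), 1 / sqrt(n - 3), tolerance = 0.1)
})

test_that("seed-map z agrees in sign with the ROI-to-ROI record", {
    cfg <- smallPhantomConfig(seed = 51, r = 0.7)
    ph <- makePhantom(cfg)
    gmMask <- ph$tissue@gm > 0.5
    masks <- lapply(cfg@roiSpecs, roiMask, gmMask = gmMask,
                    affine = spatialAffine(ph$run))
    voxels <- sort(unique(unlist(masks)))
    den <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = voxels)
    rts <- lapply(seq_along(masks), function(j)
        roiTimeseries(den$clean, voxels, masks[[j]], c("L", "R")[j]))
    fc <- fcMatrix(rts)
    sm <- seedMap(rts[[1]], den$clean, voxels, gmMask,
                  spatialAffine(ph$run))
    partnerMean <- mean(zMap(sm)[masks[[2]]])
    expect_identical(sign(partnerMean), sign(fc$z[1]))
})

test_that("laterality index follows counts, symmetry and missingness", {
    g <- c(8L, 6L, 6L)
    aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-10.5, -7.5, -7.5)
    mk <- function(zvals) new("SeedMapStats", seedLabel = "s",
                              zmap = zvals, affine = aff, li = NA_real_,
                              lhCount = 0L, rhCount = 0L, qc = list())
    # mirror-symmetric strong map -> LI = 0
    z <- array(0, g); z[2, 3, 3] <- 2; z[7, 3, 3] <- 2
    res <- lateralityIndex(mk(z), df = 100)
    expect_identical(latIndex(res), 0)

    # all suprathreshold on the left -> LI = 1
    z2 <- array(0, g); z2[1:2, 2, 2] <- 2
    expect_identical(latIndex(lateralityIndex(mk(z2), df = 100)), 1)

    # LH = 100, RH = 50 -> 1/3 (pure arithmetic on planted counts)
    z3 <- array(0, g)
    lhIdx <- which(rep(3 * (0:7) - 10.5, times = 36) < 0)
    z3[lhIdx[1:100]] <- 2; z3[setdiff(which(z3 == 0),
                                      lhIdx)[1:50]] <- 2
    res3 <- lateralityIndex(mk(z3), df = 100)
    expect_identical(res3@lhCount, 100L)
    expect_identical(res3@rhCount, 50L)
    expect_equal(latIndex(res3), 1 / 3)

    # negative z excluded under one-sided counting, included two-sided
    z4 <- array(0, g); z4[2, 3, 3] <- -2
    expect_true(is.na(latIndex(lateralityIndex(mk(z4), df = 100))))
    expect_identical(latIndex(lateralityIndex(mk(z4), df = 100,
                                              positiveOnly = FALSE)), 1)

    # nothing suprathreshold -> missing, not zero
    expect_true(is.na(latIndex(lateralityIndex(mk(array(0, g)),
                                               df = 100))))
})
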