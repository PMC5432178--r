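# Denoising: tissue means, nuisance design, regression, band-pass,
# framewise displacement, scrubbing.

test_that("tissue means average exactly the suprathreshold voxels", {
    arr <- array(5, c(3, 3, 3, 4))
    run <- boldRun(arr, diag(4), tr = 2)
    expect_equal(extractTissueMean(run, array(1 - 1e-9, c(3, 3, 3))),
                 rep(5, 4))

    # exactly two voxels above .75 holding series a and b -> (a+b)/2
    arr2 <- array(0, c(3, 3, 3, 4))
    arr2[1, 1, 1, ] <- 1:4
    arr2[2, 1, 1, ] <- c(10, 20, 30, 40)
    map <- array(0.2, c(3, 3, 3))
    map[1, 1, 1] <- 0.9; map[2, 1, 1] <- 0.8
    run2 <- boldRun(arr2, diag(4), tr = 2)
    expect_equal(extractTissueMean(run2, map),
                 (1:4 + c(10, 20, 30, 40)) / 2)
    expect_error(extractTissueMean(run2, array(0.1, c(3, 3, 3)),
                                   tissue = "white matter"),
                 "white matter")

    # phantom WM compartment carries its planted signal
    cfg <- smallPhantomConfig(seed = 11, noiseSd = 0.05, nuisanceGain = 1)
    ph <- makePhantom(cfg)
    wm <- extractTissueMean(ph$run, ph$tissue@wm, 0.75, "white matter")
    # the same compartment extracted from a noise-free clone is the signal
    ph0 <- makePhantom(smallPhantomConfig(seed = 11, noiseSd = 0,
                                          nuisanceGain = 1))
    wm0 <- extractTissueMean(ph0$run, ph0$tissue@wm, 0.75, "white matter")
    expect_gt(cor(wm, wm0), 0.99)
})

test_that("nuisance design has the documented 27-column structure", {
    n <- 20
    motion <- matrix(0, n, 6)
    motion[, 1] <- seq_len(n)            # ramp in tx
    X <- buildNuisanceDesign(motionTrace(motion), rep(0, n), rep(0, n))
    expect_identical(ncol(X), 27L)
    expect_equal(unname(X[, "d_tx"]), c(0, rep(1, n - 1)))
    expect_equal(unname(X[, "tx_sq"]), as.numeric(seq_len(n))^2)
    expect_equal(unname(X[, "d_tx_sq"]), c(0, rep(1, n - 1)))
    expect_true(all(X[1, grep("^d_", colnames(X))] == 0))
    X18 <- buildNuisanceDesign(motionTrace(motion), rep(0, n), rep(0, n),
                               expansion = "derivsq")
    expect_identical(ncol(X18), 21L)
    expect_error(buildNuisanceDesign(motionTrace(motion), rep(0, n - 1),
                                     rep(0, n)), "same frames")
})

test_that("regression annihilates its own span and only that", {
    set.seed(42)
    n <- 60
    motion <- matrix(cumsum(rnorm(n * 6, 0, 0.01)), n, 6)
    wm <- rnorm(n); csf <- rnorm(n)
    X <- buildNuisanceDesign(motionTrace(motion), wm, csf)

    # intercept-only design demeans
    y <- rnorm(n)
    expect_equal(as.vector(regressOut(y, matrix(1, n, 1,
        dimnames = list(NULL, "intercept")))), y - mean(y))

    # a regressor regressed on the design containing it vanishes
    expect_lt(max(abs(regressOut(wm, X))), 1e-8)

    # series built from wm loses more variance than its noise floor
    noise <- rnorm(n, 0, 0.3)
    y2 <- 2 * wm + noise
    expect_lt(var(as.vector(regressOut(y2, X))), var(noise))

    # orthogonality property over random inputs
    for (rep in 1:5) {
        Y <- matrix(rnorm(n * 3), n, 3)
        R <- regressOut(Y, X)
        ip <- crossprod(X, R)
        norms <- outer(sqrt(colSums(X^2)), sqrt(colSums(R^2)))
        expect_lt(max(abs(ip) / pmax(norms, 1e-12)), 1e-8)
    }

    # duplicated columns are reported as collinear
    Xbad <- cbind(X[, 1:3], X[, 1, drop = FALSE])
    colnames(Xbad) <- c("tx", "ty", "tz", "tx_copy")
    expect_error(regressOut(matrix(rnorm(n)), Xbad), "tx_copy")
})

test_that("band-pass keeps 0.05 Hz, rejects DC and 0.2 Hz", {
    n <- 180; tr <- 2
    t <- (0:(n - 1)) * tr
    expect_equal(bandpassFilter(rep(7, n), tr), rep(0, n))

    ampRatio <- function(f) {
        x <- sin(2 * pi * f * t)
        y <- bandpassFilter(x, tr)
        k <- round(f * n * tr) + 1L       # exact FFT bin
        abs(fft(y))[k] / abs(fft(x - mean(x)))[k]
    }
    expect_gte(ampRatio(0.05), 0.9)
    expect_lte(ampRatio(0.2), 0.1)
    y <- bandpassFilter(sin(2 * pi * 0.05 * t), tr)
    expect_lt(abs(mean(y)), 1e-12)
    expect_error(bandpassFilter(rnorm(n), tr, fHi = 0.3), "Nyquist")
})

test_that("framewise displacement matches geometry and dense sampling", {
    # pure translation jump: FD equals the jump norm exactly
    m <- matrix(0, 3, 6); m[2, 1] <- 0.6
    expect_equal(framewiseDisplacement(motionTrace(m)), c(0, 0.6, 0.6))

    # pure rotation about z: ~ radius * angle at the sphere surface
    m2 <- matrix(0, 2, 6); m2[2, 6] <- 0.01
    fd2 <- framewiseDisplacement(motionTrace(m2))[2]
    expect_equal(fd2, 50 * sqrt(2 - 2 * cos(0.01)), tolerance = 1e-9)
    expect_equal(fd2, fdDenseOracle(m2[1, ], m2[2, ]), tolerance = 1e-3)

    # random rigid motions: exact solver vs 10,000-point surface sampling
    set.seed(1)
    for (rep in 1:25) {
        prev <- c(rnorm(3, 0, 0.3), rnorm(3, 0, 0.01))
        cur <- c(rnorm(3, 0, 0.3), rnorm(3, 0, 0.01))
        exact <- framewiseDisplacement(motionTrace(rbind(prev, cur)))[2]
        dense <- fdDenseOracle(prev, cur)
        expect_lt(abs(exact - dense), 1e-3)
        expect_gte(exact, dense - 1e-12)   # sampling can only undershoot
    }

    # exact max-over-sphere dominates the translation-only displacement
    set.seed(2)
    tr6 <- matrix(c(rnorm(30, 0, 0.2), rnorm(30, 0, 0.005)), 10, 6)
    fdS <- framewiseDisplacement(motionTrace(tr6))
    fdT <- c(0, sqrt(rowSums(diff(tr6[, 1:3])^2)))
    expect_true(all(fdS >= fdT - 1e-12))

    # Power-style alternative mode is available and non-negative
    fdP <- framewiseDisplacement(motionTrace(tr6), mode = "power")
    expect_true(all(fdP >= 0) && fdP[1] == 0)
    expect_error(framewiseDisplacement(motionTrace(matrix(0, 1, 6))),
                 "at least 2")
})

test_that("scrubbing applies the strict threshold and the 5-minute rule", {
    series <- matrix(rnorm(180 * 2), 180, 2)
    fd0 <- rep(0, 180)
    res <- censorFrames(series, fd0, tr = 2)
    expect_true(res$pass)
    expect_identical(res$nCensored, 0L)
    expect_equal(res$keptFraction, 1)

    # 31 frames above threshold: 149 x 2 s = 298 s < 300 s -> fail
    fd <- rep(0, 180); fd[10:40] <- 0.6
    res2 <- censorFrames(series, fd, threshold = 0.5, minSeconds = 300,
                         tr = 2)
    expect_identical(nFrames(res2$clean), 149L)
    expect_equal(res2$keptSeconds, 298)
    expect_false(res2$pass)

    # FD exactly at threshold is kept (strict inequality)
    fd3 <- rep(0, 180); fd3[5] <- 0.5
    res3 <- censorFrames(series, fd3, threshold = 0.5, tr = 2)
    expect_identical(res3$nCensored, 0L)

    # censored + kept = total
    expect_identical(res2$nCensored + nFrames(res2$clean), 180L)
})

test_that("denoising is near-transparent on a zero-nuisance phantom", {
    cfg <- smallPhantomConfig(seed = 21, r = 0.6, noiseSd = 0.1,
                              nuisanceGain = 0)
    # the same ROI correlation with and without the denoising stages
    ph <- makePhantom(cfg)
    masks <- lapply(cfg@roiSpecs, roiMask, gmMask = ph$tissue@gm > 0.5,
                    affine = spatialAffine(ph$run))
    voxels <- sort(unique(unlist(masks)))
    den <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = voxels)
    # raw-path correlation on exactly the frames the denoised path kept,
    # so the comparison isolates regression + filtering
    flat <- t(matrix(boldData(ph$run), prod(dim(ph$tissue@gm)), 160))
    keep <- keptFrames(den$clean) + den$qc$droppedInitial
    rawR <- cor(firstEigenvariate(flat[keep, masks[[1]]]),
                firstEigenvariate(flat[keep, masks[[2]]]))
    denoisedR <- cor(
        firstEigenvariate(seriesMatrix(den$clean)[, match(masks[[1]], voxels)]),
        firstEigenvariate(seriesMatrix(den$clean)[, match(masks[[2]], voxels)]))
    expect_lt(abs(denoisedR - rawR), 0.02)
})
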