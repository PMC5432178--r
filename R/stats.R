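#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Normality gate
## ---------------------------------------------------------------------------

.lillieforsD <- function(xs) {
    ## xs: matrix with sorted rows, already standardized per row
    n <- ncol(xs)
    ph <- stats::pnorm(xs)
    i <- matrix(seq_len(n), nrow(xs), n, byrow = TRUE)
    pmax(apply(i / n - ph, 1L, max), apply(ph - (i - 1) / n, 1L, max))
}

#' Lilliefors (Kolmogorov-Smirnov) test of composite normality
#'
#' KS distance between the sample's empirical distribution and a normal
#' with mean and SD estimated from the sample; because the parameters are
#' estimated, the p-value comes from a seeded Monte-Carlo null (standard
#' normal samples of the same size, same statistic). The statistic is
#' location/scale invariant by construction.
#'
#' @param x numeric sample, n >= 5, non-constant.
#' @param nSim Monte-Carlo null size (default 100000).
#' @param seed integer seed for the null draws; `NULL` uses the current
#'   stream.
#' @return A [StatResult-class] with the D statistic and Monte-Carlo p.
#' @export
lillieforsTest <- function(x, nSim = 100000, seed = NULL) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 5L) stop("Lilliefors test needs at least 5 observations")
    s <- stats::sd(x)
    if (s < 1e-12) stop("sample is constant; normality test undefined")
    zs <- matrix(sort((x - mean(x)) / s), 1L)
    D <- .lillieforsD(zs)
    p <- .withSeed(seed, {
        null <- matrix(stats::rnorm(nSim * n), nSim, n)
        null <- matrix(null[order(row(null), null)], nSim, n, byrow = TRUE)
        m <- rowMeans(null)
        sdv <- sqrt(rowSums((null - m)^2) / (n - 1))
        nullD <- .lillieforsD((null - m) / sdv)
        (1 + sum(nullD >= D - 1e-12)) / (nSim + 1)
    })
    statResult("Lilliefors normality test", estimate = NA_real_,
               statistic = D, df = NA_real_, p = p, n = n,
               details = list(nSim = nSim))
}

## ---------------------------------------------------------------------------
## Correlation with exact t-based p
## ---------------------------------------------------------------------------

#' Two-tailed p-value of a correlation coefficient
#'
#' The exact t-based p for a Pearson correlation under bivariate
#' normality: `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom, two-tailed. Also used as the large-sample approximation for
#' Spearman's rho on ranks. A perfect correlation is reported at the
#' machine floor rather than 0.
#'
#' @param r correlation coefficient.
#' @param n sample size (>= 4 for a meaningful test).
#' @return Two-tailed p-value.
#' @examples
#' round(correlationPValue(-0.63, 18), 3)  # 0.005
#' @export
correlationPValue <- function(r, n) {
    stopifnot(n >= 3, abs(r) <= 1)
    if (abs(r) >= 1) return(.Machine$double.xmin)
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    max(2 * stats::pt(-abs(tstat), n - 2), .Machine$double.xmin)
}

#' Correlation test (Pearson or Spearman) with t-based p
#'
#' Pearson r (or Spearman's rho, i.e. Pearson on ranks) with the
#' two-tailed p from [correlationPValue()].
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite, non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [StatResult-class].
#' @export
correlateWithP <- function(x, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (length(x) != length(y)) stop("x and y must have equal length")
    ok <- is.finite(x) & is.finite(y)
    if (!all(ok)) stop("x and y must be finite")
    n <- length(x)
    if (n < 4L) stop("correlation test needs at least 4 pairs")
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
        stop("zero-variance input; correlation undefined")
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    r <- stats::cor(x, y)
    tstat <- if (abs(r) < 1) r * sqrt(n - 2) / sqrt(1 - r^2) else
        sign(r) * Inf
    statResult(sprintf("%s correlation (t approximation)", method),
               estimate = r, statistic = tstat, df = n - 2,
               p = correlationPValue(r, n), n = n)
}

#' Bonferroni adjustment of a family of results
#'
#' Multiplies each p by the family size m and caps at 1; a result is
#' significant when the adjusted p stays at or below `alpha`.
#'
#' @param results a [StatResult-class] or list of them.
#' @param m family size (defaults to the number of results).
#' @param alpha significance level recorded in the details (default .05).
#' @return List of [StatResult-class] with `adjustedP`, `mTests` and a
#'   `significant` flag in the details (a single input returns a single
#'   result).
#' @export
bonferroniAdjust <- function(results, m = NULL, alpha = 0.05) {
    single <- is(results, "StatResult")
    if (single) results <- list(results)
    stopifnot(all(vapply(results, is, TRUE, class2 = "StatResult")))
    if (is.null(m)) m <- length(results)
    stopifnot(m >= 1)
    out <- lapply(results, function(res) {
        res@adjustedP <- min(1, res@p * m)
        res@mTests <- as.numeric(m)
        res@details$significant <- res@adjustedP <= alpha
        validObject(res)
        res
    })
    if (single) out[[1L]] else out
}

## ---------------------------------------------------------------------------
## Permutation test on condition differences of correlation strength
## ---------------------------------------------------------------------------

## columnwise Pearson correlation of two n x P matrices; zero-variance
## columns return NA
.colCor <- function(X, Y) {
    X <- sweep(X, 2L, colMeans(X))
    Y <- sweep(Y, 2L, colMeans(Y))
    den <- sqrt(colSums(X^2) * colSums(Y^2))
    num <- colSums(X * Y)
    ifelse(den > 1e-300, num / den, NA_real_)
}

#' Permutation test for a condition difference in correlation strength
#'
#' Tests whether the across-subject correlation between connectivity and
#' behavior differs between two within-subject conditions (e.g. sham vs
#' real stimulation). The observed statistic is the difference of
#' Fisher-transformed Pearson correlations,
#' `delta = atanh(r_cond1) - atanh(r_cond2)`. The null distribution is
#' built by independently swapping each subject's condition pair with
#' probability 1/2 (the literal "random assignment of condition to
#' individual data"); the two-tailed Monte-Carlo p uses add-one smoothing,
#' `p = (1 + #{|delta*| >= |delta|}) / (nPerm + 1)`. When `2^n <= nPerm`
#' all `2^n` assignments are enumerated instead and the exact unsmoothed
#' proportion is reported. Degenerate permuted samples (zero variance)
#' contribute `delta* = 0` and are counted in the QC details.
#'
#' @param data data.frame (or matrix) with columns `z_cond1`,
#'   `behav_cond1`, `z_cond2`, `behav_cond2`; complete cases only, n >= 4.
#' @param nPerm number of Monte-Carlo draws (default 10000).
#' @param seed integer seed; `NULL` uses the current stream.
#' @param exhaustive `"auto"` (default: enumerate when `2^n <= nPerm`),
#'   `"always"`, or `"never"`.
#' @return A [StatResult-class]; `details` carries `nPerm`, `mode`
#'   (`"exhaustive"` or `"montecarlo"`), the per-condition correlations and
#'   the degenerate-draw count.
#' @export
permCorrDiff <- function(data, nPerm = 10000, seed = NULL,
                         exhaustive = c("auto", "always", "never")) {
    exhaustive <- match.arg(exhaustive)
    data <- as.data.frame(data)
    need <- c("z_cond1", "behav_cond1", "z_cond2", "behav_cond2")
    miss <- setdiff(need, names(data))
    if (length(miss))
        stop("data lacks column(s): ", paste(miss, collapse = ", "))
    data <- data[stats::complete.cases(data[, need]), need]
    n <- nrow(data)
    if (n < 4L) stop("permutation test needs at least 4 complete cases")

    z1 <- data$z_cond1; b1 <- data$behav_cond1
    z2 <- data$z_cond2; b2 <- data$behav_cond2
    if (stats::sd(z1) < 1e-12 || stats::sd(b1) < 1e-12 ||
        stats::sd(z2) < 1e-12 || stats::sd(b2) < 1e-12)
        stop("zero-variance observed sample; correlation difference undefined")
    r1 <- stats::cor(z1, b1)
    r2 <- stats::cor(z2, b2)
    delta <- fisherZ(r1) - fisherZ(r2)

    if (exhaustive == "always" && n > 20L)
        stop("exhaustive enumeration is limited to n <= 20 subjects")
    doExhaustive <- exhaustive == "always" ||
        (exhaustive == "auto" && n <= 20L && 2^n <= nPerm)

    deltaFromSwaps <- function(swap) {
        ## swap: n x P logical matrix; TRUE = subject's pair exchanged
        Z1 <- ifelse(swap, z2, z1); B1 <- ifelse(swap, b2, b1)
        Z2 <- ifelse(swap, z1, z2); B2 <- ifelse(swap, b1, b2)
        ra <- .colCor(Z1, B1); rb <- .colCor(Z2, B2)
        d <- fisherZ(ra) - fisherZ(rb)
        bad <- !is.finite(d)
        d[bad] <- 0
        list(d = d, nDegenerate = sum(bad))
    }

    if (doExhaustive) {
        P <- 2^n
        swap <- vapply(seq_len(P) - 1L,
                       function(m) bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L,
                       logical(n))
        res <- deltaFromSwaps(swap)
        p <- mean(abs(res$d) >= abs(delta) - 1e-12)
        mode <- "exhaustive"
        used <- P
    } else {
        res <- .withSeed(seed, {
            swap <- matrix(stats::runif(n * nPerm) < 0.5, n, nPerm)
            deltaFromSwaps(swap)
        })
        p <- (1 + sum(abs(res$d) >= abs(delta) - 1e-12)) / (nPerm + 1)
        mode <- "montecarlo"
        used <- nPerm
    }
    if (res$nDegenerate > 0)
        warning(sprintf("%d degenerate permutation draw(s) recorded as delta* = 0",
                        res$nDegenerate))
    statResult("permutation test of correlation difference (Fisher z)",
               estimate = delta, statistic = delta, df = NA_real_, p = p,
               n = n,
               details = list(rCond1 = r1, rCond2 = r2, nPerm = used,
                              mode = mode,
                              nDegenerate = res$nDegenerate))
}

## ---------------------------------------------------------------------------
## Repeated-measures ANOVA with sphericity handling
## ---------------------------------------------------------------------------

## orthonormal contrast rows for a k-level within factor ((k-1) x k)
.orthoContrasts <- function(k) {
    C <- stats::contr.helmert(k)
    t(sweep(C, 2L, sqrt(colSums(C^2)), "/"))
}

#' Repeated-measures ANOVA with Mauchly test and Greenhouse-Geisser
#' correction
#'
#' Fully within-subject factorial ANOVA computed from orthonormal
#' within-subject contrasts: for each effect with transformation matrix M
#' (rows orthonormal), the contrast scores `D = Y M'` give
#' `F = [n sum(colMeans(D)^2) / q] / [sum((D - colMeans(D))^2) / (q(n-1))]`
#' on `(q, q(n-1))` degrees of freedom. Sphericity per effect is assessed
#' with Mauchly's W on the covariance of D; when Mauchly's p < .05 the
#' degrees of freedom are multiplied by the Greenhouse-Geisser epsilon
#' `tr(S)^2 / (q tr(S^2))` (Huynh-Feldt is not implemented). Effects whose
#' between-condition variation vanishes entirely report F = 0, p = 1.
#'
#' @param data long-format data.frame with one observation per subject and
#'   cell (complete and balanced; missing cells are rejected, never
#'   imputed).
#' @param dv name of the response column.
#' @param within character vector of within-subject factor column names
#'   (one or two factors).
#' @param subject name of the subject identifier column.
#' @param mauchlyAlpha sphericity-test level gating the correction
#'   (default .05).
#' @return data.frame with one row per effect: effect, df1, df2, F, p,
#'   mauchly_w, mauchly_p, gg_epsilon, gg_applied, df1_corr, df2_corr.
#'   The reported `p` uses the corrected dfs whenever `gg_applied`.
#' @export
rmAnovaGG <- function(data, dv, within, subject = "subject",
                      mauchlyAlpha = 0.05) {
    stopifnot(length(within) %in% 1:2,
              all(c(dv, within, subject) %in% names(data)))
    levs <- lapply(within, function(f) {
        v <- data[[f]]
        if (is.factor(v)) levels(v) else unique(v)
    })
    names(levs) <- within
    subjects <- unique(data[[subject]])
    n <- length(subjects)
    if (n < 3L) stop("repeated-measures ANOVA needs at least 3 subjects")
    nlev <- vapply(levs, length, 1L)
    if (any(nlev < 2L)) stop("each within factor needs at least 2 levels")

    ## wide response matrix, first factor slowest
    cells <- if (length(within) == 2L)
        expand.grid(b = levs[[2]], a = levs[[1]],
                    stringsAsFactors = FALSE)[, c("a", "b")]
    else data.frame(a = levs[[1]], stringsAsFactors = FALSE)
    Y <- matrix(NA_real_, n, nrow(cells))
    key <- do.call(paste, c(lapply(within, function(f) data[[f]]),
                            sep = "\r"))
    cellKey <- do.call(paste, c(unname(as.list(cells)), sep = "\r"))
    for (j in seq_len(nrow(cells))) {
        sub <- data[key == cellKey[j], ]
        v <- sub[[dv]][match(subjects, sub[[subject]])]
        Y[, j] <- v
    }
    if (anyNA(Y))
        stop("design is incomplete: every subject needs exactly one value per cell")

    effects <- list()
    Ca <- .orthoContrasts(nlev[1])
    if (length(within) == 1L) {
        effects[[within[1]]] <- Ca
    } else {
        Cb <- .orthoContrasts(nlev[2])
        ja <- matrix(1 / sqrt(nlev[1]), 1L, nlev[1])
        jb <- matrix(1 / sqrt(nlev[2]), 1L, nlev[2])
        effects[[within[1]]] <- kronecker(Ca, jb)
        effects[[within[2]]] <- kronecker(ja, Cb)
        effects[[paste(within, collapse = ":")]] <- kronecker(Ca, Cb)
    }

    scale <- mean(Y^2) + 1
    rows <- lapply(names(effects), function(nm) {
        M <- effects[[nm]]
        q <- nrow(M)
        D <- Y %*% t(M)
        dbar <- colMeans(D)
        ssEff <- n * sum(dbar^2)
        Dc <- sweep(D, 2L, dbar)
        ssErr <- sum(Dc^2)
        df1 <- q
        df2 <- q * (n - 1)
        if (ssEff <= 1e-12 * scale) {
            Fv <- 0; df1c <- df1; df2c <- df2
            W <- NA_real_; Wp <- NA_real_; eps <- NA_real_; applied <- FALSE
            p <- 1
        } else {
            Fv <- (ssEff / df1) / (ssErr / df2)
            S <- crossprod(Dc) / (n - 1)
            eps <- if (q == 1L) 1 else
                sum(diag(S))^2 / (q * sum(S * S))
            if (q == 1L || n - 1 <= q) {
                W <- NA_real_; Wp <- NA_real_
            } else {
                W <- det(S) / (sum(diag(S)) / q)^q
                if (!is.finite(W) || W <= 0) {
                    W <- NA_real_; Wp <- NA_real_
                } else {
                    ## Mauchly's chi-square approximation with the
                    ## second-order correction term
                    f <- q * (q + 1) / 2 - 1
                    rho <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
                    chi <- -(n - 1) * rho * log(W)
                    w2 <- (q + 2) * (q - 1) * (q - 2) *
                        (2 * q^3 + 6 * q^2 + 3 * q + 2) /
                        (288 * q^2 * (n - 1)^2 * rho^2)
                    p1 <- stats::pchisq(chi, f, lower.tail = FALSE)
                    Wp <- min(1, max(0, p1 +
                        w2 * (stats::pchisq(chi, f + 4,
                                            lower.tail = FALSE) - p1)))
                }
            }
            applied <- !is.na(Wp) && Wp < mauchlyAlpha
            df1c <- if (applied) eps * df1 else df1
            df2c <- if (applied) eps * df2 else df2
            p <- if (is.finite(Fv)) stats::pf(Fv, df1c, df2c,
                                              lower.tail = FALSE) else 0
        }
        data.frame(effect = nm, df1 = df1, df2 = df2, F = Fv, p = p,
                   mauchly_w = W, mauchly_p = Wp, gg_epsilon = eps,
                   gg_applied = applied, df1_corr = df1c, df2_corr = df2c,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "n") <- n
    out
}

## ---------------------------------------------------------------------------
## Paired tests
## ---------------------------------------------------------------------------

## exact null of the signed-rank statistic with tied ranks, via
## convolution on doubled ranks
.signedRankExactP <- function(d) {
    r2 <- round(2 * rank(abs(d)))
    W2 <- sum(r2[d > 0])
    tot <- sum(r2)
    f <- c(1, rep(0, tot))           # counts over W2 = 0..tot
    for (r in r2) {
        shifted <- c(rep(0, r), f[seq_len(length(f) - r)])
        f <- f + shifted
    }
    f <- f / 2^length(d)
    pLe <- sum(f[seq_len(W2 + 1L)])
    pGe <- sum(f[(W2 + 1L):length(f)])
    min(1, 2 * min(pLe, pGe))
}

#' Paired comparison: t-test or Wilcoxon signed-rank
#'
#' `method = "t"`: the standard two-tailed paired t-test (identical pairs
#' report t = 0, p = 1 rather than failing on zero variance).
#' `method = "wilcoxon"`: zero differences are dropped (signed-rank
#' convention); the null is exact — tied ranks handled by convolution —
#' for up to 25 non-zero differences, and the normal approximation with
#' continuity correction beyond that.
#'
#' @param x,y paired numeric vectors; n >= 3 for t, n >= 5 for wilcoxon.
#' @param method `"t"` or `"wilcoxon"`.
#' @return A [StatResult-class].
#' @export
pairedTests <- function(x, y, method = c("t", "wilcoxon")) {
    method <- match.arg(method)
    if (length(x) != length(y)) stop("x and y must be paired")
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    d <- x - y
    n <- length(d)
    if (method == "t") {
        if (n < 3L) stop("paired t-test needs at least 3 pairs")
        if (stats::sd(d) < 1e-12) {
            est <- mean(d)
            if (abs(est) < 1e-12)
                return(statResult("paired t-test", estimate = 0,
                                  statistic = 0, df = n - 1, p = 1, n = n))
            return(statResult("paired t-test", estimate = est,
                              statistic = sign(est) * Inf, df = n - 1,
                              p = .Machine$double.xmin, n = n))
        }
        ht <- stats::t.test(x, y, paired = TRUE)
        statResult("paired t-test", estimate = unname(ht$estimate),
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value, n = n)
    } else {
        if (n < 5L) stop("Wilcoxon signed-rank test needs at least 5 pairs")
        dnz <- d[abs(d) > 1e-12]
        if (!length(dnz))
            stop("all paired differences are zero; signed-rank test undefined")
        V <- sum(rank(abs(dnz))[dnz > 0])
        if (length(dnz) <= 25L) {
            p <- .signedRankExactP(dnz)
            details <- list(exact = TRUE)
        } else {
            ht <- suppressWarnings(stats::wilcox.test(dnz, exact = FALSE,
                                                      correct = TRUE))
            p <- ht$p.value
            details <- list(exact = FALSE)
        }
        statResult("Wilcoxon signed-rank test", estimate = stats::median(d),
                   statistic = V, df = NA_real_, p = p, n = n,
                   details = details)
    }
}
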