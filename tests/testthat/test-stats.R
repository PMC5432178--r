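# Inferential layer: Lilliefors, correlation tests, Bonferroni,
# permutation test, repeated-measures ANOVA, paired tests.

test_that("Lilliefors statistic matches the reference implementation", {
    skip_if_not_installed("nortest")
    set.seed(5)
    for (n in c(10, 19, 40)) {
        x <- rexp(n)
        mine <- lillieforsTest(x, nSim = 20000, seed = 1)
        ref <- nortest::lillie.test(x)
        expect_equal(mine@statistic, unname(ref$statistic),
                     tolerance = 1e-10)
        # Monte-Carlo p agrees with nortest's analytic approximation
        expect_lt(abs(pValue(mine) - ref$p.value), 0.05)
    }
})

test_that("Lilliefors test is calibrated, powered and scale-invariant", {
    reject <- vapply(1:400, function(i) {
        set.seed(1000 + i)
        pValue(lillieforsTest(rnorm(20), nSim = 600, seed = 2000 + i)) < 0.05
    }, logical(1))
    se <- sqrt(0.05 * 0.95 / 400)
    expect_gt(mean(reject), 0.05 - 3 * se)
    expect_lt(mean(reject), 0.05 + 3 * se)

    # power against a skewed alternative at the study's n
    power <- vapply(1:150, function(i) {
        set.seed(i)
        pValue(lillieforsTest(rexp(19), nSim = 600, seed = 300 + i)) < 0.05
    }, logical(1))
    expect_gt(mean(power), 0.4)

    # location/scale invariance of the statistic
    set.seed(9); x <- rgamma(25, 2)
    expect_equal(lillieforsTest(x, nSim = 10, seed = 1)@statistic,
                 lillieforsTest(100 + 7 * x, nSim = 10, seed = 1)@statistic,
                 tolerance = 1e-12)

    expect_error(lillieforsTest(rep(1, 10)), "constant")
    expect_error(lillieforsTest(rnorm(4)), "at least 5")
})

test_that("correlation p-values reproduce the published Table 1 values", {
    expect_equal(round(correlationPValue(-0.63, 18), 3), 0.005)
    expect_equal(round(correlationPValue(-0.46, 18), 3), 0.055)
    expect_equal(round(correlationPValue(-0.59, 18), 3), 0.010)
    expect_equal(round(correlationPValue(0.03, 18), 3), 0.906,
                 tolerance = 0.02)

    # perfect correlation: p at the floor, no crash
    x <- rnorm(10)
    res <- correlateWithP(x, x)
    expect_equal(estimateValue(res), 1)
    expect_lte(pValue(res), .Machine$double.xmin)

    # spearman path works on monotone data
    set.seed(2); y <- exp(x) + rnorm(10, 0, 0.1)
    rs <- correlateWithP(x, y, method = "spearman")
    expect_gt(estimateValue(rs), 0.8)

    expect_error(correlateWithP(rnorm(3), rnorm(3)), "at least 4")
    expect_error(correlateWithP(rep(1, 8), rnorm(8)), "zero-variance")
})

test_that("analytic correlation p agrees with a permutation oracle", {
    set.seed(12)
    n <- 20
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    pAna <- pValue(correlateWithP(x, y))
    robs <- abs(cor(x, y))
    set.seed(13)
    pPerm <- mean(vapply(1:10000, function(i)
        abs(cor(x, sample(y))) >= robs - 1e-12, logical(1)))
    expect_lt(abs(pAna - pPerm), 0.02)
})

test_that("Bonferroni control is multiplicative, capped and monotone", {
    r1 <- bonferroniAdjust(correlateWithP(rnorm(18),
                                          rnorm(18)), m = 6)
    expect_equal(adjustedPValue(r1), min(1, pValue(r1) * 6))

    mk <- function(p) new("StatResult", method = "m", estimate = 0,
                          statistic = 0, df = 1, p = p, n = 10,
                          adjustedP = NA_real_, mTests = NA_real_,
                          details = list())
    out <- bonferroniAdjust(list(mk(0.005), mk(0.010), mk(0.5)), m = 6)
    expect_equal(vapply(out, adjustedPValue, 1), c(0.03, 0.06, 1))
    expect_true(out[[1]]@details$significant)     # the starred cell
    expect_false(out[[2]]@details$significant)    # does not survive
    # never decreases p; monotone in m
    expect_true(all(vapply(out, adjustedPValue, 1) >=
                        vapply(out, pValue, 1)))
    expect_lte(adjustedPValue(bonferroniAdjust(mk(0.01), m = 3)),
               adjustedPValue(bonferroniAdjust(mk(0.01), m = 6)))
})

test_that("permutation test matches exhaustive enumeration and identities", {
    set.seed(21)
    toy <- data.frame(z_cond1 = rnorm(5), behav_cond1 = rnorm(5),
                      z_cond2 = rnorm(5), behav_cond2 = rnorm(5))
    pe <- permCorrDiff(toy, exhaustive = "always")
    expect_identical(pe@details$mode, "exhaustive")
    expect_identical(pe@details$nPerm, 32)
    pm <- permCorrDiff(toy, nPerm = 10000, seed = 3, exhaustive = "never")
    expect_lt(abs(pValue(pe) - pValue(pm)), 0.02)

    # auto mode enumerates when 2^n <= nPerm
    expect_identical(permCorrDiff(toy, nPerm = 10000)@details$mode,
                     "exhaustive")

    # identical conditions: delta = 0, p = 1
    idd <- data.frame(z_cond1 = rnorm(6), behav_cond1 = rnorm(6))
    idd$z_cond2 <- idd$z_cond1; idd$behav_cond2 <- idd$behav_cond1
    resId <- permCorrDiff(idd, seed = 1)
    expect_equal(estimateValue(resId), 0)
    expect_equal(pValue(resId), 1)

    # invariance to affine rescaling applied to both conditions' behavior
    sc <- toy
    sc$behav_cond1 <- 3 + 10 * sc$behav_cond1
    sc$behav_cond2 <- 3 + 10 * sc$behav_cond2
    expect_equal(pValue(permCorrDiff(sc, exhaustive = "always")),
                 pValue(pe))

    expect_error(permCorrDiff(toy[1:3, ]), "at least 4")
})

test_that("repeated-measures ANOVA matches aov and car on random data", {
    skip_if_not_installed("car")
    set.seed(42)
    n <- 12; A <- c("a1", "a2", "a3"); B <- c("b1", "b2", "b3", "b4")
    d <- expand.grid(subject = sprintf("s%02d", 1:n), site = A, cond = B,
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d)) + rep(rnorm(n), times = 12) +
        ifelse(d$cond == "b4", 1.5, 0)
    res <- rmAnovaGG(d, "value", c("site", "cond"))

    fit <- aov(value ~ site * cond + Error(subject / (site * cond)),
               data = d)
    s <- summary(fit)
    expect_equal(res$F[res$effect == "site"],
                 s[["Error: subject:site"]][[1]]$F[1], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "cond"],
                 s[["Error: subject:cond"]][[1]]$F[1], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "site:cond"],
                 s[["Error: subject:site:cond"]][[1]]$F[1],
                 tolerance = 1e-8)

    # car: GG epsilon and Mauchly per effect
    Y <- matrix(NA_real_, n, 12)
    cells <- as.vector(t(outer(A, B, paste, sep = "_")))
    key <- paste(d$site, d$cond, sep = "_")
    for (j in seq_along(cells)) {
        sub <- d[key == cells[j], ]
        Y[, j] <- sub$value[match(sprintf("s%02d", 1:n), sub$subject)]
    }
    idata <- expand.grid(cond = factor(B), site = factor(A))[,
                                                             c("site", "cond")]
    av <- suppressWarnings(
        summary(car::Anova(lm(Y ~ 1), idata = idata,
                           idesign = ~ site * cond, type = 3),
                multivariate = FALSE))
    gg <- av$pval.adjustments[, "GG eps"]
    expect_equal(res$gg_epsilon, unname(gg[c("site", "cond", "site:cond")]),
                 tolerance = 1e-8)
    mau <- av$sphericity.tests[, "p-value"]
    expect_equal(res$mauchly_p, unname(mau[c("site", "cond", "site:cond")]),
                 tolerance = 1e-3)
})

test_that("repeated-measures ANOVA handles degenerate and 2-level designs", {
    n <- 8
    d <- expand.grid(subject = sprintf("s%d", 1:n), site = c("x", "y"),
                     cond = c("p", "q", "r"), stringsAsFactors = FALSE)
    # all cells equal (per subject): F = 0, p = 1 everywhere
    d$value <- rep(rnorm(n), times = 6)
    res <- rmAnovaGG(d, "value", c("site", "cond"))
    expect_equal(res$F, c(0, 0, 0))
    expect_equal(res$p, c(1, 1, 1))

    # 2-level factor: sphericity trivially satisfied, epsilon = 1
    set.seed(77)
    d$value <- rnorm(nrow(d)) + ifelse(d$site == "y", 1, 0)
    res2 <- rmAnovaGG(d, "value", c("site", "cond"))
    expect_equal(res2$gg_epsilon[res2$effect == "site"], 1)
    expect_false(res2$gg_applied[res2$effect == "site"])
    # with epsilon 1 the corrected dfs equal the uncorrected
    expect_equal(res2$df1_corr[1], res2$df1[1])
    expect_equal(pf(res2$F[1], res2$df1[1], res2$df2[1],
                    lower.tail = FALSE), res2$p[1])

    # incomplete design is rejected, not imputed
    expect_error(rmAnovaGG(d[-1, ], "value", c("site", "cond")),
                 "incomplete")
})

test_that("simulated cohorts show a condition effect but no site effect", {
    coh <- makeCohort(cohortConfig(nSubjects = 14, seed = 9))
    beh <- summarizeConditions(cleanTrials(coh$trials)$trials, coh$trials)
    long <- do.call(rbind, lapply(
        c("expected", "unexpected", "anomalous", "pseudoword"),
        function(cond) data.frame(subject = beh$subject,
                                  site = beh$session, cond = cond,
                                  value = beh[[paste0("mean_rt_", cond)]])))
    res <- rmAnovaGG(long, "value", c("site", "cond"))
    expect_lt(res$p[res$effect == "cond"], 0.001)
    expect_gt(res$p[res$effect == "site"], 0.05)
})

test_that("paired tests handle identities, shifts and tied ranks exactly", {
    x <- c(1.2, 0.8, 1.5, 1.1, 0.9)
    resT <- pairedTests(x, x, "t")
    expect_equal(resT@statistic, 0)
    expect_equal(pValue(resT), 1)

    # {1..6} vs {2..7}: all differences -1 (fully tied); exact sign-flip
    # null gives 2/64
    resW <- pairedTests(1:6, 2:7, "wilcoxon")
    expect_equal(pValue(resW), 2 / 64)

    # tie-free data agrees with the reference exact distribution
    set.seed(3)
    a <- rnorm(12); b <- rnorm(12) + 0.8
    expect_equal(pValue(pairedTests(a, b, "wilcoxon")),
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(pValue(pairedTests(a, b, "t")),
                 t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)

    # large-n path switches to the corrected normal approximation
    set.seed(4)
    a2 <- rnorm(30); b2 <- rnorm(30) + 0.3
    res30 <- pairedTests(a2, b2, "wilcoxon")
    expect_false(res30@details$exact)
    expect_equal(pValue(res30),
                 suppressWarnings(wilcox.test(a2 - b2, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-12)

    expect_error(pairedTests(1:2, 2:3, "t"), "at least 3")
    expect_error(pairedTests(1:4, 2:5, "wilcoxon"), "at least 5")
    expect_error(pairedTests(x, x, "wilcoxon"), "zero")
})
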