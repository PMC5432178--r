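#' @include AllClasses.R phantom.R
NULL

#' Generate a synthetic behavioral cohort with planted connectivity coupling
#'
#' Simulates trial-level lexical-decision data per subject and session
#' (multiplicative subject speed factor, additive within-cell RT noise,
#' Bernoulli errors) and, per session, a set of ROI-pair Fisher-z values.
#' The coupled pair's z is generated conditionally on the standardized
#' realized normalized-RT measure
#' (`z = zMean + zSd (rho s + sqrt(1 - rho^2) eps)` with `s` the
#' standardized measure), so its across-subject Pearson correlation with
#' that measure targets the configured `behaviorConnectivityR` exactly in
#' population, without touching the RT marginals.
#'
#' @param config a [CohortConfig-class].
#' @return List with components `trials` (data.frame: subject, session,
#'   trial, condition, rt_ms, correct), `connectivity` (data.frame:
#'   subject, session, roi_a, roi_b, z) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' coh <- makeCohort(cohortConfig(nSubjects = 6, seed = 3))
#' head(coh$trials)
#' @export
makeCohort <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    n <- config@nSubjects
    conds <- c("expected", "unexpected", "anomalous", "pseudoword")
    counts <- config@trialCounts[conds]
    mus <- config@conditionMeanRts[conds]

    .withSeed(config@seed, {
        speed <- stats::rlnorm(n, 0, config@speedSdLog)
        subjects <- sprintf("S%02d", seq_len(n))

        trialsPerSession <- sum(counts)
        condVec <- rep(conds, counts)
        pairs <- t(utils::combn(config@roiLabels, 2L))

        allTrials <- vector("list", length(config@sessions))
        allConn <- vector("list", length(config@sessions))
        for (si in seq_along(config@sessions)) {
            sess <- config@sessions[si]
            rt <- matrix(0, trialsPerSession, n)
            for (s in seq_len(n))
                rt[, s] <- speed[s] *
                    pmax(50, mus[condVec] +
                             stats::rnorm(trialsPerSession, 0, config@rtSd))
            correct <- matrix(stats::rbinom(trialsPerSession * n, 1L,
                                            1 - config@errorRate) == 1L,
                              trialsPerSession, n)
            trials <- data.frame(
                subject = rep(subjects, each = trialsPerSession),
                session = sess,
                trial = rep(seq_len(trialsPerSession), n),
                condition = rep(condVec, n),
                rt_ms = as.vector(rt),
                correct = as.vector(correct),
                stringsAsFactors = FALSE)

            ## coupled normalized-RT measure, computed with the package's
            ## own behavior path so the planted correlation refers to what
            ## the analysis actually measures
            cleaned <- cleanTrials(trials)$trials
            summ <- normalizeRts(summarizeConditions(cleaned, trials))
            meas <- summ[[paste0("norm_rt_", config@coupledMeasure)]]
            names(meas) <- summ$subject
            meas <- meas[subjects]

            rho <- if (sess %in% names(config@behaviorConnectivityR))
                unname(config@behaviorConnectivityR[sess]) else 0
            scores <- as.vector(scale(meas))
            zc <- config@zMean + config@zSd *
                (rho * scores + sqrt(1 - rho^2) * stats::rnorm(n))

            conn <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
                coupled <- setequal(pairs[p, ], config@coupledPair)
                data.frame(subject = subjects, session = sess,
                           roi_a = pairs[p, 1], roi_b = pairs[p, 2],
                           z = if (coupled) zc else
                               config@zMean + config@zSd * stats::rnorm(n),
                           stringsAsFactors = FALSE)
            }))
            allTrials[[si]] <- trials
            allConn[[si]] <- conn
        }

        effect <- rep(0, length(config@sessions))
        names(effect) <- config@sessions
        effect[names(config@behaviorConnectivityR)] <-
            config@behaviorConnectivityR
        truth <- new("SyntheticTruth",
                     trueRoiCorrelations = matrix(numeric(0), 0, 0),
                     trueBehaviorEffect = effect,
                     spikeFrames = integer(0))
        list(trials = do.call(rbind, allTrials),
             connectivity = do.call(rbind, allConn),
             truth = truth)
    })
}
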