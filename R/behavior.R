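#' @include AllClasses.R
NULL

.checkTrialTable <- function(trials) {
    need <- c("subject", "session", "condition", "rt_ms", "correct")
    miss <- setdiff(need, names(trials))
    if (length(miss))
        stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(trials$condition),
                   c("expected", "unexpected", "anomalous", "pseudoword"))
    if (length(bad))
        stop("unknown condition(s): ", paste(bad, collapse = ", "))
    invisible(trials)
}

#' Clean trial-level lexical-decision data
#'
#' Two-step, single-pass cleaning: incorrect (or unanswered) trials are
#' removed first; then, within each cell, correct trials with
#' `rt > mean + outlierSd * sd` (mean and sd of that cell's correct trials,
#' strict inequality) are removed. The cutoff is NOT recomputed after
#' removal. A cell is the subject x session x condition combination by
#' default; `outlierScope = "session"` pools conditions within a session
#' when computing cutoffs.
#'
#' @param trials data.frame with columns subject, session, condition,
#'   rt_ms, correct.
#' @param outlierSd cutoff in standard deviations (default 2).
#' @param outlierScope `"cell"` (default) or `"session"`.
#' @return List with `trials` (the cleaned table) and `report`
#'   (`nIncorrectRemoved`, `nOutlierRemoved`, `nTotal`).
#' @export
cleanTrials <- function(trials, outlierSd = 2,
                        outlierScope = c("cell", "session")) {
    outlierScope <- match.arg(outlierScope)
    .checkTrialTable(trials)
    answered <- !is.na(trials$rt_ms) & trials$rt_ms > 0
    ok <- trials$correct & answered
    correct <- trials[ok, , drop = FALSE]

    key <- if (outlierScope == "cell")
        interaction(correct$subject, correct$session, correct$condition,
                    drop = TRUE)
    else interaction(correct$subject, correct$session, drop = TRUE)
    mu <- tapply(correct$rt_ms, key, mean)
    sdv <- tapply(correct$rt_ms, key, stats::sd)
    sdv[is.na(sdv)] <- 0           # single-trial cells: no spread, keep
    cutoff <- mu[key] + outlierSd * sdv[key]
    keep <- correct$rt_ms <= cutoff

    cleaned <- correct[keep, , drop = FALSE]
    cells <- interaction(trials$subject, trials$session, trials$condition,
                         drop = TRUE)
    left <- interaction(cleaned$subject, cleaned$session, cleaned$condition,
                        drop = TRUE)
    empty <- setdiff(levels(cells), unique(as.character(left)))
    if (length(empty))
        stop("cleaning emptied cell(s): ", paste(empty, collapse = ", "))
    list(trials = cleaned,
         report = list(nIncorrectRemoved = sum(!ok),
                       nOutlierRemoved = sum(!keep),
                       nTotal = nrow(trials)))
}

#' Per-condition mean RTs and error rates per subject and session
#'
#' Mean RTs come from the cleaned table; error rates are computed on the
#' raw (pre-cleaning) table — an incorrect or unanswered trial counts
#' against all trials presented in its cell, so cleaning never shrinks the
#' error denominator.
#'
#' @param trials cleaned trial table (from [cleanTrials()]).
#' @param raw the original trial table; defaults to `trials` (valid only
#'   when nothing was removed).
#' @return data.frame with one row per subject x session and columns
#'   `mean_rt_<condition>` and `error_rate_<condition>`.
#' @export
summarizeConditions <- function(trials, raw = trials) {
    .checkTrialTable(trials)
    .checkTrialTable(raw)
    conds <- c("expected", "unexpected", "anomalous", "pseudoword")
    keys <- unique(trials[, c("subject", "session")])
    keys <- keys[order(keys$subject, keys$session), , drop = FALSE]
    out <- keys
    rownames(out) <- NULL
    for (cond in conds) {
        sub <- trials[trials$condition == cond, , drop = FALSE]
        if (!nrow(sub))
            stop(sprintf("condition '%s' is missing from the trial table",
                         cond))
        mu <- tapply(sub$rt_ms,
                     interaction(sub$subject, sub$session, drop = FALSE),
                     mean)
        key <- interaction(out$subject, out$session)
        if (anyNA(mu[as.character(key)]))
            stop(sprintf("condition '%s' is missing for some subject-session",
                         cond))
        out[[paste0("mean_rt_", cond)]] <- as.numeric(mu[as.character(key)])
        rsub <- raw[raw$condition == cond, , drop = FALSE]
        err <- tapply(!(rsub$correct & !is.na(rsub$rt_ms) & rsub$rt_ms > 0),
                      interaction(rsub$subject, rsub$session, drop = FALSE),
                      mean)
        out[[paste0("error_rate_", cond)]] <-
            as.numeric(err[as.character(key)])
    }
    out
}

#' Normalized reaction-time ratios
#'
#' Divides each non-expected condition's mean RT by the expected-condition
#' mean of the same subject and session, removing subject-general speed:
#' `norm_rt_unexpected = mean_rt_unexpected / mean_rt_expected`, etc.
#'
#' @param summary data.frame from [summarizeConditions()].
#' @return The input with `norm_rt_unexpected`, `norm_rt_anomalous`,
#'   `norm_rt_pseudoword` columns appended.
#' @export
normalizeRts <- function(summary) {
    if (!"mean_rt_expected" %in% names(summary))
        stop("summary lacks mean_rt_expected")
    if (any(summary$mean_rt_expected <= 0))
        stop("expected-condition mean RT must be positive")
    for (cond in c("unexpected", "anomalous", "pseudoword"))
        summary[[paste0("norm_rt_", cond)]] <-
            summary[[paste0("mean_rt_", cond)]] / summary$mean_rt_expected
    summary
}
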