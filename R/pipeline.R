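#' @include AllClasses.R phantom.R cohort.R preprocess.R connectivity.R
#' @include behavior.R stats.R
NULL

.defaultRunConfig <- function() list(
    seed = 1L,
    subjects = 6L,
    sessions = c("sham", "aifg", "pmtg"),
    imaging = TRUE,
    rois = NULL,                    # NULL = phantom defaults
    phantom = list(),               # overrides for phantomConfig()
    cohort = list(),                # overrides for cohortConfig()
    motion_spikes = list(),         # list of (subject, session, frame, magnitude)
    preprocess = list(fd_threshold = 0.5, min_seconds = 300,
                      band = c(0.01, 0.08), drop_initial = 4L,
                      wm_prob = 0.75, csf_prob = 0.75, fd_radius = 50),
    stats = list(n_perm = 10000L, bonferroni_m = 6L, alpha = 0.05,
                 normality_alpha = 0.05, lilliefors_sims = 2000L)
)

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
            !is.null(names(base[[nm]])))
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration and fills unset fields with the study-default
#' parameters (FD threshold .5 mm, 5-minute rule, 0.01-0.08 Hz band, 7 mm
#' ROI spheres, 2 SD outlier cut, 10,000 permutations, Bonferroni family 6).
#'
#' @param path YAML file path, or a list to merge over the defaults.
#' @return Named configuration list.
#' @export
readRunConfig <- function(path) {
    user <- if (is.character(path)) yaml::read_yaml(path) else
        if (is.list(path)) path else stop("path must be a file or a list")
    cfg <- .mergeConfig(.defaultRunConfig(), user)
    cfg$seed <- as.integer(cfg$seed)
    if (!length(cfg$seed) || is.na(cfg$seed))
        stop("config must set an integer seed")
    if (!is.null(cfg$rois) && length(cfg$rois)) {
        cfg$rois <- lapply(cfg$rois, function(r) {
            if (is(r, "RoiSpec")) return(r)
            center <- if (!is.null(r$center)) unlist(r$center) else
                c(r$x, if (!is.null(r$y)) r$y else r[["TRUE"]], r$z)
            roiSpec(r$label, center,
                    if (is.null(r$radius)) 7 else r$radius)
        })
    }
    cfg
}

.configHash <- function(cfg) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(yaml::as.yaml(cfg[order(names(cfg))]), f)
    unname(tools::md5sum(f))
}

## imaging stage for one subject-session; returns connectivity rows + QC
.imageOneRun <- function(cfg, subject, session, rois) {
    pcArgs <- cfg$phantom
    pcArgs$seed <- childSeed(cfg$seed, "phantom", subject, session)
    spikes <- Filter(function(s) s$subject == subject &&
                                 s$session == session, cfg$motion_spikes)
    if (length(spikes))
        pcArgs$spikes <- lapply(spikes, function(s) c(s$frame, s$magnitude))
    if (!is.null(rois)) pcArgs$roiSpecs <- rois
    if (!is.null(pcArgs$roiSpecs) && is.null(pcArgs$roiCovariance)) {
        ## equicorrelated planted signals when the config names its own ROIs
        k <- length(pcArgs$roiSpecs)
        r <- if (is.null(pcArgs$roiR)) 0.5 else pcArgs$roiR
        pcArgs$roiCovariance <- matrix(r, k, k) + diag(1 - r, k)
    }
    pcArgs$roiR <- NULL
    pc <- do.call(phantomConfig, pcArgs)
    ph <- makePhantom(pc)

    pp <- cfg$preprocess
    gmMask <- ph$tissue@gm > 0.5
    masks <- lapply(pc@roiSpecs, roiMask, gmMask = gmMask,
                    affine = ph$run@affine)
    voxels <- sort(unique(unlist(masks)))
    den <- denoiseRun(ph$run, ph$tissue, ph$motion, voxels = voxels,
                      dropInitial = pp$drop_initial, wmProb = pp$wm_prob,
                      csfProb = pp$csf_prob, band = pp$band,
                      fdThreshold = pp$fd_threshold,
                      minSeconds = pp$min_seconds, fdRadius = pp$fd_radius)
    qc <- data.frame(subject = subject, session = session,
                     n_frames = den$qc$nFrames,
                     n_censored = den$qc$nCensored,
                     n_kept = den$qc$nFrames - den$qc$nCensored,
                     kept_seconds = den$qc$keptSeconds,
                     excluded = !den$pass,
                     rule = if (den$pass) "" else
                         sprintf("kept time %gs < %gs minimum",
                                 den$qc$keptSeconds, pp$min_seconds),
                     stringsAsFactors = FALSE)
    if (!den$pass) return(list(connectivity = NULL, qc = qc))
    rts <- lapply(seq_along(masks), function(j)
        roiTimeseries(den$clean, voxels, masks[[j]], pc@roiSpecs[[j]]@label))
    conn <- fcMatrix(rts)
    conn <- cbind(data.frame(subject = subject, session = session,
                             stringsAsFactors = FALSE), conn)
    list(connectivity = conn, qc = qc)
}

.pairZ <- function(conn, pair) {
    sel <- (conn$roi_a == pair[1] & conn$roi_b == pair[2]) |
           (conn$roi_a == pair[2] & conn$roi_b == pair[1])
    conn[sel, c("subject", "session", "z")]
}

.statResultRow <- function(res, family = NA_character_, label = NA_character_)
    data.frame(family = family, label = label, method = res@method,
               estimate = res@estimate, statistic = res@statistic,
               df = res@df, p = res@p, adjusted_p = res@adjustedP,
               m_tests = res@mTests, n = res@n, stringsAsFactors = FALSE)

#' Run the full simulate - preprocess - connect - behave - infer pipeline
#'
#' Deterministic given (config, seed): simulates a cohort (and, in imaging
#' mode, a BOLD phantom per subject and session that is denoised, scrubbed
#' and reduced to ROI-pair Fisher-z values), cleans and summarizes the
#' behavioral trials, then runs the inferential layer: connectivity-behavior
#' correlations for the reference (first) session with a Lilliefors
#' normality gate (any non-normal variable switches the family to
#' Spearman) and Bonferroni control, plus a permutation test of the
#' correlation-strength difference between the reference session and each
#' stimulation session. Subject-sessions failing the minimum-duration rule
#' are excluded and named in the QC report.
#'
#' @param config configuration list or YAML path (see [readRunConfig()]).
#' @return A results bundle: list with `connectivity`, `behavior`,
#'   `stats` (correlations + permutation tables), `qc` and `provenance`.
#' @export
runPipeline <- function(config) {
    cfg <- readRunConfig(config)
    sessions <- cfg$sessions
    subjects <- sprintf("S%02d", seq_len(cfg$subjects))

    ## --- simulate behavior (and coupled z in cohort mode) ---------------
    coArgs <- cfg$cohort
    coArgs$nSubjects <- cfg$subjects
    coArgs$sessions <- sessions
    coArgs$seed <- childSeed(cfg$seed, "cohort")
    co <- do.call(cohortConfig, coArgs)
    cohort <- makeCohort(co)

    ## --- connectivity: imaging phantoms or cohort-coupled z -------------
    qc <- NULL
    if (isTRUE(cfg$imaging)) {
        runs <- list()
        for (subject in subjects)
            for (session in sessions)
                runs[[paste(subject, session)]] <-
                    .imageOneRun(cfg, subject, session, cfg$rois)
        connectivity <- do.call(rbind, c(lapply(runs, `[[`, "connectivity"),
                                         list(make.row.names = FALSE)))
        qc <- do.call(rbind, c(lapply(runs, `[[`, "qc"),
                               list(make.row.names = FALSE)))
    } else {
        connectivity <- cohort$connectivity
        qc <- data.frame(subject = character(0), session = character(0))
    }

    ## --- behavior --------------------------------------------------------
    cleaned <- cleanTrials(cohort$trials)
    behavior <- normalizeRts(summarizeConditions(cleaned$trials,
                                                 cohort$trials))

    ## --- stats -----------------------------------------------------------
    st <- cfg$stats
    ref <- sessions[1]
    refBeh <- behavior[behavior$session == ref, ]
    pairLabels <- unique(connectivity[, c("roi_a", "roi_b")])
    measures <- c("unexpected", "anomalous")

    corRows <- list(); corResults <- list(); labels <- character(0)
    for (pi in seq_len(nrow(pairLabels))) {
        pair <- unlist(pairLabels[pi, ], use.names = FALSE)
        zref <- .pairZ(connectivity[connectivity$session == ref, ], pair)
        df <- merge(zref, refBeh, by = "subject")
        for (meas in measures) {
            v <- df[[paste0("norm_rt_", meas)]]
            useSpearman <- tryCatch({
                lz <- lillieforsTest(df$z, nSim = st$lilliefors_sims,
                                     seed = childSeed(cfg$seed, "lz", pi))
                lv <- lillieforsTest(v, nSim = st$lilliefors_sims,
                                     seed = childSeed(cfg$seed, "lv", pi,
                                                      meas))
                lz@p < st$normality_alpha || lv@p < st$normality_alpha
            }, error = function(e) TRUE)
            res <- tryCatch(
                correlateWithP(df$z, v,
                               method = if (useSpearman) "spearman"
                                        else "pearson"),
                error = function(e) statResult(
                    "correlation (not computable)", n = nrow(df),
                    details = list(reason = conditionMessage(e))))
            corResults[[length(corResults) + 1L]] <- res
            labels <- c(labels, sprintf("%s-%s ~ norm_rt_%s",
                                        pair[1], pair[2], meas))
        }
    }
    corResults <- bonferroniAdjust(corResults, m = st$bonferroni_m,
                                   alpha = st$alpha)
    corTable <- do.call(rbind, Map(.statResultRow, corResults,
                                   family = "connectivity-behavior",
                                   label = labels))

    permTable <- NULL
    coupled <- if (isTRUE(cfg$imaging))
        unlist(pairLabels[1L, ], use.names = FALSE) else co@coupledPair
    permRows <- list()
    for (session in setdiff(sessions, ref)) {
        zr <- .pairZ(connectivity[connectivity$session == ref, ], coupled)
        zs <- .pairZ(connectivity[connectivity$session == session, ],
                     coupled)
        br <- behavior[behavior$session == ref,
                       c("subject", paste0("norm_rt_", co@coupledMeasure))]
        bs <- behavior[behavior$session == session,
                       c("subject", paste0("norm_rt_", co@coupledMeasure))]
        names(br)[2] <- "behav_cond1"; names(bs)[2] <- "behav_cond2"
        names(zr)[names(zr) == "z"] <- "z_cond1"
        names(zs)[names(zs) == "z"] <- "z_cond2"
        df <- Reduce(function(a, b) merge(a, b, by = "subject"),
                     list(zr[, c("subject", "z_cond1")], br,
                          zs[, c("subject", "z_cond2")], bs))
        res <- tryCatch(
            permCorrDiff(df, nPerm = st$n_perm,
                         seed = childSeed(cfg$seed, "perm", session)),
            error = function(e) statResult(
                "permutation test (not computable)", n = nrow(df),
                details = list(reason = conditionMessage(e))))
        permRows[[session]] <- .statResultRow(
            res, family = "permutation",
            label = sprintf("%s vs %s: %s-%s ~ norm_rt_%s", ref, session,
                            coupled[1], coupled[2], co@coupledMeasure))
    }
    if (length(permRows))
        permTable <- do.call(rbind, c(permRows,
                                      list(make.row.names = FALSE)))

    list(connectivity = connectivity,
         behavior = behavior,
         stats = list(correlations = corTable, permutation = permTable,
                      cleaning = cleaned$report),
         qc = list(runs = qc,
                   excluded = if (!is.null(qc) && nrow(qc))
                       qc[qc$excluded, c("subject", "session", "rule")]
                   else NULL),
         provenance = list(seed = cfg$seed, config_hash = .configHash(cfg),
                           package_version =
                               as.character(utils::packageVersion("restfc"))))
}

#' Write a results bundle to disk
#'
#' TSV tables plus JSON stats/QC/provenance, each written atomically
#' (temp file, then rename), so a partial failure never leaves a
#' truncated bundle component behind.
#'
#' @param bundle list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeResultsBundle <- function(bundle, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    written <- character(0)
    atomically <- function(name, writer) {
        final <- file.path(dir, name)
        tmp <- paste0(final, ".tmp")
        writer(tmp)
        if (!file.rename(tmp, final)) stop("cannot write ", final)
        written <<- c(written, final)
    }
    atomically("connectivity.tsv", function(f)
        utils::write.table(bundle$connectivity, f, sep = "\t",
                           row.names = FALSE, quote = FALSE))
    atomically("behavior.tsv", function(f)
        utils::write.table(bundle$behavior, f, sep = "\t",
                           row.names = FALSE, quote = FALSE))
    atomically("stats.json", function(f)
        jsonlite::write_json(bundle$stats, f, auto_unbox = TRUE,
                             digits = NA, dataframe = "rows", na = "null"))
    atomically("qc.json", function(f)
        jsonlite::write_json(bundle$qc, f, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", na = "null"))
    atomically("provenance.json", function(f)
        jsonlite::write_json(bundle$provenance, f, auto_unbox = TRUE,
                             digits = NA))
    invisible(written)
}
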