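#' @include AllClasses.R
NULL

.writeNiftiVolume <- function(arr, affine, file, tr = NULL) {
    d <- dim(arr)
    nd <- length(d)
    hdr <- RNifti::niftiHeader(list(
        dim = c(nd, d, rep(1L, 7L - nd)),
        pixdim = c(1, abs(diag(affine)[1:3]),
                   if (!is.null(tr)) tr else 0, 0, 0, 0)))
    img <- RNifti::asNifti(arr, reference = hdr, datatype = "double")
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, file)
    file
}

#' Read a NIfTI volume back as a BoldRun
#'
#' @param file path to a `.nii`/`.nii.gz` written by [writeDataset()] (or
#'   any NIfTI-1 volume with a valid sform and TR in pixdim).
#' @return A [BoldRun-class] (4D input) or a plain array with an `affine`
#'   attribute (3D input).
#' @export
readBoldRun <- function(file) {
    img <- RNifti::readNifti(file)
    aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
    attr(aff, "code") <- NULL
    attr(aff, "imagedim") <- NULL
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) == 4L) {
        tr <- RNifti::pixdim(img)[4]
        boldRun(arr, matrix(aff, 4, 4), if (tr > 0) tr else 1)
    } else {
        attr(arr, "affine") <- matrix(aff, 4, 4)
        arr
    }
}

#' Write a synthetic dataset to disk with a checksummed manifest
#'
#' Serializes the components produced by [makePhantom()] and/or
#' [makeCohort()]: BOLD and tissue volumes as uncompressed NIfTI-1 (RAS
#' sform, TR in pixdim), motion as 6-column whitespace-delimited text,
#' trials/connectivity/truth as TSV with headers. The manifest lists every
#' file with its MD5 checksum, so reruns with the same seed and
#' configuration can be audited byte for byte.
#'
#' @param dataset list with any of: `run`, `tissue`, `motion`, `truth`
#'   (from [makePhantom()]), `trials`, `connectivity` (from
#'   [makeCohort()]).
#' @param dir output directory (created if needed).
#' @return data.frame manifest: file, md5, bytes. Also written as
#'   `manifest.tsv` (not listed in itself).
#' @export
writeDataset <- function(dataset, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    files <- character(0)
    put <- function(f) files[[length(files) + 1L]] <<- f

    if (!is.null(dataset$run)) {
        run <- dataset$run
        put(.writeNiftiVolume(run@data, run@affine,
                              file.path(dir, "bold.nii"), tr = run@tr))
    }
    if (!is.null(dataset$tissue)) {
        tis <- dataset$tissue
        for (nm in c("gm", "wm", "csf"))
            put(.writeNiftiVolume(slot(tis, nm), tis@affine,
                                  file.path(dir, paste0(nm, ".nii"))))
    }
    if (!is.null(dataset$motion)) {
        f <- file.path(dir, "motion.txt")
        utils::write.table(dataset$motion@params, f, row.names = FALSE,
                           col.names = FALSE)
        put(f)
    }
    writeTsv <- function(df, name) {
        f <- file.path(dir, name)
        utils::write.table(df, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        put(f)
    }
    if (!is.null(dataset$trials)) writeTsv(dataset$trials, "trials.tsv")
    if (!is.null(dataset$connectivity))
        writeTsv(dataset$connectivity, "connectivity.tsv")
    if (!is.null(dataset$truth)) {
        tr <- dataset$truth
        if (nrow(tr@trueRoiCorrelations))
            writeTsv(as.data.frame(tr@trueRoiCorrelations),
                     "truth_roi_correlations.tsv")
        eff <- tr@trueBehaviorEffect
        hasEff <- length(eff) && any(!is.na(eff))
        fields <- c(if (hasEff) paste0("behavior_effect_", names(eff)),
                    if (length(tr@spikeFrames)) "spike_frames")
        if (length(fields))
            writeTsv(data.frame(
                field = fields,
                value = c(if (hasEff) as.character(eff),
                          if (length(tr@spikeFrames))
                              paste(tr@spikeFrames, collapse = ","))),
                "truth.tsv")
    }
    if (!length(files)) stop("dataset contains nothing to write")
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           bytes = file.size(files),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest
}
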