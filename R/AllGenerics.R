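#' @include AllClasses.R
NULL

#' Accessors for restfc containers
#'
#' Small accessor family so that user code never touches slots directly:
#' `boldData()` returns the 4D array of a [BoldRun-class]; `spatialAffine()`
#' the voxel-to-mm map of any spatial object; `repetitionTime()` the TR in
#' seconds; `motionParams()` the frames x 6 parameter matrix;
#' `seriesMatrix()` and `keptFrames()` the contents of a
#' [CleanSeries-class]; `roiLabel()`, `roiCenter()`, `roiRadius()` the
#' fields of a [RoiSpec-class]; `eigSeries()` and `nVoxels()` those of a
#' [RoiTimeseries-class]; `zMap()` and `latIndex()` those of a
#' [SeedMapStats-class]; `pValue()`, `adjustedPValue()` and `estimateValue()`
#' those of a [StatResult-class].
#'
#' @param x an object of the documented class.
#' @return The slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("spatialAffine", function(x) standardGeneric("spatialAffine"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))
#' @rdname accessors
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))
#' @rdname accessors
#' @export
setGeneric("keptFrames", function(x) standardGeneric("keptFrames"))
#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setGeneric("roiCenter", function(x) standardGeneric("roiCenter"))
#' @rdname accessors
#' @export
setGeneric("roiRadius", function(x) standardGeneric("roiRadius"))
#' @rdname accessors
#' @export
setGeneric("eigSeries", function(x) standardGeneric("eigSeries"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("zMap", function(x) standardGeneric("zMap"))
#' @rdname accessors
#' @export
setGeneric("latIndex", function(x) standardGeneric("latIndex"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("adjustedPValue", function(x) standardGeneric("adjustedPValue"))
#' @rdname accessors
#' @export
setGeneric("estimateValue", function(x) standardGeneric("estimateValue"))

#' Number of frames of a time-series container
#'
#' @param x a [BoldRun-class], [MotionTrace-class] or [CleanSeries-class].
#' @return Integer frame count (for `CleanSeries`, surviving frames).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Drop initial frames of a run
#'
#' Discards the leading frames of a run (and, with the matching method, of
#' its motion trace) before any processing, the standard allowance for
#' magnetic-field saturation. The default of 4 frames follows the emulated
#' acquisition protocol.
#'
#' @param x a [BoldRun-class], [MotionTrace-class], or frames x channels
#'   matrix.
#' @param n number of leading frames to drop (default 4).
#' @return Object of the same class with the first `n` frames removed.
#' @export
setGeneric("dropInitialFrames", function(x, n = 4L)
    standardGeneric("dropInitialFrames"))

#' @rdname accessors
setMethod("boldData", "BoldRun", function(x) x@data)
#' @rdname accessors
setMethod("spatialAffine", "BoldRun", function(x) x@affine)
#' @rdname accessors
setMethod("spatialAffine", "TissueMaps", function(x) x@affine)
#' @rdname accessors
setMethod("spatialAffine", "SeedMapStats", function(x) x@affine)
#' @rdname accessors
setMethod("repetitionTime", "BoldRun", function(x) x@tr)
#' @rdname accessors
setMethod("repetitionTime", "CleanSeries", function(x) x@tr)
#' @rdname accessors
setMethod("motionParams", "MotionTrace", function(x) x@params)
#' @rdname accessors
setMethod("seriesMatrix", "CleanSeries", function(x) x@series)
#' @rdname accessors
setMethod("keptFrames", "CleanSeries", function(x) x@keptFrames)
#' @rdname accessors
setMethod("roiLabel", "RoiSpec", function(x) x@label)
#' @rdname accessors
setMethod("roiLabel", "RoiTimeseries", function(x) x@label)
#' @rdname accessors
setMethod("roiCenter", "RoiSpec", function(x) x@center)
#' @rdname accessors
setMethod("roiRadius", "RoiSpec", function(x) x@radius)
#' @rdname accessors
setMethod("eigSeries", "RoiTimeseries", function(x) x@eig)
#' @rdname accessors
setMethod("nVoxels", "RoiTimeseries", function(x) x@nVoxels)
#' @rdname accessors
setMethod("zMap", "SeedMapStats", function(x) x@zmap)
#' @rdname accessors
setMethod("latIndex", "SeedMapStats", function(x) x@li)
#' @rdname accessors
setMethod("pValue", "StatResult", function(x) x@p)
#' @rdname accessors
setMethod("adjustedPValue", "StatResult", function(x) x@adjustedP)
#' @rdname accessors
setMethod("estimateValue", "StatResult", function(x) x@estimate)

#' @rdname nFrames
setMethod("nFrames", "BoldRun", function(x) dim(x@data)[4L])
#' @rdname nFrames
setMethod("nFrames", "MotionTrace", function(x) nrow(x@params))
#' @rdname nFrames
setMethod("nFrames", "CleanSeries", function(x) length(x@keptFrames))

#' @rdname dropInitialFrames
setMethod("dropInitialFrames", "BoldRun", function(x, n = 4L) {
    n <- as.integer(n)
    if (n == 0L) return(x)
    stopifnot(n > 0L, nFrames(x) - n >= 2L)
    boldRun(x@data[, , , -seq_len(n), drop = FALSE], x@affine, x@tr)
})
#' @rdname dropInitialFrames
setMethod("dropInitialFrames", "MotionTrace", function(x, n = 4L) {
    n <- as.integer(n)
    if (n == 0L) return(x)
    stopifnot(n > 0L, nFrames(x) - n >= 2L)
    motionTrace(x@params[-seq_len(n), , drop = FALSE])
})
#' @rdname dropInitialFrames
setMethod("dropInitialFrames", "matrix", function(x, n = 4L) {
    n <- as.integer(n)
    if (n == 0L) return(x)
    stopifnot(n > 0L, nrow(x) - n >= 2L)
    x[-seq_len(n), , drop = FALSE]
})
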