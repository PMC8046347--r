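#' @name accessors
#' @title Accessors for the core data classes
#' @param x an object.
#' @description \code{echoTimes}, \code{stackData}, \code{nSlices},
#'   \code{discMasks}, \code{regionLabels} and \code{discLevels} extract the
#'   corresponding components without touching slots directly.
NULL

#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))
#' @rdname accessors
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("discMasks", function(x) standardGeneric("discMasks"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("discLevels", function(x) standardGeneric("discLevels"))

#' @rdname accessors
setMethod("echoTimes", "EchoStack", function(x) x@echoTimes)
#' @rdname accessors
setMethod("echoTimes", "PhantomSpec", function(x) x@echoTimes)
#' @rdname accessors
setMethod("stackData", "EchoStack", function(x) x@data)
#' @rdname accessors
setMethod("nSlices", "EchoStack", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("nSlices", "PhantomSpec", function(x) x@nSlices)
#' @rdname accessors
setMethod("discMasks", "DiscSegmentation", function(x) x@masks)
#' @rdname accessors
setMethod("discMasks", "PhantomTruth", function(x) x@discMasks)
#' @rdname accessors
setMethod("regionLabels", "SubregionPartition", function(x) x@regionLabels)
#' @rdname accessors
setMethod("regionLabels", "PhantomTruth", function(x) x@regionLabels)
#' @rdname accessors
setMethod("discLevels", "PhantomSpec", function(x) x@discLabels)
#' @rdname accessors
setMethod("discLevels", "DiscSegmentation", function(x) x@discLabels)

setMethod("show", "EchoStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("EchoStack: %d x %d pixels, %d slice(s), %d echoes (%.1f-%.1f ms)\n",
              d[1], d[2], d[3], d[4], min(object@echoTimes),
              max(object@echoTimes)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d grid, %d slice(s), %d discs, %d echoes\n",
    object@gridHeight, object@gridWidth, object@nSlices, object@nDiscs,
    length(object@echoTimes)))
  cat(sprintf("  noise: %s (sigma = %g); seed: %s\n", object@noiseModel,
              object@noiseSigma, format(object@seed)))
})

setMethod("show", "StudySpec", function(object) {
  cat(sprintf(
    "StudySpec: %d subjects x %d sessions (dropout %s)\n",
    object@nSubjects, object@nSessions,
    paste(object@dropout, collapse = ",")))
  cat(sprintf("  betweenSD %.2f, withinSD %.2f ms => true ICC %.3f\n",
              object@betweenSD, object@withinSD, trueICC(object)))
})

setMethod("show", "DiscSegmentation", function(object) {
  cat(sprintf("DiscSegmentation: %d disc(s) on %d slice(s), centre column %d\n",
              length(object@discLabels), dim(object@masks)[3],
              object@centreColumn))
})

setMethod("show", "SubregionPartition", function(object) {
  cat(sprintf("SubregionPartition: %d disc-slice partitions\n",
              nrow(object@geometry)))
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams:\n")
  cat(sprintf("  median window 1 x %d; locate diff >= %g; endplate < %g\n",
              object@medianHeight, object@diffThresholdLocate,
              object@endplateIntensityThreshold))
  cat(sprintf("  >= %d dark neighbours; A/P border diff >= %g\n",
              object@neighborCountMin, object@apBorderThreshold))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: mode %s; measures %s; seed %s\n", object@mode,
              paste(object@measures, collapse = "+"), format(object@seed)))
})
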