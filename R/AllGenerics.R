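#' @name accessors
#' @title Accessors for tpmRatiometry classes
#' @param object an object of the relevant class.
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
NULL

#' @rdname accessors
#' @export
setGeneric("probeId", function(object) standardGeneric("probeId"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("tissueClass", function(object) standardGeneric("tissueClass"))
#' @rdname accessors
#' @export
setGeneric("zPositions", function(object) standardGeneric("zPositions"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channel1", function(object) standardGeneric("channel1"))
#' @rdname accessors
#' @export
setGeneric("channel2", function(object) standardGeneric("channel2"))
#' @rdname accessors
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))
#' @rdname accessors
#' @export
setGeneric("foregroundOf", function(object) standardGeneric("foregroundOf"))
#' @rdname accessors
#' @export
setGeneric("displayRange", function(object) standardGeneric("displayRange"))
#' @rdname accessors
#' @export
setGeneric("trueRatio", function(object) standardGeneric("trueRatio"))
#' @rdname accessors
#' @export
setGeneric("brightnessField",
           function(object) standardGeneric("brightnessField"))
#' @rdname accessors
#' @export
setGeneric("glandMask", function(object) standardGeneric("glandMask"))
#' @rdname accessors
#' @export
setGeneric("sampleRatioMean",
           function(object) standardGeneric("sampleRatioMean"))
#' @rdname accessors
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))
#' @rdname accessors
#' @export
setGeneric("classSds", function(object) standardGeneric("classSds"))
#' @rdname accessors
#' @export
setGeneric("targetEnzyme", function(object) standardGeneric("targetEnzyme"))

setMethod("probeId", "ProbeCalibration", function(object) object@probeId)
setMethod("probeId", "TwoChannelStack", function(object) object@probeId)
setMethod("probeId", "RatioVolume", function(object) object@probeId)
setMethod("probeId", "DepthProfile", function(object) object@probeId)
setMethod("probeId", "LysateTimeSeries", function(object) object@probeId)
setMethod("probeId", "Phantom", function(object) object@probeId)
setMethod("probeId", "ClassifierRule", function(object) object@probeId)

setMethod("sampleId", "TwoChannelStack", function(object) object@sampleId)
setMethod("sampleId", "RatioVolume", function(object) object@sampleId)
setMethod("sampleId", "DepthProfile", function(object) object@sampleId)
setMethod("sampleId", "LysateTimeSeries", function(object) object@sampleId)

setMethod("tissueClass", "TwoChannelStack", function(object) object@tissueClass)
setMethod("tissueClass", "RatioVolume", function(object) object@tissueClass)
setMethod("tissueClass", "Phantom", function(object) object@tissueClass)
setMethod("tissueClass", "LysateTimeSeries",
          function(object) object@tissueClass)

setMethod("zPositions", "TwoChannelStack", function(object) object@zPositions)
setMethod("zPositions", "RatioVolume", function(object) object@zPositions)
setMethod("zPositions", "AcquisitionParams", function(object) object@zPositions)
setMethod("zPositions", "DepthProfile", function(object) object@z)

setMethod("pixelSize", "TwoChannelStack", function(object) object@pixelSize)
setMethod("pixelSize", "AcquisitionParams", function(object) object@pixelSize)

setMethod("channel1", "TwoChannelStack", function(object) object@ch1)
setMethod("channel2", "TwoChannelStack", function(object) object@ch2)

setMethod("ratios", "RatioVolume", function(object) object@ratios)
setMethod("ratios", "LysateTimeSeries", function(object) object@ratio)

setMethod("foregroundOf", "RatioVolume", function(object) object@mask)
setMethod("displayRange", "RatioVolume", function(object) object@displayRange)

setMethod("trueRatio", "Phantom", function(object) object@trueRatio)
setMethod("brightnessField", "Phantom", function(object) object@brightness)
setMethod("glandMask", "Phantom", function(object) object@glandMask)
setMethod("sampleRatioMean", "Phantom", function(object) object@sampleRatioMean)

setMethod("classMeans", "ProbeCalibration", function(object) object@classMeans)
setMethod("classSds", "ProbeCalibration", function(object) object@classSds)
setMethod("targetEnzyme", "ProbeCalibration",
          function(object) object@targetEnzyme)

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
setMethod("timePoints", "LysateTimeSeries", function(object) object@timeMin)
setMethod("timePoints", "LysateAssayParams", function(object) object@timePoints)

## ---- show methods -------------------------------------------------------

setMethod("show", "ProbeCalibration", function(object) {
  cat("ProbeCalibration:", object@probeId,
      sprintf("(%s)\n", object@targetEnzyme))
  cls <- names(object@classMeans)
  for (cl in cls)
    cat(sprintf("  %-8s %0.3f +/- %0.3f\n", cl,
                object@classMeans[[cl]], object@classSds[[cl]]))
})

setMethod("show", "TwoChannelStack", function(object) {
  d <- dim(object@ch1)
  cat(sprintf(
    "TwoChannelStack '%s' (probe %s, class %s)\n  %d x %d px, %d sections, z %g-%g um, pixel %g um\n",
    object@sampleId, object@probeId, object@tissueClass,
    d[1], d[2], d[3], min(object@zPositions), max(object@zPositions),
    object@pixelSize))
})

setMethod("show", "RatioVolume", function(object) {
  v <- object@ratios[object@mask]
  cat(sprintf(
    "RatioVolume '%s' (probe %s): %d masked voxels, ratio %.3f-%.3f (mean %.3f)\n",
    object@sampleId, object@probeId, sum(object@mask),
    min(v), max(v), mean(v)))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@trueRatio)
  cat(sprintf(
    "Phantom (%s, probe %s): %d x %d x %d, sample mean ratio %.3f, disorder %.2f\n",
    object@tissueClass, object@probeId, d[1], d[2], d[3],
    object@sampleRatioMean, object@geometry@disorder))
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile '%s' (probe %s): %d sections, z %g-%g um\n",
              object@sampleId, object@probeId, length(object@z),
              min(object@z), max(object@z)))
})

setMethod("show", "LysateTimeSeries", function(object) {
  cat(sprintf(
    "LysateTimeSeries '%s' (probe %s, class %s): %d points, t %g-%g min, ratio %.3f -> %.3f\n",
    object@sampleId, object@probeId, object@tissueClass,
    length(object@timeMin), min(object@timeMin), max(object@timeMin),
    object@ratio[1], object@ratio[length(object@ratio)]))
})

setMethod("show", "ClassifierRule", function(object) {
  cat(sprintf("ClassifierRule (%s): ratio %s %.4f -> %s\n",
              object@probeId, if (object@direction == "above") ">" else "<",
              object@threshold, object@positiveClass))
})

## ---- coercions ----------------------------------------------------------

#' @export
#' @method as.data.frame DepthProfile
as.data.frame.DepthProfile <- function(x, ...) {
  data.frame(sample_id = x@sampleId, probe_id = x@probeId, z_um = x@z,
             n_voxels = x@nVoxels, mean_ratio = x@meanRatio,
             min_ratio = x@minRatio, max_ratio = x@maxRatio,
             sd_ratio = x@sdRatio)
}
setMethod("as.data.frame", "DepthProfile",
          function(x, ...) as.data.frame.DepthProfile(x, ...))

#' @export
#' @method as.data.frame LysateTimeSeries
as.data.frame.LysateTimeSeries <- function(x, ...) {
  data.frame(time_min = x@timeMin, ratio = x@ratio)
}
setMethod("as.data.frame", "LysateTimeSeries",
          function(x, ...) as.data.frame.LysateTimeSeries(x, ...))
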