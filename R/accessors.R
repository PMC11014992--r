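#' @rdname accessors
setMethod("planes", "ImageStack", function(x) x@planes)

#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "InstanceLabelMap", function(x) x@pixelSize)

#' @rdname accessors
setMethod("channelName", "ImageStack", function(x) x@channel)

#' @rdname accessors
setMethod("nPlanes", "ImageStack", function(x) length(x@planes))

#' @rdname accessors
setMethod("labelMatrix", "InstanceLabelMap", function(x) x@labels)

#' @rdname accessors
setMethod("nInstances", "InstanceLabelMap",
          function(x) max(0L, x@labels))

#' @rdname accessors
setMethod("instanceMap", "GroundTruth", function(x) x@instanceMap)

#' @rdname accessors
setMethod("trueAreas", "GroundTruth", function(x) x@areas)

#' @rdname accessors
setMethod("binaryMask", "GroundTruth", function(x) x@mask)

#' @rdname accessors
setMethod("minClusterSize", "DbscanParams", function(x) x@minClusterSize)

#' @rdname accessors
setMethod("searchRadius", "DbscanParams", function(x) x@searchRadius)

#' @rdname accessors
setMethod("bestParams", "TuningResult", function(x) x@bestParams)

#' @rdname accessors
setMethod("bestIOU", "TuningResult", function(x) x@bestIOU)

#' @rdname accessors
setMethod("metTarget", "TuningResult", function(x) x@metTarget)

#' @rdname accessors
setMethod("tuningTrace", "TuningResult", function(x) x@trace)

#' @rdname accessors
setMethod("meanPercentages", "SizeClassDistribution", function(x) x@meanPct)

#' @rdname accessors
setMethod("replicatePercentages", "SizeClassDistribution",
          function(x) x@perReplicatePct)

#' @rdname accessors
setMethod("replicateCounts", "SizeClassDistribution",
          function(x) x@perReplicateCounts)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@planes[[1]])
  cat(sprintf("ImageStack '%s': %d plane(s) of %d x %d px, %.4g um/px\n",
              object@channel, length(object@planes), d[1], d[2],
              object@pixelSize))
})

setMethod("show", "InstanceLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("InstanceLabelMap: %d x %d px, %d instance(s), %.4g um/px\n",
              d[1], d[2], max(0L, object@labels), object@pixelSize))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d/%d instance(s) placed, total area %.3f um^2\n",
              object@nPlaced, object@nRequested, sum(object@areas)))
})

setMethod("show", "DbscanParams", function(object) {
  cat(sprintf("DbscanParams: minClusterSize = %d, searchRadius = %.4g\n",
              object@minClusterSize, object@searchRadius))
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf(
    "TuningResult: best IOU %.4f (target > %.2f, %s) after %d iteration(s)\n",
    object@bestIOU, object@targetIOU,
    if (object@metTarget) "met" else "not met", nrow(object@trace)))
  cat(sprintf("  best params: minClusterSize = %d, searchRadius = %.4g\n",
              object@bestParams@minClusterSize,
              object@bestParams@searchRadius))
})

setMethod("show", "SizeClassDistribution", function(object) {
  cat(sprintf(
    "SizeClassDistribution '%s' (%d replicate(s)): small %.1f%% / medium %.1f%% / large %.1f%%\n",
    object@groupLabel, nrow(object@perReplicatePct),
    object@meanPct[1], object@meanPct[2], object@meanPct[3]))
})

setMethod("show", "Roi", function(object) {
  cat(sprintf("Roi '%s' (%s, %d vertices)\n", object@label, object@shape,
              nrow(object@vertices)))
})
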