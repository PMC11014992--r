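#' @name accessors
#' @title Accessors for mitomorph classes
#' @param x an object
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))

#' @rdname accessors
#' @export
setGeneric("instanceMap", function(x) standardGeneric("instanceMap"))

#' @rdname accessors
#' @export
setGeneric("trueAreas", function(x) standardGeneric("trueAreas"))

#' @rdname accessors
#' @export
setGeneric("binaryMask", function(x) standardGeneric("binaryMask"))

#' @rdname accessors
#' @export
setGeneric("minClusterSize", function(x) standardGeneric("minClusterSize"))

#' @rdname accessors
#' @export
setGeneric("searchRadius", function(x) standardGeneric("searchRadius"))

#' @rdname accessors
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))

#' @rdname accessors
#' @export
setGeneric("bestIOU", function(x) standardGeneric("bestIOU"))

#' @rdname accessors
#' @export
setGeneric("metTarget", function(x) standardGeneric("metTarget"))

#' @rdname accessors
#' @export
setGeneric("tuningTrace", function(x) standardGeneric("tuningTrace"))

#' @rdname accessors
#' @export
setGeneric("meanPercentages", function(x) standardGeneric("meanPercentages"))

#' @rdname accessors
#' @export
setGeneric("replicatePercentages",
           function(x) standardGeneric("replicatePercentages"))

#' @rdname accessors
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' Maximum-intensity z-projection
#'
#' Collapse a stack to one plane by taking the per-pixel maximum across
#' z-planes (the projection used before thresholding in the TMRE and
#' MitoTracker area measurements).
#'
#' @param x an [ImageStack-class] or a single matrix (returned unchanged)
#' @return a 2D numeric matrix
#' @export
setGeneric("maxProject", function(x) standardGeneric("maxProject"))
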