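#' ImageStack: a calibrated stack of intensity planes
#'
#' The pipeline's universal input: a z-ordered list of 2D non-negative
#' intensity grids (matrices, rows = y, columns = x) sharing one pixel
#' calibration in micrometres per pixel.
#'
#' @slot planes list of numeric matrices, identical dimensions, z order
#' @slot pixelSize micrometres per pixel (> 0)
#' @slot channel channel name, free text
#' @export
setClass("ImageStack",
  representation(planes = "list", pixelSize = "numeric", channel = "character"),
  prototype(planes = list(), pixelSize = NA_real_, channel = "")
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(object@planes) == 0L)
    msg <- c(msg, "stack must contain at least one plane")
  if (!all(vapply(object@planes, is.matrix, logical(1))))
    msg <- c(msg, "planes must be matrices")
  dims <- vapply(object@planes, dim, integer(2))
  if (length(object@planes) > 1L && any(dims != dims[, 1]))
    msg <- c(msg, "all planes must share identical dimensions")
  if (!isTRUE(object@pixelSize > 0))
    msg <- c(msg, "pixelSize must be a positive number (um per pixel)")
  if (any(vapply(object@planes, function(p) any(p < 0), logical(1))))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param planes a matrix or list of matrices (rows = y, columns = x)
#' @param pixelSizeUm pixel calibration, micrometres per pixel
#' @param channel channel name
#' @return an [ImageStack-class] object
#' @examples
#' s <- ImageStack(matrix(runif(100), 10), pixelSizeUm = 0.1)
#' nPlanes(s)
#' @export
ImageStack <- function(planes, pixelSizeUm, channel = "") {
  if (is.matrix(planes)) planes <- list(planes)
  new("ImageStack", planes = planes, pixelSize = as.numeric(pixelSizeUm),
      channel = channel)
}

#' InstanceLabelMap: per-pixel instance assignment
#'
#' A 2D integer grid in which 0 marks background (or DBSCAN noise) and
#' k >= 1 marks the k-th segmented instance; ids are consecutive from 1.
#' Carries the pixel calibration of its source so areas stay in um^2.
#'
#' @slot labels integer matrix
#' @slot pixelSize micrometres per pixel
#' @export
setClass("InstanceLabelMap",
  representation(labels = "matrix", pixelSize = "numeric")
)

setValidity("InstanceLabelMap", function(object) {
  msg <- character()
  lab <- object@labels
  if (any(lab < 0)) msg <- c(msg, "labels must be >= 0")
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
    msg <- c(msg, "instance ids must be consecutive from 1")
  if (!isTRUE(object@pixelSize > 0))
    msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

InstanceLabelMap <- function(labels, pixelSizeUm) {
  storage.mode(labels) <- "integer"
  new("InstanceLabelMap", labels = labels, pixelSize = as.numeric(pixelSizeUm))
}

#' GroundTruth: exact per-instance truth for a synthetic image
#'
#' @slot instanceMap an [InstanceLabelMap-class] of the true instances
#' @slot areas true per-instance areas in um^2 (pixel count x pixel area)
#' @slot mask logical matrix, union of all instances
#' @slot nRequested,nPlaced requested vs successfully placed instance counts
#' @export
setClass("GroundTruth",
  representation(instanceMap = "InstanceLabelMap", areas = "numeric",
                 mask = "matrix", nRequested = "integer", nPlaced = "integer")
)

setValidity("GroundTruth", function(object) {
  lab <- object@instanceMap@labels
  px2 <- object@instanceMap@pixelSize^2
  n <- max(0L, lab)
  if (length(object@areas) != n)
    return("areas length must equal the number of instances")
  if (n > 0) {
    counts <- tabulate(lab[lab > 0], nbins = n)
    if (!isTRUE(all.equal(object@areas, counts * px2)))
      return("areas must equal pixel counts x pixel_size^2")
  }
  if (!identical(unname(object@mask), unname(lab > 0L)))
    return("mask must equal instanceMap > 0")
  TRUE
})

GroundTruth <- function(instanceMap, areas, nRequested = length(areas),
                        nPlaced = length(areas)) {
  new("GroundTruth", instanceMap = instanceMap, areas = as.numeric(areas),
      mask = instanceMap@labels > 0L, nRequested = as.integer(nRequested),
      nPlaced = as.integer(nPlaced))
}

#' DbscanParams: the two clustering parameters
#'
#' Minimum cluster (mitochondrion) size in pixels and the search radius in
#' feature-space units. A point is core when at least `minClusterSize`
#' points, itself included, lie within `searchRadius`.
#'
#' @slot minClusterSize integer >= 1
#' @slot searchRadius positive distance in feature-space units
#' @export
setClass("DbscanParams",
  representation(minClusterSize = "integer", searchRadius = "numeric")
)

setValidity("DbscanParams", function(object) {
  if (!isTRUE(object@minClusterSize >= 1L))
    return("minClusterSize must be an integer >= 1")
  if (!isTRUE(object@searchRadius > 0))
    return("searchRadius must be > 0")
  TRUE
})

#' @rdname DbscanParams-class
#' @param minClusterSize minimum pixels per instance (minPts), >= 1
#' @param searchRadius DBSCAN eps in feature-space units, > 0
#' @export
dbscanParams <- function(minClusterSize, searchRadius) {
  new("DbscanParams", minClusterSize = as.integer(minClusterSize),
      searchRadius = as.numeric(searchRadius))
}

#' TuningResult: outcome of the Monte-Carlo parameter search
#'
#' @slot bestParams the [DbscanParams-class] with the highest IOU
#' @slot bestIOU the highest intersection-over-union reached, in [0, 1]
#' @slot metTarget TRUE iff bestIOU exceeds the tuning target
#' @slot targetIOU the IOU criterion the search aims to exceed
#' @slot trace data.frame of every sampled iteration
#'   (min_cluster_size, search_radius, iou)
#' @export
setClass("TuningResult",
  representation(bestParams = "DbscanParams", bestIOU = "numeric",
                 metTarget = "logical", targetIOU = "numeric",
                 trace = "data.frame")
)

setValidity("TuningResult", function(object) {
  if (nrow(object@trace) == 0L) return("trace must be non-empty")
  if (!isTRUE(all.equal(object@bestIOU, max(object@trace$iou))))
    return("bestIOU must be the maximum of the trace")
  if (!identical(object@metTarget, object@bestIOU > object@targetIOU))
    return("metTarget must equal bestIOU > targetIOU")
  TRUE
})

#' SizeClassDistribution: per-replicate size-class percentages
#'
#' Percentages of small / medium / large mitochondria computed within each
#' replicate, plus their arithmetic mean across replicates. Raw per-class
#' counts are retained so the chi-square comparison can also be run on
#' pooled counts.
#'
#' @slot groupLabel group name
#' @slot perReplicatePct n x 3 matrix of percentages, rows sum to 100
#' @slot perReplicateCounts n x 3 matrix of raw counts
#' @slot meanPct length-3 mean percentage vector, sums to 100
#' @export
setClass("SizeClassDistribution",
  representation(groupLabel = "character", perReplicatePct = "matrix",
                 perReplicateCounts = "matrix", meanPct = "numeric")
)

setValidity("SizeClassDistribution", function(object) {
  p <- object@perReplicatePct
  if (ncol(p) != 3L) return("three size classes expected")
  if (any(abs(rowSums(p) - 100) > 1e-9))
    return("per-replicate percentages must sum to 100")
  if (abs(sum(object@meanPct) - 100) > 1e-9)
    return("mean percentages must sum to 100")
  TRUE
})

#' Roi: a rectangular or polygonal region of interest
#'
#' Vertices are (x, y) pixel coordinates, 0-based, in image axes
#' (x = column, y = row).
#'
#' @slot shape "rectangle" or "polygon"
#' @slot vertices n x 2 numeric matrix of (x, y) vertices
#' @slot label free-text label
#' @export
setClass("Roi",
  representation(shape = "character", vertices = "matrix", label = "character")
)

setValidity("Roi", function(object) {
  if (!object@shape %in% c("rectangle", "polygon"))
    return("shape must be 'rectangle' or 'polygon'")
  if (object@shape == "polygon" && nrow(object@vertices) < 3L)
    return("polygon needs >= 3 vertices")
  if (object@shape == "rectangle" && nrow(object@vertices) != 2L)
    return("rectangle is given by 2 corner vertices")
  TRUE
})

#' @rdname Roi-class
#' @param x,y 0-based pixel coordinates of the top-left corner
#' @param width,height extent in pixels (> 0)
#' @param label free-text label
#' @export
rectRoi <- function(x, y, width, height, label = "") {
  stopifnot(width > 0, height > 0)
  new("Roi", shape = "rectangle",
      vertices = rbind(c(x, y), c(x + width - 1, y + height - 1)),
      label = label)
}

#' @rdname Roi-class
#' @param vertices n x 2 matrix of (x, y) polygon vertices, 0-based pixels
#' @export
polygonRoi <- function(vertices, label = "") {
  new("Roi", shape = "polygon",
      vertices = matrix(as.numeric(vertices), ncol = 2), label = label)
}
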