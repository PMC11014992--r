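# DBSCAN-based mitochondrial instance segmentation:
# k-means background removal -> per-pixel feature matrix (x, y, scaled
# intensity) -> density-based clustering -> label map, with Monte-Carlo
# tuning of the two clustering parameters against an annotated reference
# image under an intersection-over-union objective.

#' Separate background from signal by 2-class k-means on pixel intensity
#'
#' Clusters scalar pixel intensities into two groups (Lloyd's algorithm,
#' initialised at the 25th and 75th intensity percentiles so the result is
#' fully deterministic); the cluster with the lower mean intensity is called
#' background. The convention is intensity-based, never size-based: on an
#' inverted-contrast image the bright majority is *not* background.
#'
#' @param plane 2D numeric intensity matrix with at least two distinct values
#' @return logical matrix, TRUE = background
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10)
#' table(classifyBackground(img))
#' @export
classifyBackground <- function(plane) {
  stopifnot(is.matrix(plane), length(plane) > 0)
  v <- as.vector(plane)
  if (max(v) == min(v))
    stop("no intensity contrast: the image is constant")
  init <- quantile(v, c(0.25, 0.75), names = FALSE)
  if (init[1] == init[2]) init <- range(v)
  km <- kmeans(v, centers = matrix(init, ncol = 1), iter.max = 100L,
               algorithm = "Lloyd")
  bgCluster <- which.min(km$centers)
  matrix(km$cluster == bgCluster, nrow = nrow(plane))
}

#' Build the per-pixel feature matrix for clustering
#'
#' One row per retained (non-background) pixel with its x (column) and y
#' (row) coordinates in pixels, 0-based, and its intensity linearly rescaled
#' from the [min, max] of the retained pixels to [0, intensityWeight].
#' Rows are in row-major pixel order (y, then x), which downstream fixes the
#' deterministic tie-break for DBSCAN border pixels. A constant retained
#' intensity rescales to 0 everywhere; `intensityWeight = 0` removes the
#' intensity dimension and clustering becomes purely spatial.
#'
#' @param plane 2D numeric intensity matrix
#' @param backgroundMask logical matrix of the same dimensions, TRUE =
#'   background (as returned by [classifyBackground()])
#' @param intensityWeight upper end of the scaled intensity range
#'   (dimensionless, in pixel units; default 10)
#' @return data.frame with columns x, y, intensity_scaled
#' @export
buildFeatureMatrix <- function(plane, backgroundMask, intensityWeight = 10) {
  stopifnot(identical(dim(plane), dim(backgroundMask)), intensityWeight >= 0)
  keep <- which(!backgroundMask)
  if (length(keep) == 0L)
    stop("no candidate pixels: every pixel is background")
  nr <- nrow(plane)
  row0 <- (keep - 1L) %% nr        # 0-based y
  col0 <- (keep - 1L) %/% nr       # 0-based x
  ord <- order(row0, col0)         # row-major pixel order
  keep <- keep[ord]
  v <- plane[keep]
  rng <- range(v)
  sc <- if (rng[2] > rng[1])
    (v - rng[1]) / (rng[2] - rng[1]) * intensityWeight
  else rep(0, length(v))
  out <- data.frame(x = col0[ord], y = row0[ord], intensity_scaled = sc)
  attr(out, "dim_px") <- dim(plane)
  out
}

#' Cluster the feature matrix with DBSCAN and return an instance label map
#'
#' Canonical DBSCAN with Euclidean distance in the (x, y, scaled intensity)
#' space: eps = `searchRadius`, and a point is core when at least
#' `minClusterSize` points (itself included) lie within eps. Noise pixels
#' map to label 0 (background); border pixels reachable from several
#' clusters keep the first cluster that reaches them in row-major pixel
#' order, so output is bit-reproducible. Instance ids are consecutive from 1
#' in order of cluster creation.
#'
#' @param features data.frame from [buildFeatureMatrix()] (columns x, y,
#'   intensity_scaled; attribute dim_px), or any numeric matrix whose first
#'   two columns are spatial
#' @param params a [dbscanParams()] object
#' @param dimPx image dimensions (rows, cols); taken from the feature
#'   matrix attribute when absent
#' @param pixelSizeUm calibration to attach to the label map
#' @return an [InstanceLabelMap-class]
#' @export
dbscanCluster <- function(features, params, dimPx = attr(features, "dim_px"),
                          pixelSizeUm = 1) {
  stopifnot(nrow(features) > 0)
  validObject(params)
  m <- as.matrix(features[, c("x", "y", "intensity_scaled")])
  labels <- cpp_dbscan(m, params@searchRadius, params@minClusterSize)
  if (is.null(dimPx))
    stop("image dimensions unknown: supply dimPx")
  lab <- matrix(0L, nrow = dimPx[1], ncol = dimPx[2])
  lab[cbind(features$y + 1L, features$x + 1L)] <- labels
  InstanceLabelMap(lab, pixelSizeUm)
}

#' Raw DBSCAN labels for an arbitrary feature matrix
#'
#' Lower-level interface used by the tuner and by equivalence tests:
#' clusters n points in d-dimensional feature space and returns the integer
#' label vector (0 = noise) without rasterising to an image.
#'
#' @inheritParams dbscanCluster
#' @param features numeric matrix, points in rows
#' @return integer vector of labels, 0 = noise, clusters numbered from 1
#' @export
dbscanLabels <- function(features, params) {
  validObject(params)
  cpp_dbscan(as.matrix(features), params@searchRadius, params@minClusterSize)
}

#' Intersection over union of two pixel masks
#'
#' `|A intersect B| / |A union B|` over foreground pixels. Label maps are
#' binarised as label > 0. Two empty masks have IOU 1 by convention.
#'
#' @param predicted logical/numeric matrix or [InstanceLabelMap-class]
#' @param reference logical/numeric matrix or [InstanceLabelMap-class]
#' @return a fraction in [0, 1]
#' @export
computeIOU <- function(predicted, reference) {
  toMask <- function(x) {
    if (is(x, "InstanceLabelMap")) x@labels > 0L else x > 0
  }
  a <- toMask(predicted)
  b <- toMask(reference)
  if (!identical(dim(a), dim(b)))
    stop("mask dimensions differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' TuningConfig: Monte-Carlo search settings for the DBSCAN parameters
#'
#' @slot minClusterSizeRange integer interval for the minimum cluster size
#' @slot searchRadiusRange positive interval for the search radius
#' @slot nIterations parameter pairs to sample (>= 1)
#' @slot targetIOU IOU criterion to exceed, in (0, 1] (default 0.95)
#' @slot intensityWeight feature-matrix intensity scale
#' @slot seed RNG seed
#' @export
setClass("TuningConfig",
  representation(minClusterSizeRange = "integer",
                 searchRadiusRange = "numeric", nIterations = "integer",
                 targetIOU = "numeric", intensityWeight = "numeric",
                 seed = "integer")
)

setValidity("TuningConfig", function(object) {
  msg <- character()
  r <- object@minClusterSizeRange
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
    msg <- c(msg, "minClusterSizeRange must be a non-empty integer interval >= 1")
  s <- object@searchRadiusRange
  if (length(s) != 2L || s[1] > s[2] || s[1] <= 0)
    msg <- c(msg, "searchRadiusRange must be a non-empty positive interval")
  if (!isTRUE(object@nIterations >= 1L))
    msg <- c(msg, "nIterations must be >= 1")
  if (!isTRUE(object@targetIOU > 0 && object@targetIOU <= 1))
    msg <- c(msg, "targetIOU must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname TuningConfig-class
#' @param minClusterSizeRange length-2 integer range (default c(3, 50))
#' @param searchRadiusRange length-2 positive range (default c(0.5, 5))
#' @param nIterations Monte-Carlo samples (default 200)
#' @param targetIOU IOU criterion (default 0.95)
#' @param intensityWeight feature-matrix intensity scale (default 10)
#' @param seed integer RNG seed
#' @export
tuningConfig <- function(minClusterSizeRange = c(3L, 50L),
                         searchRadiusRange = c(0.5, 5),
                         nIterations = 200L, targetIOU = 0.95,
                         intensityWeight = 10, seed = 1L) {
  new("TuningConfig",
      minClusterSizeRange = as.integer(minClusterSizeRange),
      searchRadiusRange = as.numeric(searchRadiusRange),
      nIterations = as.integer(nIterations),
      targetIOU = as.numeric(targetIOU),
      intensityWeight = as.numeric(intensityWeight),
      seed = as.integer(seed))
}

#' Monte-Carlo tuning of the DBSCAN parameters against an annotation
#'
#' Samples `nIterations` parameter pairs independently — the minimum cluster
#' size uniformly on its integer range, the search radius log-uniformly on
#' its range — runs the clustering at each pair and scores the binarised
#' output against the annotation mask by IOU. Returns the best pair with its
#' IOU and the full search trace; stops early at the first sample whose IOU
#' exceeds `targetIOU`. Fully deterministic for a fixed seed. The tuned pair
#' is meant to be applied unchanged to all subsequent images of the same
#' experiment.
#'
#' @param plane 2D intensity matrix (the representative image)
#' @param backgroundMask logical background mask for `plane`
#' @param annotation logical matrix, the manual/ground-truth foreground mask
#' @param config a [tuningConfig()] object
#' @return a [TuningResult-class]
#' @export
tuneParameters <- function(plane, backgroundMask, annotation,
                           config = tuningConfig()) {
  validObject(config)
  stopifnot(identical(dim(plane), dim(annotation)))
  feats <- buildFeatureMatrix(plane, backgroundMask, config@intensityWeight)
  annot <- annotation > 0
  withSeed(config@seed, {
    n <- config@nIterations
    # one (size, radius) pair is drawn per iteration so that, for a fixed
    # seed, a longer search extends the sample sequence rather than
    # reshuffling it (best IOU is then non-decreasing in nIterations)
    sizes <- integer(0)
    radii <- numeric(0)
    ious <- numeric(0)
    for (i in seq_len(n)) {
      u <- runif(2)
      sizes[i] <- as.integer(config@minClusterSizeRange[1] +
        floor(u[1] * (diff(config@minClusterSizeRange) + 1L)))
      radii[i] <- exp(log(config@searchRadiusRange[1]) +
        u[2] * diff(log(config@searchRadiusRange)))
      p <- dbscanParams(sizes[i], radii[i])
      lm <- dbscanCluster(feats, p, dimPx = dim(plane))
      ious[i] <- computeIOU(lm, annot)
      if (ious[i] > config@targetIOU) break
    }
    trace <- data.frame(min_cluster_size = sizes, search_radius = radii,
                        iou = ious)
    best <- which.max(ious)
    new("TuningResult",
        bestParams = dbscanParams(sizes[best], radii[best]),
        bestIOU = ious[best], metTarget = ious[best] > config@targetIOU,
        targetIOU = config@targetIOU, trace = trace)
  })
}

#' Segment an image stack into mitochondrial instances
#'
#' Runs the full per-plane chain (background k-means, feature matrix, DBSCAN)
#' on the plane selected by `planePolicy`: `"max_projection"` (default)
#' collapses the stack by per-pixel maximum first; `"plane_index"` takes the
#' given plane; `"per_plane"` returns one label map per plane.
#'
#' @param stack an [ImageStack-class]
#' @param params a [dbscanParams()] object (typically from
#'   [tuneParameters()])
#' @param planePolicy "max_projection", "plane_index" or "per_plane"
#' @param planeIndex plane to use when `planePolicy = "plane_index"`
#' @param intensityWeight feature-matrix intensity scale
#' @return an [InstanceLabelMap-class], or a list of them for "per_plane"
#' @export
segmentStack <- function(stack, params,
                         planePolicy = c("max_projection", "plane_index",
                                         "per_plane"),
                         planeIndex = 1L, intensityWeight = 10) {
  planePolicy <- match.arg(planePolicy)
  segOne <- function(plane) {
    bg <- classifyBackground(plane)
    feats <- buildFeatureMatrix(plane, bg, intensityWeight)
    dbscanCluster(feats, params, dimPx = dim(plane),
                  pixelSizeUm = stack@pixelSize)
  }
  switch(planePolicy,
    max_projection = segOne(maxProject(stack)),
    plane_index = segOne(stack@planes[[planeIndex]]),
    per_plane = lapply(stack@planes, segOne)
  )
}
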