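# Calibrated synthetic confocal-like images with exact ground truth.
# Instances are filled ellipses realised at the exact drawn pixel count, so
# ground-truth areas equal the sampled lognormal areas up to integer-pixel
# rounding and every downstream stage can be tested without external data.

#' MitoImageSpec: parameters of the synthetic mitochondria generator
#'
#' @slot width,height,nPlanes image dimensions in pixels and z-planes
#' @slot pixelSize micrometres per pixel (> 0)
#' @slot nInstances number of instances to place (>= 0)
#' @slot log10AreaMean,log10AreaSd lognormal law of instance areas:
#'   log10(area in um^2) ~ Normal(log10AreaMean, log10AreaSd)
#' @slot foreground,background mean grey levels; foreground > background
#' @slot noiseSd additive Gaussian noise sd (clipped at 0)
#' @slot seed RNG seed; the whole generator is deterministic given it
#' @export
setClass("MitoImageSpec",
  representation(width = "integer", height = "integer", nPlanes = "integer",
                 pixelSize = "numeric", nInstances = "integer",
                 log10AreaMean = "numeric", log10AreaSd = "numeric",
                 foreground = "numeric", background = "numeric",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("MitoImageSpec", function(object) {
  msg <- character()
  if (!isTRUE(object@width >= 8L && object@height >= 8L))
    msg <- c(msg, "image must be at least 8 x 8 px")
  if (!isTRUE(object@nPlanes >= 1L)) msg <- c(msg, "nPlanes must be >= 1")
  if (!isTRUE(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
  if (!isTRUE(object@nInstances >= 0L))
    msg <- c(msg, "nInstances must be >= 0")
  if (!isTRUE(object@foreground > object@background))
    msg <- c(msg, "foreground must be brighter than background")
  if (!isTRUE(object@noiseSd >= 0)) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname MitoImageSpec-class
#' @param width,height image size in pixels
#' @param nPlanes z-planes; planes share the instance layout, noise is drawn
#'   independently per plane
#' @param pixelSizeUm micrometres per pixel
#' @param nInstances instances to place
#' @param log10AreaMean,log10AreaSd lognormal instance-area parameters
#'   (log10 um^2); defaults span the small/medium/large classes
#' @param foreground,background mean grey levels
#' @param noiseSd additive Gaussian noise sd
#' @param seed integer RNG seed
#' @export
mitoImageSpec <- function(width = 512L, height = 512L, nPlanes = 3L,
                          pixelSizeUm = 0.1, nInstances = 30L,
                          log10AreaMean = -0.25, log10AreaSd = 0.35,
                          foreground = 180, background = 20, noiseSd = 5,
                          seed = 1L) {
  new("MitoImageSpec", width = as.integer(width), height = as.integer(height),
      nPlanes = as.integer(nPlanes), pixelSize = as.numeric(pixelSizeUm),
      nInstances = as.integer(nInstances),
      log10AreaMean = as.numeric(log10AreaMean),
      log10AreaSd = as.numeric(log10AreaSd),
      foreground = as.numeric(foreground),
      background = as.numeric(background),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Offsets (dr, dc) of exactly nPix pixels forming a discrete filled ellipse
# with the given aspect ratio (>= 1) and orientation: pixels ranked by the
# elliptical metric, first nPix taken, so the realised pixel count is exact.
ellipseOffsets <- function(nPix, aspect, theta) {
  b <- sqrt(nPix / (pi * aspect))
  a <- aspect * b
  R <- ceiling(a) + 2L
  dc <- rep(-R:R, each = 2L * R + 1L)
  dr <- rep(-R:R, times = 2L * R + 1L)
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  ord <- order(u^2 + v^2, dr, dc)[seq_len(nPix)]
  cbind(dr = dr[ord], dc = dc[ord])
}

# Rejection placement of instances given their pixel counts; instances are
# kept >= `gap` px apart so ground-truth areas stay unambiguous.
placeInstances <- function(width, height, pixelCounts, aspects, thetas,
                           gap = 2L, maxAttempts = 1000L) {
  lab <- matrix(0L, nrow = height, ncol = width)
  blocked <- matrix(FALSE, nrow = height, ncol = width)
  gapOff <- which(outer((-gap:gap)^2, (-gap:gap)^2, "+") <= gap^2,
                  arr.ind = TRUE) - (gap + 1L)
  placed <- 0L
  for (i in seq_along(pixelCounts)) {
    off <- ellipseOffsets(pixelCounts[i], aspects[i], thetas[i])
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      r0 <- sample.int(height, 1L)
      c0 <- sample.int(width, 1L)
      rr <- r0 + off[, 1L]
      cc <- c0 + off[, 2L]
      if (any(rr < 1L | rr > height | cc < 1L | cc > width)) next
      idx <- rr + (cc - 1L) * height
      if (any(blocked[idx])) next
      placed <- placed + 1L
      lab[idx] <- placed
      # block the instance plus a circular margin of `gap` px
      br <- rep(rr, each = nrow(gapOff)) + gapOff[, 1L]
      bc <- rep(cc, each = nrow(gapOff)) + gapOff[, 2L]
      keep <- br >= 1L & br <= height & bc >= 1L & bc <= width
      blocked[br[keep] + (bc[keep] - 1L) * height] <- TRUE
      ok <- TRUE
      break
    }
    if (!ok)
      warning(sprintf(
        "instance %d could not be placed after %d attempts; placed %d of %d",
        i, maxAttempts, placed, length(pixelCounts)), call. = FALSE)
  }
  list(labels = lab, nPlaced = placed)
}

renderPlanes <- function(mask, nPlanes, foreground, background, noiseSd) {
  base <- matrix(background, nrow = nrow(mask), ncol = ncol(mask))
  base[mask] <- foreground
  lapply(seq_len(nPlanes), function(z) {
    p <- base + matrix(rnorm(length(base), sd = noiseSd), nrow = nrow(base))
    p[p < 0] <- 0
    p
  })
}

#' Generate a synthetic mitochondria image with exact ground truth
#'
#' Places non-overlapping bright elliptical instances (aspect ratio uniform
#' in [1, 2], random orientation) whose pixel areas are drawn from a
#' lognormal law, on a darker background, with independent additive Gaussian
#' noise per z-plane clipped at zero. Placement is by rejection sampling
#' (up to 1000 attempts per instance); if an instance cannot be placed the
#' ground truth reports how many were, never silently fewer.
#'
#' @param spec a [mitoImageSpec()] object
#' @return a list with elements `stack` ([ImageStack-class]) and
#'   `truth` ([GroundTruth-class])
#' @examples
#' sim <- simulateMitoImage(mitoImageSpec(width = 128, height = 128,
#'                                        nInstances = 5, seed = 7))
#' trueAreas(sim$truth)
#' @export
simulateMitoImage <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    px2 <- spec@pixelSize^2
    n <- spec@nInstances
    areas <- 10^rnorm(n, spec@log10AreaMean, spec@log10AreaSd)
    counts <- pmax(1L, as.integer(round(areas / px2)))
    aspects <- runif(n, 1, 2)
    thetas <- runif(n, 0, pi)
    pl <- placeInstances(spec@width, spec@height, counts, aspects, thetas)
    stack <- ImageStack(
      renderPlanes(pl$labels > 0L, spec@nPlanes, spec@foreground,
                   spec@background, spec@noiseSd),
      pixelSizeUm = spec@pixelSize, channel = "mito")
    nPlaced <- pl$nPlaced
    realAreas <- if (nPlaced > 0)
      tabulate(pl$labels[pl$labels > 0L], nbins = nPlaced) * px2
    else numeric()
    truth <- GroundTruth(InstanceLabelMap(pl$labels, spec@pixelSize),
                         realAreas, nRequested = n, nPlaced = nPlaced)
    list(stack = stack, truth = truth)
  })
}

#' Generate a two-channel (total / active mitochondria) synthetic pair
#'
#' Emulates a MitoTracker-type channel labelling all mitochondria and a
#' TMRE-type channel labelling only polarized (active) ones: the active
#' channel renders a seed-deterministic random subset of the instances whose
#' summed area is within one instance of `activeFraction` times the total
#' instance area (random permutation, greedy prefix).
#'
#' @param spec a [mitoImageSpec()] object
#' @param activeFraction target active area fraction in [0, 1]
#' @return a list: `total`, `active` (ImageStacks), `truth` (GroundTruth for
#'   the total channel), `activeIds` (instance ids in the active channel),
#'   `activeFractionRealized` (realized area fraction)
#' @export
simulateTwoChannel <- function(spec, activeFraction) {
  stopifnot(activeFraction >= 0, activeFraction <= 1)
  sim <- simulateMitoImage(spec)
  lab <- labelMatrix(instanceMap(sim$truth))
  areas <- trueAreas(sim$truth)
  n <- length(areas)
  withSeed(spec@seed + 1L, {
    target <- activeFraction * sum(areas)
    ids <- integer()
    if (n > 0 && activeFraction > 0) {
      perm <- sample.int(n)
      tot <- 0
      for (i in perm) {
        if (tot + areas[i] <= target + 1e-9) {
          ids <- c(ids, i)
          tot <- tot + areas[i]
        }
      }
      ids <- sort(ids)
    }
    activeMask <- matrix(lab %in% ids, nrow = nrow(lab))
    active <- ImageStack(
      renderPlanes(activeMask, spec@nPlanes, spec@foreground,
                   spec@background, spec@noiseSd),
      pixelSizeUm = spec@pixelSize, channel = "tmre")
    sim$stack@channel <- "mitotracker"
    list(total = sim$stack, active = active, truth = sim$truth,
         activeIds = ids,
         activeFractionRealized =
           if (sum(areas) > 0) sum(areas[ids]) / sum(areas) else 0)
  })
}

#' Generate a synthetic lipid-droplet image
#'
#' Disjoint bright disks on a dark background; per-droplet areas are drawn
#' uniformly from `areaRangeUm2` and realised exactly on the grid (up to one
#' pixel area), so size filters are testable against ground truth.
#'
#' @param width,height field size in pixels
#' @param pixelSizeUm micrometres per pixel
#' @param nDroplets droplets to place
#' @param areaRangeUm2 length-2 range of droplet areas in um^2
#' @param foreground,background,noiseSd intensity model as in
#'   [simulateMitoImage()]
#' @param nPlanes z-planes
#' @param seed integer RNG seed
#' @return list with `stack` and `truth` as in [simulateMitoImage()]
#' @export
simulateDropletImage <- function(width = 200L, height = 200L,
                                 pixelSizeUm = 0.5, nDroplets = 25L,
                                 areaRangeUm2 = c(0.5, 5), foreground = 180,
                                 background = 20, noiseSd = 5, nPlanes = 1L,
                                 seed = 1L) {
  stopifnot(length(areaRangeUm2) == 2L, all(areaRangeUm2 > 0),
            areaRangeUm2[1] <= areaRangeUm2[2], nDroplets >= 0)
  withSeed(seed, {
    px2 <- pixelSizeUm^2
    areas <- runif(nDroplets, areaRangeUm2[1], areaRangeUm2[2])
    counts <- pmax(1L, as.integer(round(areas / px2)))
    pl <- placeInstances(width, height, counts, rep(1, nDroplets),
                         rep(0, nDroplets))
    stack <- ImageStack(
      renderPlanes(pl$labels > 0L, nPlanes, foreground, background, noiseSd),
      pixelSizeUm = pixelSizeUm, channel = "lipidtox")
    realAreas <- if (pl$nPlaced > 0)
      tabulate(pl$labels[pl$labels > 0L], nbins = pl$nPlaced) * px2
    else numeric()
    truth <- GroundTruth(InstanceLabelMap(pl$labels, pixelSizeUm), realAreas,
                         nRequested = nDroplets, nPlaced = pl$nPlaced)
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic muscle-fillet image with a known attached fraction
#'
#' Bright "muscle" patches cover `attachedFraction` of the field. The patch
#' mask is a smoothed Gaussian random field thresholded at the matching
#' sample quantile, which pins the realised coverage to the target within
#' one pixel in n; the realised fraction is returned alongside the stack.
#'
#' @param width,height field size in pixels
#' @param attachedFraction target covered fraction in [0, 1]
#' @param pixelSizeUm micrometres per pixel
#' @param foreground,background,noiseSd intensity model
#' @param nPlanes z-planes
#' @param smoothSigmaPx patch scale: blur sd of the random field, px
#' @param seed integer RNG seed
#' @return list: `stack` ([ImageStack-class]), `attachedFractionTrue`
#'   (realized fraction), `mask` (logical ground-truth muscle mask)
#' @export
simulateFilletImage <- function(width = 256L, height = 256L,
                                attachedFraction = 0.5, pixelSizeUm = 0.65,
                                foreground = 180, background = 20,
                                noiseSd = 5, nPlanes = 3L,
                                smoothSigmaPx = 12, seed = 1L) {
  stopifnot(attachedFraction >= 0, attachedFraction <= 1)
  withSeed(seed, {
    if (attachedFraction == 0) {
      mask <- matrix(FALSE, nrow = height, ncol = width)
    } else if (attachedFraction == 1) {
      mask <- matrix(TRUE, nrow = height, ncol = width)
    } else {
      field <- matrix(rnorm(width * height), nrow = height)
      field <- gaussianBlur(field, smoothSigmaPx)
      mask <- field > quantile(field, 1 - attachedFraction)
    }
    stack <- ImageStack(
      renderPlanes(mask, nPlanes, foreground, background, noiseSd),
      pixelSizeUm = pixelSizeUm, channel = "phalloidin")
    list(stack = stack, attachedFractionTrue = mean(mask), mask = mask)
  })
}
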