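# Macro-style fluorescence quantifications: TMRE/MitoTracker active-area
# ratio, lipid-droplet particle counting and density, total corrected cell
# fluorescence (TCCF), per-nucleus intensity ratios, and percent muscle
# attachment within a cuticle ROI.

#' Percentage of active mitochondria from a TMRE / MitoTracker pair
#'
#' Both channels are processed identically — max-intensity z-projection,
#' 8-bit conversion, Gaussian blur, bright-outlier removal, optional
#' rectangular ROI crop, IsoData auto-threshold — and the thresholded
#' foreground area of the membrane-potential (TMRE) channel is divided by
#' that of the total-mitochondria (MitoTracker) channel, times 100.
#'
#' @param totalStack [ImageStack-class], the all-mitochondria channel
#' @param activeStack [ImageStack-class], the membrane-potential channel;
#'   same dimensions and calibration
#' @param roi optional rectangular [Roi-class] to crop both channels to
#' @param sigmaPx Gaussian blur sd in px (default 2)
#' @param outlierRadiusPx,outlierThreshold despeckle settings (defaults 2, 50)
#' @return list: `area_total_um2`, `area_active_um2`, `percent_active`,
#'   `flagged` (TRUE when the ratio exceeds 100)
#' @export
percentActiveMitochondria <- function(totalStack, activeStack, roi = NULL,
                                      sigmaPx = 2, outlierRadiusPx = 2L,
                                      outlierThreshold = 50) {
  stopifnot(identical(dim(totalStack@planes[[1]]),
                      dim(activeStack@planes[[1]])),
            isTRUE(all.equal(totalStack@pixelSize, activeStack@pixelSize)))
  px2 <- totalStack@pixelSize^2
  chainArea <- function(stack) {
    img <- maxProject(stack)
    img <- to8bit(img)
    img <- gaussianBlur(img, sigmaPx)
    img <- removeOutliers(img, outlierRadiusPx, outlierThreshold)
    if (!is.null(roi)) {
      m <- roiMask(roi, dim(img))
      rows <- range(which(rowSums(m) > 0))
      cols <- range(which(colSums(m) > 0))
      img <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    }
    if (max(img) == min(img)) return(0)  # no signal, nothing to threshold
    sum(isodataThreshold(img)$mask) * px2
  }
  areaTotal <- chainArea(totalStack)
  if (areaTotal == 0)
    stop("no mitochondrial area detected in the total channel")
  areaActive <- chainArea(activeStack)
  pct <- 100 * areaActive / areaTotal
  if (pct > 100)
    warning("active area exceeds total area (> 100%)", call. = FALSE)
  list(area_total_um2 = areaTotal, area_active_um2 = areaActive,
       percent_active = pct, flagged = pct > 100)
}

#' ParticleFilter: a calibrated size window for particle analysis
#'
#' Components are kept when min_area <= area < max_area (half-open), in
#' calibrated um^2 by default; `maxArea = Inf` reproduces the
#' "2-infinity" extramyocellular setting and `c(0, 10)` the "0.00-10"
#' droplet setting.
#'
#' @param minArea,maxArea area window; 0 <= minArea < maxArea
#' @param units "um2" (calibrated, default) or "px"
#' @return a classed list used by [countParticles()]
#' @export
particleFilter <- function(minArea = 0, maxArea = Inf, units = c("um2", "px")) {
  stopifnot(minArea >= 0, minArea < maxArea)
  structure(list(min_area = minArea, max_area = maxArea,
                 units = match.arg(units)),
            class = "ParticleFilter")
}

#' Count particles in a binary mask with a size filter
#'
#' 8-connected component labelling followed by the half-open size filter
#' `[minArea, maxArea)`; the count is normalised to the field area to give a
#' density per mm^2. With no `fieldAreaMm2` supplied the full mask area is
#' used.
#'
#' @param mask logical (or 0/1) matrix, TRUE = particle
#' @param filter a [particleFilter()]
#' @param pixelSizeUm micrometres per pixel
#' @param fieldAreaMm2 normalisation area in mm^2 (default: whole field)
#' @return list: `count`, `areas_um2` (kept particles, label order),
#'   `density_per_mm2`, `n_components` (before filtering)
#' @export
countParticles <- function(mask, filter = particleFilter(),
                           pixelSizeUm, fieldAreaMm2 = NULL) {
  stopifnot(pixelSizeUm > 0)
  if (is.null(fieldAreaMm2))
    fieldAreaMm2 <- length(mask) * pixelSizeUm^2 / 1e6
  stopifnot(fieldAreaMm2 > 0)
  lab <- cpp_label8(matrix(mask > 0, nrow = nrow(mask)))
  n <- max(0L, lab)
  if (n == 0L)
    return(list(count = 0L, areas_um2 = numeric(),
                density_per_mm2 = 0, n_components = 0L))
  px <- tabulate(lab[lab > 0L], nbins = n)
  areas <- if (filter$units == "um2") px * pixelSizeUm^2 else px
  keep <- areas >= filter$min_area & areas < filter$max_area
  areasOut <- if (filter$units == "um2") areas[keep]
              else px[keep] * pixelSizeUm^2
  list(count = sum(keep), areas_um2 = areasOut,
       density_per_mm2 = sum(keep) / fieldAreaMm2, n_components = n)
}

#' Total corrected cell fluorescence (TCCF)
#'
#' TCCF = integrated intensity of the cell ROI minus (cell ROI pixel count
#' x mean intensity over the pooled background ROIs); invariant to adding a
#' constant offset to the whole image.
#'
#' @param image numeric matrix
#' @param cellRoi [Roi-class] around the structure of interest
#' @param backgroundRois list of one or more background [Roi-class]s
#' @return list: `integrated_density`, `roi_area_px`, `background_mean`,
#'   `tccf`
#' @export
tccf <- function(image, cellRoi, backgroundRois) {
  if (is(backgroundRois, "Roi")) backgroundRois <- list(backgroundRois)
  stopifnot(length(backgroundRois) >= 1L)
  cellMask <- roiMask(cellRoi, dim(image))
  if (!any(cellMask)) stop("cell ROI covers no pixels")
  bgMask <- Reduce(`|`, lapply(backgroundRois, roiMask, dimPx = dim(image)))
  if (!any(bgMask)) stop("background ROIs cover no pixels")
  if (any(cellMask & bgMask))
    warning("cell and background ROIs overlap", call. = FALSE)
  intden <- sum(image[cellMask])
  bgMean <- mean(image[bgMask])
  npx <- sum(cellMask)
  list(integrated_density = intden, roi_area_px = npx,
       background_mean = bgMean, tccf = intden - npx * bgMean)
}

#' Per-ROI intensity ratio between two channels
#'
#' For each (typically nuclear) ROI, the mean grey value in the numerator
#' channel divided by the mean grey value in the denominator channel — the
#' FOXO/DAPI normalisation, and equally the mCherry/GFP tandem-reporter
#' ratio. An ROI with zero denominator mean is reported as NA with a
#' warning; the others are still returned.
#'
#' @param numeratorImage,denominatorImage numeric matrices, same dimensions
#' @param rois list of [Roi-class]s
#' @return numeric vector of ratios, one per ROI (named by ROI labels)
#' @export
nuclearRatio <- function(numeratorImage, denominatorImage, rois) {
  stopifnot(identical(dim(numeratorImage), dim(denominatorImage)))
  if (is(rois, "Roi")) rois <- list(rois)
  out <- vapply(rois, function(r) {
    m <- roiMask(r, dim(numeratorImage))
    if (!any(m)) stop(sprintf("ROI '%s' covers no pixels", r@label))
    den <- mean(denominatorImage[m])
    if (den == 0) {
      warning(sprintf("ROI '%s': zero denominator mean", r@label),
              call. = FALSE)
      return(NA_real_)
    }
    mean(numeratorImage[m]) / den
  }, numeric(1))
  names(out) <- vapply(rois, function(r) r@label, character(1))
  out
}

#' Percent muscle attachment within a cuticle ROI
#'
#' The image is binarised with the IsoData auto-threshold computed from the
#' pixels inside the ROI; the raw fraction is thresholded-foreground pixels
#' over ROI pixels. When a control mean is supplied the fraction is also
#' normalised so the control group sits at 1.
#'
#' @param image numeric matrix (typically a phalloidin channel plane or
#'   projection)
#' @param cuticleRoi [Roi-class] drawn around the fillet cuticle
#' @param controlMean optional raw fraction of the control group
#' @return list: `raw_fraction`, `normalized_fraction` (NA when no control
#'   mean is given), `threshold`
#' @export
muscleIntegrity <- function(image, cuticleRoi, controlMean = NULL) {
  m <- roiMask(cuticleRoi, dim(image))
  if (!any(m)) stop("cuticle ROI covers no pixels")
  v <- image[m]
  if (max(v) == min(v)) {
    # constant ROI: nothing to threshold; all-bright counts as attached
    th <- NA_real_
    raw <- as.numeric(v[1] > 0)
  } else {
    th <- isodataThreshold(matrix(v, ncol = 1))$threshold
    raw <- mean(v > th)
  }
  list(raw_fraction = raw,
       normalized_fraction = if (is.null(controlMean)) NA_real_
                             else raw / controlMean,
       threshold = th)
}
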