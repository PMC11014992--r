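# Rasterisation of rectangle/polygon ROIs to pixel masks. Coordinates are
# 0-based (x = column, y = row); a pixel belongs to a polygon when its
# centre is inside (even-odd rule).

#' Rasterise an ROI to a logical pixel mask
#'
#' @param roi a [Roi-class] from [rectRoi()] or [polygonRoi()]
#' @param dimPx image dimensions as c(rows, cols)
#' @return logical matrix, TRUE = inside the ROI
#' @export
roiMask <- function(roi, dimPx) {
  stopifnot(is(roi, "Roi"), length(dimPx) == 2L)
  nr <- dimPx[1]; nc <- dimPx[2]
  mask <- matrix(FALSE, nr, nc)
  v <- roi@vertices
  if (roi@shape == "rectangle") {
    rows <- max(1L, floor(v[1, 2]) + 1L):min(nr, floor(v[2, 2]) + 1L)
    cols <- max(1L, floor(v[1, 1]) + 1L):min(nc, floor(v[2, 1]) + 1L)
    mask[rows, cols] <- TRUE
    return(mask)
  }
  # even-odd crossing number at pixel centres, vectorised over pixels
  px <- rep(seq_len(nc) - 1L, each = nr)
  py <- rep(seq_len(nr) - 1L, times = nc)
  inside <- rep(FALSE, nr * nc)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

roiPixels <- function(image, roi) {
  m <- roiMask(roi, dim(image))
  if (!any(m)) stop(sprintf("ROI '%s' covers no pixels", roi@label))
  image[m]
}
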