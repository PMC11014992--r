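# Image-processing steps of the fluorescence macros: max projection, 8-bit
# conversion, Gaussian smoothing, outlier removal and IsoData
# (Ridler-Calvard iterative intermeans) auto-thresholding.

#' @rdname maxProject
setMethod("maxProject", "ImageStack", function(x) {
  Reduce(pmax, x@planes)
})

#' @rdname maxProject
setMethod("maxProject", "matrix", function(x) x)

#' Convert an image to 8-bit by linear min-max rescale
#'
#' Maps [min, max] linearly onto [0, 255] with half-up rounding; a constant
#' image maps to all zeros.
#'
#' @param image numeric matrix
#' @return integer matrix with values in 0..255
#' @examples
#' to8bit(matrix(c(0, 100, 200), 1))   # 0, 128, 255
#' @export
to8bit <- function(image) {
  rng <- range(image)
  out <- if (rng[2] > rng[1])
    floor((image - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  else image * 0
  storage.mode(out) <- "integer"
  out
}

# reflect-pad a matrix by k rows/cols on every side
reflectPad <- function(m, k) {
  if (k == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(k, nr))), seq_len(nr),
          nr + 1 - rev(seq_len(min(k, nr))))
  ci <- c(rev(seq_len(min(k, nc))), seq_len(nc),
          nc + 1 - rev(seq_len(min(k, nc))))
  m[ri, ci, drop = FALSE]
}

#' Isotropic Gaussian blur
#'
#' Separable convolution with a normalised Gaussian kernel truncated at
#' 3 sigma, with reflective borders. `sigmaPx = 0` is the identity; a
#' constant image is unchanged (the kernel sums to 1).
#'
#' @param image numeric matrix
#' @param sigmaPx Gaussian sd in pixels (>= 0)
#' @return numeric matrix of the same dimensions
#' @export
gaussianBlur <- function(image, sigmaPx) {
  stopifnot(sigmaPx >= 0)
  if (sigmaPx == 0) return(image)
  k <- max(1L, ceiling(3 * sigmaPx))
  kern <- dnorm(-k:k, sd = sigmaPx)
  kern <- kern / sum(kern)
  pad <- reflectPad(image, k)
  nr <- nrow(image); nc <- ncol(image)
  # vertical then horizontal pass, accumulating shifted slices
  tmp <- matrix(0, nr, nc + 2L * k)
  for (i in seq_along(kern))
    tmp <- tmp + kern[i] * pad[(i - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(kern))
    out <- out + kern[i] * tmp[, (i - 1L) + seq_len(nc), drop = FALSE]
  out
}

#' Remove outlier pixels by a circular median filter
#'
#' Each pixel is replaced by the median of its circular neighbourhood
#' (radius in px, centre included, clipped at the borders) if and only if it
#' deviates from that median by more than `threshold` — the despeckle
#' behaviour of the ImageJ "Remove Outliers" tool. The default removes
#' bright outliers; dark and two-sided modes are available.
#'
#' @param image numeric matrix
#' @param radiusPx neighbourhood radius in pixels (>= 1; default 2)
#' @param threshold deviation above which a pixel is replaced (default 50)
#' @param mode "bright" (default), "dark" or "both"
#' @return numeric matrix
#' @export
removeOutliers <- function(image, radiusPx = 2L, threshold = 50,
                           mode = c("bright", "dark", "both")) {
  stopifnot(radiusPx >= 1)
  mode <- match.arg(mode)
  cpp_remove_outliers(image, as.integer(radiusPx), threshold,
                      match(mode, c("bright", "dark", "both")))
}

#' IsoData (Ridler-Calvard) automatic threshold
#'
#' Iterative intermeans: starting from the middle of the dynamic range, the
#' threshold T is
#' replaced by the average of the mean intensity at or below T and the mean
#' above T, until it no longer moves. The mask selects pixels strictly above
#' the converged threshold. Adding a constant to the image shifts T by that
#' constant and leaves the mask unchanged.
#'
#' @param image numeric matrix with at least two distinct values
#' @return list with `threshold` (numeric) and `mask` (logical matrix,
#'   TRUE = foreground)
#' @examples
#' isodataThreshold(matrix(c(10, 10, 200, 200), 2))$threshold  # 105
#' @export
isodataThreshold <- function(image) {
  v <- as.vector(image)
  if (max(v) == min(v))
    stop("cannot threshold a constant image")
  t0 <- (max(v) + min(v)) / 2  # classical mid-range initialisation
  for (i in 1:1000) {
    lo <- v[v <= t0]
    hi <- v[v > t0]
    if (length(hi) == 0L) { t0 <- max(v[v < max(v)]); next }
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-9) { t0 <- t1; break }
    t0 <- t1
  }
  list(threshold = t0, mask = matrix(image > t0, nrow = nrow(image)))
}
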