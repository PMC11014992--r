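# TIFF / CSV / JSON input-output. Grey-level convention: stacks hold raw
# intensities on a 0..(2^bits - 1) scale; TIFFs are written as 8- or 16-bit
# grayscale with values rounded to integers, so a write/read cycle of
# integer data is bit-identical.

#' Read a grayscale TIFF into an ImageStack
#'
#' Accepts single- or multi-page 8/16-bit grayscale TIFF; pages become
#' planes in file order and intensities are kept on their native integer
#' scale. The pixel calibration comes from the caller; the TIFF X-resolution
#' tag is used only as a fallback (with a message) when none is supplied.
#'
#' @param path TIFF file
#' @param pixelSizeUm calibration in micrometres per pixel; if NULL the TIFF
#'   resolution tag is tried
#' @param channel channel name to attach
#' @return an [ImageStack-class]
#' @export
readStack <- function(path, pixelSizeUm = NULL, channel = "") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("RGB or multi-sample TIFF not supported: expected grayscale")
  if (is.null(pixelSizeUm)) {
    res <- attr(pages[[1]], "x.resolution")
    if (is.null(res) || !isTRUE(res > 0))
      stop("missing calibration: supply pixelSizeUm")
    # resolution tags are pixels per unit; assume the unit is cm unless told
    unit <- attr(pages[[1]], "resolution.unit")
    perUm <- if (identical(unit, "inch")) res / 25400 else res / 10000
    pixelSizeUm <- 1 / perUm
    message(sprintf(
      "pixel size taken from TIFF resolution tag: %.6g um/px", pixelSizeUm))
  }
  ImageStack(lapply(pages, function(p) {
    matrix(as.double(p), nrow = nrow(p))  # drop TIFF tag attributes
  }), pixelSizeUm = pixelSizeUm, channel = channel)
}

#' Write an ImageStack as a multi-page grayscale TIFF
#'
#' Intensities are rounded, clipped to the sample range and stored at the
#' requested bit depth.
#'
#' @param stack an [ImageStack-class]
#' @param path output file
#' @param bitsPerSample 8 or 16
#' @return the path, invisibly
#' @export
writeStack <- function(stack, path, bitsPerSample = 16L) {
  stopifnot(bitsPerSample %in% c(8L, 16L))
  top <- 2^bitsPerSample - 1
  pages <- lapply(stack@planes, function(p) {
    q <- pmin(pmax(floor(p + 0.5), 0), top)
    q / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample,
                  compression = "none")
  invisible(path)
}

#' Write / read an instance label map as 16-bit TIFF
#'
#' @param labelMap an [InstanceLabelMap-class] (at most 65535 instances)
#' @param path TIFF file
#' @param pixelSizeUm calibration to attach on read
#' @return the path (write) or an [InstanceLabelMap-class] (read)
#' @export
writeLabelMap <- function(labelMap, path) {
  lab <- labelMap@labels
  stopifnot(max(0L, lab) <= 65535L)
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path, pixelSizeUm) {
  p <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(p) <- "integer"
  InstanceLabelMap(p, pixelSizeUm)
}

#' Read a binary annotation mask from TIFF (nonzero = foreground)
#'
#' @param path TIFF file
#' @return logical matrix
#' @export
readMask <- function(path) {
  p <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(p)) != 2L) stop("expected a single-page grayscale mask")
  p > 0
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

writeTable <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
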