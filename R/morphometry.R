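# Calibrated area morphometry: per-instance areas (pixel count x pixel
# area), log10 transform, small/medium/large size classes, per-replicate
# size-class distributions and their chi-square comparison.

#' Measure calibrated areas of every segmented instance
#'
#' The area of an instance is its pixel count multiplied by the pixel area
#' (pixel_size_um squared); the log10-transformed area drives the size
#' classes.
#'
#' @param labelMap an [InstanceLabelMap-class] carrying its calibration
#' @return data.frame with one row per instance, sorted by instance id:
#'   instance_id, pixel_count, area_um2, log10_area, size_class
#' @examples
#' lab <- matrix(0L, 20, 20); lab[1:10, 1:10] <- 1L
#' measureAreas(InstanceLabelMap(lab, 0.1))   # 100 px -> 1 um^2, medium
#' @export
measureAreas <- function(labelMap) {
  stopifnot(is(labelMap, "InstanceLabelMap"))
  if (!isTRUE(labelMap@pixelSize > 0))
    stop("label map has no pixel calibration")
  lab <- labelMap@labels
  n <- max(0L, lab)
  if (n == 0L)
    return(data.frame(instance_id = integer(), pixel_count = integer(),
                      area_um2 = numeric(), log10_area = numeric(),
                      size_class = character()))
  counts <- tabulate(lab[lab > 0L], nbins = n)
  area <- counts * labelMap@pixelSize^2
  # log10(count) + 2 log10(px) is better conditioned than log10(count*px^2):
  # it keeps areas landing exactly on a class boundary (e.g. 100 px at
  # 0.1 um/px = 1 um^2) on the correct side
  out <- data.frame(instance_id = seq_len(n), pixel_count = counts,
                    area_um2 = area,
                    log10_area = log10(counts) + 2 * log10(labelMap@pixelSize))
  out$size_class <- classifySizes(out$log10_area)
  out
}

#' Assign log10-area size classes
#'
#' Bins log10-transformed areas (um^2) into three classes:
#' small when X <= -0.5, medium when -0.5 < X <= 0, large when X > 0 —
#' i.e. class boundaries at about 0.316 um^2 and exactly 1 um^2, inclusive
#' on the left class. Every finite value maps to exactly one class.
#'
#' @param x numeric vector of log10 areas, or a data.frame with a
#'   `log10_area` column (rows are returned with `size_class` filled)
#' @return character vector (or the data.frame) of "small"/"medium"/"large"
#' @export
classifySizes <- function(x) {
  if (is.data.frame(x)) {
    x$size_class <- classifySizes(x$log10_area)
    return(x)
  }
  stopifnot(all(is.finite(x)))
  ifelse(x <= -0.5, "small", ifelse(x <= 0, "medium", "large"))
}

#' Summarise size-class percentages across replicates
#'
#' Computes, within each replicate, the percentage of instances in each size
#' class (from that replicate's own total) and averages the percentages
#' across replicates.
#'
#' @param replicateRecords list of per-replicate record data.frames as
#'   returned by [measureAreas()]
#' @param groupLabel group name
#' @return a [SizeClassDistribution-class]
#' @export
summarizeDistribution <- function(replicateRecords, groupLabel = "") {
  stopifnot(is.list(replicateRecords), length(replicateRecords) >= 1L)
  classes <- c("small", "medium", "large")
  counts <- t(vapply(seq_along(replicateRecords), function(i) {
    rec <- replicateRecords[[i]]
    if (nrow(rec) == 0L)
      stop(sprintf("replicate %d has no instances", i))
    vapply(classes, function(cl) sum(rec$size_class == cl), numeric(1))
  }, numeric(3)))
  pct <- counts / rowSums(counts) * 100
  colnames(counts) <- colnames(pct) <- classes
  new("SizeClassDistribution", groupLabel = groupLabel,
      perReplicatePct = pct, perReplicateCounts = counts,
      meanPct = colMeans(pct))
}

#' Chi-square comparison of two size-class distributions
#'
#' Pearson chi-square (no continuity correction) on a 2 x 3 contingency
#' table, df = 2, p from the upper tail. `tableMode` selects the table:
#' `"percent_as_count"` (default) uses each group's mean percentages as the
#' row entries — mirroring the common practice of testing the averaged
#' percentage distribution — while `"pooled_counts"` uses raw instance
#' counts summed across replicates, the statistically orthodox choice. Both
#' are reported by the pipeline so the reader can compare.
#'
#' @param a,b [SizeClassDistribution-class] objects
#' @param tableMode "percent_as_count" or "pooled_counts"
#' @return list: `chi2`, `df`, `p_value`, `table`, `table_mode`
#' @export
compareDistributions <- function(a, b,
                                 tableMode = c("percent_as_count",
                                               "pooled_counts")) {
  tableMode <- match.arg(tableMode)
  tab <- switch(tableMode,
    percent_as_count = rbind(round(a@meanPct, 6), round(b@meanPct, 6)),
    pooled_counts = rbind(colSums(a@perReplicateCounts),
                          colSums(b@perReplicateCounts))
  )
  rownames(tab) <- c(a@groupLabel, b@groupLabel)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("degenerate table: an expected cell is 0")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), table = tab, table_mode = tableMode)
}
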