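# Independent oracles, kept deliberately naive: a brute-force O(n^2) DBSCAN
# and an exhaustive-scan intermeans threshold. They share only the contract
# with the package implementations, not the code path.

# Canonical DBSCAN by full pairwise distances: points visited in row order,
# neighbours (self included) sorted by index, border points keep the first
# cluster that reaches them.
bruteDbscan <- function(m, eps, minPts) {
  m <- as.matrix(m)
  n <- nrow(m)
  d2 <- as.matrix(dist(m))^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  labels <- integer(n)
  visited <- logical(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nb[[i]]) < minPts) next
    cid <- cid + 1L
    labels[i] <- cid
    seeds <- nb[[i]]
    s <- 1L
    while (s <= length(seeds)) {
      q <- seeds[s]
      s <- s + 1L
      if (!visited[q]) {
        visited[q] <- TRUE
        if (length(nb[[q]]) >= minPts) seeds <- c(seeds, nb[[q]])
      }
      if (labels[q] == 0L) labels[q] <- cid
    }
  }
  labels
}

# Exhaustive scan over every possible cut of an integer-valued image: a cut
# value s (largest grey level in the lower part) is an intermeans fixed
# point when thresholding at its own intermean reproduces the same
# partition, i.e. s <= intermean(s) < next grey level above s. The induced
# foreground mask is {x > s}.
isodataFixedPoints <- function(v) {
  vals <- sort(unique(v))
  n <- length(vals)
  keep <- vapply(seq_len(n - 1), function(k) {
    s <- vals[k]
    im <- (mean(v[v <= s]) + mean(v[v > s])) / 2
    im >= s && im < vals[k + 1]
  }, logical(1))
  vals[seq_len(n - 1)][keep]
}

# Hand computation of the Pearson chi-square statistic on a contingency table
pearsonChi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

smallSpec <- function(...) {
  do.call(mitoImageSpec,
          utils::modifyList(list(width = 160L, height = 160L,
                                 nInstances = 8L), list(...)))
}
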