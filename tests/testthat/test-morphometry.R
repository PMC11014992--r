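test_that("areas are pixel counts times pixel area", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L
  rec <- measureAreas(InstanceLabelMap(lab, 0.1))
  expect_equal(rec$pixel_count, 100L)
  expect_equal(rec$area_um2, 1.0)
  expect_equal(rec$log10_area, 0)
  expect_equal(rec$size_class, "medium")

  empty <- measureAreas(InstanceLabelMap(matrix(0L, 5, 5), 0.1))
  expect_equal(nrow(empty), 0)

  # identity pipeline: measuring the ground-truth map returns its areas
  sim <- simulateMitoImage(smallSpec(seed = 71L))
  rec <- measureAreas(instanceMap(sim$truth))
  expect_equal(rec$area_um2, trueAreas(sim$truth))
  expect_equal(rec$instance_id, seq_along(trueAreas(sim$truth)))
})

test_that("size classes follow the log10 boundary rule exactly", {
  expect_equal(classifySizes(-0.5), "small")    # X <= -0.5
  expect_equal(classifySizes(0), "medium")      # -0.5 < X <= 0
  expect_equal(classifySizes(0.001), "large")   # X > 0
  expect_equal(classifySizes(c(-3, -0.50000001, -0.499999, 2)),
               c("small", "small", "medium", "large"))

  # the binning is a partition: one class per area over a wide sweep
  x <- seq(-4, 4, length.out = 10000)
  cls <- classifySizes(x)
  expect_true(all(cls %in% c("small", "medium", "large")))
  expect_equal((x <= -0.5) + (x > -0.5 & x <= 0) + (x > 0), rep(1, 10000))
  # boundaries sit at 10^-0.5 and 1 um^2
  expect_equal(classifySizes(log10(10^-0.5)), "small")
  expect_equal(classifySizes(log10(1)), "medium")
})

test_that("distributions summarise per replicate and average", {
  mk <- function(classes) data.frame(
    instance_id = seq_along(classes),
    pixel_count = rep(1L, length(classes)),
    area_um2 = rep(1, length(classes)),
    log10_area = rep(0, length(classes)), size_class = classes)
  d1 <- summarizeDistribution(list(mk(rep("large", 10))), "g")
  expect_equal(unname(meanPercentages(d1)), c(0, 0, 100))

  d2 <- summarizeDistribution(list(mk(rep("small", 4)),
                                   mk(rep("large", 7))), "g")
  expect_equal(unname(meanPercentages(d2)), c(50, 0, 50))

  d3 <- summarizeDistribution(list(mk(c(rep("small", 2), rep("medium", 3),
                                        rep("large", 5)))), "g")
  expect_equal(unname(meanPercentages(d3)), c(20, 30, 50))
  expect_equal(unname(rowSums(replicatePercentages(d3))), 100)

  expect_error(summarizeDistribution(list(mk(character(0))), "g"),
               "replicate 1")
})

test_that("chi-square comparison matches the hand formula", {
  mk <- function(s, m, l, label) {
    cls <- c(rep("small", s), rep("medium", m), rep("large", l))
    summarizeDistribution(list(data.frame(instance_id = seq_along(cls),
                                          pixel_count = 1L, area_um2 = 1,
                                          log10_area = 0, size_class = cls)),
                          label)
  }
  a <- mk(20, 30, 50, "a")
  b <- mk(50, 30, 20, "b")
  cmp <- compareDistributions(a, b, "percent_as_count")
  expect_equal(cmp$df, 2)
  expect_equal(cmp$chi2, pearsonChi2(rbind(c(20, 30, 50), c(50, 30, 20))),
               tolerance = 1e-10)
  expect_equal(cmp$chi2, 25.7142857142857, tolerance = 1e-6)

  same <- compareDistributions(a, mk(20, 30, 50, "a2"))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  pooled <- compareDistributions(a, b, "pooled_counts")
  expect_equal(pooled$chi2, cmp$chi2)  # counts were 100 per group here

  degenerate <- mk(0, 50, 50, "d")
  degenerate2 <- mk(0, 30, 70, "d2")
  expect_error(compareDistributions(degenerate, degenerate2), "degenerate")
})

test_that("null chi-square calibration and proportional-row zero", {
  set.seed(500)
  mkDist <- function(counts, label) {
    new("SizeClassDistribution", groupLabel = label,
        perReplicatePct = matrix(counts / sum(counts) * 100, 1),
        perReplicateCounts = matrix(counts, 1),
        meanPct = counts / sum(counts) * 100)
  }
  rejected <- 0L
  reps <- 1000L
  for (i in seq_len(reps)) {
    a <- mkDist(as.numeric(rmultinom(1, 150, c(0.3, 0.4, 0.3))), "a")
    b <- mkDist(as.numeric(rmultinom(1, 150, c(0.3, 0.4, 0.3))), "b")
    p <- compareDistributions(a, b, "pooled_counts")$p_value
    if (p < 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected / reps, 0.03)
  expect_lte(rejected / reps, 0.07)

  # proportional rows give exactly zero
  a <- mkDist(c(10, 20, 30), "a")
  b <- mkDist(c(20, 40, 60), "b")
  expect_equal(compareDistributions(a, b, "pooled_counts")$chi2, 0)
})

test_that("larger generator areas shift the distribution toward large", {
  largePct <- vapply(c(-0.6, -0.25, 0.1, 0.45), function(mu) {
    mean(vapply(1:5, function(s) {
      sim <- simulateMitoImage(mitoImageSpec(width = 384L, height = 384L,
                                             nInstances = 60L,
                                             log10AreaMean = mu, seed = s))
      rec <- measureAreas(instanceMap(sim$truth))
      100 * mean(rec$size_class == "large")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(largePct) > 0))
})
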