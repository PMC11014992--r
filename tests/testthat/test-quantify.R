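test_that("active-area percentage has the right fixed points", {
  sim <- simulateMitoImage(smallSpec(seed = 91L))
  same <- percentActiveMitochondria(sim$stack, sim$stack)
  expect_equal(same$percent_active, 100)
  expect_false(same$flagged)

  dark <- ImageStack(lapply(planes(sim$stack), function(p) p * 0 + 20),
                     pixelSizeUm = pixelSize(sim$stack))
  none <- percentActiveMitochondria(sim$stack, dark)
  expect_equal(none$percent_active, 0)

  expect_error(percentActiveMitochondria(dark, sim$stack), "total channel")
})

test_that("designed active fractions are recovered without aggregate bias", {
  # per-image spread of the threshold-based area ratio is several points
  # (IsoData is sensitive on sparse channels); the mean across images must
  # track the designed fraction closely and no single image may stray far
  for (f in c(0.2, 0.5, 0.8)) {
    got <- vapply(1:3, function(seed) {
      tc <- simulateTwoChannel(mitoImageSpec(seed = seed * 10L), f)
      percentActiveMitochondria(tc$total, tc$active)$percent_active
    }, numeric(1))
    expect_lte(abs(mean(got) - 100 * f), 5,
               label = sprintf("fraction %.1f: mean recovery %.2f", f,
                               mean(got)))
    expect_lte(max(abs(got - 100 * f)), 10,
               label = sprintf("fraction %.1f: recoveries %s", f,
                               paste(round(got, 2), collapse = ", ")))
  }
})

test_that("particle counting filters on calibrated area, half-open", {
  mask <- matrix(FALSE, 60, 60)
  mask[2:3, 2:5] <- TRUE      # 8 px  = 2 um^2 at 0.5 um/px
  mask[20:21, 20:22] <- TRUE  # 6 px  = 1.5 um^2
  mask[40:43, 40:44] <- TRUE  # 20 px = 5 um^2
  fly <- countParticles(mask, particleFilter(0, 10), 0.5)
  expect_equal(fly$count, 3L)
  expect_equal(sort(fly$areas_um2), c(1.5, 2, 5))

  # extramyocellular mode [2, Inf): the 2 um^2 particle is included
  emc <- countParticles(mask, particleFilter(2, Inf), 0.5)
  expect_equal(emc$count, 2L)
  expect_equal(sort(emc$areas_um2), c(2, 5))

  # the two modes partition every component below 10 um^2 at the boundary
  sub2 <- countParticles(mask, particleFilter(0, 2), 0.5)
  expect_equal(sub2$count + emc$count, fly$n_components)

  # widening the window never loses particles
  expect_gte(countParticles(mask, particleFilter(0, Inf), 0.5)$count,
             fly$count)

  # density: 25 droplets on a 0.01 mm^2 field -> 2500 per mm^2
  sim <- simulateDropletImage(width = 200L, height = 200L, pixelSizeUm = 0.5,
                              nDroplets = 25L, seed = 14L)
  d <- countParticles(binaryMask(sim$truth), particleFilter(0, Inf), 0.5)
  expect_equal(d$count, 25L)
  expect_equal(d$density_per_mm2, 2500)
})

test_that("diagonally touching pixels form one 8-connected particle", {
  mask <- matrix(FALSE, 5, 5)
  mask[2, 2] <- TRUE
  mask[3, 3] <- TRUE
  expect_equal(countParticles(mask, particleFilter(0, Inf), 1)$count, 1L)
})

test_that("TCCF subtracts background and ignores offsets", {
  img <- matrix(10, 40, 40)
  img[1:10, 1:10] <- 50
  cell <- rectRoi(0, 0, 10, 10)
  bg <- rectRoi(25, 25, 10, 10)
  r <- tccf(img, cell, list(bg))
  expect_equal(r$integrated_density, 5000)
  expect_equal(r$roi_area_px, 100)
  expect_equal(r$background_mean, 10)
  expect_equal(r$tccf, 4000)

  expect_equal(tccf(img + 123, cell, list(bg))$tccf, r$tccf)
  expect_equal(tccf(matrix(9, 20, 20), rectRoi(0, 0, 5, 5),
                    list(rectRoi(10, 10, 5, 5)))$tccf, 0)
  expect_warning(tccf(img, cell, list(rectRoi(5, 5, 10, 10))), "overlap")
})

test_that("nuclear ratios are per-ROI means of channel ratios", {
  den <- matrix(60, 30, 30)
  num <- den / 2
  rois <- list(rectRoi(0, 0, 5, 5, "n1"), rectRoi(10, 10, 5, 5, "n2"))
  expect_equal(unname(nuclearRatio(num, den, rois)), c(0.5, 0.5))
  expect_equal(unname(nuclearRatio(den, den, rois)), c(1, 1))
  expect_equal(unname(nuclearRatio(2 * den, den, rois)), c(2, 2))

  den0 <- den
  den0[1:5, 1:5] <- 0
  expect_warning(r <- nuclearRatio(num, den0, rois), "zero denominator")
  expect_true(is.na(r[["n1"]]))
  expect_equal(r[["n2"]], 0.5)
})

test_that("muscle integrity recovers the attached fraction", {
  bright <- matrix(200, 50, 50)
  r <- muscleIntegrity(bright, rectRoi(0, 0, 50, 50))
  expect_equal(r$raw_fraction, 1.0)

  sim <- simulateFilletImage(attachedFraction = 0.5, seed = 33L)
  r5 <- muscleIntegrity(maxProject(sim$stack), rectRoi(0, 0, 256, 256))
  expect_gte(r5$raw_fraction, 0.45)
  expect_lte(r5$raw_fraction, 0.55)

  norm <- muscleIntegrity(maxProject(sim$stack), rectRoi(0, 0, 256, 256),
                          controlMean = r5$raw_fraction)
  expect_equal(norm$normalized_fraction, 1.0)
})

test_that("polygon ROIs rasterise by pixel-centre containment", {
  tri <- polygonRoi(rbind(c(0, 0), c(20, 0), c(0, 20)), "tri")
  m <- roiMask(tri, c(30, 30))
  expect_true(m[1, 1])
  expect_false(m[25, 25])
  # half of the 20 x 20 bounding square, up to the diagonal pixel row
  expect_gt(sum(m), 150)
  expect_lt(sum(m), 250)

  rect <- roiMask(rectRoi(2, 3, 4, 5), c(20, 20))
  expect_equal(sum(rect), 20)
  expect_true(rect[4, 3])   # (x=2, y=3) is row 4, col 3 in 1-based R
})
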