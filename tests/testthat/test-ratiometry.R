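sg1 <- imagingCalibrations()$SG1
acq <- smallAcq()

test_that("ratio map matches hand computation and the identity case", {
  ch1 <- matrix(c(100, 400, 200, 500), 2)  # column-major: [[100,200],[400,500]]
  ch2 <- matrix(c(50, 200, 300, 1000), 2)
  st <- stackFromChannels(ch1, ch2)
  mask <- array(TRUE, c(2, 2, 1))
  rv <- ratioMap(st, mask)
  expect_equal(ratios(rv)[, , 1], matrix(c(0.5, 0.5, 1.5, 2.0), 2))

  stEq <- stackFromChannels(matrix(7, 3, 3), matrix(7, 3, 3))
  rvEq <- ratioMap(stEq, array(TRUE, c(3, 3, 1)))
  expect_true(all(ratios(rvEq) == 1))
})

test_that("ratio map is scale-invariant", {
  sim <- simulateSample("cancer", sg1, acq, seed = 31)
  mask <- foregroundMask(sim$stack)
  rv <- ratioMap(sim$stack, mask)
  for (c in c(0.5, 3)) {
    scaled <- stackFromChannels(channel1(sim$stack) * c,
                                channel2(sim$stack) * c,
                                z = zPositions(sim$stack))
    expect_equal(ratios(ratioMap(scaled, mask)), ratios(rv),
                 tolerance = 1e-12)
  }
})

test_that("noise-free rendered phantom recovers the true ratio field", {
  ph <- buildPhantom("cancer", sg1, acquisition = acq, seed = 12)
  st <- renderStack(ph, acq, noise = FALSE)
  mask <- glandMask(ph)
  rv <- ratioMap(st, mask)
  relErr <- abs(ratios(rv)[mask] - trueRatio(ph)[mask]) /
    trueRatio(ph)[mask]
  expect_lt(max(relErr), 1e-9)
})

test_that("Otsu mask recovers a two-population gland image", {
  # background counts ~5, gland counts ~500
  set.seed(99)
  ph <- buildPhantom("normal", sg1, acquisition = acq, seed = 44)
  st <- renderStack(ph, acq, seed = 45)
  mask <- foregroundMask(st, method = "otsu")
  truth <- glandMask(ph)
  recovery <- sum(mask & truth) / sum(truth)
  expect_gte(recovery, 0.99)
  # and little background leaks in
  expect_lt(sum(mask & !truth) / sum(!truth), 0.05)
})

test_that("mask boundary behavior and forced failures", {
  # all-zero Ch1 is an analysis error
  stZero <- stackFromChannels(array(0, c(4, 4, 2)),
                              array(10, c(4, 4, 2)), z = c(100, 150))
  expect_error(foregroundMask(stZero), "empty foreground")

  # percentile p = 0 keeps every voxel with ch1 > 0
  ch1 <- array(c(0, 1, 2, 3), c(2, 2, 1))
  st <- stackFromChannels(ch1, ch1 + 1)
  m <- foregroundMask(st, method = "percentile", p = 0)
  expect_identical(m, ch1 > 0)

  # saturated voxels are excluded from the mask
  chS <- array(c(65535, 100, 100, 100), c(2, 2, 1))
  stS <- stackFromChannels(chS, array(100, c(2, 2, 1)))
  mS <- foregroundMask(stS, method = "percentile", p = 0)
  expect_false(mS[1, 1, 1])
  expect_true(all(mS[-1]))
})

test_that("sample mean ratio: uniform case, hand case, depth window", {
  rvU <- ratioMap(uniformStack(1.7), array(TRUE, c(4, 4, 3)))
  expect_equal(sampleMeanRatio(rvU)$mean_ratio, 1.7, tolerance = 1e-12)

  # two sections with masked ratios {1, 2} and {3} -> mean 2
  ch1 <- array(1, c(2, 1, 2))
  ch2 <- array(c(1, 2, 3, 99), c(2, 1, 2))
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), c(2, 1, 2))
  st <- stackFromChannels(ch1, ch2, z = c(100, 150))
  sm <- sampleMeanRatio(ratioMap(st, mask))
  expect_equal(sm$mean_ratio, 2)
  expect_equal(sm$n_foreground_voxels, 3L)
  expect_equal(sm$n_sections, 2L)

  # depth window with no sections inside is an analysis error
  expect_error(sampleMeanRatio(ratioMap(st, mask),
                               depthWindow = c(300, 400)),
               "no sections")
})

test_that("sample mean increases when every true ratio increases", {
  ph <- buildPhantom("normal", sg1, acquisition = acq, seed = 7)
  st1 <- renderStack(ph, acq, noise = FALSE)
  ph2 <- ph
  ph2@trueRatio <- trueRatio(ph) + 0.2
  st2 <- renderStack(ph2, acq, noise = FALSE)
  mask <- glandMask(ph)
  m1 <- sampleMeanRatio(ratioMap(st1, mask))$mean_ratio
  m2 <- sampleMeanRatio(ratioMap(st2, mask))$mean_ratio
  expect_gt(m2, m1)
})

test_that("ratio map and sample mean match the brute-force oracle", {
  set.seed(5)
  for (rep in 1:3) {
    ch1 <- array(sample(50:500, 48, TRUE), c(4, 4, 3))
    ch2 <- array(sample(50:500, 48, TRUE), c(4, 4, 3))
    mask <- array(sample(c(TRUE, FALSE), 48, TRUE, c(0.7, 0.3)),
                  c(4, 4, 3))
    if (!any(mask)) next
    st <- stackFromChannels(ch1, ch2)
    rv <- ratioMap(st, mask)
    oracle <- bruteForceRatio(ch1, ch2, mask)
    expect_identical(ratios(rv), oracle$map)
    expect_equal(sampleMeanRatio(rv)$mean_ratio, oracle$mean,
                 tolerance = 1e-15)
  }
})

test_that("pseudocolor: midpoint color, scale invariance, hue ordering", {
  cmap <- ratioColormap()
  # ratio at the display-range midpoint renders the midpoint colormap color
  st <- uniformStack(1.0, dims = c(2, 2, 1))
  rv <- ratioMap(st, array(TRUE, c(2, 2, 1)), displayRange = c(0.5, 1.5))
  secs <- pseudocolor(rv, st)
  expect_equal(as.numeric(secs[[1]][1, 1, ]), as.numeric(cmap(0.5)),
               tolerance = 1e-9)

  # global x10 intensity leaves hue untouched (brightness normalized)
  sim <- simulateSample("cancer", sg1, acq, seed = 61)
  mask <- foregroundMask(sim$stack)
  rv1 <- ratioMap(sim$stack, mask)
  st10 <- stackFromChannels(channel1(sim$stack) * 10,
                            channel2(sim$stack) * 10,
                            z = zPositions(sim$stack))
  p1 <- pseudocolor(rv1, sim$stack)
  p10 <- pseudocolor(ratioMap(st10, mask, displayRange = displayRange(rv1)),
                     st10)
  expect_equal(p1, p10, tolerance = 1e-9)

  # normal vs cancer SG1 renders shift toward the high-ratio (red) end
  hueOf <- function(cls, seed) {
    s <- simulateSample(cls, sg1, acq, seed = seed)
    m <- foregroundMask(s$stack)
    r <- ratioMap(s$stack, m)
    secs <- pseudocolor(r, s$stack)
    rgb <- sapply(secs, function(x) {
      mz <- apply(x, c(1, 2), max) > 0
      c(sum(x[, , 1][mz]), sum(x[, , 2][mz]), sum(x[, , 3][mz]))
    })
    tot <- rowSums(rgb)
    tot[1] / (tot[3] + 1e-9)  # red-to-blue balance
  }
  expect_gt(hueOf("cancer", 71), hueOf("normal", 72))

  expect_error(pseudocolor(rv1, sim$stack, displayRange = c(2, 1)),
               "increasing")
})
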