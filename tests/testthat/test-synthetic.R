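acq <- smallAcq()
sg1 <- imagingCalibrations()$SG1

test_that("phantom sample means follow the calibration distribution", {
  # degenerate draw: zero SD fixes the sample mean at the class mean
  degen <- ProbeCalibration("SG1",
    classMeans = c(cancer = 1.127), classSds = c(cancer = 1e-12))
  ph <- buildPhantom("cancer", degen, acquisition = acq, seed = 3)
  expect_equal(sampleRatioMean(ph), 1.127, tolerance = 1e-6)

  # Monte-Carlo against the sampling distribution (summary-level draws use
  # the same truncated-normal sampler as buildPhantom)
  draws <- simulateCohortSummaries("SG1", counts = c(normal = 10000L),
                                   seed = 42)$mean_ratio
  se <- 0.142 / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.656), 3 * se)

  # phantom-level draws agree with the calibration at modest n
  ms <- vapply(1:200, function(i)
    sampleRatioMean(buildPhantom("normal", sg1, acquisition = acq,
                                 seed = i)), numeric(1))
  expect_lt(abs(mean(ms) - 0.656), 4 * 0.142 / sqrt(200))
  expect_true(all(ms > 0))
})

test_that("phantom structure: positivity, disorder and periodicity", {
  ph <- buildPhantom("cancer", sg1, acquisition = acq, seed = 1)
  expect_true(all(trueRatio(ph) > 0))
  expect_gte(ph@geometry@disorder, 0.5)  # cancer is disordered
  expect_equal(dim(trueRatio(ph)), dim(brightnessField(ph)))

  # disorder 0 with no jitter reproduces a periodic lattice: every section
  # identical, and the pattern is invariant under a one-spacing shift
  geomP <- GlandGeometry(disorder = 0, jitterSd = 0, spacing = 16,
                         tubuleRadius = 6, wallThickness = 3)
  acq32 <- AcquisitionParams(imageSize = 32L, pixelSize = 1,
                             zPositions = seq(80, 200, length.out = 3))
  php <- buildPhantom("normal", sg1, geometry = geomP,
                      acquisition = acq32, seed = 5)
  m <- glandMask(php)
  expect_identical(m[, , 1], m[, , 2])
  expect_identical(m[, , 1], m[, , 3])
  sec <- m[, , 1]
  expect_identical(sec[1:16, ], sec[17:32, ])  # shift by one spacing
  # background voxels are near-zero brightness
  expect_lt(max(brightnessField(php)[!m]), 0.05)
})

test_that("rendering follows the closed-form channel split", {
  # single voxel, B = 1000, r = 2, noise disabled
  cal <- ProbeCalibration("SG1", classMeans = c(cancer = 2),
                          classSds = c(cancer = 1e-12))
  acq1 <- AcquisitionParams(imageSize = 1L, zPositions = 0.0001,
                            photonBudget = 1000, readNoiseSd = 0)
  geom1 <- GlandGeometry(tubuleRadius = 5, spacing = 4, wallThickness = 5,
                         disorder = 0, jitterSd = 0)
  ph <- buildPhantom("cancer", cal, geometry = geom1, acquisition = acq1,
                     seed = 1, textureSd = 0)
  st <- renderStack(ph, acq1, noise = FALSE)
  b <- brightnessField(ph)[1, 1, 1] * 1000 * exp(-0.0001 / 150)
  expect_equal(channel2(st)[1, 1, 1], b * 2 / 3, tolerance = 1e-3)
  expect_equal(channel1(st)[1, 1, 1], b * 1 / 3, tolerance = 1e-3)
})

test_that("noise-free channels conserve brightness and split symmetrically", {
  ph <- buildPhantom("normal", sg1, acquisition = acq, seed = 2)
  st <- renderStack(ph, acq, noise = FALSE)
  att <- exp(-zPositions(st) / 150)
  B <- brightnessField(ph) * 500 * rep(att, each = 16 * 16)
  expect_equal(channel1(st) + channel2(st), B, tolerance = 1e-9)

  # r = 1 everywhere, noise disabled: channels identical
  cal1 <- ProbeCalibration("SG1", classMeans = c(normal = 1),
                           classSds = c(normal = 1e-12))
  ph1 <- buildPhantom("normal", cal1, acquisition = acq, seed = 2,
                      textureSd = 0)
  st1 <- renderStack(ph1, acq, noise = FALSE)
  expect_equal(channel1(st1), channel2(st1), tolerance = 1e-9)
})

test_that("depth attenuation is exponential in z", {
  acqA <- AcquisitionParams(imageSize = 8L, zPositions = c(100, 200),
                            attenuationLength = 100, readNoiseSd = 0)
  cal <- ProbeCalibration("SG1", classMeans = c(normal = 1),
                          classSds = c(normal = 1e-12))
  geom <- GlandGeometry(disorder = 0, jitterSd = 0)
  ph <- buildPhantom("normal", cal, geometry = geom, acquisition = acqA,
                     seed = 1, textureSd = 0)
  st <- renderStack(ph, acqA, noise = FALSE)
  tot <- channel1(st) + channel2(st)
  expect_equal(sum(tot[, , 2]) / sum(tot[, , 1]), exp(-1),
               tolerance = 1e-9)
})

test_that("seed determinism and cohort bookkeeping", {
  st1 <- renderStack(buildPhantom("cancer", sg1, acquisition = acq,
                                  seed = 9), acq, seed = 4)
  st2 <- renderStack(buildPhantom("cancer", sg1, acquisition = acq,
                                  seed = 9), acq, seed = 4)
  expect_identical(channel1(st1), channel1(st2))
  expect_identical(channel2(st1), channel2(st2))

  tiny <- CohortDesign(counts = c(normal = 1L, ulcer = 1L, adenoma = 1L,
                                  cancer = 1L),
                       probes = "SG1",
                       acquisition = smallAcq(nSections = 3L,
                                              imageSize = 8L),
                       masterSeed = 7L)
  c1 <- simulateCohort(tiny)
  c2 <- simulateCohort(tiny)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$stacks, c2$stacks)
  # manifest class labels match the phantom classes
  expect_identical(c1$manifest$tissue_class,
                   vapply(c1$stacks, tissueClass, character(1),
                          USE.NAMES = FALSE))

  # Table-1 counts give 76 samples per probe
  full <- CohortDesign(probes = "SE1",
                       acquisition = AcquisitionParams(imageSize = 4L,
                         zPositions = c(100, 150)),
                       masterSeed = 11L)
  man <- simulateCohort(full)$manifest
  expect_equal(nrow(man), 76L)
  expect_equal(unname(table(man$tissue_class)[c("normal", "ulcer",
                                                "adenoma", "cancer")]),
               c(21L, 18L, 17L, 20L), ignore_attr = TRUE)
})

test_that("lysate trajectory follows the first-order closed form", {
  # k = 0: flat at R0
  p0 <- LysateAssayParams(k = 0, R0 = 0.9, Rinf = 1.5, noiseSd = 0)
  s0 <- simulateLysateSeries(p0)
  expect_equal(ratios(s0), rep(0.9, 13))
  expect_equal(timePoints(s0), seq(0, 120, 10))

  # closed-form endpoint: R0 = 0.5, Rinf = 1.8, k = 0.05 at t = 120
  p1 <- LysateAssayParams(k = 0.05, R0 = 0.5, Rinf = 1.8, noiseSd = 0)
  s1 <- simulateLysateSeries(p1)
  expect_equal(ratios(s1)[13], 1.8 - 1.3 * exp(-6), tolerance = 1e-9)
  expect_equal(round(ratios(s1)[13], 4), 1.7968)

  expect_error(LysateAssayParams(k = -1, R0 = 0.5, Rinf = 1.8),
               "non-negative")
})

test_that("configuration errors are raised for unknown class or probe", {
  expect_error(buildPhantom("polyp", sg1, acquisition = acq, seed = 1),
               "not present")
  expect_error(simulateLysateCohort("XYZ", "cancer", 3), "no lysate")
  expect_error(simulateCohortSummaries("XYZ"), "no calibration")
})
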