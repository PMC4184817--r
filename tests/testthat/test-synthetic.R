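# Synthetic-data generators: kernel, movies, cohorts

test_that("the biphasic kernel has the documented shape", {
  expect_equal(biphasicKernel(0), 0)
  expect_equal(biphasicKernel(-3), 0)
  tt <- seq(0, 60, 0.01)
  k <- biphasicKernel(tt, a = 1)
  expect_gt(max(k), 0)
  expect_lt(min(k), 0)          # undershoot exists for u = 0.6
  expect_lt(tt[which.max(k)], tt[which.min(k)])  # peak precedes trough
  # u = 0: non-negative everywhere
  expect_true(all(biphasicKernel(tt, a = 1, u = 0) >= 0))
  # single sign change after the peak
  signChanges <- sum(diff(sign(k[k != 0])) != 0)
  expect_equal(signChanges, 1)
})

test_that("the kernel argmax matches the peak frame found on a rendered movie", {
  sc <- sceneParams(noiseScale = 0)
  mv <- renderMovie(sc, seed = 1)
  d <- computeDff(mv$stack)
  ai <- afiIntensity(d, RoiSpec(mv$truth$blobCenters$ipsi, size = 10))
  seg <- attr(ai, "segmentation")
  ft <- frameTimes(d)
  kGrid <- biphasicKernel(ft - sc$stimOnset, a = 1, tau1 = sc$tau1,
                          tau2 = sc$tau2, tau3 = sc$tau3, u = sc$u)
  expect_equal(peakFrame(seg), which.max(kGrid))
})

test_that("a zero-amplitude movie is pure noise around baseline", {
  sc <- sceneParams(ipsiAmp = 0, contraAmp = 0)
  mv <- renderMovie(sc, seed = 5)
  d <- computeDff(mv$stack)
  post <- which(frameTimes(d) >= stimOnset(d))
  pixMean <- colMeans(dff(d)[post, , , drop = FALSE], dims = 1)
  nBase <- length(baselineWindow(d))
  sdMean <- sc$noiseScale / sqrt(sc$baselineLevel) *
    sqrt(1 / length(post) + 1 / nBase)
  frac <- mean(abs(pixMean[validMask(d)]) > 3 * sdMean)
  expect_lt(frac, 0.01)  # Gaussian tail: ~0.27% expected beyond 3 SD
})

test_that("rendering is a pure function of parameters and seed", {
  sc <- sceneParams()
  a <- renderMovie(sc, seed = 42)
  b <- renderMovie(sc, seed = 42)
  expect_identical(frames(a$stack), frames(b$stack))
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  writeFluorescenceStack(a$stack, f1)
  writeFluorescenceStack(b$stack, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c_ <- renderMovie(sc, seed = 43)
  expect_false(identical(frames(a$stack), frames(c_$stack)))
})

test_that("a scene exceeding 16-bit headroom is rejected before rendering", {
  sc <- sceneParams(baselineLevel = 65500)
  expect_error(renderMovie(sc, seed = 1), "16-bit headroom")
})

test_that("vein rows are constant and masked at the default level", {
  sc <- sceneParams()
  mv <- renderMovie(sc, seed = 8)
  expect_true(all(frames(mv$stack)[, sc$veinRows, ] == sc$veinLevel))
  d <- computeDff(mv$stack)
  expect_true(all(!validMask(d)[sc$veinRows, ]))
})

test_that("noiseless identifiability: pipeline metrics equal sidecar truth", {
  mv <- renderMovie(sceneParams(noiseScale = 0), seed = 2)
  d <- computeDff(mv$stack)
  aiI <- afiIntensity(d, RoiSpec(mv$truth$blobCenters$ipsi, size = 10))
  expect_equal(as.numeric(aiI), 100 * mv$truth$ipsiAmp, tolerance = 1e-9)
  aiC <- afiIntensity(d, RoiSpec(mv$truth$blobCenters$contra, size = 10,
                                 side = "contralateral"))
  expect_equal(as.numeric(aiC), 100 * mv$truth$contraAmp, tolerance = 1e-9)
})

test_that("mean AFI intensity bias is below 10% of the amplitude", {
  sc <- sceneParams()
  vals <- vapply(1:100, function(s) {
    mv <- renderMovie(sc, seed = 500 + s)
    d <- computeDff(mv$stack)
    as.numeric(afiIntensity(d, RoiSpec(mv$truth$blobCenters$ipsi, size = 10)))
  }, numeric(1))
  bias <- mean(vals) - 100 * sc$ipsiAmp
  expect_lt(abs(bias), 0.1 * 100 * sc$ipsiAmp)
})

test_that("treatment cohorts recover preset parameters exactly without noise", {
  tc <- generateScsCohort(seed = 1, scs = noiselessPreset("scs"),
                          sham = noiselessPreset("sham"))
  scsArm <- tc[tc$group == "SCS", ]
  r <- timecourseRegression(scsArm)
  expect_equal(r$slope, 0.92, tolerance = 1e-9)
  expect_equal(r$intercept, 45, tolerance = 1e-9)
  expect_equal(r$r, 1, tolerance = 1e-9)
  shamArm <- tc[tc$group == "sham", ]
  expect_equal(timecourseRegression(shamArm)$slope, 0.19, tolerance = 1e-9)
  # before-treatment rows are exactly 100 by construction
  expect_true(all(tc$relative_intensity[tc$timepoint_min == -30] == 100))
})

test_that("cohort generators are deterministic given the seed", {
  expect_identical(generateScsCohort(seed = 9), generateScsCohort(seed = 9))
  expect_identical(generateBehaviorCohort(5, seed = 9),
                   generateBehaviorCohort(5, seed = 9))
  expect_identical(generateAfiCohort(5, effectPreset("null"), seed = 9),
                   generateAfiCohort(5, effectPreset("null"), seed = 9))
  expect_error(generateScsCohort(nScs = 1, seed = 1), "at least 2")
})

test_that("behavioral cohorts without noise land exactly on the preset drop", {
  p <- behaviorParams(vfBetweenSd = 0, vfWithinSd = 0,
                      hpBetweenSd = 0, hpWithinSd = 0)
  d <- generateBehaviorCohort(3, neuropathy = TRUE, seed = 1, params = p)
  expect_true(all(d$vf_threshold[d$day == 0] == p$vfBaseline))
  expect_true(all(d$vf_threshold[d$day > 0] == p$vfBaseline - p$vfDrop))
  expect_true(all(d$hp_latency[d$day == 0] == p$hpBaseline))
  expect_true(all(d$hp_latency[d$day > 0] == p$hpBaseline - p$hpDrop))
  expect_true(all(d$vf_threshold %in% p$filaments))
  # control cohorts stay at baseline
  d0 <- generateBehaviorCohort(2, neuropathy = FALSE, seed = 1, params = p)
  expect_true(all(d0$vf_threshold == p$vfBaseline))
})

test_that("palpation-naive preset has a zero ipsilateral amplitude", {
  p <- effectPreset("palpation-naive")
  expect_equal(p$movie$ipsiAmp, 0)
  expect_equal(unname(p$cohort$intensityMean["ipsi"]), 0)
})
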