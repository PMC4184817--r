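# ROI traces, AFI intensity and area of excitation

test_that("ROI mean trace matches trivial arithmetic and the loop oracle", {
  # 2x2 ROI with per-frame values 0.01..0.04 -> mean 0.025
  arr <- array(0, c(2, 4, 4))
  arr[2, 1:2, 1:2] <- c(0.01, 0.02, 0.03, 0.04)
  x <- dffFieldStack(arr)
  tr <- roiTrace(x, RoiSpec(c(1, 1), size = 2, side = "ipsilateral"),
                 checkSide = FALSE)
  expect_equal(tr[2], 0.025)
  expect_equal(tr[1], 0)
  expect_equal(attr(tr, "nValid"), 4L)

  # random field + random ROI vs brute-force double loop
  for (s in 1:5) {
    set.seed(s)
    arr <- array(rnorm(6 * 10 * 10, 0, 0.01), c(6, 10, 10))
    valid <- matrix(runif(100) > 0.1, 10, 10)
    arr2 <- arr
    for (t in 1:6) { m <- arr2[t, , ]; m[!valid] <- NA; arr2[t, , ] <- m }
    x <- dffFieldStack(arr2, valid = valid)
    ctr <- c(sample(3:8, 1), sample(3:8, 1))
    roi <- RoiSpec(ctr, size = 4)
    rows <- (ctr[1] - 1):(ctr[1] + 2); cols <- (ctr[2] - 1):(ctr[2] + 2)
    if (!any(valid[rows, cols])) next
    tr <- roiTrace(x, roi, checkSide = FALSE)
    expect_equal(as.numeric(tr), roiTraceOracle(arr, valid, rows, cols),
                 tolerance = 1e-12)
  }
})

test_that("a fully masked ROI is an error and bounds are enforced", {
  arr <- array(0.01, c(3, 6, 6))
  valid <- matrix(TRUE, 6, 6); valid[1:2, 1:2] <- FALSE
  for (t in 1:3) { m <- arr[t, , ]; m[!valid] <- NA; arr[t, , ] <- m }
  x <- dffFieldStack(arr, valid = valid)
  expect_error(roiTrace(x, RoiSpec(c(1, 1), size = 2), checkSide = FALSE),
               "no valid pixels")
  expect_error(roiTrace(x, RoiSpec(c(6, 6), size = 4), checkSide = FALSE),
               "bounds")
})

test_that("AFI intensity is zero with a no-response flag on a null stack", {
  arr <- array(0, c(6, 8, 8))
  x <- dffFieldStack(arr)
  ai <- afiIntensity(x, RoiSpec(c(2, 4), size = 2), checkSide = FALSE)
  expect_equal(as.numeric(ai), 0)
  expect_true(attr(ai, "noResponse"))
})

test_that("noiseless rendering recovers the injected peak amplitude", {
  mv <- renderMovie(sceneParams(noiseScale = 0), seed = 7)
  d <- computeDff(mv$stack)
  onBlob <- RoiSpec(mv$truth$blobCenters$ipsi, size = 10)
  ai <- afiIntensity(d, onBlob)
  expect_equal(as.numeric(ai), 100 * mv$truth$ipsiAmp, tolerance = 1e-9)
  expect_false(attr(ai, "noResponse"))
  # an off-blob ROI in the same half responds strictly less
  offBlob <- RoiSpec(c(8, 8), size = 6)
  aiOff <- afiIntensity(d, offBlob)
  expect_lt(as.numeric(aiOff), as.numeric(ai))
})

test_that("with shot noise the ROI intensity stays within 3 noise SDs", {
  sc <- sceneParams()
  roiSd <- 100 * sc$noiseScale / sqrt(sc$baselineLevel) / sqrt(100)  # pct units
  for (s in 1:10) {
    mv <- renderMovie(sc, seed = 100 + s)
    d <- computeDff(mv$stack)
    ai <- afiIntensity(d, RoiSpec(mv$truth$blobCenters$ipsi, size = 10))
    expect_lt(abs(as.numeric(ai) - 100 * mv$truth$ipsiAmp), 3 * roiSd)
  }
})

test_that("area of excitation handles the all-below and all-above extremes", {
  arrLow <- array(0.001, c(3, 6, 6))
  xLow <- dffFieldStack(arrLow)
  expect_equal(areaOfExcitation(xLow, threshold = 0.5, window = 2:3)$areaPixels, 0L)
  arrHigh <- array(0.01, c(3, 6, 6))
  xHigh <- dffFieldStack(arrHigh)
  ar <- areaOfExcitation(xHigh, threshold = 0.5, window = 2:3)
  expect_equal(ar$areaPixels, 36L)
  expect_equal(ar$areaMm2, 36 * (10 / 1000)^2)
  expect_equal(ar$ipsiPixels + ar$contraPixels, ar$areaPixels)
})

test_that("area equals the exhaustive count oracle and is monotone in threshold", {
  for (s in 1:6) {
    set.seed(s)
    arr <- array(rnorm(5 * 16 * 16, 0, 0.003), c(5, 16, 16))
    valid <- matrix(runif(256) > 0.05, 16, 16)
    for (t in 1:5) { m <- arr[t, , ]; m[!valid] <- NA; arr[t, , ] <- m }
    x <- dffFieldStack(arr, valid = valid)
    prev <- Inf
    for (thr in c(0.05, 0.15, 0.3, 0.6)) {
      ar <- areaOfExcitation(x, threshold = thr, window = 2:5)
      expect_equal(ar$areaPixels,
                   areaOracle(arr, valid, 2:5, thr / 100))
      expect_lte(ar$areaPixels, prev)
      expect_equal(ar$ipsiPixels + ar$contraPixels, ar$areaPixels)
      prev <- ar$areaPixels
    }
  }
})

test_that("a pixel exactly at the threshold does not count (strictly above)", {
  arr <- array(0, c(2, 4, 4))
  arr[2, 1, 1] <- 0.0025   # exactly 0.25 %
  arr[2, 1, 2] <- 0.0025 + 1e-9
  x <- dffFieldStack(arr)
  ar <- areaOfExcitation(x, threshold = 0.25, window = 1:2)
  expect_equal(ar$areaPixels, 1L)
})

test_that("translating the blob translates the supra-threshold region", {
  sc1 <- sceneParams(noiseScale = 0)
  shift <- c(2, 3)
  sc2 <- sceneParams(noiseScale = 0,
                     blobCenters = list(ipsi = sc1$blobCenters$ipsi + shift,
                                        contra = sc1$blobCenters$contra))
  hitCentroid <- function(sc) {
    d <- computeDff(renderMovie(sc, seed = 1)$stack)
    win <- which(frameTimes(d) >= stimOnset(d))
    px <- apply(dff(d)[win, , , drop = FALSE], c(2, 3), max)
    hit <- validMask(d) & !is.na(px) & px > 0.0025
    idx <- which(hit, arr.ind = TRUE)
    colMeans(idx)
  }
  expect_equal(unname(hitCentroid(sc2) - hitCentroid(sc1)), shift,
               tolerance = 1e-6)
})

test_that("measureAfiResponse assembles a coherent AfiResponse", {
  mv <- renderMovie(sceneParams(noiseScale = 0), seed = 3)
  d <- computeDff(mv$stack)
  resp <- measureAfiResponse(d, RoiSpec(mv$truth$blobCenters$ipsi, size = 10),
                             threshold = 0.25)
  expect_s4_class(resp, "AfiResponse")
  expect_equal(intensity(resp), 0.5, tolerance = 1e-9)
  expect_gt(areaPixels(resp), 0)
  expect_equal(areaMm2(resp), areaPixels(resp) * (10 / 1000)^2)
  expect_false(resp@noResponse)
  expect_equal(resp@ipsiPixels, areaPixels(resp))  # contra amp 0.2% < 0.25%
})

test_that("an ROI side label inconsistent with orientation warns", {
  arr <- array(0, c(3, 8, 8))
  x <- dffFieldStack(arr)
  expect_warning(roiTrace(x, RoiSpec(c(6, 4), size = 2, side = "ipsilateral")),
                 "inconsistent")
  expect_silent(roiTrace(x, RoiSpec(c(2, 4), size = 2, side = "ipsilateral")))
})
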