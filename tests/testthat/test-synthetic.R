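test_that("static slit has constant analytic area restGap * foldLength", {
  sim <- shortSim(ampLeft = 0, ampRight = 0, restGap = 0.3, duration = 0.002)
  expect_equal(trueArea(sim$truth), rep(0.3 * 1.2, nFrames(sim$stack)),
               tolerance = 1e-12)
})

test_that("frame count is round(fps * duration)", {
  expect_equal(nFrames(shortSim(duration = 0.008)$stack), 160L)
  sim <- generateGlottalVideo(GlottalKinematics(duration = 0.0035),
                              Calibration(fps = 10000))
  expect_equal(nFrames(sim$stack), 35L)
})

test_that("true area oscillates at f0: autocorrelation peaks at fps/f0 lags", {
  sim <- generateGlottalVideo(GlottalKinematics(f0 = 250, duration = 0.02),
                              Calibration())
  a <- trueArea(sim$truth)
  expect_length(a, 400L)
  ac <- stats::acf(a, lag.max = 120, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[60:120]) + 59L, 80L)  # period 1/250 s = 80 frames
})

test_that("analytic area matches the rendered dark-region mass", {
  sim <- shortSim(duration = 0.004)   # 120 glottal rows >= 64
  fr <- frames(sim$stack)
  gRows <- sim$truth@glottalRows
  s <- mmPerPixel(sim$stack)
  rendered <- vapply(seq_len(nFrames(sim$stack)), function(t)
    sum((0.8 - fr[gRows, , t]) / 0.7) * s^2, numeric(1))
  expect_lt(max(abs(rendered - trueArea(sim$truth)) / trueArea(sim$truth)), 0.02)
})

test_that("gap is never negative under any amplitudes (rectification)", {
  set.seed(42)
  for (i in 1:8) {
    kin <- GlottalKinematics(f0 = runif(1, 100, 1000),
                             restGap = runif(1, 0, 0.3),
                             ampLeft = runif(1, 0, 0.15),
                             ampRight = runif(1, 0, 0.15),
                             apPhaseLag = runif(1, -pi, pi),
                             duration = 0.002)
    sim <- generateGlottalVideo(kin, Calibration())
    expect_gte(min(trueRightEdge(sim$truth) - trueLeftEdge(sim$truth)), 0)
  }
})

test_that("fixed seed reproduces the noise field bit-identically", {
  a <- shortSim(noiseSigma = 0.03, seed = 7, duration = 0.001)
  b <- shortSim(noiseSigma = 0.03, seed = 7, duration = 0.001)
  c <- shortSim(noiseSigma = 0.03, seed = 8, duration = 0.001)
  expect_identical(frames(a$stack), frames(b$stack))
  expect_false(identical(frames(a$stack), frames(c$stack)))
})

test_that("zero AP phase lag gives a rank-1 space-time displacement matrix", {
  sim <- shortSim(apPhaseLag = 0, duration = 0.004)
  D <- trueRightEdge(sim$truth) - 0.3 / 2     # oscillatory displacement part
  sv <- svd(D)$d
  expect_lt(sv[2] / sv[1], 1e-8)
})

test_that("a glottis too wide for the image is refused, naming the width", {
  expect_error(shortSim(ampLeft = 0.5, ampRight = 0.5),
               "width")
})

test_that("pressure sweep: onset time, amplitude and absence semantics", {
  ## fs a multiple of 4*f0 so the sine peaks fall exactly on samples
  tr <- generatePressureSweep(onsetPressure = 3, rampRate = 1, oscAmp = 0.5,
                              f0 = 200, fs = 4000, duration = 5,
                              noiseSigma = 0)
  md <- traceMetadata(tr)
  expect_true(md$onsetPresent)
  expect_equal(md$onsetTime, 3.0)
  t <- (seq_along(samples(tr)) - 1) / fps(tr)
  dev <- abs(samples(tr) - 1 * t)
  firstDev <- t[which(dev > 1e-9)[1]]
  expect_lt(abs(firstDev - 3.0), 1 / 4000 + 1e-9)   # within one sample
  expect_equal(max(dev), 0.5, tolerance = 1e-9)     # full-grown amplitude

  ramp <- generatePressureSweep(oscAmp = 0, noiseSigma = 0.01, seed = 1)
  expect_false(traceMetadata(ramp)$onsetPresent)

  short <- generatePressureSweep(onsetPressure = 10, rampRate = 1,
                                 duration = 2, noiseSigma = 0)
  expect_false(traceMetadata(short)$onsetPresent)

  expect_error(generatePressureSweep(f0 = 3000, fs = 5000), "fs")
  expect_error(generatePressureSweep(oscAmp = -1), ">= 0")
})

test_that("diffusion series hits coverage targets to one pixel quantum", {
  ser <- generateDiffusionSeries(c(0, 0.32, 0.41, 1.0))
  nROI <- sum(ser$roiMask)
  stained <- vapply(ser$images, function(im) sum(im[ser$roiMask] >= 0.5),
                    numeric(1))
  expect_equal(stained[1], 0)
  expect_equal(stained[4], nROI)
  expect_lte(max(abs(stained - c(0, 0.32, 0.41, 1) * nROI)), 1)
  # half coverage of a 100 x 100 ROI is 5000 pixels within one quantum
  half <- generateDiffusionSeries(0.5, imageSize = c(120, 120),
                                  roiSize = c(100, 100))
  expect_lte(abs(sum(half$images[[1]][half$roiMask] >= 0.5) - 5000), 1)
  expect_error(generateDiffusionSeries(c(0.4, 0.3)), "monotone")
})

test_that("live/dead generator: counts, determinism, overcrowding", {
  blank <- generateLiveDeadImage(0, 0, imageSize = c(64, 64), seed = 1)
  expect_equal(max(blank$live), 0)
  expect_equal(max(blank$dead), 0)

  img <- generateLiveDeadImage(74, 26, imageSize = c(256, 256),
                               blobRadius = 4, seed = 2)
  expect_equal(img$nLive / (img$nLive + img$nDead), 0.74)

  a <- generateLiveDeadImage(10, 10, imageSize = c(128, 128), seed = 5)
  b <- generateLiveDeadImage(10, 10, imageSize = c(128, 128), seed = 5)
  expect_identical(a$live, b$live)
  expect_identical(a$dead, b$dead)

  expect_error(generateLiveDeadImage(200, 200, imageSize = c(64, 64),
                                     blobRadius = 6, seed = 1, maxTries = 50),
               "could not place")
})
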