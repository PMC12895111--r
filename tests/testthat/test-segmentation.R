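test_that("grayscale conversion: identity, symmetry, luminance weights", {
  m <- matrix(runif(12), 3, 4)
  expect_identical(toGrayscale(m), m)
  eq <- array(rep(m, 3), dim = c(3, 4, 3))
  expect_equal(toGrayscale(eq), m, tolerance = 1e-12)
  red <- array(0, dim = c(3, 4, 3)); red[, , 1] <- 1
  expect_equal(toGrayscale(red), matrix(0.2126, 3, 4), tolerance = 1e-12)
  expect_error(toGrayscale(array(0, dim = c(3, 4, 2))), "channel")
})

test_that("uniform bright frames give an empty mask", {
  expect_false(any(segmentGlottis(matrix(0.9, 40, 40))))
})

test_that("a painted dark ellipse is recovered within 2% of its pixel count", {
  nr <- 64; nc <- 64
  d <- outer(((1:nr) - 32) / 14, ((1:nc) - 32) / 8,
             function(a, b) a^2 + b^2)
  frame <- matrix(0.85, nr, nc)
  frame[d <= 1] <- 0.1
  n <- sum(d <= 1)
  got <- sum(segmentGlottis(frame))
  expect_lt(abs(got - n) / n, 0.02)
})

test_that("only the largest dark component survives; 8-connectivity merges diagonals", {
  fr <- matrix(0.9, 40, 40)
  fr[5:10, 5:12] <- 0.1       # 48 px
  fr[25:28, 25:28] <- 0.1     # 16 px
  m <- segmentGlottis(fr)
  expect_true(all(m[5:10, 5:12]))
  expect_false(any(m[25:28, 25:28]))

  # two squares touching only at a corner are one 8-connected component
  fr2 <- matrix(0.9, 40, 40)
  fr2[10:14, 10:14] <- 0.1
  fr2[15:19, 15:19] <- 0.1
  m2 <- segmentGlottis(fr2)
  expect_true(all(m2[10:14, 10:14]) && all(m2[15:19, 15:19]))
})

test_that("pixel area scale squares the linear scale", {
  expect_identical(pixelAreaScale(0.01), 1e-4)
  expect_identical(pixelAreaScale(1.0), 1.0)
  expect_identical(pixelAreaScale(0.5), 0.25)
  expect_equal(pixelAreaScale(Calibration(20000, 0.01)), 1e-4)
  expect_error(pixelAreaScale(-1), "positive")
})

test_that("moving average: closed forms, identity, and argument checks", {
  expect_equal(movingAverage(c(0, 0, 1, 0, 0), 3), c(0, 1/3, 1/3, 1/3, 0))
  x <- rep(2.5, 10)
  expect_equal(movingAverage(x, 5), x)
  y <- rnorm(20)
  expect_identical(movingAverage(y, 1), y)
  expect_error(movingAverage(y, 4), "odd")
  expect_error(movingAverage(y, 21), "window")
})

test_that("moving average equals the brute-force truncated-window oracle", {
  set.seed(1)
  for (w in c(3L, 7L, 11L)) {
    x <- rnorm(50)
    expect_equal(movingAverage(x, w), bruteMovingAverage(x, w),
                 tolerance = 1e-12)
  }
})

test_that("local-mean segmentation matches exhaustive evaluation on small images", {
  set.seed(2)
  for (i in 1:5) {
    fr <- matrix(runif(16 * 16), 16, 16)
    cfg <- thresholdConfig(windowSize = 5, offset = 0.05,
                           largestOnly = FALSE, fillHoles = FALSE)
    expect_identical(segmentGlottis(fr, cfg),
                     bruteLocalMeanMask(fr, 5, 0.05))
  }
})

test_that("doubling the spatial scale quadruples every area exactly", {
  sim <- shortSim(duration = 0.002)
  a1 <- areaWaveform(FrameStack(frames(sim$stack), Calibration(20000, 0.01)))
  a2 <- areaWaveform(FrameStack(frames(sim$stack), Calibration(20000, 0.02)))
  expect_equal(areaRaw(a2$waveform), 4 * areaRaw(a1$waveform),
               tolerance = 1e-14)
  expect_equal(areaSmooth(a2$waveform), 4 * areaSmooth(a1$waveform),
               tolerance = 1e-14)
})

test_that("smoothing is mean-preserving on the interior", {
  sim <- shortSim(duration = 0.004)
  aw <- areaWaveform(sim$stack, window = 5)
  raw <- areaRaw(aw$waveform); sm <- areaSmooth(aw$waveform)
  interior <- 3:(length(raw) - 2)
  expect_equal(mean(sm[interior]),
               mean(vapply(interior, function(i) mean(raw[(i-2):(i+2)]),
                           numeric(1))),
               tolerance = 1e-12)
})

test_that("a static dark rectangle yields a constant exact area", {
  fr <- matrix(0.8, 60, 60)
  fr[26:35, 21:40] <- 0.1                    # 10 x 20 px = 200 px
  stack <- FrameStack(array(rep(fr, 6), dim = c(60, 60, 6)),
                      Calibration(20000, 0.01))
  aw <- areaWaveform(stack)
  expect_equal(areaRaw(aw$waveform), rep(0.02, 6), tolerance = 1e-14)
  expect_equal(areaSmooth(aw$waveform), rep(0.02, 6), tolerance = 1e-14)
})

test_that("an all-bright stack yields an identically zero waveform", {
  stack <- FrameStack(array(0.9, dim = c(20, 20, 5)), Calibration())
  aw <- areaWaveform(stack)
  expect_identical(areaRaw(aw$waveform), rep(0, 5))
  expect_identical(max(areaSmooth(aw$waveform)), 0)
})

test_that("otsu segmentation also isolates the dark region", {
  fr <- matrix(0.85, 40, 40)
  fr[10:20, 15:25] <- 0.1
  m <- segmentGlottis(fr, thresholdConfig(method = "otsu"))
  expect_equal(sum(m), 11 * 11)
})
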