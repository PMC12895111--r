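test_that("kymogram columns are verbatim scanline copies", {
  sim <- shortSim(duration = 0.002)
  aw <- areaWaveform(sim$stack)
  kg <- extractKymogram(sim$stack, 0.5, aw$masks)
  for (t in c(1L, 10L, 40L))
    expect_identical(kg@matrix[, t], frames(sim$stack)[kg@scanRow, , t])
})

test_that("a static stack gives identical kymogram columns and constant tracks", {
  fr <- matrix(0.8, 40, 40); fr[10:30, 18:22] <- 0.1
  stack <- FrameStack(array(rep(fr, 8), dim = c(40, 40, 8)), Calibration())
  aw <- areaWaveform(stack)
  res <- multiPositionKymograms(stack, masks = aw$masks)
  for (el in res) {
    expect_true(all(el$kymogram@matrix == el$kymogram@matrix[, 1]))
    expect_equal(length(unique(leftPos(el$edges))), 1L)
    expect_equal(length(unique(rightPos(el$edges))), 1L)
  }
})

test_that("edge-track gap is periodic at fps/f0 and correlates with ground truth", {
  sim <- shortSim(f0 = 500)
  aw <- areaWaveform(sim$stack)
  kg <- extractKymogram(sim$stack, 0.5, aw$masks)
  e <- traceEdges(kg, aw$masks)
  gap <- rightPos(e) - leftPos(e)
  f0 <- estimateF0(gap, fps(calibration(e)))
  expect_lt(abs(1 / f0 - 1 / 500), 1 / 20000)     # period within one frame
  midRow <- kg@scanRow - sim$truth@glottalRows[1] + 1L
  trueGap <- trueRightEdge(sim$truth)[midRow, ] - trueLeftEdge(sim$truth)[midRow, ]
  expect_gt(cor(gap, trueGap), 0.99)
})

test_that("period recovery holds across the phonatory frequency range", {
  for (f0 in c(150, 900)) {
    sim <- shortSim(f0 = f0, duration = max(0.008, 4 / f0))
    aw <- areaWaveform(sim$stack)
    e <- traceEdges(extractKymogram(sim$stack, 0.5, aw$masks), aw$masks)
    est <- estimateF0(rightPos(e) - leftPos(e), 20000)
    expect_lt(abs(1 / est - 1 / f0), 1 / 20000)
  }
})

test_that("zero phase lag makes gap series proportional across positions", {
  sim <- shortSim(apPhaseLag = 0)
  res <- multiPositionKymograms(sim$stack, c(0.25, 0.75))
  g1 <- rightPos(res[[1]]$edges) - leftPos(res[[1]]$edges)
  g2 <- rightPos(res[[2]]$edges) - leftPos(res[[2]]$edges)
  expect_gt(cor(g1, g2), 0.99)
})

test_that("symmetric videos give mirror-image edge tracks", {
  sim <- shortSim()
  aw <- areaWaveform(sim$stack)
  e <- traceEdges(extractKymogram(sim$stack, 0.5, aw$masks), aw$masks)
  expect_lte(max(abs(leftPos(e) + rightPos(e))), 0.01 + 1e-12)  # 1 px * scale
})

test_that("closed frames are flagged with both edges at zero", {
  sim <- shortSim(restGap = 0)
  aw <- areaWaveform(sim$stack)
  e <- traceEdges(extractKymogram(sim$stack, 0.5, aw$masks), aw$masks)
  expect_gt(sum(isClosed(e)), 0)
  expect_true(all(leftPos(e)[isClosed(e)] == 0))
  expect_true(all(rightPos(e)[isClosed(e)] == 0))
  expect_true(all(rightPos(e) - leftPos(e) >= 0))
})

test_that("a single fraction reproduces extractKymogram, and bad input errors", {
  sim <- shortSim(duration = 0.002)
  aw <- areaWaveform(sim$stack)
  one <- multiPositionKymograms(sim$stack, 0.5, masks = aw$masks)
  ref <- extractKymogram(sim$stack, 0.5, aw$masks)
  expect_identical(one[[1]]$kymogram@matrix, ref@matrix)
  expect_identical(one[[1]]$kymogram@scanRow, ref@scanRow)

  bright <- FrameStack(array(0.9, dim = c(20, 20, 4)), Calibration())
  expect_error(extractKymogram(bright, 0.5), "no glottal extent")
  expect_error(multiPositionKymograms(sim$stack, c(0.9, 0.1)), "sorted")
  expect_error(extractKymogram(sim$stack, 1.5, aw$masks), "axisFraction")
})

test_that("an imposed anterior-posterior phase lag is recovered by regression", {
  sim <- shortSim(f0 = 500, apPhaseLag = pi / 4, duration = 0.016)
  res <- multiPositionKymograms(sim$stack)
  expect_lt(abs(apPhaseLagEstimate(res) - pi / 4), 0.1)
})
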