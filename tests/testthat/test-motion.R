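makeMaskSeries <- function(maskArr, calib = Calibration()) {
  new("GlottalMaskSeries", masks = maskArr,
      pixelCounts = as.integer(apply(maskArr, 3, sum)), calib = calib)
}

test_that("a static stack yields zero flow", {
  set.seed(3)
  fr <- EBImage::gblur(matrix(runif(60 * 60), 60, 60), 2)
  stack <- FrameStack(array(rep(fr, 3), dim = c(60, 60, 3)), Calibration())
  m <- array(FALSE, dim = c(60, 60, 3)); m[20:40, 20:40, ] <- TRUE
  fl <- opticalFlow(stack, makeMaskSeries(m))
  for (f in fl) {
    expect_lt(max(abs(f$u)), 0.05)
    expect_lt(max(abs(f$v)), 0.05)
  }
})

test_that("a rigid 1 px lateral shift is recovered", {
  set.seed(4)
  base <- EBImage::gblur(matrix(runif(80 * 80), 80, 80), 1.5)
  base <- (base - min(base)) / diff(range(base))
  shifted <- base[, c(1, 1:79)]          # content moves +1 column
  stack <- FrameStack(array(c(base, shifted), dim = c(80, 80, 2)),
                      Calibration())
  m <- array(FALSE, dim = c(80, 80, 2)); m[25:55, 25:55, ] <- TRUE
  fl <- opticalFlow(stack, makeMaskSeries(m), flowConfig(dilateRadius = 0))
  roi <- fl[[1]]$roi
  expect_gt(mean(fl[[1]]$u[roi]), 0.8)
  expect_lt(mean(fl[[1]]$u[roi]), 1.2)
  expect_lt(abs(mean(fl[[1]]$v[roi])), 0.2)
})

test_that("during opening, lateral flow sign is opposite across the midline", {
  sim <- shortSim(f0 = 500)
  aw <- areaWaveform(sim$stack)
  fl <- opticalFlow(sim$stack, aw$masks)
  k <- 5L                                  # inside the first opening quarter-cycle
  f <- fl[[k]]
  mid <- sim$truth@midlineCol
  colIdx <- matrix(rep(seq_len(ncol(f$u)), each = nrow(f$u)), nrow(f$u))
  act <- f$roi & abs(f$u) > 0.02
  agree <- sign(f$u[act]) == sign(colIdx[act] - mid)
  expect_gte(mean(agree), 0.9)
})

test_that("GOFW tracks the derivative of the true area and scales with amplitude", {
  sim <- shortSim(f0 = 500)
  aw <- areaWaveform(sim$stack)
  gw <- gofw(opticalFlow(sim$stack, aw$masks), aw$masks)
  expect_gte(cor(gw$gofw, diff(trueArea(sim$truth))), 0.9)

  sim2 <- shortSim(f0 = 500, ampLeft = 0.05, ampRight = 0.05)
  aw2 <- areaWaveform(sim2$stack)
  gw2 <- gofw(opticalFlow(sim2$stack, aw2$masks), aw2$masks)
  ratio <- max(abs(gw$gofw)) / max(abs(gw2$gofw))
  expect_gt(ratio, 2 * 0.85)
  expect_lt(ratio, 2 * 1.15)
})

test_that("all-zero flow fields produce a zero waveform; empty ROI flagged", {
  m <- array(FALSE, dim = c(10, 10, 3)); m[4:6, 4:6, 1:2] <- TRUE
  ms <- makeMaskSeries(m)
  z <- matrix(0, 10, 10)
  fields <- list(list(u = z, v = z, roi = m[, , 1], pair = c(1L, 2L)),
                 list(u = z, v = z, roi = matrix(FALSE, 10, 10), pair = c(2L, 3L)))
  gw <- gofw(fields, ms)
  expect_identical(gw$gofw, c(0, 0))
  expect_identical(gw$empty, c(FALSE, TRUE))
})

test_that("GOFW is antisymmetric under time reversal", {
  sim <- shortSim(f0 = 500, duration = 0.004)
  aw <- areaWaveform(sim$stack)
  gw <- gofw(opticalFlow(sim$stack, aw$masks), aw$masks)

  nT <- nFrames(sim$stack)
  revStack <- FrameStack(frames(sim$stack)[, , nT:1], calibration(sim$stack))
  revMasks <- makeMaskSeries(masks(aw$masks)[, , nT:1])
  gwRev <- gofw(opticalFlow(revStack, revMasks), revMasks)
  expect_equal(gwRev$gofw, -rev(gw$gofw), tolerance = 1e-10)
})

test_that("fold trajectories: symmetry, deflection sum, and phase", {
  sim <- shortSim(f0 = 500)
  aw <- areaWaveform(sim$stack)
  kg <- extractKymogram(sim$stack, 0.5, aw$masks)
  e <- traceEdges(kg, aw$masks)
  tj <- foldTrajectories(e)
  expect_gte(symmetryIndex(tj), 0.95)
  expect_lte(abs(phaseLag(tj)), 0.1)

  midRow <- kg@scanRow - sim$truth@glottalRows[1] + 1L
  trueGap <- trueRightEdge(sim$truth)[midRow, ] - trueLeftEdge(sim$truth)[midRow, ]
  expect_lte(max(abs(deltaLeft(tj) + deltaRight(tj) - trueGap)), 0.01 + 1e-12)
})

test_that("2:1 amplitudes give a 2:1 mean deflection ratio", {
  sim <- shortSim(f0 = 500, restGap = 0, ampLeft = 0.2, ampRight = 0.1)
  aw <- areaWaveform(sim$stack)
  tj <- foldTrajectories(traceEdges(extractKymogram(sim$stack, 0.5, aw$masks),
                                    aw$masks))
  r <- mean(deltaLeft(tj)) / mean(deltaRight(tj))
  expect_gt(r, 2 * 0.9); expect_lt(r, 2 * 1.1)
})

test_that("an all-closed track yields flagged zero trajectories", {
  e <- new("EdgeTrack", leftPos = rep(0, 20), rightPos = rep(0, 20),
           closed = rep(TRUE, 20), axisFraction = 0.5, calib = Calibration())
  tj <- foldTrajectories(e)
  expect_true(tj@allClosed)
  expect_true(is.na(symmetryIndex(tj)))
  expect_identical(deltaLeft(tj), rep(0, 20))
})

test_that("trajectory and kymography periods agree within one frame", {
  sim <- shortSim(f0 = 400)
  aw <- areaWaveform(sim$stack)
  e <- traceEdges(extractKymogram(sim$stack, 0.5, aw$masks), aw$masks)
  tj <- foldTrajectories(e)
  fTraj <- estimateF0(deltaLeft(tj) + deltaRight(tj), 20000)
  fKymo <- estimateF0(rightPos(e) - leftPos(e), 20000)
  expect_lt(abs(1 / fTraj - 1 / fKymo), 1 / 20000)
})

test_that("fewer than two frames is refused", {
  stack <- FrameStack(array(0.5, dim = c(8, 8, 1)), Calibration())
  m <- array(TRUE, dim = c(8, 8, 1))
  expect_error(opticalFlow(stack, makeMaskSeries(m)), "2 frames")
})
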