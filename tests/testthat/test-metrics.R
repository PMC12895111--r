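test_that("F0 estimation: pure tones, constants, and accuracy", {
  t <- (0:399) / 20000
  expect_lt(abs(estimateF0(sin(2 * pi * 250 * t), 20000) - 250), 5)
  expect_true(is.na(estimateF0(rep(1, 400), 20000)))
  for (f0 in c(100, 333, 750, 1200)) {
    t <- (0:999) / 20000
    est <- estimateF0(sin(2 * pi * f0 * t), 20000)
    expect_lt(abs(est - f0) / f0, 0.01)
  }
  expect_error(estimateF0(1:10, fs = -1), "fs")
})

test_that("F0 survives half-wave-rectified waveforms (glottal-area shape)", {
  t <- (0:799) / 20000
  x <- pmax(0, sin(2 * pi * 400 * t))
  expect_lt(abs(estimateF0(x, 20000) - 400) / 400, 0.01)
})

test_that("maximum glottal area takes the smoothed peak", {
  wave <- new("AreaWaveform", time = (0:4) / 100, areaRaw = rep(0.02, 5),
              areaSmooth = rep(0.02, 5), window = 1L)
  expect_equal(maxGlottalArea(wave), 0.02)
  zero <- new("AreaWaveform", time = (0:4) / 100, areaRaw = rep(0, 5),
              areaSmooth = rep(0, 5), window = 1L)
  expect_equal(maxGlottalArea(zero), 0)
})

test_that("SPL closed forms and scale covariance", {
  t <- seq(0, 1, length.out = 48000)
  x <- sqrt(2) * sin(2 * pi * 440 * t)       # RMS 1 Pa
  expect_equal(spl(x), 20 * log10(1 / 2e-5), tolerance = 1e-3)
  xref <- sqrt(2) * 2e-5 * sin(2 * pi * 440 * t)
  expect_equal(spl(xref), 0, tolerance = 1e-3)
  expect_equal(spl(2 * x) - spl(x), 20 * log10(2), tolerance = 1e-9)
  expect_equal(spl(3.7 * x), spl(x) + 20 * log10(3.7), tolerance = 1e-9)
  expect_error(spl(rep(5, 100)), "zero-power")
  pres <- SignalTrace(rnorm(100), 1000, "pressure")
  expect_error(spl(pres), "acoustic")
})

test_that("onset detection: accuracy, absence, ordering, ramp-rate robustness", {
  tr <- generatePressureSweep(onsetPressure = 3, rampRate = 1, oscAmp = 0.5,
                              f0 = 200, fs = 10000, duration = 6,
                              noiseSigma = 0.01, seed = 3)
  expect_lt(abs(as.numeric(detectOnsetPressure(tr)) - 3.0), 0.1)

  ramp <- generatePressureSweep(onsetPressure = 3, rampRate = 1, oscAmp = 0,
                                duration = 5, noiseSigma = 0.01, seed = 4)
  expect_true(is.na(detectOnsetPressure(ramp)))

  lo <- generatePressureSweep(onsetPressure = 2, rampRate = 1, duration = 6,
                              noiseSigma = 0.01, seed = 5)
  hi <- generatePressureSweep(onsetPressure = 4, rampRate = 1, duration = 6,
                              noiseSigma = 0.01, seed = 5)
  expect_lt(as.numeric(detectOnsetPressure(lo)),
            as.numeric(detectOnsetPressure(hi)))

  for (rate in c(0.5, 5)) {                  # a decade of ramp rates
    tr <- generatePressureSweep(onsetPressure = 3, rampRate = rate,
                                oscAmp = 0.5, f0 = 200, fs = 10000,
                                duration = 3 / rate + 2, noiseSigma = 0.01,
                                seed = 6)
    expect_lt(abs(as.numeric(detectOnsetPressure(tr)) - 3.0), 0.1)
  }

  ac <- SignalTrace(rnorm(1000), 1000, "acoustic")
  expect_error(detectOnsetPressure(ac), "pressure")
})

test_that("end-to-end video metrics recover simulator parameters", {
  sim <- shortSim(f0 = 500)
  pm <- phonatoryMetrics(sim$stack)
  expect_lt(abs(pm@f0 - 500) / 500, 0.02)
  expect_lt(abs(pm@maxArea - max(trueArea(sim$truth))) /
              max(trueArea(sim$truth)), 0.05)
  expect_true(is.na(pm@onsetPressure))
  expect_true(is.na(pm@spl))
})

test_that("relative phase of shifted sinusoids is their phase offset", {
  t <- (0:999) / 10000
  for (ph in c(-0.8, 0.3, 1.2)) {
    x <- sin(2 * pi * 300 * t + ph)
    y <- sin(2 * pi * 300 * t)
    expect_lt(abs(relativePhase(x, y, 10000, 300) - ph), 0.05)
  }
})
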