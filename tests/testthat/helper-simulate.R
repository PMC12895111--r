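# Short simulations shared across tests: 8 ms at 20 kHz (160 frames),
# enough for 4 cycles at 500 Hz while keeping the suite fast.
shortSim <- function(f0 = 500, restGap = 0.3, ampLeft = 0.1, ampRight = 0.1,
                     apPhaseLag = 0, duration = 0.008, noiseSigma = 0,
                     seed = NULL, ...) {
  generateGlottalVideo(
    GlottalKinematics(f0 = f0, restGap = restGap, ampLeft = ampLeft,
                      ampRight = ampRight, apPhaseLag = apPhaseLag,
                      duration = duration, ...),
    Calibration(), noiseSigma = noiseSigma, seed = seed)
}

relRMS <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))

# Brute-force centred moving average with edge truncation (oracle).
bruteMovingAverage <- function(x, window) {
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

# Exhaustive per-pixel local-mean threshold with replicated borders (oracle).
bruteLocalMeanMask <- function(frame, windowSize, offset) {
  h <- windowSize %/% 2
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      acc <- acc + frame[ii, jj]
    }
    out[i, j] <- frame[i, j] < acc / windowSize^2 - offset
  }
  out
}
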