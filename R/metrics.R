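#' Estimate the fundamental frequency of a short oscillatory record
#'
#' Autocorrelation-peak estimator with parabolic interpolation, suited to
#' the short (tens of ms) analysis windows of high-speed video, where bare
#' FFT bins would be 50 Hz apart. The unbiased sample autocorrelation is
#' scanned for local maxima between \code{fs/maxF0} and \code{fs/minF0};
#' the smallest peak lag within 85 percent of the strongest peak is taken
#' (guarding against octave errors), then refined by locating the
#' highest-order visible harmonic of that lag and dividing. When the best
#' normalised peak falls below \code{prominence}, no oscillation is
#' declared and \code{NA} is returned (non-oscillating configurations are
#' data, not errors).
#'
#' @param x numeric series, or an \code{\link{AreaWaveform}} (its smoothed
#'   series is used).
#' @param fs sampling rate (1/s); taken from the waveform when omitted.
#' @param minF0,maxF0 search band (Hz).
#' @param prominence minimum normalised autocorrelation peak height.
#' @return Fundamental frequency in Hz, or \code{NA_real_} when no
#'   oscillation is detected.
#' @examples
#' t <- (0:399) / 20000
#' estimateF0(sin(2 * pi * 250 * t), 20000)
#' @export
estimateF0 <- function(x, fs = NULL, minF0 = 40, maxF0 = 2500,
                       prominence = 0.3) {
  if (is(x, "AreaWaveform")) {
    if (is.null(fs)) fs <- 1 / diff(x@time[1:2])
    x <- x@areaSmooth
  }
  if (is.null(fs) || fs <= 0) stop("'fs' must be > 0")
  x <- as.numeric(x)
  n <- length(x)
  x <- x - mean(x)
  if (n < 8L || stats::sd(x) == 0) return(NA_real_)

  maxLag <- min(n - 2L, floor(fs / minF0))
  minLag <- max(2L, floor(fs / maxF0))
  if (maxLag <= minLag + 1L) return(NA_real_)

  ## unbiased autocorrelation via FFT, normalised by overlap length
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(maxLag + 1L)]
  ac <- ac / (n - (0:maxLag))
  r <- ac / ac[1L]

  lag <- seq.int(minLag, maxLag)
  inner <- lag[lag > minLag & lag < maxLag]
  isPeak <- r[inner + 1L] > r[inner] & r[inner + 1L] >= r[inner + 2L]
  peaks <- inner[isPeak]
  if (!length(peaks)) return(NA_real_)
  best <- max(r[peaks + 1L])
  if (best < prominence) return(NA_real_)
  k0 <- min(peaks[r[peaks + 1L] >= 0.85 * best])

  refine <- function(k) {      # parabolic interpolation around integer lag k
    if (k <= 1L || k >= maxLag) return(as.numeric(k))
    y1 <- r[k]; y2 <- r[k + 1L]; y3 <- r[k + 2L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < 1e-15) return(as.numeric(k))
    k + 0.5 * (y1 - y3) / den
  }
  p <- refine(k0)
  ## sharpen using the highest visible harmonic of the period
  for (mult in rev(seq_len(max(1L, floor(maxLag / k0))))) {
    kApprox <- as.integer(round(mult * p))
    lo <- max(2L, kApprox - max(2L, k0 %/% 4L))
    hi <- min(maxLag - 1L, kApprox + max(2L, k0 %/% 4L))
    if (lo >= hi) next
    win <- lo:hi
    kLoc <- win[which.max(r[win + 1L])]
    if (r[kLoc + 1L] >= 0.7 * best) { p <- refine(kLoc) / mult; break }
  }
  fs / p
}

#' Relative oscillation phase of two series
#'
#' Phase advance of \code{x} relative to \code{y} at frequency \code{f0},
#' from Hann-windowed quadrature demodulation: each mean-removed series is
#' projected onto \code{exp(-2i*pi*f0*t)} and the result is the argument
#' difference of the two complex amplitudes. The projection uses the full
#' record, so pixel-quantisation noise in edge tracks averages out.
#' Positive values mean \code{x} leads \code{y}.
#'
#' @param x,y numeric series of equal length.
#' @param fs sampling rate (1/s).
#' @param f0 oscillation frequency (Hz); estimated from \code{y} when NULL.
#' @return Phase in radians, in (-pi, pi].
#' @export
relativePhase <- function(x, y, fs, f0 = NULL) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (is.null(f0)) f0 <- estimateF0(y, fs)
  if (is.na(f0)) stop("no oscillation frequency available")
  n <- length(x)
  t <- (seq_len(n) - 1L) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))   # Hann
  carrier <- w * exp(-2i * pi * f0 * t)
  zx <- sum((x - mean(x)) * carrier)
  zy <- sum((y - mean(y)) * carrier)
  if (Mod(zx) == 0 || Mod(zy) == 0) stop("no oscillatory power at f0")
  ph <- Arg(zx * Conj(zy))
  ((ph + pi) %% (2 * pi)) - pi
}

#' Maximum glottal area
#'
#' The maximum of the smoothed glottal area waveform, the summary used to
#' compare fold opening across replicas and airflow levels.
#'
#' @param wave an \code{\link{AreaWaveform}}.
#' @return Maximum smoothed area (mm^2).
#' @export
maxGlottalArea <- function(wave) {
  stopifnot(is(wave, "AreaWaveform"))
  if (!length(wave@areaSmooth)) stop("empty area waveform")
  max(wave@areaSmooth)
}

#' Sound pressure level of an acoustic trace
#'
#' \code{20 * log10(rms / 20e-6)} dB of the mean-removed signal, with the
#' standard acoustic reference pressure of 20 micropascal.
#'
#' @param trace a \code{\link{SignalTrace}} of kind \code{"acoustic"}, or a
#'   numeric vector in Pa.
#' @param pRef reference pressure (Pa).
#' @return SPL in dB.
#' @examples
#' spl(sqrt(2) * sin(seq(0, 2 * pi, length.out = 1000)))  # RMS 1 Pa ~ 94 dB
#' @export
spl <- function(trace, pRef = 20e-6) {
  if (is(trace, "SignalTrace")) {
    if (trace@kind != "acoustic")
      stop("SPL requires an acoustic-kind trace")
    trace <- trace@samples
  }
  x <- trace - mean(trace)
  rms <- sqrt(mean(x^2))
  if (rms == 0) stop("zero-power trace: SPL undefined")
  20 * log10(rms / pRef)
}

#' Detect the phonation onset pressure in a pressure sweep
#'
#' Finds the subglottal pressure at which self-sustained oscillation
#' starts. The trace is linearly detrended and band-passed around its
#' dominant oscillation frequency (Butterworth, zero-phase); the
#' oscillation envelope (moving RMS over \code{m} cycles) is compared with
#' the pre-onset noise floor estimated from the first
#' \code{preFraction} of the record. Onset is the first time the envelope
#' exceeds \code{k} times the floor for at least \code{m} consecutive
#' cycles; the onset pressure is the low-pass (two-cycle moving average)
#' trace value at that time. When the threshold is never sustained the
#' result is absent (\code{NA}), mirroring configurations that never
#' oscillate.
#'
#' @param trace a \code{\link{SignalTrace}} of kind \code{"pressure"}.
#' @param k envelope-to-noise-floor ratio required at onset.
#' @param m number of cycles the exceedance must persist (also the
#'   envelope window length in cycles).
#' @param preFraction fraction of the record assumed oscillation-free,
#'   used for the noise floor.
#' @return Onset pressure in kPa with attributes \code{time} (s) and
#'   \code{frequency} (Hz), or \code{NA_real_} when absent.
#' @export
detectOnsetPressure <- function(trace, k = 5, m = 3, preFraction = 0.1) {
  stopifnot(is(trace, "SignalTrace"))
  if (trace@kind != "pressure")
    stop("onset detection requires a pressure-kind trace")
  x <- trace@samples
  fs <- trace@fs
  n <- length(x)
  tt <- (seq_len(n) - 1L) / fs

  ## remove the slow ramp, then find the dominant oscillation frequency
  detr <- stats::residuals(stats::lm(x ~ tt))
  spec <- Mod(stats::fft(detr))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1L) * fs / n
  band <- freqs > 20 & freqs < 0.45 * fs
  if (!any(band)) return(NA_real_)
  f0 <- freqs[band][which.max(spec[band])]

  lohi <- c(0.5, 1.5) * f0 / (fs / 2)
  lohi[2] <- min(lohi[2], 0.99)
  bf <- signal::butter(2, lohi, type = "pass")
  bp <- signal::filtfilt(bf, detr)

  w <- as.integer(round(fs / f0 * m))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= n) return(NA_real_)
  env <- sqrt(movingAverage(bp^2, w))

  nPre <- max(w, as.integer(floor(preFraction * n)))
  floorEnv <- max(stats::median(env[seq_len(nPre)]), 1e-9 * max(env), 1e-12)

  guard <- w                                  # skip filter edge transients
  ok <- env > k * floorEnv
  ok[seq_len(min(guard, n))] <- FALSE
  ok[seq.int(max(1L, n - guard + 1L), n)] <- FALSE
  rl <- rle(ok)
  ends <- cumsum(rl$lengths)
  hit <- which(rl$values & rl$lengths >= w)
  if (!length(hit)) return(NA_real_)
  onsetIdx <- ends[hit[1L]] - rl$lengths[hit[1L]] + 1L

  wLP <- as.integer(round(2 * fs / f0)); if (wLP %% 2L == 0L) wLP <- wLP + 1L
  lp <- movingAverage(x, min(wLP, if (n %% 2L) n else n - 1L))
  structure(lp[onsetIdx], time = tt[onsetIdx], frequency = f0)
}

#' Full phonatory report of a video (plus optional signal traces)
#'
#' Convenience wrapper: segments a stack, extracts the area waveform,
#' estimates F0 and maximum glottal area, and, when traces are supplied,
#' onset pressure and SPL.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param pressure optional pressure \code{\link{SignalTrace}}.
#' @param acoustic optional acoustic \code{\link{SignalTrace}}.
#' @param cfg segmentation settings.
#' @param window area smoothing window (frames).
#' @return A \code{\link{PhonatoryMetrics}}.
#' @export
phonatoryMetrics <- function(stack, pressure = NULL, acoustic = NULL,
                             cfg = thresholdConfig(), window = 5L) {
  aw <- areaWaveform(stack, cfg, window)
  f0 <- estimateF0(aw$waveform)
  onset <- if (!is.null(pressure)) as.numeric(detectOnsetPressure(pressure)) else NA_real_
  lvl <- if (!is.null(acoustic)) spl(acoustic) else NA_real_
  new("PhonatoryMetrics", f0 = f0, maxArea = maxGlottalArea(aw$waveform),
      onsetPressure = onset, spl = lvl)
}
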