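#' Simulate a subglottal pressure sweep with a known phonation onset
#'
#' Forward model for onset-pressure detection: a linear pressure ramp with
#' a sinusoidal oscillation superimposed once the ramp crosses the onset
#' pressure. The oscillation amplitude grows smoothly (smoothstep) over 10
#' cycles, emulating the gradual build-up of self-sustained fold
#' oscillation at phonation onset. The true onset is recorded in the trace
#' metadata; when the ramp never reaches the onset pressure within
#' \code{duration}, or \code{oscAmp} is 0, the onset metadata is marked
#' absent and no oscillation is added.
#'
#' @param onsetPressure subglottal pressure at which oscillation starts (kPa).
#' @param rampRate linear ramp rate (kPa/s).
#' @param oscAmp oscillation amplitude once fully grown (kPa).
#' @param f0 oscillation frequency (Hz); \code{fs} must exceed \code{2 * f0}.
#' @param fs sampling rate (1/s).
#' @param duration record length (s).
#' @param noiseSigma additive Gaussian noise s.d. (kPa).
#' @param seed integer seed for the noise.
#' @return A \code{\link{SignalTrace}} of kind \code{"pressure"} whose
#'   metadata holds \code{onsetPresent}, \code{onsetPressure},
#'   \code{onsetTime} and \code{f0}.
#' @examples
#' tr <- generatePressureSweep(onsetPressure = 3, rampRate = 1, duration = 5)
#' traceMetadata(tr)$onsetTime
#' @export
generatePressureSweep <- function(onsetPressure = 3, rampRate = 1,
                                  oscAmp = 0.5, f0 = 200, fs = 10000,
                                  duration = 5, noiseSigma = 0.01,
                                  seed = NULL) {
  if (any(c(onsetPressure, rampRate, oscAmp, noiseSigma) < 0))
    stop("pressures, rates and amplitudes must be >= 0")
  if (fs <= 2 * f0) stop("'fs' must exceed 2 * f0")
  n <- as.integer(round(fs * duration))
  t <- (seq_len(n) - 1L) / fs
  ramp <- rampRate * t

  tOnset <- if (rampRate > 0) onsetPressure / rampRate else Inf
  present <- oscAmp > 0 && tOnset <= t[n]
  x <- ramp
  if (present) {
    ## smoothstep growth over 10 cycles after onset
    u <- pmin(pmax((t - tOnset) * f0 / 10, 0), 1)
    grow <- u * u * (3 - 2 * u)
    x <- x + oscAmp * grow * sin(2 * pi * f0 * (t - tOnset))
  }
  if (noiseSigma > 0) {
    if (is.null(seed)) stop("a 'seed' is required when noiseSigma > 0")
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(n, sd = noiseSigma)
  }
  md <- list(onsetPresent = present,
             onsetPressure = if (present) onsetPressure else NA_real_,
             onsetTime = if (present) tOnset else NA_real_,
             f0 = f0, rampRate = rampRate, oscAmp = oscAmp,
             noiseSigma = noiseSigma,
             seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  SignalTrace(x, fs, "pressure", md)
}

#' Simulate a dye-diffusion image series with known coverage
#'
#' Emulates time-lapse brightfield imaging of a hydrogel construct into
#' which a dye diffuses from one side under oscillatory conditioning. Each
#' image contains a rectangular construct ROI whose stained sub-region
#' occupies the requested fraction of the ROI to within one pixel-area
#' quantum; the stained front advances column-wise from the left ROI edge,
#' so successive images are nested (diffusion is monotone).
#'
#' Intensities: background 0.05, unstained ROI 0.3, stained ROI 0.85.
#'
#' @param coverageTargets non-decreasing stained fractions in [0, 1], one
#'   per timepoint.
#' @param timepoints minutes per image (defaults to 0, 1, 2, ...).
#' @param imageSize c(height, width) of each image in pixels.
#' @param roiSize c(height, width) of the centred construct ROI.
#' @param noiseSigma optional additive Gaussian intensity noise s.d.
#' @param seed integer seed for the noise.
#' @return A list: \code{images} (list of matrices), \code{roiMask}
#'   (logical matrix), \code{trueCoverage} (achieved fractions after pixel
#'   quantisation) and \code{timepoints}.
#' @examples
#' ser <- generateDiffusionSeries(c(0.32, 0.41, 1.0))
#' ser$trueCoverage
#' @export
generateDiffusionSeries <- function(coverageTargets,
                                    timepoints = seq_along(coverageTargets) - 1,
                                    imageSize = c(128, 128),
                                    roiSize = c(64, 64), noiseSigma = 0,
                                    seed = NULL) {
  if (any(coverageTargets < 0 | coverageTargets > 1))
    stop("coverage targets must lie in [0, 1]")
  if (is.unsorted(coverageTargets))
    stop("coverage targets must be non-decreasing (diffusion is monotone)")
  if (length(timepoints) != length(coverageTargets))
    stop("'timepoints' must match 'coverageTargets' in length")
  if (any(roiSize > imageSize)) stop("ROI larger than the image")

  r0 <- floor((imageSize[1] - roiSize[1]) / 2)
  c0 <- floor((imageSize[2] - roiSize[2]) / 2)
  roiMask <- matrix(FALSE, imageSize[1], imageSize[2])
  roiMask[r0 + seq_len(roiSize[1]), c0 + seq_len(roiSize[2])] <- TRUE
  nROI <- sum(roiMask)
  ## fixed column-major fill order inside the ROI = advancing stain front
  roiIdx <- which(roiMask)
  if (!is.null(seed)) set.seed(as.integer(seed))

  images <- vector("list", length(coverageTargets))
  trueCov <- numeric(length(coverageTargets))
  for (i in seq_along(coverageTargets)) {
    nStain <- as.integer(round(coverageTargets[i] * nROI))
    img <- matrix(0.05, imageSize[1], imageSize[2])
    img[roiMask] <- 0.3
    if (nStain > 0) img[roiIdx[seq_len(nStain)]] <- 0.85
    if (noiseSigma > 0) {
      img <- img + stats::rnorm(length(img), sd = noiseSigma)
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    images[[i]] <- img
    trueCov[i] <- nStain / nROI
  }
  list(images = images, roiMask = roiMask, trueCoverage = trueCov,
       timepoints = as.numeric(timepoints))
}

#' Simulate a two-channel live/dead fluorescence image
#'
#' Places \code{nLive} bright Gaussian blobs in the live channel and
#' \code{nDead} in the dead channel, with all blob centres (across both
#' channels) separated by at least \code{minSeparation} via rejection
#' sampling, so each cell produces exactly one intensity peak. With a fixed
#' seed the image is bit-identical on regeneration.
#'
#' @param nLive,nDead non-negative blob counts.
#' @param imageSize c(height, width) in pixels.
#' @param blobRadius blob radius in pixels (Gaussian sigma = radius / 2).
#' @param minSeparation minimum centre-to-centre distance (defaults to 4
#'   blob radii, the spacing at which peak counting is exact).
#' @param noiseSigma optional Gaussian intensity noise s.d.
#' @param seed integer seed (placement and noise).
#' @param maxTries rejection-sampling attempts per blob before giving up.
#' @return A list: \code{live}, \code{dead} (intensity matrices in [0, 1]),
#'   \code{nLive}, \code{nDead}, \code{centersLive}, \code{centersDead}.
#' @examples
#' img <- generateLiveDeadImage(10, 5, seed = 1)
#' img$nLive
#' @export
generateLiveDeadImage <- function(nLive, nDead, imageSize = c(192, 192),
                                  blobRadius = 4,
                                  minSeparation = 4 * blobRadius,
                                  noiseSigma = 0, seed = NULL,
                                  maxTries = 2000) {
  if (nLive < 0 || nDead < 0) stop("counts must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nTot <- nLive + nDead
  margin <- 2 * blobRadius
  lo <- margin + 1; hiR <- imageSize[1] - margin; hiC <- imageSize[2] - margin
  if (nTot > 0 && (hiR < lo || hiC < lo))
    stop("image size: too small for the requested blob radius")

  centers <- matrix(NA_real_, nTot, 2)
  for (i in seq_len(nTot)) {
    placed <- FALSE
    for (tries in seq_len(maxTries)) {
      cand <- c(stats::runif(1, lo, hiR), stats::runif(1, lo, hiC))
      if (i == 1L || all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                            2, cand)^2)) >= minSeparation)) {
        centers[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("could not place %d non-overlapping blobs of radius %g in a %d x %d image",
                   nTot, blobRadius, imageSize[1], imageSize[2]))
  }

  renderChannel <- function(ctr) {
    img <- matrix(0, imageSize[1], imageSize[2])
    if (nrow(ctr)) {
      sig <- blobRadius / 2
      rr <- seq_len(imageSize[1]); cc <- seq_len(imageSize[2])
      for (i in seq_len(nrow(ctr))) {
        g <- outer(exp(-(rr - ctr[i, 1])^2 / (2 * sig^2)),
                   exp(-(cc - ctr[i, 2])^2 / (2 * sig^2)))
        img <- pmax(img, g)
      }
    }
    if (noiseSigma > 0) {
      img <- img + stats::rnorm(length(img), sd = noiseSigma)
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    img
  }
  liveIdx <- seq_len(nLive)
  ctrLive <- centers[liveIdx, , drop = FALSE]
  ctrDead <- centers[setdiff(seq_len(nTot), liveIdx), , drop = FALSE]
  list(live = renderChannel(ctrLive), dead = renderChannel(ctrDead),
       nLive = as.integer(nLive), nDead = as.integer(nDead),
       centersLive = ctrLive, centersDead = ctrDead)
}
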