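#' Segmentation settings
#'
#' Configuration for \code{\link{segmentGlottis}}. The default follows the
#' common recipe for isolating a dark glottis between bright folds: a
#' local-mean adaptive threshold (square neighbourhood, replicated
#' borders) minus a fixed offset, keeping only the largest dark
#' 8-connected component. A global per-frame Otsu threshold is available
#' as an alternative.
#'
#' @param method \code{"localMean"} or \code{"otsu"}.
#' @param windowSize odd side length (px) of the local-mean neighbourhood;
#'   clipped to the image when larger.
#' @param offset intensity offset subtracted from the local mean; a pixel
#'   is glottal when \code{value < localMean - offset}.
#' @param largestOnly keep only the largest 8-connected dark component.
#' @param fillHoles fill enclosed holes in the thresholded mask. A
#'   local-mean threshold only responds within half a window of an
#'   intensity edge, so the interior of a dark region wider than the
#'   neighbourhood is missed; hole filling restores it.
#' @return A named list of settings.
#' @export
thresholdConfig <- function(method = c("localMean", "otsu"), windowSize = 31,
                            offset = 0.1, largestOnly = TRUE,
                            fillHoles = TRUE) {
  windowSize <- as.integer(windowSize)
  if (windowSize < 1L || windowSize %% 2L == 0L)
    stop("'windowSize' must be odd and >= 1")
  list(method = match.arg(method), windowSize = windowSize,
       offset = offset, largestOnly = largestOnly, fillHoles = fillHoles)
}

#' Convert a frame to grayscale
#'
#' Single-channel frames pass through unchanged; 3-channel frames are
#' reduced with the Rec. 709 luminance weights (0.2126, 0.7152, 0.0722).
#'
#' @param frame a matrix, or an array with 1 or 3 channels in the third
#'   dimension, intensities in [0, 1].
#' @return A single-channel matrix in [0, 1].
#' @export
toGrayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 1L) return(frame[, , 1L])
  if (length(d) == 3L && d[3] == 3L)
    return(0.2126 * frame[, , 1L] + 0.7152 * frame[, , 2L] + 0.0722 * frame[, , 3L])
  stop(sprintf("unsupported channel count: %s",
               if (length(d) == 3L) d[3] else "not a 2-d or 3-d image"))
}

## 8-connected component labelling: EBImage::bwlabel is 4-connected, so
## labels touching diagonally are merged with a union-find pass over the
## label adjacency induced by the two diagonal shifts.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

.otsuThreshold <- function(x, levels = 256L) {
  h <- tabulate(pmin(pmax(floor(x * levels), 0), levels - 1L) + 1L, levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 1L))
  muT <- mu[levels]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  ## bimodal histograms give a plateau of optimal cuts; take its midpoint
  k <- mean(which(sb >= max(sb) - 1e-12))
  (k - 0.5) / levels
}

#' Segment the dark glottal region of one frame
#'
#' Adaptive thresholding of the dark glottis against the brighter
#' surrounding folds, optionally restricted to the largest dark
#' 8-connected component. Degenerate frames (uniformly bright, fully
#' closed glottis) yield an empty mask, which is valid data, not an error.
#'
#' @param frame grayscale matrix with intensities in [0, 1].
#' @param cfg settings from \code{\link{thresholdConfig}}.
#' @return Logical matrix; \code{TRUE} marks glottal pixels.
#' @export
segmentGlottis <- function(frame, cfg = thresholdConfig()) {
  frame <- toGrayscale(frame)
  if (min(frame) < -1e-9 || max(frame) > 1 + 1e-9)
    stop("frame intensities must lie in [0, 1]")
  if (cfg$method == "localMean") {
    w <- min(cfg$windowSize,
             max(1L, 2L * ((min(dim(frame)) - 1L) %/% 2L) + 1L))
    if (w >= 3L) {
      kern <- matrix(1 / (w * w), w, w)
      localMean <- EBImage::filter2(frame, kern, boundary = "replicate")
    } else localMean <- frame
    mask <- frame < localMean - cfg$offset
  } else {
    mask <- frame < .otsuThreshold(frame)
  }
  if (isTRUE(cfg$fillHoles) && any(mask))
    mask <- EBImage::fillHull(mask * 1) > 0
  if (cfg$largestOnly && any(mask)) {
    lab <- .label8(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  mask
}

#' @rdname pixelAreaScale
setMethod("pixelAreaScale", "Calibration", function(calib) calib@mmPerPixel^2)

#' @rdname pixelAreaScale
setMethod("pixelAreaScale", "numeric", function(calib) {
  if (length(calib) != 1L || !is.finite(calib) || calib <= 0)
    stop("mm-per-pixel scale must be a single positive number")
  calib^2
})

#' Centred moving average with edge truncation
#'
#' Smooths a series with an odd, centred window; at the boundaries the
#' window is truncated to the available samples, so the filter is
#' mean-preserving on the interior and a window of 1 is the identity.
#'
#' @param x numeric series.
#' @param window odd window length, between 1 and \code{length(x)}.
#' @return Smoothed series of the same length.
#' @examples
#' movingAverage(c(0, 0, 1, 0, 0), 3)   # 0, 1/3, 1/3, 1/3, 0
#' @export
movingAverage <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (window < 1L || window > n)
    stop(sprintf("'window' must lie in [1, %d]", n))
  if (window == 1L) return(x)
  h <- window %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Glottal area waveform of a frame stack
#'
#' Runs the frame-wise segmentation over a stack, counts glottal pixels,
#' converts counts to physical area via \code{\link{pixelAreaScale}}, and
#' smooths the raw waveform with a centred moving average.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param cfg segmentation settings from \code{\link{thresholdConfig}}.
#' @param window odd smoothing window in frames.
#' @return A list with elements \code{masks} (a
#'   \code{\link{GlottalMaskSeries}}) and \code{waveform} (an
#'   \code{\link{AreaWaveform}}).
#' @examples
#' sim <- generateGlottalVideo(GlottalKinematics(duration = 0.004))
#' aw <- areaWaveform(sim$stack)
#' aw$waveform
#' @export
areaWaveform <- function(stack, cfg = thresholdConfig(), window = 5L) {
  stopifnot(is(stack, "FrameStack"))
  arr <- stack@frames
  nT <- dim(arr)[3]
  m <- array(FALSE, dim = dim(arr))
  for (t in seq_len(nT)) m[, , t] <- segmentGlottis(arr[, , t], cfg)
  counts <- as.integer(apply(m, 3, sum))
  scale <- pixelAreaScale(stack@calib)
  raw <- counts * scale
  w <- min(as.integer(window), nT)
  if (w %% 2L == 0L) w <- w - 1L          # keep the window odd on short stacks
  ms <- new("GlottalMaskSeries", masks = m, pixelCounts = counts,
            calib = stack@calib)
  wf <- new("AreaWaveform", time = (seq_len(nT) - 1L) / stack@calib@fps,
            areaRaw = raw, areaSmooth = movingAverage(raw, w), window = w)
  list(masks = ms, waveform = wf)
}
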