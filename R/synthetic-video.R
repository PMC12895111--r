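## Analytic glottal edge model.
##
## Lateral edge position of each fold, in mm from the midline:
##   x_{l,r}(y, t) = -/+ [ G/2 + A_{l,r} * sin(pi*y/L)^q * max(0, sin(2*pi*f0*t + phi(y))) ]
## with phi(y) linear from 0 at the posterior end (y = 0) to apPhaseLag at
## the anterior end (y = L). The half-wave rectification reproduces the
## collision closure of oscillating folds: during the closed half-cycle the
## medial gap returns to the rest gap (or to full closure when restGap = 0)
## and the edges never cross the midline.

.edgeModel <- function(kin, times, y) {
  L <- kin@foldLength
  env <- sin(pi * y / L)^kin@axisProfileExponent
  phi <- kin@apPhaseLag * y / L
  ## rows = axis positions, cols = time
  osc <- pmax(0, sin(outer(phi, 2 * pi * kin@f0 * times, `+`)))
  excL <- kin@restGap / 2 + kin@ampLeft * env * osc
  excR <- kin@restGap / 2 + kin@ampRight * env * osc
  left <- pmin(-excL, 0); right <- pmax(excR, 0)
  dim(left) <- dim(right) <- c(length(y), length(times))
  list(left = left, right = right)
}

#' Simulate a high-speed glottal video with analytic ground truth
#'
#' Renders a dark oscillating glottal slit (intensity 0.1) between bright
#' folds (intensity 0.8) under the half-wave-rectified sinusoidal edge
#' model of \code{\link{GlottalKinematics}}, at the acquisition settings of
#' \code{calib}. Edges are anti-aliased linearly over one pixel; optional
#' Gaussian intensity noise is clipped to [0, 1]. Alongside the stack the
#' exact analytic record is returned: per-frame area (row-wise quadrature
#' of the edge gap at pixel-row centres) and per-row edge positions.
#'
#' The image convention is origin top-left, rows = anterior--posterior axis
#' (posterior = row 1), columns = medial--lateral with the midline at the
#' central column. The folds span \code{round(foldLength / mmPerPixel)}
#' rows, padded by \code{marginRows} of closed (bright) rows at either end.
#'
#' @param kin a \code{\link{GlottalKinematics}}.
#' @param calib a \code{\link{Calibration}}; frame count is
#'   \code{round(fps * duration)}.
#' @param noiseSigma standard deviation of additive Gaussian intensity
#'   noise (on the [0, 1] scale).
#' @param seed integer seed for the noise field; required when
#'   \code{noiseSigma > 0}.
#' @param imageWidth image width in pixels; must accommodate the widest
#'   possible glottis.
#' @param marginRows bright rows added beyond each end of the folds.
#' @return A list with elements \code{stack} (a \code{\link{FrameStack}})
#'   and \code{truth} (a \code{\link{GroundTruth}}).
#' @examples
#' sim <- generateGlottalVideo(GlottalKinematics(duration = 0.004))
#' sim$stack
#' range(trueArea(sim$truth))
#' @export
generateGlottalVideo <- function(kin = GlottalKinematics(),
                                 calib = Calibration(), noiseSigma = 0,
                                 seed = NULL, imageWidth = 64,
                                 marginRows = 4) {
  stopifnot(is(kin, "GlottalKinematics"), is(calib, "Calibration"))
  validObject(kin); validObject(calib)
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0")
  if (noiseSigma > 0 && is.null(seed))
    stop("a 'seed' is required when noiseSigma > 0")

  s <- calib@mmPerPixel
  nGlottal <- max(1L, as.integer(round(kin@foldLength / s)))
  nT <- as.integer(round(calib@fps * kin@duration))
  if (nT < 1L) stop("duration too short: fewer than one frame at this fps")
  H <- nGlottal + 2L * marginRows
  W <- as.integer(imageWidth)

  halfWidthMm <- kin@restGap / 2 + max(kin@ampLeft, kin@ampRight)
  if (2 * (halfWidthMm / s + 1) > W - 2)
    stop(sprintf(paste0("image width: %d px cannot contain a glottis of ",
                        "half-width %.3f mm at %.3g mm/px"),
                 W, halfWidthMm, s))

  times <- (seq_len(nT) - 1L) / calib@fps
  y <- (seq_len(nGlottal) - 0.5) * s          # row-centre axis positions, mm
  edges <- .edgeModel(kin, times, y)

  midCol <- (W + 1) / 2                       # midline at the central column
  xc <- (seq_len(W) - midCol) * s             # column-centre lateral pos, mm
  xLo <- xc - s / 2
  xHi <- xc + s / 2

  foldI <- 0.8; glotI <- 0.1
  if (!is.null(seed)) set.seed(as.integer(seed))
  arr <- array(foldI, dim = c(H, W, nT))
  glottalRows <- as.integer(marginRows) + seq_len(nGlottal)
  for (t in seq_len(nT)) {
    l <- edges$left[, t]; r <- edges$right[, t]
    ## per-pixel coverage of the glottal interval [l, r], linear anti-alias
    ov <- pmin(outer(r, xHi, function(a, b) pmin(a, b)) -
               outer(l, xLo, function(a, b) pmax(a, b)), s)
    cov <- pmax(ov, 0) / s
    arr[glottalRows, , t] <- foldI * (1 - cov) + glotI * cov
  }
  if (noiseSigma > 0) {
    arr <- arr + stats::rnorm(length(arr), sd = noiseSigma)
    arr[arr < 0] <- 0; arr[arr > 1] <- 1
  }

  truth <- new("GroundTruth",
               trueF0 = kin@f0,
               trueArea = colSums(edges$right - edges$left) * s,
               trueLeftEdge = edges$left, trueRightEdge = edges$right,
               glottalRows = glottalRows, midlineCol = midCol,
               params = kin,
               seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  list(stack = FrameStack(arr, calib), truth = truth)
}
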