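#' Optical-flow settings
#'
#' @param windowSize odd side (px) of the local integration window of the
#'   gradient-based (Lucas--Kanade) estimator.
#' @param dilateRadius dilation radius (px) applied to the glottal mask to
#'   form the flow ROI, so that the moving fold edges are included.
#' @param presmooth Gaussian blur sigma (px) applied to both frames before
#'   differentiation; 0 disables.
#' @param minDet smallest normal-matrix determinant accepted; pixels below
#'   it (textureless regions) get zero flow.
#' @return A named list of settings.
#' @export
flowConfig <- function(windowSize = 15, dilateRadius = 5, presmooth = 1,
                       minDet = 1e-9) {
  windowSize <- as.integer(windowSize)
  if (windowSize < 3L || windowSize %% 2L == 0L)
    stop("'windowSize' must be odd and >= 3")
  list(windowSize = windowSize, dilateRadius = as.integer(dilateRadius),
       presmooth = presmooth, minDet = minDet)
}

.boxSum <- function(x, w) {
  EBImage::filter2(x, matrix(1, w, w), boundary = "replicate")
}

.dilateMask <- function(mask, radius) {
  if (radius < 1L) return(mask)
  EBImage::dilate(mask * 1, EBImage::makeBrush(2L * radius + 1L, "disc")) > 0
}

## Symmetric local gradient-based flow for one frame pair: spatial
## gradients from the frame average (so time reversal exactly negates the
## recovered flow), temporal gradient from the difference, 2x2 normal
## equations accumulated over a square window.
.flowPair <- function(I1, I2, cfg) {
  if (cfg$presmooth > 0) {
    I1 <- EBImage::gblur(I1, sigma = cfg$presmooth, boundary = "replicate")
    I2 <- EBImage::gblur(I2, sigma = cfg$presmooth, boundary = "replicate")
  }
  A <- (I1 + I2) / 2
  nr <- nrow(A); nc <- ncol(A)
  ## central differences with replicated borders; x = columns (lateral),
  ## y = rows (anterior--posterior)
  Ix <- (A[, c(2:nc, nc)] - A[, c(1, 1:(nc - 1))]) / 2
  Iy <- (A[c(2:nr, nr), ] - A[c(1, 1:(nr - 1)), ]) / 2
  It <- I2 - I1
  w <- cfg$windowSize
  Sxx <- .boxSum(Ix * Ix, w); Syy <- .boxSum(Iy * Iy, w)
  Sxy <- .boxSum(Ix * Iy, w)
  Sxt <- .boxSum(Ix * It, w); Syt <- .boxSum(Iy * It, w)
  det <- Sxx * Syy - Sxy * Sxy
  ok <- det > cfg$minDet
  u <- v <- matrix(0, nr, nc)
  u[ok] <- (Sxy[ok] * Syt[ok] - Syy[ok] * Sxt[ok]) / det[ok]
  v[ok] <- (Sxy[ok] * Sxt[ok] - Sxx[ok] * Syt[ok]) / det[ok]
  list(u = u, v = v)
}

#' Frame-to-frame optical flow over the glottal region
#'
#' Computes a dense displacement field (u = lateral/column component,
#' v = anterior--posterior/row component, px/frame) between each pair of
#' consecutive frames with a local gradient-based estimator, restricted to
#' the glottal ROI: the union of the pair's segmentation masks dilated by
#' \code{dilateRadius} pixels, so the bright/dark fold edges whose motion
#' carries the signal are inside the ROI. Flow outside the ROI is zero.
#'
#' @param stack a \code{\link{FrameStack}} with at least 2 frames.
#' @param masks the stack's \code{\link{GlottalMaskSeries}}.
#' @param cfg settings from \code{\link{flowConfig}}.
#' @return A list of T-1 flow fields, each a list with matrices \code{u},
#'   \code{v}, logical \code{roi} and \code{pair = c(t, t + 1)}.
#' @export
opticalFlow <- function(stack, masks, cfg = flowConfig()) {
  stopifnot(is(stack, "FrameStack"), is(masks, "GlottalMaskSeries"))
  nT <- nFrames(stack)
  if (nT < 2L) stop("optical flow needs at least 2 frames")
  out <- vector("list", nT - 1L)
  for (t in seq_len(nT - 1L)) {
    fl <- .flowPair(stack@frames[, , t], stack@frames[, , t + 1L], cfg)
    roi <- .dilateMask(masks@masks[, , t] | masks@masks[, , t + 1L],
                       cfg$dilateRadius)
    fl$u[!roi] <- 0; fl$v[!roi] <- 0
    out[[t]] <- list(u = fl$u, v = fl$v, roi = roi, pair = c(t, t + 1L))
  }
  out
}

#' Glottal optical-flow waveform (GOFW)
#'
#' Collapses each flow field to one signed number summarising lateral wall
#' divergence/convergence: the ROI mean of \code{sign(column - midline) *
#' u}. Both walls moving away from the midline (opening) give positive
#' values, both converging (closing) negative ones. Pairs with an empty
#' ROI contribute 0 and are flagged.
#'
#' @param fields flow fields from \code{\link{opticalFlow}}.
#' @param masks the \code{\link{GlottalMaskSeries}} used for the flow.
#' @return A data.frame with columns \code{time} (s, at the pair
#'   midpoint), \code{gofw} (px/frame) and \code{empty}.
#' @export
gofw <- function(fields, masks) {
  stopifnot(is(masks, "GlottalMaskSeries"))
  if (length(fields) != dim(masks@masks)[3] - 1L)
    stop("flow fields and masks are not aligned")
  midCol <- .midlineColumn(masks)
  nc <- dim(masks@masks)[2]
  lateralSign <- matrix(sign(seq_len(nc) - midCol), dim(masks@masks)[1], nc,
                        byrow = TRUE)
  vals <- numeric(length(fields)); empty <- logical(length(fields))
  for (i in seq_along(fields)) {
    roi <- fields[[i]]$roi
    if (!any(roi)) { empty[i] <- TRUE; next }
    vals[i] <- mean((lateralSign * fields[[i]]$u)[roi])
  }
  fpsHz <- fps(calibration(masks))
  data.frame(time = (seq_along(fields) - 0.5) / fpsHz, gofw = vals,
             empty = empty)
}

#' Left/right vocal-fold deflection trajectories
#'
#' Converts an edge track at a fixed anterior--posterior location into
#' per-fold deflection magnitudes (half-gap contributions, mm from the
#' midline) and computes the left/right symmetry index
#' \code{1 - mean(|dL - dR|) / mean(dL + dR)} and the left-vs-right phase
#' lag (quadrature demodulation at the dominant frequency, see
#' \code{\link{relativePhase}}). A track in which the glottis never
#' opens yields zero trajectories with both metrics undefined and the
#' pair flagged.
#'
#' @param edges an \code{\link{EdgeTrack}} (its own axis fraction is used).
#' @return A \code{\link{FoldTrajectoryPair}}.
#' @export
foldTrajectories <- function(edges) {
  stopifnot(is(edges, "EdgeTrack"))
  dl <- abs(edges@leftPos); dr <- abs(edges@rightPos)
  if (all(edges@closed) || mean(dl + dr) == 0) {
    return(new("FoldTrajectoryPair", deltaLeft = dl, deltaRight = dr,
               axisFraction = edges@axisFraction,
               symmetryIndex = NA_real_, phaseLag = NA_real_,
               allClosed = TRUE))
  }
  sym <- 1 - mean(abs(dl - dr)) / mean(dl + dr)
  fsHz <- fps(edges@calib)
  f0 <- estimateF0(dl + dr, fsHz)
  ph <- if (is.na(f0)) NA_real_ else relativePhase(dl, dr, fsHz, f0)
  new("FoldTrajectoryPair", deltaLeft = dl, deltaRight = dr,
      axisFraction = edges@axisFraction, symmetryIndex = sym,
      phaseLag = ph, allClosed = FALSE)
}
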