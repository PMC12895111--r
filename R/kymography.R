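## Shared helpers over the union of segmentation masks: the glottal row
## span (rows touched by the glottis in any frame) and the midline column
## (median column index of union-mask pixels).

.unionMask <- function(ms) apply(ms@masks, c(1, 2), any)

.glottalRowSpan <- function(ms) {
  rows <- which(apply(.unionMask(ms), 1, any))
  if (!length(rows)) stop("no glottal extent: the union segmentation mask is empty")
  rows
}

## Midline column: the fold contact line, found by extrapolating the
## per-frame mask centroid column to zero glottal area. As the glottis
## closes the slit collapses onto the contact line, and for edge motion
## proportional to a common gating waveform the centroid is linear in the
## pixel count, so the regression intercept locates the anatomical
## midline even when the folds oscillate with unequal amplitudes (a
## union-mask median would be dragged toward the larger-amplitude fold).
.midlineColumn <- function(ms) {
  cnt <- ms@pixelCounts
  open <- which(cnt > 0L)
  if (!length(open)) stop("no glottal extent: the union segmentation mask is empty")
  cents <- vapply(open, function(t)
    mean(which(ms@masks[, , t], arr.ind = TRUE)[, 2]), numeric(1))
  n <- cnt[open]
  if (length(open) < 3L || stats::sd(n) < 1e-9) return(stats::median(cents))
  unname(stats::coef(stats::lm(cents ~ n))[1L])
}

#' Extract a videokymogram at an anterior--posterior position
#'
#' Builds the space--time matrix whose column \code{t} is the
#' medial--lateral scanline of frame \code{t} at the image row
#' corresponding to \code{axisFraction} of the segmented glottal extent
#' (0 = posterior end, 1 = anterior end). Using the segmented extent,
#' rather than the full image, keeps the scanline placement robust to
#' framing. Columns are verbatim copies of the source scanlines.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param axisFraction anterior--posterior position in [0, 1].
#' @param masks a \code{\link{GlottalMaskSeries}} for the same stack;
#'   computed with default settings when omitted.
#' @return A \code{\link{Kymogram}}.
#' @export
extractKymogram <- function(stack, axisFraction = 0.5, masks = NULL) {
  stopifnot(is(stack, "FrameStack"))
  if (axisFraction < 0 || axisFraction > 1)
    stop("'axisFraction' must lie in [0, 1]")
  if (is.null(masks)) masks <- areaWaveform(stack)$masks
  rows <- .glottalRowSpan(masks)
  scanRow <- rows[1L + round(axisFraction * (length(rows) - 1L))]
  mat <- stack@frames[scanRow, , , drop = TRUE]
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)   # single frame
  new("Kymogram", matrix = mat, axisFraction = axisFraction,
      scanRow = as.integer(scanRow), calib = stack@calib)
}

#' Trace left/right glottal edges along a kymogram scanline
#'
#' For every frame, the left/right glottal edges start from the outermost
#' mask-true pixels on the kymogram's scanline and are refined to the
#' half-contrast crossing of the intensity profile (linear interpolation
#' between the dark glottal and bright fold levels around the mask
#' boundary), then reported in mm from the midline. The midline is
#' estimated from the most-closed open frames, where the slit collapses
#' onto the fold contact line. Frames with no glottal pixel on the
#' scanline are closed: both edges sit at 0 and the frame is flagged.
#' With \code{subPixel = FALSE} the edges fall back to the outer boundary
#' of the outermost glottal pixel.
#'
#' @param kymo a \code{\link{Kymogram}}.
#' @param masks the \code{\link{GlottalMaskSeries}} of the same stack.
#' @param subPixel refine edges to the half-contrast intensity crossing.
#' @return An \code{\link{EdgeTrack}}.
#' @export
traceEdges <- function(kymo, masks, subPixel = TRUE) {
  stopifnot(is(kymo, "Kymogram"), is(masks, "GlottalMaskSeries"))
  nT <- dim(masks@masks)[3]
  if (ncol(kymo@matrix) != nT)
    stop("kymogram and masks must come from the same stack")
  midCol <- .midlineColumn(masks)
  s <- masks@calib@mmPerPixel
  nc <- dim(masks@masks)[2]
  left <- right <- numeric(nT)
  closed <- logical(nT)
  for (t in seq_len(nT)) {
    on <- which(masks@masks[kymo@scanRow, , t])
    if (!length(on)) { closed[t] <- TRUE; next }
    cl <- on[1L] - 0.5; cr <- on[length(on)] + 0.5   # outer pixel boundaries
    if (subPixel) {
      prof <- kymo@matrix[, t]
      cl <- .refineEdge(prof, on[1L], -1L, nc, cl)
      cr <- .refineEdge(prof, on[length(on)], +1L, nc, cr)
    }
    left[t] <- min(0, (cl - midCol) * s)
    right[t] <- max(0, (cr - midCol) * s)
  }
  new("EdgeTrack", leftPos = left, rightPos = right, closed = closed,
      axisFraction = kymo@axisFraction, calib = masks@calib)
}

## Half-contrast sub-pixel edge localisation along a scanline intensity
## profile. From the outermost glottal pixel `cIn`, looks `dir` (+1 right,
## -1 left) for the crossing of the midpoint between the local dark
## (glottal) and bright (fold) levels, linearly interpolated between
## pixel centres. Falls back to `fallback` when no bracketing is found.
.refineEdge <- function(prof, cIn, dir, nc, fallback, reach = 4L) {
  inner <- cIn - dir * (0:(reach - 1L))
  inner <- inner[inner >= 1L & inner <= nc]
  outer <- cIn + dir * (1:reach)
  outer <- outer[outer >= 1L & outer <= nc]
  if (!length(outer)) return(fallback)
  dark <- min(prof[inner]); bright <- max(prof[outer])
  if (bright - dark < 1e-6) return(fallback)
  half <- (dark + bright) / 2
  path <- c(cIn, outer)
  for (i in seq_len(length(path) - 1L)) {
    a <- path[i]; b <- path[i + 1L]
    if ((prof[a] - half) * (prof[b] - half) <= 0 && prof[b] != prof[a])
      return(a + dir * (half - prof[a]) / (prof[b] - prof[a]))
  }
  fallback
}

#' Kymograms and edge tracks at several anterior--posterior positions
#'
#' Convenience wrapper extracting one kymogram and its edge track per
#' axis fraction (posterior, middle, anterior by default), reusing one
#' shared segmentation.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param fractions sorted anterior--posterior fractions in [0, 1].
#' @param masks optional precomputed \code{\link{GlottalMaskSeries}}.
#' @param cfg segmentation settings used when \code{masks} is missing.
#' @return A named list (one element per fraction), each a list with
#'   \code{kymogram} and \code{edges}.
#' @export
multiPositionKymograms <- function(stack, fractions = c(0.25, 0.5, 0.75),
                                   masks = NULL, cfg = thresholdConfig()) {
  if (is.unsorted(fractions)) stop("'fractions' must be sorted")
  if (any(fractions < 0 | fractions > 1)) stop("'fractions' must lie in [0, 1]")
  if (is.null(masks)) masks <- areaWaveform(stack, cfg)$masks
  out <- lapply(fractions, function(f) {
    kg <- extractKymogram(stack, f, masks)
    list(kymogram = kg, edges = traceEdges(kg, masks))
  })
  names(out) <- sprintf("p%.2f", fractions)
  out
}

#' Estimate the anterior--posterior phase lag from multi-position tracks
#'
#' Measures the relative oscillation phase of the glottal gap at several
#' anterior--posterior scanline positions and regresses phase on axis
#' fraction; the slope is the total posterior-to-anterior phase lag in
#' radians. With a linear phase gradient along the folds, tracks at
#' fractions a and b differ in phase by (b - a) times the total lag, so
#' the regression recovers the full lag from interior scanlines.
#'
#' @param tracks list of \code{\link{EdgeTrack}}s at distinct axis
#'   fractions (e.g. from \code{\link{multiPositionKymograms}}).
#' @return Estimated total anterior--posterior phase lag (radians).
#' @export
apPhaseLagEstimate <- function(tracks) {
  if (is.list(tracks) && !is(tracks, "EdgeTrack") &&
      all(vapply(tracks, function(x) is.list(x) && "edges" %in% names(x), logical(1))))
    tracks <- lapply(tracks, `[[`, "edges")
  if (length(tracks) < 2L) stop("need edge tracks at >= 2 axis fractions")
  fr <- vapply(tracks, axisFraction, numeric(1))
  fsHz <- fps(calibration(tracks[[1L]]))
  gaps <- lapply(tracks, function(tr) rightPos(tr) - leftPos(tr))
  f0 <- estimateF0(gaps[[which.min(abs(fr - stats::median(fr)))]], fsHz)
  if (is.na(f0)) stop("no oscillation detected in the edge tracks")
  ph <- vapply(seq_along(gaps), function(i)
    relativePhase(gaps[[i]], gaps[[1L]], fsHz, f0), numeric(1))
  unname(stats::coef(stats::lm(ph ~ fr))[2L])
}
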