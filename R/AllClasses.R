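#' @import methods
NULL

.chkLen1Pos <- function(x, name, strict = TRUE) {
  if (length(x) != 1L || !is.finite(x)) return(sprintf("'%s' must be a single finite number", name))
  if (strict && x <= 0) return(sprintf("'%s' must be > 0", name))
  if (!strict && x < 0) return(sprintf("'%s' must be >= 0", name))
  NULL
}

#' Acquisition calibration
#'
#' Frame rate and spatial scale of a high-speed recording. The defaults
#' match a 20,000 frames-per-second camera with a 0.01 mm/pixel optical
#' scale, typical of transilluminated vocal-fold replica imaging.
#'
#' @slot fps frames per second (1/s).
#' @slot mmPerPixel spatial scale (mm per pixel, square pixels).
#' @export
setClass("Calibration", representation(fps = "numeric", mmPerPixel = "numeric"))

setValidity("Calibration", function(object) {
  msg <- c(.chkLen1Pos(object@fps, "fps"),
           .chkLen1Pos(object@mmPerPixel, "mmPerPixel"))
  if (length(msg)) msg else TRUE
})

#' @param fps frames per second.
#' @param mmPerPixel spatial scale in mm per pixel.
#' @rdname Calibration-class
#' @export
Calibration <- function(fps = 20000, mmPerPixel = 0.01) {
  new("Calibration", fps = as.numeric(fps), mmPerPixel = as.numeric(mmPerPixel))
}

#' Glottal oscillation kinematics
#'
#' Parameters of the analytic left/right edge model used by
#' \code{\link{generateGlottalVideo}}. Each fold edge oscillates as a
#' half-wave-rectified sinusoid (folds collide at the midline during the
#' closed phase) with a \code{sin(pi*y/L)^q} anterior--posterior amplitude
#' envelope and a linear anterior--posterior phase gradient.
#'
#' @slot f0 oscillation frequency (Hz).
#' @slot restGap medial gap between the folds at rest (mm).
#' @slot ampLeft,ampRight peak lateral excursion of each fold edge (mm).
#' @slot axisProfileExponent dimensionless shaping power of the
#'   anterior--posterior amplitude envelope.
#' @slot apPhaseLag phase difference between the posterior and anterior
#'   ends of the folds (radians); positive values make the anterior end lag.
#' @slot foldLength anterior--posterior extent of the glottis (mm).
#' @slot duration record length (s).
#' @export
setClass("GlottalKinematics",
  representation(f0 = "numeric", restGap = "numeric",
                 ampLeft = "numeric", ampRight = "numeric",
                 axisProfileExponent = "numeric", apPhaseLag = "numeric",
                 foldLength = "numeric", duration = "numeric"))

setValidity("GlottalKinematics", function(object) {
  msg <- c(.chkLen1Pos(object@f0, "f0"),
           .chkLen1Pos(object@restGap, "restGap", strict = FALSE),
           .chkLen1Pos(object@ampLeft, "ampLeft", strict = FALSE),
           .chkLen1Pos(object@ampRight, "ampRight", strict = FALSE),
           .chkLen1Pos(object@axisProfileExponent, "axisProfileExponent", strict = FALSE),
           .chkLen1Pos(object@foldLength, "foldLength"),
           .chkLen1Pos(object@duration, "duration"))
  if (length(object@apPhaseLag) != 1L || !is.finite(object@apPhaseLag))
    msg <- c(msg, "'apPhaseLag' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @param f0,restGap,ampLeft,ampRight,axisProfileExponent,apPhaseLag,foldLength,duration
#'   see the corresponding slots.
#' @rdname GlottalKinematics-class
#' @export
GlottalKinematics <- function(f0 = 250, restGap = 0.3, ampLeft = 0.1,
                              ampRight = 0.1, axisProfileExponent = 1,
                              apPhaseLag = 0, foldLength = 1.2,
                              duration = 0.02) {
  new("GlottalKinematics", f0 = as.numeric(f0), restGap = as.numeric(restGap),
      ampLeft = as.numeric(ampLeft), ampRight = as.numeric(ampRight),
      axisProfileExponent = as.numeric(axisProfileExponent),
      apPhaseLag = as.numeric(apPhaseLag), foldLength = as.numeric(foldLength),
      duration = as.numeric(duration))
}

#' Ordered grayscale frame stack
#'
#' Container for a high-speed grayscale image sequence together with its
#' acquisition calibration. Frames are stored as a \code{height x width x T}
#' array with intensities in [0, 1]. The image convention is origin
#' top-left, rows along the anterior--posterior axis (posterior = row 1),
#' columns along the medial--lateral axis with the anatomical midline near
#' the central column.
#'
#' @slot frames numeric array, \code{dim = c(height, width, T)}, values in [0, 1].
#' @slot calib a \code{\link{Calibration}}.
#' @slot axisOrientation which image axis runs anterior--posterior
#'   (currently always \code{"row"}).
#' @export
setClass("FrameStack",
  representation(frames = "array", calib = "Calibration",
                 axisOrientation = "character"))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 3L || d[3] < 1L)
    msg <- c(msg, "'frames' must be a height x width x T array with T >= 1")
  rng <- range(object@frames)
  if (!all(is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "frame intensities must be finite and within [0, 1]")
  if (!identical(object@axisOrientation, "row"))
    msg <- c(msg, "'axisOrientation' must be \"row\"")
  if (length(msg)) msg else TRUE
})

#' @param frames height x width x T numeric array in [0, 1].
#' @param calib a \code{\link{Calibration}}.
#' @param axisOrientation anterior--posterior image axis.
#' @rdname FrameStack-class
#' @export
FrameStack <- function(frames, calib = Calibration(), axisOrientation = "row") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  new("FrameStack", frames = frames, calib = calib,
      axisOrientation = axisOrientation)
}

#' Analytic ground truth of a simulated recording
#'
#' The exact kinematic record emitted alongside a synthetic glottal video:
#' true fundamental frequency, analytic glottal area per frame (row-wise
#' quadrature of the edge gap), and per-row left/right edge positions.
#' Every analysis stage can be scored against it.
#'
#' @slot trueF0 oscillation frequency used by the simulator (Hz).
#' @slot trueArea analytic glottal area per frame (mm^2).
#' @slot trueLeftEdge,trueRightEdge matrices (glottal rows x T) of lateral
#'   edge positions in mm from the midline (left <= 0 <= right).
#' @slot glottalRows image row indices covered by the folds.
#' @slot midlineCol image column of the anatomical midline.
#' @slot params the \code{\link{GlottalKinematics}} used.
#' @slot seed random seed used for the noise field (NA when noise-free).
#' @export
setClass("GroundTruth",
  representation(trueF0 = "numeric", trueArea = "numeric",
                 trueLeftEdge = "matrix", trueRightEdge = "matrix",
                 glottalRows = "integer", midlineCol = "numeric",
                 params = "GlottalKinematics", seed = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (ncol(object@trueLeftEdge) != length(object@trueArea) ||
      !identical(dim(object@trueLeftEdge), dim(object@trueRightEdge)))
    msg <- c(msg, "edge matrices must be (glottal rows) x T, matching 'trueArea'")
  if (any(object@trueRightEdge - object@trueLeftEdge < -1e-12))
    msg <- c(msg, "instantaneous gap must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-frame glottal segmentation masks
#'
#' @slot masks logical array (height x width x T); \code{TRUE} marks a
#'   glottal pixel.
#' @slot pixelCounts integer vector of per-frame mask pixel counts.
#' @slot calib a \code{\link{Calibration}}.
#' @export
setClass("GlottalMaskSeries",
  representation(masks = "array", pixelCounts = "integer",
                 calib = "Calibration"))

setValidity("GlottalMaskSeries", function(object) {
  msg <- character()
  d <- dim(object@masks)
  if (length(d) != 3L) msg <- c(msg, "'masks' must be a 3-d logical array")
  if (!is.logical(object@masks)) msg <- c(msg, "'masks' must be logical")
  else if (length(object@pixelCounts) != d[3] ||
           !identical(object@pixelCounts,
                      as.integer(apply(object@masks, 3, sum))))
    msg <- c(msg, "'pixelCounts' must equal the per-frame number of TRUE pixels")
  if (length(msg)) msg else TRUE
})

#' Glottal area waveform
#'
#' Raw and moving-average-smoothed glottal area (mm^2) per frame. The
#' smoothed series uses a centred window with edge truncation, so its
#' maximum can never exceed the raw maximum.
#'
#' @slot time seconds at each frame.
#' @slot areaRaw,areaSmooth glottal area per frame (mm^2).
#' @slot window smoothing window length (odd number of frames).
#' @export
setClass("AreaWaveform",
  representation(time = "numeric", areaRaw = "numeric",
                 areaSmooth = "numeric", window = "integer"))

setValidity("AreaWaveform", function(object) {
  msg <- character()
  n <- length(object@areaRaw)
  if (length(object@areaSmooth) != n || length(object@time) != n)
    msg <- c(msg, "'time', 'areaRaw' and 'areaSmooth' must have equal length")
  if (any(object@areaRaw < 0) || any(object@areaSmooth < 0))
    msg <- c(msg, "areas must be non-negative")
  if (n && max(object@areaSmooth) > max(object@areaRaw) + 1e-12)
    msg <- c(msg, "max(areaSmooth) must not exceed max(areaRaw)")
  if (object@window %% 2L == 0L) msg <- c(msg, "'window' must be odd")
  if (length(msg)) msg else TRUE
})

#' Videokymogram
#'
#' Space--time intensity matrix built by stacking one medial--lateral
#' scanline of every frame: rows are scanline pixels, columns are time.
#'
#' @slot matrix scanline-pixels x T intensity matrix in [0, 1].
#' @slot axisFraction anterior--posterior position in [0, 1] of the
#'   scanline, measured along the segmented glottal extent.
#' @slot scanRow image row the scanline was taken from.
#' @slot calib a \code{\link{Calibration}}.
#' @export
setClass("Kymogram",
  representation(matrix = "matrix", axisFraction = "numeric",
                 scanRow = "integer", calib = "Calibration"))

setValidity("Kymogram", function(object) {
  msg <- character()
  if (object@axisFraction < 0 || object@axisFraction > 1)
    msg <- c(msg, "'axisFraction' must lie in [0, 1]")
  rng <- range(object@matrix)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "kymogram intensities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Traced glottal edge positions along one scanline
#'
#' Left/right glottal edge lateral positions per frame, in mm from the
#' midline (left <= 0 <= right). Frames where the glottis is closed on the
#' scanline carry both edges at 0 and are flagged.
#'
#' @slot leftPos,rightPos lateral edge position per frame (mm from midline).
#' @slot closed logical per frame; \code{TRUE} when no glottal pixel lies
#'   on the scanline.
#' @slot axisFraction anterior--posterior position of the scanline.
#' @slot calib a \code{\link{Calibration}}.
#' @export
setClass("EdgeTrack",
  representation(leftPos = "numeric", rightPos = "numeric",
                 closed = "logical", axisFraction = "numeric",
                 calib = "Calibration"))

setValidity("EdgeTrack", function(object) {
  msg <- character()
  n <- length(object@leftPos)
  if (length(object@rightPos) != n || length(object@closed) != n)
    msg <- c(msg, "'leftPos', 'rightPos' and 'closed' must have equal length")
  if (any(object@rightPos - object@leftPos < -1e-12))
    msg <- c(msg, "rightPos - leftPos must be non-negative")
  if (any(object@leftPos > 1e-12) || any(object@rightPos < -1e-12))
    msg <- c(msg, "leftPos must be <= 0 and rightPos >= 0")
  if (length(msg)) msg else TRUE
})

#' Left/right vocal-fold deflection trajectories
#'
#' Per-frame deflection magnitudes of each fold at a fixed
#' anterior--posterior location, with left/right symmetry and phase
#' metrics. The symmetry index is
#' \code{1 - mean(|dL - dR|) / mean(dL + dR)} (1 = perfectly symmetric);
#' the phase lag is the left-vs-right cross-correlation lag expressed in
#' radians at the dominant oscillation frequency.
#'
#' @slot deltaLeft,deltaRight deflection magnitude per frame (mm).
#' @slot axisFraction anterior--posterior location of the analysis line.
#' @slot symmetryIndex left/right amplitude symmetry in (-Inf, 1]; NA when
#'   the glottis never opens.
#' @slot phaseLag left-vs-right phase difference (radians); NA when
#'   undefined.
#' @slot allClosed TRUE when every frame was closed (metrics undefined).
#' @export
setClass("FoldTrajectoryPair",
  representation(deltaLeft = "numeric", deltaRight = "numeric",
                 axisFraction = "numeric", symmetryIndex = "numeric",
                 phaseLag = "numeric", allClosed = "logical"))

setValidity("FoldTrajectoryPair", function(object) {
  msg <- character()
  if (length(object@deltaLeft) != length(object@deltaRight))
    msg <- c(msg, "trajectories must have equal length")
  if (any(object@deltaLeft < 0) || any(object@deltaRight < 0))
    msg <- c(msg, "deflections must be non-negative")
  if (!is.na(object@symmetryIndex) && object@symmetryIndex > 1 + 1e-12)
    msg <- c(msg, "symmetryIndex must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Sampled 1-d signal in physical units
#'
#' A pressure (kPa) or acoustic (Pa) time series with its sampling rate and
#' free-form metadata (synthetic traces carry their ground-truth onset
#' there).
#'
#' @slot samples signal values in physical units.
#' @slot fs sampling rate (1/s).
#' @slot kind \code{"pressure"} or \code{"acoustic"}.
#' @slot metadata named list of provenance/ground-truth entries.
#' @export
setClass("SignalTrace",
  representation(samples = "numeric", fs = "numeric", kind = "character",
                 metadata = "list"))

setValidity("SignalTrace", function(object) {
  msg <- c(.chkLen1Pos(object@fs, "fs"))
  if (!object@kind %in% c("pressure", "acoustic"))
    msg <- c(msg, "'kind' must be \"pressure\" or \"acoustic\"")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' @param samples,fs,kind,metadata see the corresponding slots.
#' @rdname SignalTrace-class
#' @export
SignalTrace <- function(samples, fs, kind = c("pressure", "acoustic"),
                        metadata = list()) {
  new("SignalTrace", samples = as.numeric(samples), fs = as.numeric(fs),
      kind = match.arg(kind), metadata = metadata)
}

#' Scalar phonatory descriptors
#'
#' @slot f0 fundamental frequency (Hz); NA when no oscillation detected.
#' @slot maxArea maximum smoothed glottal area (mm^2).
#' @slot onsetPressure phonation onset pressure (kPa); NA when absent.
#' @slot spl sound pressure level (dB re 20 uPa); NA when no acoustic trace.
#' @export
setClass("PhonatoryMetrics",
  representation(f0 = "numeric", maxArea = "numeric",
                 onsetPressure = "numeric", spl = "numeric"))

setValidity("PhonatoryMetrics", function(object) {
  msg <- character()
  if (!is.na(object@f0) && object@f0 <= 0)
    msg <- c(msg, "'f0' must be > 0 when present")
  if (!is.na(object@maxArea) && object@maxArea < 0)
    msg <- c(msg, "'maxArea' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Live/dead cell counts
#'
#' @slot nLive,nDead non-negative blob counts per channel.
#' @slot viability percent live of total; NA (flagged) when no cells.
#' @export
setClass("CellCounts",
  representation(nLive = "integer", nDead = "integer", viability = "numeric"))

setValidity("CellCounts", function(object) {
  msg <- character()
  if (object@nLive < 0L || object@nDead < 0L)
    msg <- c(msg, "counts must be non-negative")
  tot <- object@nLive + object@nDead
  if (tot > 0L) {
    if (!isTRUE(all.equal(object@viability, 100 * object@nLive / tot)))
      msg <- c(msg, "viability must equal 100 * nLive / (nLive + nDead)")
  } else if (!is.na(object@viability))
    msg <- c(msg, "viability must be NA when no cells are present")
  if (length(msg)) msg else TRUE
})

#' @param nLive,nDead blob counts.
#' @rdname CellCounts-class
#' @export
CellCounts <- function(nLive, nDead) {
  nLive <- as.integer(nLive); nDead <- as.integer(nDead)
  tot <- nLive + nDead
  new("CellCounts", nLive = nLive, nDead = nDead,
      viability = if (tot > 0L) 100 * nLive / tot else NA_real_)
}

#' Dye coverage over time
#'
#' @slot timepoints minutes of oscillatory conditioning per image.
#' @slot coverage fraction of the construct ROI stained, in [0, 1].
#' @export
setClass("CoverageSeries",
  representation(timepoints = "numeric", coverage = "numeric"))

setValidity("CoverageSeries", function(object) {
  msg <- character()
  if (length(object@timepoints) != length(object@coverage))
    msg <- c(msg, "'timepoints' and 'coverage' must have equal length")
  if (any(object@coverage < -1e-12) || any(object@coverage > 1 + 1e-12))
    msg <- c(msg, "coverage fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
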