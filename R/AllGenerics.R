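#' Accessors for phonovision classes
#'
#' Small accessor generics exposing slot data without direct slot access.
#'
#' @param object a phonovision object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("mmPerPixel", function(object) standardGeneric("mmPerPixel"))
#' @rdname accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("masks", function(object) standardGeneric("masks"))
#' @rdname accessors
#' @export
setGeneric("pixelCounts", function(object) standardGeneric("pixelCounts"))
#' @rdname accessors
#' @export
setGeneric("areaRaw", function(object) standardGeneric("areaRaw"))
#' @rdname accessors
#' @export
setGeneric("areaSmooth", function(object) standardGeneric("areaSmooth"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("leftPos", function(object) standardGeneric("leftPos"))
#' @rdname accessors
#' @export
setGeneric("rightPos", function(object) standardGeneric("rightPos"))
#' @rdname accessors
#' @export
setGeneric("isClosed", function(object) standardGeneric("isClosed"))
#' @rdname accessors
#' @export
setGeneric("deltaLeft", function(object) standardGeneric("deltaLeft"))
#' @rdname accessors
#' @export
setGeneric("deltaRight", function(object) standardGeneric("deltaRight"))
#' @rdname accessors
#' @export
setGeneric("symmetryIndex", function(object) standardGeneric("symmetryIndex"))
#' @rdname accessors
#' @export
setGeneric("phaseLag", function(object) standardGeneric("phaseLag"))
#' @rdname accessors
#' @export
setGeneric("axisFraction", function(object) standardGeneric("axisFraction"))
#' @rdname accessors
#' @export
setGeneric("trueArea", function(object) standardGeneric("trueArea"))
#' @rdname accessors
#' @export
setGeneric("trueF0", function(object) standardGeneric("trueF0"))
#' @rdname accessors
#' @export
setGeneric("trueLeftEdge", function(object) standardGeneric("trueLeftEdge"))
#' @rdname accessors
#' @export
setGeneric("trueRightEdge", function(object) standardGeneric("trueRightEdge"))
#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))
#' @rdname accessors
#' @export
setGeneric("viability", function(object) standardGeneric("viability"))

#' Physical pixel area from a spatial calibration
#'
#' Converts a linear spatial scale into the physical area covered by one
#' pixel: a scale of 0.01 mm/pixel yields 0.0001 mm^2 per pixel.
#'
#' @param calib a \code{\link{Calibration}} or a numeric mm-per-pixel scale.
#' @return Area of one pixel in mm^2.
#' @examples
#' pixelAreaScale(0.01)                 # 1e-4 mm^2
#' pixelAreaScale(Calibration())        # default calibration
#' @export
setGeneric("pixelAreaScale", function(calib) standardGeneric("pixelAreaScale"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
setMethod("fps", "Calibration", function(object) object@fps)
#' @rdname accessors
setMethod("mmPerPixel", "Calibration", function(object) object@mmPerPixel)
#' @rdname accessors
setMethod("fps", "FrameStack", function(object) object@calib@fps)
#' @rdname accessors
setMethod("mmPerPixel", "FrameStack", function(object) object@calib@mmPerPixel)
#' @rdname accessors
setMethod("calibration", "FrameStack", function(object) object@calib)
#' @rdname accessors
setMethod("frames", "FrameStack", function(object) object@frames)
#' @rdname accessors
setMethod("nFrames", "FrameStack", function(object) dim(object@frames)[3])
#' @rdname accessors
setMethod("masks", "GlottalMaskSeries", function(object) object@masks)
#' @rdname accessors
setMethod("pixelCounts", "GlottalMaskSeries", function(object) object@pixelCounts)
#' @rdname accessors
setMethod("calibration", "GlottalMaskSeries", function(object) object@calib)
#' @rdname accessors
setMethod("nFrames", "GlottalMaskSeries", function(object) dim(object@masks)[3])
#' @rdname accessors
setMethod("areaRaw", "AreaWaveform", function(object) object@areaRaw)
#' @rdname accessors
setMethod("areaSmooth", "AreaWaveform", function(object) object@areaSmooth)
#' @rdname accessors
setMethod("frameTimes", "AreaWaveform", function(object) object@time)
#' @rdname accessors
setMethod("leftPos", "EdgeTrack", function(object) object@leftPos)
#' @rdname accessors
setMethod("rightPos", "EdgeTrack", function(object) object@rightPos)
#' @rdname accessors
setMethod("isClosed", "EdgeTrack", function(object) object@closed)
#' @rdname accessors
setMethod("axisFraction", "EdgeTrack", function(object) object@axisFraction)
#' @rdname accessors
setMethod("calibration", "EdgeTrack", function(object) object@calib)
#' @rdname accessors
setMethod("axisFraction", "Kymogram", function(object) object@axisFraction)
#' @rdname accessors
setMethod("deltaLeft", "FoldTrajectoryPair", function(object) object@deltaLeft)
#' @rdname accessors
setMethod("deltaRight", "FoldTrajectoryPair", function(object) object@deltaRight)
#' @rdname accessors
setMethod("symmetryIndex", "FoldTrajectoryPair", function(object) object@symmetryIndex)
#' @rdname accessors
setMethod("phaseLag", "FoldTrajectoryPair", function(object) object@phaseLag)
#' @rdname accessors
setMethod("axisFraction", "FoldTrajectoryPair", function(object) object@axisFraction)
#' @rdname accessors
setMethod("trueArea", "GroundTruth", function(object) object@trueArea)
#' @rdname accessors
setMethod("trueF0", "GroundTruth", function(object) object@trueF0)
#' @rdname accessors
setMethod("trueLeftEdge", "GroundTruth", function(object) object@trueLeftEdge)
#' @rdname accessors
setMethod("trueRightEdge", "GroundTruth", function(object) object@trueRightEdge)
#' @rdname accessors
setMethod("samples", "SignalTrace", function(object) object@samples)
#' @rdname accessors
setMethod("fps", "SignalTrace", function(object) object@fs)
#' @rdname accessors
setMethod("traceMetadata", "SignalTrace", function(object) object@metadata)
#' @rdname accessors
setMethod("viability", "CellCounts", function(object) object@viability)

## ---- show methods ---------------------------------------------------------

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %g fps, %g mm/pixel (%g mm^2/pixel)\n",
              object@fps, object@mmPerPixel, object@mmPerPixel^2))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px (%.4g s at %g fps, %g mm/px)\n",
              d[3], d[1], d[2], d[3] / object@calib@fps, object@calib@fps,
              object@calib@mmPerPixel))
})

setMethod("show", "GlottalKinematics", function(object) {
  cat(sprintf(paste0("GlottalKinematics: f0 = %g Hz, rest gap = %g mm, ",
                     "amp L/R = %g/%g mm,\n  envelope exponent = %g, ",
                     "AP phase lag = %g rad, fold length = %g mm, %g s\n"),
              object@f0, object@restGap, object@ampLeft, object@ampRight,
              object@axisProfileExponent, object@apPhaseLag,
              object@foldLength, object@duration))
})

setMethod("show", "AreaWaveform", function(object) {
  cat(sprintf("AreaWaveform: %d frames, area %.4g-%.4g mm^2 (smoothed, window %d)\n",
              length(object@areaRaw), min(object@areaSmooth),
              max(object@areaSmooth), object@window))
})

setMethod("show", "GlottalMaskSeries", function(object) {
  d <- dim(object@masks)
  cat(sprintf("GlottalMaskSeries: %d frames of %d x %d px, %d-%d glottal px/frame\n",
              d[3], d[1], d[2], min(object@pixelCounts), max(object@pixelCounts)))
})

setMethod("show", "Kymogram", function(object) {
  cat(sprintf("Kymogram: scanline of %d px over %d frames (axis fraction %.2f, image row %d)\n",
              nrow(object@matrix), ncol(object@matrix), object@axisFraction,
              object@scanRow))
})

setMethod("show", "EdgeTrack", function(object) {
  cat(sprintf("EdgeTrack at axis fraction %.2f: %d frames, %d closed; max gap %.4g mm\n",
              object@axisFraction, length(object@leftPos), sum(object@closed),
              max(object@rightPos - object@leftPos)))
})

setMethod("show", "FoldTrajectoryPair", function(object) {
  cat(sprintf(paste0("FoldTrajectoryPair at axis fraction %.2f: %d frames\n",
                     "  symmetry index = %.3f, phase lag = %.3f rad%s\n"),
              object@axisFraction, length(object@deltaLeft),
              object@symmetryIndex, object@phaseLag,
              if (object@allClosed) " [all frames closed]" else ""))
})

setMethod("show", "SignalTrace", function(object) {
  cat(sprintf("SignalTrace (%s): %d samples at %g Hz (%.3g s)\n",
              object@kind, length(object@samples), object@fs,
              length(object@samples) / object@fs))
})

setMethod("show", "PhonatoryMetrics", function(object) {
  cat("PhonatoryMetrics:\n")
  cat(sprintf("  f0             : %s\n",
              if (is.na(object@f0)) "absent (no oscillation)" else sprintf("%.4g Hz", object@f0)))
  cat(sprintf("  max area       : %.4g mm^2\n", object@maxArea))
  cat(sprintf("  onset pressure : %s\n",
              if (is.na(object@onsetPressure)) "absent" else sprintf("%.4g kPa", object@onsetPressure)))
  cat(sprintf("  SPL            : %s\n",
              if (is.na(object@spl)) "absent" else sprintf("%.4g dB", object@spl)))
})

setMethod("show", "CellCounts", function(object) {
  cat(sprintf("CellCounts: %d live, %d dead; viability %s\n",
              object@nLive, object@nDead,
              if (is.na(object@viability)) "undefined (no cells)"
              else sprintf("%.1f%%", object@viability)))
})

setMethod("show", "CoverageSeries", function(object) {
  cat("CoverageSeries:\n")
  for (i in seq_along(object@timepoints))
    cat(sprintf("  %6g min : %5.1f%%\n", object@timepoints[i],
                100 * object@coverage[i]))
})
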