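#' Stained coverage fraction of a construct ROI
#'
#' Fraction of region-of-interest pixels whose normalised intensity
#' reaches the stain threshold, the quantity used to follow dye diffusion
#' through a hydrogel construct over oscillatory conditioning. Pixels
#' outside the ROI never influence the result.
#'
#' @param image grayscale matrix in [0, 1].
#' @param roiMask logical matrix of the same shape marking the construct.
#' @param stainThreshold intensity at or above which a pixel counts as
#'   stained.
#' @return Stained fraction in [0, 1].
#' @export
coverageFraction <- function(image, roiMask, stainThreshold = 0.5) {
  if (!identical(dim(image), dim(roiMask)))
    stop("'image' and 'roiMask' must have identical dimensions")
  if (!any(roiMask)) stop("empty ROI")
  mean(image[roiMask] >= stainThreshold)
}

#' Coverage of a dye-diffusion image series
#'
#' Applies \code{\link{coverageFraction}} to each image of a time-lapse
#' series sharing one ROI.
#'
#' @param images list of grayscale matrices.
#' @param roiMask logical ROI mask shared by all images.
#' @param timepoints minutes per image.
#' @param stainThreshold see \code{\link{coverageFraction}}.
#' @return A \code{\link{CoverageSeries}}.
#' @export
coverageSeries <- function(images, roiMask,
                           timepoints = seq_along(images) - 1,
                           stainThreshold = 0.5) {
  cov <- vapply(images, coverageFraction, numeric(1), roiMask = roiMask,
                stainThreshold = stainThreshold)
  new("CoverageSeries", timepoints = as.numeric(timepoints), coverage = cov)
}

#' Count live and dead cells in a two-channel fluorescence image
#'
#' Per-channel blob counting: each channel is Gaussian-smoothed and local
#' intensity maxima above a threshold are counted as cells; viability is
#' the live percentage of the total. With blobs separated by at least four
#' radii each cell carries exactly one maximum, so counting is exact.
#' Blank channels give zero counts and an undefined (NA) viability.
#'
#' @param live,dead grayscale matrices in [0, 1] of identical shape
#'   (live = channel 1, dead = channel 2).
#' @param smoothSigma Gaussian smoothing sigma (px).
#' @param intensityThreshold smoothed intensity a maximum must exceed.
#' @return A \code{\link{CellCounts}}.
#' @export
countLiveDead <- function(live, dead, smoothSigma = 2,
                          intensityThreshold = 0.2) {
  if (!identical(dim(live), dim(dead)))
    stop("channel shapes differ")
  countChannel <- function(ch) {
    sm <- if (smoothSigma > 0)
      EBImage::gblur(ch, sigma = smoothSigma, boundary = "replicate") else ch
    mx <- EBImage::dilate(sm, EBImage::makeBrush(5, "box"))
    sum(sm >= mx & sm > intensityThreshold)
  }
  CellCounts(countChannel(live), countChannel(dead))
}

#' Blank-normalise absorbance readings
#'
#' Subtracts the mean blank (cell-free construct) absorbance from each
#' sample reading, the standard background correction for colorimetric
#' metabolic assays read at a fixed wavelength. Values that fall below the
#' blank mean are clipped to 0 and flagged. Adding a constant to all
#' samples and blanks leaves the corrected values unchanged.
#'
#' @param odSamples numeric sample absorbances.
#' @param odBlanks numeric blank absorbances (at least one).
#' @return Corrected absorbances with a logical attribute \code{clipped}
#'   marking readings that fell below the blank mean.
#' @examples
#' cck8Normalize(0.61, c(0.10, 0.12))   # 0.50
#' @export
cck8Normalize <- function(odSamples, odBlanks) {
  if (!length(odSamples) || !length(odBlanks))
    stop("'odSamples' and 'odBlanks' must be non-empty")
  corrected <- odSamples - mean(odBlanks)
  clipped <- corrected < 0
  corrected[clipped] <- 0
  structure(corrected, clipped = clipped)
}
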