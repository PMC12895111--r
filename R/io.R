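#' Write a frame stack to disk
#'
#' Writes either a multi-page 16-bit TIFF (\code{<path>.tif}) or a
#' directory of numbered 8-bit PNG frames, plus a YAML sidecar
#' (\code{<path>.yml}) holding the calibration and axis orientation so the
#' stack can be read back losslessly up to the format's quantisation.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param path output path without extension (TIFF) or a directory (PNG).
#' @param format \code{"tiff"} or \code{"png"}.
#' @return Invisibly, the sidecar path.
#' @export
writeFrameStack <- function(stack, path, format = c("tiff", "png")) {
  stopifnot(is(stack, "FrameStack"))
  format <- match.arg(format)
  meta <- list(fps = fps(stack), mm_per_pixel = mmPerPixel(stack),
               axis_orientation = stack@axisOrientation,
               n_frames = nFrames(stack), format = format)
  if (format == "tiff") {
    pages <- lapply(seq_len(nFrames(stack)), function(t) stack@frames[, , t])
    tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 16L)
    side <- paste0(path, ".yml")
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_len(nFrames(stack)))
      png::writePNG(stack@frames[, , t],
                    file.path(path, sprintf("frame_%05d.png", t)))
    side <- file.path(path, "stack.yml")
  }
  yaml::write_yaml(meta, side)
  invisible(side)
}

#' Read a frame stack written by \code{\link{writeFrameStack}}
#'
#' @param path the path given to \code{\link{writeFrameStack}} (without
#'   extension for TIFF; the frame directory for PNG).
#' @return A \code{\link{FrameStack}}.
#' @export
readFrameStack <- function(path) {
  side <- if (dir.exists(path)) file.path(path, "stack.yml")
          else paste0(path, ".yml")
  if (!file.exists(side))
    stop(sprintf("missing stack metadata: %s", side))
  meta <- yaml::read_yaml(side)
  if (identical(meta$format, "png")) {
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    pages <- lapply(files, png::readPNG)
  } else {
    pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  }
  arr <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  FrameStack(arr, Calibration(meta$fps, meta$mm_per_pixel),
             axisOrientation = meta$axis_orientation)
}

#' Write simulator ground truth as CSV
#'
#' Two plain-text tables: the per-frame analytic area
#' (\code{frame_index,time_s,area_mm2}) and the per-row edge positions in
#' long form (\code{frame_index,row,left_mm,right_mm}).
#'
#' @param truth a \code{\link{GroundTruth}}.
#' @param path output path prefix; \code{_area.csv} and \code{_edges.csv}
#'   are appended.
#' @param fps frames per second used for the time column.
#' @return Invisibly, the two file paths.
#' @export
writeGroundTruth <- function(truth, path, fps = 20000) {
  nT <- length(truth@trueArea)
  areaCsv <- paste0(path, "_area.csv")
  utils::write.csv(data.frame(frame_index = seq_len(nT),
                              time_s = (seq_len(nT) - 1) / fps,
                              area_mm2 = truth@trueArea),
                   areaCsv, row.names = FALSE)
  edgesCsv <- paste0(path, "_edges.csv")
  nR <- nrow(truth@trueLeftEdge)
  utils::write.csv(data.frame(frame_index = rep(seq_len(nT), each = nR),
                              row = rep(seq_len(nR), nT),
                              left_mm = as.vector(truth@trueLeftEdge),
                              right_mm = as.vector(truth@trueRightEdge)),
                   edgesCsv, row.names = FALSE)
  invisible(c(areaCsv, edgesCsv))
}

#' Write / read a signal trace as two-column CSV
#'
#' The CSV carries \code{time_s,value} columns; kind, sampling rate and
#' any scalar metadata travel in \code{#}-prefixed header comment lines.
#'
#' @param trace a \code{\link{SignalTrace}}.
#' @param path CSV path.
#' @return \code{writeSignalTrace}: invisibly, \code{path};
#'   \code{readSignalTrace}: a \code{\link{SignalTrace}}.
#' @export
writeSignalTrace <- function(trace, path) {
  stopifnot(is(trace, "SignalTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", trace@kind), con)
  writeLines(sprintf("# fs: %.10g", trace@fs), con)
  for (nm in names(trace@metadata)) {
    v <- trace@metadata[[nm]]
    if (length(v) == 1L && (is.numeric(v) || is.logical(v)))
      writeLines(sprintf("# %s: %.10g", nm, as.numeric(v)), con)
  }
  writeLines("time_s,value", con)
  t <- (seq_along(trace@samples) - 1L) / trace@fs
  writeLines(sprintf("%.10g,%.10g", t, trace@samples), con)
  invisible(path)
}

#' @rdname writeSignalTrace
#' @export
readSignalTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr)))
  meta <- as.list(kv[, 3]); names(meta) <- kv[, 2]
  kind <- meta$kind; meta$kind <- NULL
  fsHz <- as.numeric(meta$fs); meta$fs <- NULL
  meta <- lapply(meta, function(v) suppressWarnings(as.numeric(v)))
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  SignalTrace(dat$value, fsHz, kind, meta)
}

#' Write an edge track as CSV
#'
#' Columns \code{t,left_mm,right_mm,closed}.
#'
#' @param edges an \code{\link{EdgeTrack}}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeTrack <- function(edges, path) {
  stopifnot(is(edges, "EdgeTrack"))
  nT <- length(edges@leftPos)
  utils::write.csv(data.frame(t = (seq_len(nT) - 1) / fps(edges@calib),
                              left_mm = edges@leftPos,
                              right_mm = edges@rightPos,
                              closed = edges@closed),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a kymogram image
#'
#' The space--time intensity matrix as a 16-bit PNG (rows = scanline
#' pixels, columns = time) plus a small YAML sidecar with the axis
#' fraction and source row.
#'
#' @param kymo a \code{\link{Kymogram}}.
#' @param path output path without extension.
#' @return Invisibly, the PNG path.
#' @export
writeKymogram <- function(kymo, path) {
  stopifnot(is(kymo, "Kymogram"))
  png::writePNG(kymo@matrix, paste0(path, ".png"))
  yaml::write_yaml(list(axis_fraction = kymo@axisFraction,
                        scan_row = kymo@scanRow,
                        fps = fps(kymo@calib),
                        mm_per_pixel = mmPerPixel(kymo@calib)),
                   paste0(path, ".yml"))
  invisible(paste0(path, ".png"))
}
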