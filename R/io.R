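## Trace tables use one CSV dialect: comma separator, '.' decimal, UTF-8,
## header row required. Columns: time_s (or time), f_bleach or f_bleach_<i>,
## f_background, f_reference, optional bleach_end (constant metadata column).

.TIME_COLS <- c("time_s", "time")

#' Read a ROI trace table
#'
#' Reads a CSV of per-frame ROI mean intensities into a
#' \code{\linkS4class{RoiTraceSet}}. The table must contain a time column
#' (\code{time_s} or \code{time}), one or more bleach-ROI columns
#' (\code{f_bleach} or \code{f_bleach_1}, \code{f_bleach_2}, ...), and exactly
#' one \code{f_background} and one \code{f_reference} column. The index of the
#' first post-bleach frame is taken from a constant \code{bleach_end} column
#' or from the \code{bleachEnd} argument (the argument wins).
#'
#' @param path path to the CSV file
#' @param bleachEnd integer, first post-bleach frame index (overrides any
#'   \code{bleach_end} column)
#' @param pixelSize microns per pixel (metadata, optional)
#' @param roiRadius bleach-ROI radius in microns (metadata, optional)
#' @param condition condition label (metadata, optional)
#' @return a validated \code{\linkS4class{RoiTraceSet}}
#' @seealso \code{\link{writeTraceTable}}, \code{\link{normalizeTrace}}
#' @export
readTraceTable <- function(path, bleachEnd = NULL, pixelSize = NA_real_,
                           roiRadius = NA_real_, condition = "") {
  if (!file.exists(path))
    mfStop(sprintf("trace table not found: %s", path), "validation")
  d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  cn <- names(d)
  tc <- intersect(.TIME_COLS, cn)
  if (length(tc) < 1L)
    mfStop("missing required column: time_s (or time)", "format")
  for (col in c("f_background", "f_reference"))
    if (!col %in% cn)
      mfStop(sprintf("missing required column: %s", col), "format")
  blCols <- grep("^f_bleach(_[0-9]+)?$", cn, value = TRUE)
  if (length(blCols) < 1L)
    mfStop("missing required column: f_bleach", "format")
  if (is.null(bleachEnd)) {
    if (!"bleach_end" %in% cn)
      mfStop(paste("bleach_end not found: supply the bleachEnd argument or a",
                   "bleach_end metadata column"), "format")
    be <- unique(d$bleach_end)
    if (length(be) != 1L)
      mfStop("bleach_end column must be constant", "format")
    bleachEnd <- be
  }
  bl <- as.matrix(d[blCols])
  storage.mode(bl) <- "double"
  tryCatch(
    newRoiTraceSet(d[[tc[1L]]], bl, d$f_background, d$f_reference,
                   bleachEnd, pixelSize, roiRadius, condition),
    error = function(e) mfStop(conditionMessage(e), "validation"))
}

#' Write a ROI trace table
#'
#' Inverse of \code{\link{readTraceTable}}. Values are written with 17
#' significant digits so a read/write round trip reproduces every double
#' bit-exactly.
#'
#' @param x a \code{\linkS4class{RoiTraceSet}}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeTraceTable <- function(x, path) {
  stopifnot(is(x, "RoiTraceSet"))
  cols <- c(list(time_s = x@time),
            stats::setNames(
              lapply(seq_len(ncol(x@bleach)), function(j) x@bleach[, j]),
              if (ncol(x@bleach) == 1L) "f_bleach"
              else paste0("f_bleach_", seq_len(ncol(x@bleach)))),
            list(f_background = x@background, f_reference = x@reference,
                 bleach_end = rep(x@bleachEnd, nFrames(x))))
  lines <- c(paste(names(cols), collapse = ","),
             do.call(paste, c(lapply(cols, function(v)
               sprintf("%.17g", as.numeric(v))), sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a multi-page grayscale TIFF stack
#'
#' @param path path to a single-file multi-page TIFF
#' @return numeric 3D array (rows x cols x frames)
#' @export
readImageStack <- function(path) {
  if (!file.exists(path))
    mfStop(sprintf("image stack not found: %s", path), "validation")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    mfStop("image stack must be grayscale (one plane per page)", "format")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    mfStop("all stack frames must share dimensions", "format")
  array(unlist(pages, use.names = FALSE),
        dim = c(dims[1, 1], dims[2, 1], length(pages)))
}

## Pixel-center-in-circle mask, boundary inclusive. Pixel (row i, col j) has
## its center at x = j, y = i (pixel units).
.roiMask <- function(nrow, ncol, cx, cy, r) {
  jj <- seq_len(ncol)
  ii <- seq_len(nrow)
  outer(ii, jj, function(i, j) (j - cx)^2 + (i - cy)^2 <= r^2)
}

#' Extract mean-intensity ROI traces from an image stack
#'
#' For every frame and every ROI, averages the pixel values whose centers lie
#' inside the ROI circle (boundary inclusive). The ROI table must contain at
#' least one \code{bleach} ROI and exactly one \code{background} and one
#' \code{reference} ROI. Bleach ROIs must lie fully inside the image.
#'
#' @param stack 3D numeric array (rows x cols x frames) or a path accepted by
#'   \code{\link{readImageStack}}
#' @param rois data.frame with columns \code{center_x}, \code{center_y},
#'   \code{radius} (pixels; centers in pixel units where pixel (1,1) is at
#'   x = 1, y = 1) and \code{kind} (\code{"bleach"}, \code{"background"} or
#'   \code{"reference"})
#' @param bleachEnd first post-bleach frame index
#' @param frameInterval seconds between frames (default 1)
#' @param pixelSize microns per pixel (metadata)
#' @param condition condition label
#' @return a \code{\linkS4class{RoiTraceSet}}
#' @export
extractRoiTraces <- function(stack, rois, bleachEnd, frameInterval = 1,
                             pixelSize = NA_real_, condition = "") {
  if (is.character(stack)) stack <- readImageStack(stack)
  if (length(dim(stack)) != 3L)
    mfStop("stack must be a 3D array (rows x cols x frames)", "validation")
  need <- c("center_x", "center_y", "radius", "kind")
  if (!all(need %in% names(rois)))
    mfStop(paste("rois must contain columns:", paste(need, collapse = ", ")),
           "validation")
  if (any(rois$radius < 1))
    mfStop("ROI radius must be at least 1 pixel", "validation")
  kinds <- as.character(rois$kind)
  if (sum(kinds == "background") != 1L || sum(kinds == "reference") != 1L ||
      sum(kinds == "bleach") < 1L)
    mfStop("need >= 1 bleach ROI and exactly one background and one reference",
           "validation")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  means <- matrix(NA_real_, nf, nrow(rois))
  for (k in seq_len(nrow(rois))) {
    cx <- rois$center_x[k]; cy <- rois$center_y[k]; r <- rois$radius[k]
    if (kinds[k] == "bleach" &&
        (cx - r < 0.5 || cx + r > nc + 0.5 || cy - r < 0.5 || cy + r > nr + 0.5))
      mfStop(sprintf("bleach ROI %d extends outside the image", k),
             "validation")
    m <- .roiMask(nr, nc, cx, cy, r)
    if (!any(m))
      mfStop(sprintf("ROI %d covers no pixel centers", k), "validation")
    for (f in seq_len(nf)) means[f, k] <- mean(stack[, , f][m])
  }
  bl <- means[, kinds == "bleach", drop = FALSE]
  colnames(bl) <- paste0("roi", seq_len(ncol(bl)))
  roiRad <- if (is.na(pixelSize)) NA_real_ else
    rois$radius[kinds == "bleach"] * pixelSize
  newRoiTraceSet(frameInterval * (seq_len(nf) - 1), bl,
                 means[, kinds == "background"],
                 means[, kinds == "reference"],
                 bleachEnd, pixelSize, roiRad, condition)
}

#' Read a 2D localization table
#'
#' Reads a CSV with columns \code{x_nm}, \code{y_nm} and \code{channel}
#' (optional extra columns such as \code{frame} are ignored) into a
#' \code{\linkS4class{LocalizationMap}}. Coordinates must be finite and
#' non-negative nanometres.
#'
#' @param path path to the CSV file
#' @param fieldArea analysed area in um^2; when NULL the bounding-box area of
#'   all points is used
#' @return a validated \code{\linkS4class{LocalizationMap}}
#' @export
readLocalizations <- function(path, fieldArea = NULL) {
  if (!file.exists(path))
    mfStop(sprintf("localization table not found: %s", path), "validation")
  d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c("x_nm", "y_nm", "channel"))
    if (!col %in% names(d))
      mfStop(sprintf("missing required column: %s", col), "format")
  x <- as.numeric(d$x_nm); y <- as.numeric(d$y_nm)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    mfStop("localization coordinates must be finite", "validation")
  if (any(x < 0) || any(y < 0))
    mfStop("localization coordinates must be non-negative (nm)", "validation")
  if (is.null(fieldArea))
    fieldArea <- (max(x) - min(x)) * (max(y) - min(y)) / 1e6
  new("LocalizationMap", x = x, y = y,
      channel = factor(as.character(d$channel)),
      fieldArea = as.numeric(fieldArea))
}

#' Write a 2D localization table
#'
#' @param map a \code{\linkS4class{LocalizationMap}}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeLocalizations <- function(map, path) {
  stopifnot(is(map, "LocalizationMap"))
  lines <- c("x_nm,y_nm,channel",
             sprintf("%.17g,%.17g,%s", map@x, map@y,
                     as.character(map@channel)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
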