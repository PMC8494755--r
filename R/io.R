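#' FFA frame container
#'
#' Bundles one grayscale fundus fluorescein angiography (FFA) frame with its
#' circular field-of-view mask (ROI) and the acquisition time in minutes since
#' fluorescein injection. Pixel values are kept in the units of the source
#' file; no rescaling is applied, because the downstream quantification works
#' with relative fluorescein intensities.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param roi Logical matrix of the same dimensions (`TRUE` = inside the field
#'   of view). Computed with [detect_roi()] when `NULL`.
#' @param time_min Acquisition time in minutes since injection.
#' @param bit_depth Bit depth of the source file, if known.
#' @return An object of class `ffa_image` with fields `pixels`, `roi`,
#'   `time_min` and `bit_depth`.
#' @export
ffa_image <- function(pixels, roi = NULL, time_min = NA_real_,
                      bit_depth = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels < 0)) stop("pixel values must be >= 0")
  if (is.null(roi)) roi <- detect_roi(pixels)
  if (!is.logical(roi) || !identical(dim(roi), dim(pixels))) {
    stop("roi must be a logical matrix matching pixels")
  }
  if (!any(roi)) stop("roi must contain at least one TRUE pixel")
  structure(list(pixels = pixels, roi = roi, time_min = as.numeric(time_min),
                 bit_depth = bit_depth),
            class = "ffa_image")
}

#' @export
print.ffa_image <- function(x, ...) {
  cat(sprintf("<ffa_image> %d x %d, t = %s min, ROI %.1f%% of frame\n",
              nrow(x$pixels), ncol(x$pixels),
              format(x$time_min), 100 * mean(x$roi)))
  invisible(x)
}

#' @export
dim.ffa_image <- function(x) dim(x$pixels)

#' Detect the circular field of view of an FFA frame
#'
#' The fundus camera illuminates an approximately circular area on an
#' otherwise dark frame. The mask is the largest 8-connected component of
#' pixels above a threshold, morphologically closed and hole-filled. The
#' threshold is the Otsu threshold of the full frame, clipped from below at
#' 1% of the frame maximum so that a frame without a dark surround is not
#' split. If the component covers at least 98% of the frame, the whole frame
#' is returned as the field of view.
#'
#' @param pixels Numeric matrix of intensities.
#' @return Logical matrix, `TRUE` inside the field of view.
#' @export
detect_roi <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  mx <- max(pixels)
  if (mx <= 0) stop("no field of view detected")
  if (min(pixels) == mx) {
    return(matrix(TRUE, nrow(pixels), ncol(pixels)))
  }
  t_roi <- max(otsu_threshold(pixels), 0.01 * mx)
  mask <- pixels > t_roi
  if (!any(mask)) stop("no field of view detected")
  k <- EBImage::makeBrush(5L, "disc")
  closed <- EBImage::dilate(pad_reflect(mask * 1, 3L), k)
  closed <- EBImage::erode(closed, k)
  mask <- unpad(closed, 3L, 3L, nrow(pixels), ncol(pixels)) > 0
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(mask * 1) > 0
  if (mean(mask) >= 0.98) {
    return(matrix(TRUE, nrow(pixels), ncol(pixels)))
  }
  mask
}

read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- NA_integer_
  } else if (ext == "png") {
    img <- png::readPNG(path)
    # readPNG rescales to [0, 1]; recover native 8- or 16-bit code values.
    v8 <- img * 255
    if (max(abs(v8 - round(v8))) < 1e-8) {
      img <- v8
      depth <- 8L
    } else {
      img <- img * 65535
      depth <- 16L
    }
  } else {
    stop("unsupported image format (expect TIFF or PNG): ", path)
  }
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    for (ch in seq_len(nch)[-1L]) {
      if (max(abs(img[, , ch] - img[, , 1L])) > 1e-9) {
        stop("multi-channel image with non-identical channels: ", path)
      }
    }
    img <- img[, , 1L]
  }
  list(pixels = img, bit_depth = as.integer(depth))
}

#' Load one FFA frame
#'
#' Reads a single-channel TIFF or PNG frame without intensity rescaling
#' (integer code values are kept as-is in a floating representation), detects
#' the circular field of view and attaches the acquisition time. RGB inputs
#' whose channels are identical are collapsed to one channel; differing
#' channels are an error.
#'
#' @param path Path to a TIFF or PNG file.
#' @param time_min Acquisition time in minutes since injection.
#' @return An [ffa_image()].
#' @export
load_image <- function(path, time_min = NA_real_) {
  g <- read_gray(path)
  ffa_image(g$pixels, roi = detect_roi(g$pixels), time_min = time_min,
            bit_depth = g$bit_depth)
}

#' FFA sequence container
#'
#' An ordered set of frames of one eye, sorted by strictly increasing
#' acquisition time. All frames must share dimensions.
#'
#' @param frames List of [ffa_image()] objects.
#' @param eye_id Label for the eye.
#' @return An object of class `ffa_sequence`.
#' @export
ffa_sequence <- function(frames, eye_id = "eye") {
  if (length(frames) < 2L) stop("a sequence needs at least 2 frames")
  stopifnot(all(vapply(frames, inherits, logical(1), "ffa_image")))
  times <- vapply(frames, function(f) f$time_min, numeric(1))
  if (any(is.na(times))) stop("all frames need an acquisition time")
  if (anyDuplicated(times)) stop("duplicate acquisition times")
  frames <- frames[order(times)]
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    shapes <- paste(apply(dims, 2, paste, collapse = "x"), collapse = ", ")
    stop("frames have mismatched dimensions: ", shapes)
  }
  structure(list(frames = frames, eye_id = eye_id), class = "ffa_sequence")
}

#' @export
print.ffa_sequence <- function(x, ...) {
  cat(sprintf("<ffa_sequence> '%s': %d frames at t = %s min\n", x$eye_id,
              length(x$frames),
              paste(vapply(x$frames, function(f) format(f$time_min),
                           character(1)), collapse = ", ")))
  invisible(x)
}

#' @export
length.ffa_sequence <- function(x) length(x$frames)

#' Load an FFA sequence from a manifest
#'
#' The manifest is a data frame (or path to a CSV with a header) with columns
#' `path` and `time_min`, one row per frame. Frames are loaded with
#' [load_image()] and sorted by time.
#'
#' @param manifest Data frame or CSV path with columns `path`, `time_min`.
#' @param eye_id Label for the eye.
#' @return An [ffa_sequence()].
#' @export
load_sequence <- function(manifest, eye_id = "eye") {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!all(c("path", "time_min") %in% names(manifest))) {
    stop("manifest needs columns 'path' and 'time_min'")
  }
  if (nrow(manifest) < 2L) stop("a sequence needs at least 2 frames")
  frames <- Map(load_image, manifest$path, manifest$time_min)
  ffa_sequence(unname(frames), eye_id = eye_id)
}

roi_rle <- function(roi) {
  r <- rle(as.integer(roi))
  list(dim = dim(roi), values = r$values, lengths = r$lengths)
}

roi_from_rle <- function(x) {
  matrix(inverse.rle(list(values = as.integer(x$values),
                          lengths = as.integer(x$lengths))) > 0,
         x$dim[1L], x$dim[2L])
}

#' Write an FFA frame with its sidecar metadata
#'
#' Writes pixels as a 16-bit TIFF (values scaled by the recorded bit depth,
#' or by the frame maximum for float data) plus a JSON sidecar holding
#' `time_min`, the intensity scale, and the ROI as a run-length encoding.
#'
#' @param image An [ffa_image()].
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ffa_image <- function(image, path) {
  scale <- if (!is.na(image$bit_depth)) 2^image$bit_depth - 1 else
    max(image$pixels, 1)
  tiff::writeTIFF(pmin(image$pixels / scale, 1), path, bits.per.sample = 16L)
  meta <- list(time_min = image$time_min, scale = scale,
               roi = roi_rle(image$roi))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an FFA frame written by [write_ffa_image()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @return An [ffa_image()].
#' @export
read_ffa_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale
  ffa_image(px, roi = roi_from_rle(meta$roi), time_min = meta$time_min)
}
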