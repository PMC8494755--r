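#' Parameters for oriented-opening vessel removal
#'
#' The small-vessel step opens the image with digital line segments of length
#' `l_sv` at `n_angles` orientations and keeps the pixelwise minimum, so any
#' bright structure narrower than `l_sv` in some direction is erased. The
#' large-vessel step uses lines of length `l_lv` together with their
#' perpendiculars. Both lengths should be chosen slightly larger than the
#' diameter of the thickest vessel the step is meant to remove or enhance;
#' the defaults suit 512 x 512 frames and scale linearly with frame width.
#'
#' @param l_sv Odd line length (pixels) for small-vessel removal, >= 3.
#' @param l_lv Odd line length (pixels) for the large-vessel residues,
#'   >= `l_sv`.
#' @param n_angles Number of orientations, divisible by 4 so that every
#'   angle's perpendicular is in the set.
#' @return An object of class `opening_params`.
#' @export
opening_params <- function(l_sv = 15L, l_lv = 31L, n_angles = 8L) {
  l_sv <- as.integer(l_sv)
  l_lv <- as.integer(l_lv)
  n_angles <- as.integer(n_angles)
  if (l_sv < 3L || l_sv %% 2L == 0L) stop("l_sv must be odd and >= 3")
  if (l_lv < l_sv || l_lv %% 2L == 0L) stop("l_lv must be odd and >= l_sv")
  if (n_angles < 4L || n_angles %% 4L != 0L) {
    stop("n_angles must be a positive multiple of 4")
  }
  structure(list(l_sv = l_sv, l_lv = l_lv, n_angles = n_angles,
                 angles = (seq_len(n_angles) - 1) * pi / n_angles),
            class = "opening_params")
}

#' Vessel-free leakage image container
#'
#' Holds an intensity grid produced by the vessel-removal steps (the
#' intermediate small-vessel-removed image, directional residues, the
#' large-vessel enhancement, or the final leakage image) together with the
#' field-of-view mask of its source frame.
#'
#' @param values Numeric matrix.
#' @param roi Logical matrix of the same dimensions.
#' @param time_min Acquisition time carried over from the source frame.
#' @return An object of class `leakage_image`.
#' @export
leakage_image <- function(values, roi, time_min = NA_real_) {
  stopifnot(is.matrix(values), is.logical(roi),
            identical(dim(values), dim(roi)))
  structure(list(values = values, roi = roi, time_min = as.numeric(time_min)),
            class = "leakage_image")
}

#' @export
print.leakage_image <- function(x, ...) {
  cat(sprintf("<leakage_image> %d x %d, in-ROI mean %.2f\n",
              nrow(x$values), ncol(x$values), mean(x$values[x$roi])))
  invisible(x)
}

#' Digital line structuring element
#'
#' A straight segment of `length` pixels through the center of its bounding
#' grid, rasterized by the standard integer line-drawing rule (one pixel per
#' step of the major axis, offsets rounded half-to-even so the element is
#' symmetric under 180 degree rotation). The direction convention is
#' (row, col) = (sin(angle), cos(angle)) with rows increasing downward, so
#' angle 0 is horizontal and pi/2 vertical.
#'
#' @param length Odd positive segment length in pixels.
#' @param angle Orientation in radians; reduced modulo pi.
#' @return Logical matrix containing the segment, trimmed to its bounding box.
#' @export
line_structuring_element <- function(length, angle) {
  length <- as.integer(length)
  if (length < 1L || length %% 2L == 0L) {
    stop("length must be odd and positive")
  }
  angle <- angle %% pi
  h <- (length - 1L) %/% 2L
  t <- -h:h
  if (abs(cos(angle)) >= abs(sin(angle))) {
    cc <- t
    rr <- round(t * tan(angle))
  } else {
    rr <- t
    cc <- round(t / tan(angle))
  }
  rmin <- min(rr); cmin <- min(cc)
  se <- matrix(FALSE, max(rr) - rmin + 1L, max(cc) - cmin + 1L)
  se[cbind(rr - rmin + 1L, cc - cmin + 1L)] <- TRUE
  se
}

# Grayscale opening (erosion then dilation) with a flat structuring element,
# reflect-padded so the ROI border does not pick up spurious dark bands.
# EBImage's grayscale morphology expects values in [0, 1]; scaling by a power
# of two >= max is exact in binary floating point, so results are identical
# to operating on the raw values.
gray_open <- function(values, kernel) {
  nr <- nrow(values)
  nc <- ncol(values)
  pr <- nrow(kernel) %/% 2L
  pc <- ncol(kernel) %/% 2L
  # pad by twice the kernel half-width: the dilation consumes erosion values
  # up to a half-width outside the frame, which must themselves come from
  # full (unclipped) erosion windows of the reflect-padded image
  pad <- 2L * max(pr, pc, 1L)
  mx <- max(values)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  p <- pad_reflect(values, pad, pad) / scale
  o <- EBImage::dilate(EBImage::erode(p, kernel * 1), kernel * 1)
  unpad(o, pad, pad, nr, nc) * scale
}

open_with_line <- function(values, length, angle) {
  gray_open(values, line_structuring_element(length, angle))
}

#' Remove small vessels by oriented grayscale openings
#'
#' Opens the frame with a line element of length `l_sv` at each orientation
#' and takes the pixelwise minimum over orientations. For a pixel on a thin
#' bright vessel the minimizing orientation is perpendicular to the vessel,
#' so the vessel is replaced by the minimum along a line crossing it, while
#' broad smooth leakage regions, which contain a fully fitting line at every
#' orientation, are left (nearly) unchanged.
#'
#' @param image An [ffa_image()].
#' @param params An [opening_params()].
#' @return A [leakage_image()] with the small-vessel-removed intensities.
#' @export
remove_small_vessels <- function(image, params = opening_params()) {
  stopifnot(inherits(image, "ffa_image"), inherits(params, "opening_params"))
  opened <- lapply(params$angles, function(a) {
    open_with_line(image$pixels, params$l_sv, a)
  })
  leakage_image(Reduce(pmin, opened), image$roi, image$time_min)
}

#' Directional opening residue at one orientation
#'
#' The difference between the opening with a line of length `l_lv` at
#' `angle` and the opening with its perpendicular. On a vessel aligned with
#' `angle` the parallel opening preserves the bright ridge while the
#' perpendicular opening removes it, so the residue is large; on isotropic
#' structures such as leakage both openings agree and the residue is near
#' zero. May be negative where the structure is aligned with the
#' perpendicular.
#'
#' @param image An [ffa_image()].
#' @param angle One of the orientations in `params`.
#' @param params An [opening_params()].
#' @return Numeric matrix of residues.
#' @export
directional_residue <- function(image, angle, params = opening_params()) {
  stopifnot(inherits(image, "ffa_image"))
  open_with_line(image$pixels, params$l_lv, angle) -
    open_with_line(image$pixels, params$l_lv, angle + pi / 2)
}

#' Enhance large vessels by perpendicular-opening residues
#'
#' The pixelwise maximum of [directional_residue()] over all orientations.
#' Because the orientation set is closed under taking perpendiculars, for
#' every angle the opposite-signed residue at its perpendicular is also in
#' the set, so the maximum is nonnegative everywhere. Leakage regions are
#' suppressed; elongated bright structures wider than the small-vessel scale
#' stand out.
#'
#' @inheritParams remove_small_vessels
#' @return A [leakage_image()] carrying the large-vessel enhancement.
#' @export
enhance_large_vessels <- function(image, params = opening_params()) {
  stopifnot(inherits(image, "ffa_image"), inherits(params, "opening_params"))
  opened <- lapply(params$angles, function(a) {
    open_with_line(image$pixels, params$l_lv, a)
  })
  n <- params$n_angles
  perp <- ((seq_len(n) - 1 + n / 2) %% n) + 1
  res <- Map(function(i, j) opened[[i]] - opened[[j]], seq_len(n), perp)
  leakage_image(Reduce(pmax, res), image$roi, image$time_min)
}

#' Remove segmented large vessels from the leakage image
#'
#' Pixels inside the vessel mask are replaced by a local background estimate:
#' the grayscale opening of the small-vessel-removed image with a disc of
#' diameter `l_lv`. The opening is anti-extensive, so infilled values never
#' exceed the surrounding leakage level; outside the mask the image is
#' unchanged. This defines the final leakage image used for quantification.
#'
#' @param small_removed A [leakage_image()] from [remove_small_vessels()].
#' @param vessel_mask Logical matrix of segmented large vessels.
#' @param params An [opening_params()]; `l_lv` sets the infill disc diameter.
#' @return A [leakage_image()], the final vessel-free leakage image.
#' @export
remove_large_vessels <- function(small_removed, vessel_mask,
                                 params = opening_params()) {
  stopifnot(inherits(small_removed, "leakage_image"),
            is.logical(vessel_mask),
            identical(dim(vessel_mask), dim(small_removed$values)))
  if (all(vessel_mask)) stop("vessel mask covers entire image")
  out <- small_removed$values
  if (any(vessel_mask)) {
    infill <- gray_open(small_removed$values,
                        EBImage::makeBrush(params$l_lv, "disc") > 0)
    out[vessel_mask] <- infill[vessel_mask]
  }
  leakage_image(out, small_removed$roi, small_removed$time_min)
}
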