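#' Rigid (rotation + translation) transform
#'
#' Maps moving-frame to fixed-frame pixel coordinates:
#' `p_fixed = R(angle) (p_moving - center) + center + translation`,
#' with (row, col) coordinates and the rotation matrix acting in that plane.
#' With `angle = 0` the mapping reduces to adding `translation`.
#'
#' @param angle Rotation angle in radians.
#' @param translation Numeric `c(d_row, d_col)` in pixels.
#' @param center Numeric `c(row, col)` rotation center.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle = 0, translation = c(0, 0),
                            center = c(0, 0)) {
  stopifnot(is.numeric(angle), length(translation) == 2L,
            length(center) == 2L, all(is.finite(c(angle, translation, center))))
  structure(list(angle = angle, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angle %.3f deg, translation (%.2f, %.2f) px, center (%.1f, %.1f)\n",
    x$angle * 180 / pi, x$translation[1L], x$translation[2L],
    x$center[1L], x$center[2L]))
  invisible(x)
}

rot_mat <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
}

#' Apply a rigid transform to points
#'
#' @param t A [rigid_transform()].
#' @param pts Two-column (row, col) matrix or a length-2 vector.
#' @return Transformed points, same shape as `pts`.
#' @export
transform_points <- function(t, pts) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, 1L, 2L)
  out <- sweep(sweep(pts, 2L, t$center) %*% t(rot_mat(t$angle)), 2L,
               t$center + t$translation, `+`)
  if (vec) out[1L, ] else out
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return The inverse `rigid_transform` (same center).
#' @export
invert_transform <- function(t) {
  rigid_transform(-t$angle,
                  as.numeric(-t(rot_mat(t$angle)) %*% t$translation),
                  t$center)
}

#' Compose two rigid transforms (`t2` after `t1`)
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @return A `rigid_transform` equal to applying `t1` then `t2`, expressed
#'   about `t2`'s center.
#' @export
compose_transforms <- function(t2, t1) {
  r1 <- rot_mat(t1$angle)
  r2 <- rot_mat(t2$angle)
  # total affine: p -> R2 R1 p + b
  b <- as.numeric(r2 %*% (t1$center + t1$translation - t2$center -
                            r1 %*% t1$center)) + t2$center + t2$translation
  ang <- t1$angle + t2$angle
  cen <- t2$center
  tr <- b + as.numeric(rot_mat(ang) %*% cen) - cen
  rigid_transform(ang, tr, cen)
}

#' Translation-only transform matching two reference points
#'
#' The registration initializer: zero rotation and the translation that
#' carries the moving frame's reference point onto the fixed frame's, with
#' the rotation center at the fixed reference point so that subsequent angle
#' optimization pivots about the optic disk.
#'
#' @param ref_moving,ref_fixed Numeric `c(row, col)` reference points.
#' @return A [rigid_transform()].
#' @export
initial_transform <- function(ref_moving, ref_fixed) {
  stopifnot(all(is.finite(ref_moving)), all(is.finite(ref_fixed)))
  rigid_transform(0, as.numeric(ref_fixed) - as.numeric(ref_moving),
                  as.numeric(ref_fixed))
}

#' Resample a moving frame into fixed-frame coordinates
#'
#' Pixels are interpolated bilinearly at the inverse-transformed positions;
#' the ROI is warped with nearest-neighbor sampling, and positions falling
#' outside the moving frame are marked outside the ROI.
#'
#' @param moving An [ffa_image()].
#' @param t A [rigid_transform()] mapping moving to fixed coordinates.
#' @param fixed_shape Output dimensions, default those of `moving`.
#' @return An [ffa_image()] in fixed-frame coordinates.
#' @export
warp <- function(moving, t, fixed_shape = dim(moving$pixels)) {
  stopifnot(inherits(moving, "ffa_image"), inherits(t, "rigid_transform"))
  nr <- fixed_shape[1L]
  nc <- fixed_shape[2L]
  if (t$angle == 0 && all(t$translation == 0)) {
    px <- moving$pixels
    roi <- moving$roi
    if (!identical(dim(px), as.integer(fixed_shape))) {
      stop("identity warp with mismatched shapes")
    }
    return(ffa_image(px, roi, moving$time_min, moving$bit_depth))
  }
  grid <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  src <- transform_points(invert_transform(t), grid)
  v <- bilinear_sample(moving$pixels, src[, 1L], src[, 2L], fill = 0)
  inside <- attr(v, "inside")
  roi <- nearest_sample(moving$roi, src[, 1L], src[, 2L], fill = FALSE) & inside
  px <- matrix(pmax(as.numeric(v), 0), nr, nc)
  roi <- matrix(roi, nr, nc)
  if (!any(roi)) roi[1L] <- TRUE   # container invariant; flagged by callers
  out <- ffa_image(px, roi, moving$time_min, moving$bit_depth)
  out
}

ncc_metric <- function(fixed, warped) {
  sel <- fixed$roi & warped$roi
  if (sum(sel) < 32L) return(NA_real_)
  a <- fixed$pixels[sel]
  b <- warped$pixels[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

downsample2 <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L)
  nc <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  0.25 * (m[seq(1L, nr, 2L), seq(1L, nc, 2L)] +
            m[seq(2L, nr, 2L), seq(1L, nc, 2L)] +
            m[seq(1L, nr, 2L), seq(2L, nc, 2L)] +
            m[seq(2L, nr, 2L), seq(2L, nc, 2L)])
}

downsample_image <- function(img) {
  ffa_image(downsample2(img$pixels),
            downsample2(img$roi * 1) > 0.5,
            img$time_min, img$bit_depth)
}

#' Rigidly register one frame to a fixed frame
#'
#' Maximizes the normalized cross-correlation (NCC) of the two frames over
#' the fixed ROI by regular-step gradient ascent on (angle, d_row, d_col),
#' starting from `init`, with a 2-level multiresolution schedule for
#' robustness. The optimizer uses central-difference gradients with
#' parameter scales of about 1 px translation per 0.01 rad rotation, accepts
#' only metric-improving steps (so the final metric is never below its value
#' at `init`), and is fully deterministic.
#'
#' @param fixed,moving [ffa_image()] objects of the same shape.
#' @param init A [rigid_transform()] initialization (e.g. from
#'   [initial_transform()]); identity about the fixed ROI centroid if `NULL`.
#' @param max_iter Iteration cap per resolution level.
#' @param tol Relative metric-improvement tolerance for convergence.
#' @param levels Number of resolution levels (1 = full resolution only).
#' @return A `rigid_transform` with attributes `metric_init` and
#'   `metric_final` (NCC at `init` and at the optimum, full resolution).
#' @export
register_pair <- function(fixed, moving, init = NULL, max_iter = 300L,
                          tol = 1e-6, levels = 2L) {
  stopifnot(inherits(fixed, "ffa_image"), inherits(moving, "ffa_image"),
            identical(dim(fixed$pixels), dim(moving$pixels)))
  if (is.null(init)) {
    cen <- roi_centroid(fixed$roi)
    init <- rigid_transform(0, c(0, 0), cen)
  }
  w0 <- warp(moving, init, dim(fixed$pixels))
  if (sum(fixed$roi & w0$roi) < 32L) stop("initialization out of field")
  m_init <- ncc_metric(fixed, w0)
  center <- init$center
  x <- c(init$angle, init$translation)

  pyr_f <- list(fixed)
  pyr_m <- list(moving)
  if (levels > 1L) {
    for (l in seq_len(levels - 1L)) {
      pyr_f[[l + 1L]] <- downsample_image(pyr_f[[l]])
      pyr_m[[l + 1L]] <- downsample_image(pyr_m[[l]])
    }
  }
  for (lev in rev(seq_len(levels))) {
    fac <- 2^(lev - 1L)
    f_l <- pyr_f[[lev]]
    m_l <- pyr_m[[lev]]
    cen_l <- (center - 0.5) / fac + 0.5
    objective <- function(xl) {
      t_l <- rigid_transform(xl[1L], xl[2:3], cen_l)
      v <- ncc_metric(f_l, warp(m_l, t_l, dim(f_l$pixels)))
      if (is.na(v)) -2 else v
    }
    xl <- c(x[1L], x[2:3] / fac)
    xl <- ascend(objective, xl, scales = c(0.01, 1, 1),
                 step0 = if (lev > 1L) 4 else 1.5,
                 step_min = if (lev > 1L) 0.05 else 0.01,
                 max_iter = max_iter, tol = tol)
    x <- c(xl[1L], xl[2:3] * fac)
  }
  cand <- rigid_transform(x[1L], x[2:3], center)
  m_final <- ncc_metric(fixed, warp(moving, cand, dim(fixed$pixels)))
  if (is.na(m_final) || m_final < m_init) {   # never worse than the init
    cand <- init
    m_final <- m_init
  }
  attr(cand, "metric_init") <- m_init
  attr(cand, "metric_final") <- m_final
  cand
}

# Regular-step gradient ascent with backtracking in scaled coordinates.
ascend <- function(f, x, scales, step0, step_min, max_iter, tol) {
  fx <- f(x)
  step <- step0
  h <- 0.25
  for (it in seq_len(max_iter)) {
    g <- vapply(seq_along(x), function(i) {
      e <- numeric(length(x))
      e[i] <- h * scales[i]
      (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    moved <- FALSE
    while (step >= step_min) {
      xn <- x + step * (g / gn) * scales
      fn <- f(xn)
      if (fn > fx) {
        improved <- (fn - fx) < tol * max(abs(fx), 1e-12)
        x <- xn
        fx <- fn
        moved <- TRUE
        if (improved) return(x)
        break
      }
      step <- step / 2
    }
    if (!moved) break
  }
  x
}

roi_centroid <- function(roi) {
  idx <- which(roi)
  nr <- nrow(roi)
  c(mean(((idx - 1L) %% nr) + 1L), mean(((idx - 1L) %/% nr) + 1L))
}

#' Register every frame of a sequence to the first timepoint
#'
#' The first frame (earliest, least leakage and saturation) is the fixed
#' frame. Each later frame is registered with [register_pair()], initialized
#' by matching the vessel-convergence reference points when both can be
#' detected ([reference_point()]) and by the identity otherwise. Frames
#' whose registration fails are flagged and excluded with a warning. The
#' analysis ROI handed to quantification is the intersection of all
#' successfully registered ROIs, so every timepoint's statistics cover the
#' same retinal area.
#'
#' @param seq An [ffa_sequence()].
#' @param T_b,L_0,params,q_low,q_high,n_s,sigma Passed to
#'   [reference_point()] / [large_vessel_mask()].
#' @param ... Passed to [register_pair()].
#' @return A list of class `ffa_registration`: `transforms` (per frame;
#'   identity for the first), `registered` (an `ffa_sequence` of warped
#'   frames), `analysis_roi`, `ok` (logical per frame) and
#'   `init_source` ("refpoint" or "identity").
#' @export
register_sequence <- function(seq, T_b = 20L, L_0 = 30L,
                              params = opening_params(), q_low = 0.90,
                              q_high = 0.98, n_s = 2L, sigma = 3, ...) {
  stopifnot(inherits(seq, "ffa_sequence"))
  frames <- seq$frames
  n <- length(frames)
  fixed <- frames[[1L]]
  ref0 <- tryCatch(
    reference_point(fixed, T_b, L_0, params, q_low, q_high, n_s, sigma),
    error = function(e) NULL)
  cen <- if (!is.null(ref0)) as.numeric(ref0) else roi_centroid(fixed$roi)
  transforms <- vector("list", n)
  registered <- vector("list", n)
  ok <- logical(n)
  init_source <- character(n)
  transforms[[1L]] <- rigid_transform(0, c(0, 0), cen)
  registered[[1L]] <- fixed
  ok[1L] <- TRUE
  init_source[1L] <- "fixed"
  for (k in seq_len(n)[-1L]) {
    mov <- frames[[k]]
    refk <- if (is.null(ref0)) NULL else tryCatch(
      reference_point(mov, T_b, L_0, params, q_low, q_high, n_s, sigma),
      error = function(e) NULL)
    if (!is.null(refk)) {
      init <- initial_transform(as.numeric(refk), as.numeric(ref0))
      init_source[k] <- "refpoint"
    } else {
      init <- rigid_transform(0, c(0, 0), cen)
      init_source[k] <- "identity"
      warning(sprintf("frame %d: no reference point, identity initialization",
                      k))
    }
    res <- tryCatch(register_pair(fixed, mov, init, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("frame %d excluded: %s", k, conditionMessage(res)))
      transforms[[k]] <- NULL
      ok[k] <- FALSE
      next
    }
    transforms[[k]] <- res
    registered[[k]] <- warp(mov, res, dim(fixed$pixels))
    ok[k] <- TRUE
  }
  kept <- which(ok)
  analysis_roi <- Reduce(`&`, lapply(registered[kept], function(f) f$roi))
  structure(list(transforms = transforms,
                 registered = ffa_sequence(registered[kept],
                                           eye_id = seq$eye_id),
                 analysis_roi = analysis_roi, ok = ok,
                 init_source = init_source),
            class = "ffa_registration")
}

#' @export
print.ffa_registration <- function(x, ...) {
  cat(sprintf("<ffa_registration> %d/%d frames registered, analysis ROI %.1f%%\n",
              sum(x$ok), length(x$ok), 100 * mean(x$analysis_roi)))
  invisible(x)
}
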