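#' Hysteresis threshold
#'
#' Keeps the 8-connected components of `values >= t_low` that contain at
#' least one pixel with `values >= t_high`. With `t_low == t_high` this
#' reduces to a simple threshold.
#'
#' @param values Numeric matrix with finite values.
#' @param t_low,t_high Low and high thresholds, `t_low <= t_high`.
#' @return Logical mask.
#' @export
hysteresis <- function(values, t_low, t_high) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (t_low > t_high) stop("t_low must be <= t_high")
  low <- values >= t_low
  if (!any(low)) return(low)
  lab <- label8(low)
  strong <- unique(lab[values >= t_high])
  array(lab %in% strong[strong > 0L], dim(values))
}

#' Two-phase Chan-Vese segmentation
#'
#' Minimizes the discrete two-phase piecewise-constant Chan-Vese energy:
#' squared deviation from the per-phase means (weighted by `lambda1` inside,
#' `lambda2` outside) plus `mu` per 4-neighbor pair of discordant labels
#' (a discrete boundary length). Minimization alternates exact updates of
#' the phase means with checkerboard coordinate-descent sweeps over the
#' labels, so the energy is non-increasing at every iteration and the result
#' is deterministic for a fixed initialization. The returned foreground is
#' the phase with the higher mean.
#'
#' `mu` has the units of a squared intensity; the default 0.1 * range^2
#' keeps the balance between data and boundary terms invariant to affine
#' intensity rescaling.
#'
#' @param values Numeric, non-constant matrix.
#' @param mu Boundary-length weight (> 0); default `0.1 * diff(range(values))^2`.
#' @param lambda1,lambda2 Data-term weights for the foreground and background
#'   phase (> 0).
#' @param max_iter Maximum number of sweeps.
#' @param tol Convergence tolerance: stop when the fraction of pixels that
#'   change label in a sweep falls below `tol`.
#' @param init Initial foreground mask, or `"auto"` for the hysteresis mask
#'   at the 70th/95th percentile of `values` (deterministic, seed-free).
#' @return Logical mask with attributes `energy` (the energy after each
#'   iteration) and `iterations`.
#' @export
chan_vese <- function(values, mu = NULL, lambda1 = 1, lambda2 = 1,
                      max_iter = 200L, tol = 1e-4, init = "auto") {
  stopifnot(is.matrix(values), all(is.finite(values)))
  rng <- range(values)
  if (rng[1] == rng[2]) stop("degenerate segmentation: constant input")
  if (is.null(mu)) mu <- 0.1 * diff(rng)^2
  stopifnot(mu > 0, lambda1 > 0, lambda2 > 0, max_iter >= 1L)
  if (identical(init, "auto")) {
    q <- stats::quantile(values, c(0.70, 0.95), names = FALSE)
    fg <- hysteresis(values, q[1], q[2])
    if (!any(fg) || all(fg)) fg <- values >= mean(rng)
  } else {
    stopifnot(is.logical(init), identical(dim(init), dim(values)))
    fg <- init
  }
  nr <- nrow(values)
  nc <- ncol(values)
  parity <- (outer(seq_len(nr), seq_len(nc), `+`)) %% 2L
  energies <- numeric(0)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    if (!any(fg) || all(fg)) break
    c1 <- mean(values[fg])
    c0 <- mean(values[!fg])
    changed <- 0L
    for (par in c(0L, 1L)) {
      nfg <- count4(fg)
      nbg <- count4(!fg)
      cost_fg <- lambda1 * (values - c1)^2 + mu * nbg
      cost_bg <- lambda2 * (values - c0)^2 + mu * nfg
      upd <- parity == par
      new_fg <- fg
      new_fg[upd & (cost_fg < cost_bg)] <- TRUE
      new_fg[upd & (cost_bg < cost_fg)] <- FALSE
      changed <- changed + sum(new_fg != fg)
      fg <- new_fg
    }
    energies <- c(energies, cv_energy(values, fg, mu, lambda1, lambda2))
    if (changed / (nr * nc) < tol) break
  }
  if (any(fg) && !all(fg) && mean(values[fg]) < mean(values[!fg])) fg <- !fg
  structure(fg, energy = energies, iterations = n_iter)
}

# Count of TRUE 4-neighbors, out-of-frame neighbors ignored.
count4 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  p[1:nr, 2:(nc + 1L)] +
    p[3:(nr + 2L), 2:(nc + 1L)] +
    p[2:(nr + 1L), 1:nc] +
    p[2:(nr + 1L), 3:(nc + 2L)]
}

cv_energy <- function(values, fg, mu, lambda1, lambda2) {
  if (any(fg) && !all(fg)) {
    c1 <- mean(values[fg])
    c0 <- mean(values[!fg])
    data <- lambda1 * sum((values[fg] - c1)^2) +
      lambda2 * sum((values[!fg] - c0)^2)
  } else {
    data <- sum((values - mean(values))^2)
  }
  per <- sum(fg[-nrow(fg), ] != fg[-1, ]) + sum(fg[, -ncol(fg)] != fg[, -1])
  data + mu * per
}

#' Segment blood vessels from a frame
#'
#' Applies [chan_vese()] to the log-Gabor vesselness map of the frame and
#' restricts the result to the field of view. If the vesselness map is
#' degenerate (constant, e.g. a blank frame) an empty mask is returned with
#' a warning.
#'
#' @param image An [ffa_image()].
#' @param n_s,sigma Passed to [enhance()].
#' @param ... Passed to [chan_vese()].
#' @return Logical vessel mask, `FALSE` outside the ROI.
#' @export
segment_vessels <- function(image, n_s = 2L, sigma = 3, ...) {
  stopifnot(inherits(image, "ffa_image"))
  lp <- enhance(image$pixels, n_s = n_s, sigma = sigma)
  mask <- tryCatch(chan_vese(lp, ...), error = function(e) {
    warning("degenerate vesselness map; returning empty vessel mask")
    array(FALSE, dim(lp))
  })
  mask & image$roi
}

#' Large-vessel mask
#'
#' The binary large-vessel image used both for vessel removal and for
#' reference-point detection: the perpendicular-residue enhancement
#' ([enhance_large_vessels()]) is regularized by the log-Gabor vesselness
#' map and thresholded with hysteresis. Thresholds are specified as
#' quantiles of the within-ROI vesselness values, which transfers across
#' exposure levels; the segmentation is not very sensitive to their exact
#' values.
#'
#' @param image An [ffa_image()].
#' @param params An [opening_params()].
#' @param q_low,q_high Hysteresis thresholds as quantiles in \[0, 1\] of the
#'   within-ROI vesselness values.
#' @param n_s,sigma Passed to [enhance()].
#' @return Logical mask of large vessels, `FALSE` outside the ROI.
#' @export
large_vessel_mask <- function(image, params = opening_params(),
                              q_low = 0.90, q_high = 0.98,
                              n_s = 2L, sigma = 3) {
  stopifnot(inherits(image, "ffa_image"))
  iv_tilde <- enhance_large_vessels(image, params)
  lp <- enhance(iv_tilde$values, n_s = n_s, sigma = sigma)
  v <- lp[image$roi]
  if (min(v) == max(v)) return(array(FALSE, dim(lp)))
  th <- stats::quantile(v, c(q_low, q_high), names = FALSE)
  hysteresis(lp, th[1], th[2]) & image$roi
}
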