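#' Multi-scale log-Gabor quadrature filter bank
#'
#' Builds frequency-domain log-Gabor filters at `n_s` scales and
#' `n_orient` orientations spread uniformly over 180 degrees. The center
#' frequency at scale s is 2^(rho_s)/M with rho_s = log2(M) - s for the
#' (power-of-two) working side length M, i.e. exactly 2^-s cycles per pixel
#' independent of the frame size. The radial profile is
#' exp(-ln^2(f/w0) / (2 ln^2 k)) with k set by the bandwidth in octaves
#' (2 octaves by default); it is exactly zero at zero frequency, so the
#' filters have no DC response. The angular profile is a Gaussian in angle of
#' standard deviation (pi/n_orient)/d_theta_on_sigma, one-sided in direction,
#' which makes the spatial filters complex-valued quadrature pairs; the
#' default spread gives near-uniform coverage of the Fourier plane over
#' orientation.
#'
#' A non-power-of-two frame size is handled by building the bank for the next
#' power of two and reflect-padding the image before filtering.
#'
#' @param N Frame side length in pixels (>= 32).
#' @param n_s Number of scales, between 1 and log2(N) - 2.
#' @param n_orient Number of orientations (8, matching the printed
#'   orientation formula theta_j = (j-1) pi/8).
#' @param bandwidth_octaves Radial bandwidth of each filter in octaves.
#' @param d_theta_on_sigma Ratio of orientation spacing to the angular
#'   Gaussian standard deviation.
#' @return An object of class `log_gabor_bank` with the frequency-domain
#'   filters, working size `M`, center frequencies `w0` and orientations.
#' @export
build_bank <- function(N, n_s = 2L, n_orient = 8L, bandwidth_octaves = 2,
                       d_theta_on_sigma = 1.2) {
  N <- as.integer(N)
  if (N < 32L) stop("N must be >= 32")
  n_s <- as.integer(n_s)
  if (n_s < 1L || n_s > floor(log2(N)) - 2L) {
    stop("n_s must be between 1 and log2(N) - 2")
  }
  M <- 2L^as.integer(ceiling(log2(N)))
  fr <- seq_len(M) - 1L
  fr[fr > M / 2] <- fr[fr > M / 2] - M
  fr <- fr / M
  frow <- matrix(fr, M, M)        # frequency along rows
  fcol <- matrix(fr, M, M, byrow = TRUE)
  rho <- sqrt(frow^2 + fcol^2)
  phi <- atan2(frow, fcol)
  log_k <- bandwidth_octaves * log(2) / (2 * sqrt(2 * log(2)))
  thetas <- (seq_len(n_orient) - 1) * pi / n_orient
  sigma_phi <- (pi / n_orient) / d_theta_on_sigma
  w0 <- 2^(-(seq_len(n_s)))
  filters <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    radial <- matrix(0, M, M)
    nz <- rho > 0
    radial[nz] <- exp(-log(rho[nz] / w0[s])^2 / (2 * log_k^2))
    filters[[s]] <- lapply(thetas, function(th) {
      dphi <- (phi - th + pi) %% (2 * pi) - pi
      radial * exp(-dphi^2 / (2 * sigma_phi^2))
    })
  }
  structure(list(N = N, M = M, n_s = n_s, n_orient = n_orient,
                 w0 = w0, thetas = thetas,
                 bandwidth_octaves = bandwidth_octaves,
                 sigma_phi = sigma_phi, filters = filters),
            class = "log_gabor_bank")
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat(sprintf(
    "<log_gabor_bank> %d scales x %d orientations, size %d (work %d), w0 = %s\n",
    x$n_s, x$n_orient, x$N, x$M,
    paste(format(x$w0), collapse = ", ")))
  invisible(x)
}

#' Apply a log-Gabor quadrature bank to an image
#'
#' Filters the image in the frequency domain with every (complex, one-sided)
#' filter of the bank and returns the complex responses per scale and
#' orientation. The image is reflect-padded to the bank's working size and
#' responses are cropped back to the input size.
#'
#' @param pixels Numeric matrix with finite values.
#' @param bank A [build_bank()] result whose `N` is at least the largest
#'   image dimension.
#' @return An object of class `quadrature_result` with field `q_nj`
#'   (list over scales of lists over orientations of complex matrices).
#' @export
apply_bank <- function(pixels, bank) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            inherits(bank, "log_gabor_bank"))
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  M <- bank$M
  if (nr > M || nc > M) stop("image larger than filter bank size")
  padded <- matrix(0, M, M)
  ri <- reflect_index(nr, M)
  ci <- reflect_index(nc, M)
  padded <- pixels[ri, ci, drop = FALSE]
  FT <- stats::fft(padded)
  q_nj <- lapply(bank$filters, function(scale_filters) {
    lapply(scale_filters, function(f) {
      q <- stats::fft(FT * f, inverse = TRUE) / (M * M)
      q[seq_len(nr), seq_len(nc), drop = FALSE]
    })
  })
  structure(list(q_nj = q_nj, q_n = NULL, P = NULL, sigma = NULL, LP = NULL,
                 bank = bank, dim = c(nr, nc)),
            class = "quadrature_result")
}

# Indices that extend 1..n to length m by repeated mirror reflection.
reflect_index <- function(n, m) {
  if (n == m) return(seq_len(n))
  period <- c(seq_len(n), rev(seq_len(n)))
  period[((seq_len(m) - 1L) %% (2L * n)) + 1L]
}

#' Sum quadrature responses over orientations
#'
#' Fills the per-scale combined response q_n as the complex sum of the eight
#' orientation responses.
#'
#' @param result A `quadrature_result` with `q_nj` present.
#' @return The result with field `q_n` filled.
#' @export
combine_orientations <- function(result) {
  stopifnot(inherits(result, "quadrature_result"), !is.null(result$q_nj))
  result$q_n <- lapply(result$q_nj, function(qs) Reduce(`+`, qs))
  result
}

#' Combine scales into the overall filter-bank response
#'
#' Fills P as the |q_n|^3-weighted mean of the per-scale responses,
#' P = sum_n q_n |q_n|^3 / sum_n |q_n|^3. Where the denominator vanishes
#' (all responses zero) P is defined as 0.
#'
#' @param result A `quadrature_result` with `q_n` present.
#' @return The result with field `P` filled.
#' @export
combine_scales <- function(result) {
  stopifnot(inherits(result, "quadrature_result"), !is.null(result$q_n))
  w <- lapply(result$q_n, function(q) Mod(q)^3)
  num <- Reduce(`+`, Map(function(q, ww) q * ww, result$q_n, w))
  den <- Reduce(`+`, w)
  P <- num
  nz <- den > 0
  P[nz] <- num[nz] / den[nz]
  P[!nz] <- 0 + 0i
  result$P <- P
  result
}

#' Regularized vesselness map
#'
#' Fills LP = Re(P |P| / (|P|^2 + sigma^2)). The regularization constant
#' sigma suppresses noise-driven responses; for sigma >= 1 the map is bounded
#' by |P|^2/(|P|^2 + sigma^2) < 1 and its value is insensitive to the exact
#' choice, so the default is 3.
#'
#' @param result A `quadrature_result` with `P` present.
#' @param sigma Positive regularization constant.
#' @return The result with fields `sigma` and `LP` filled.
#' @export
vesselness <- function(result, sigma = 3) {
  stopifnot(inherits(result, "quadrature_result"), !is.null(result$P))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  m <- Mod(result$P)
  result$sigma <- sigma
  result$LP <- Re(result$P * m / (m^2 + sigma^2))
  result
}

#' Log-Gabor vessel enhancement
#'
#' Chains [build_bank()], [apply_bank()], [combine_orientations()],
#' [combine_scales()] and [vesselness()]: the standard two-scale quadrature
#' vesselness map of a frame. The map is invariant to constant offsets (the
#' filters have no DC response) and bounded in (-1, 1) for sigma >= 1.
#'
#' @param pixels Numeric matrix.
#' @param n_s Number of scales (two scales resolve both the large vessels
#'   and the bulk of the small ones at typical frame sizes).
#' @param sigma Regularization constant for [vesselness()].
#' @param ... Passed to [build_bank()].
#' @return Numeric matrix, the vesselness map LP.
#' @export
enhance <- function(pixels, n_s = 2L, sigma = 3, ...) {
  bank <- build_bank(max(dim(pixels)), n_s = n_s, ...)
  res <- apply_bank(pixels, bank)
  res <- combine_orientations(res)
  res <- combine_scales(res)
  res <- vesselness(res, sigma = sigma)
  res$LP
}
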