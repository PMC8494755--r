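#' Vessel-free leakage image of one frame
#'
#' The single-frame leakage extraction: small vessels are removed by
#' oriented openings ([remove_small_vessels()]), large vessels are
#' segmented via perpendicular-residue enhancement, quadrature vesselness
#' and hysteresis ([large_vessel_mask()]) and then infilled
#' ([remove_large_vessels()]).
#'
#' @param image An [ffa_image()].
#' @param params An [opening_params()].
#' @param q_low,q_high,n_s,sigma Passed to [large_vessel_mask()].
#' @return A [leakage_image()] with attribute `vessel_mask`.
#' @export
extract_leakage <- function(image, params = opening_params(),
                            q_low = 0.90, q_high = 0.98, n_s = 2L,
                            sigma = 3) {
  small_removed <- remove_small_vessels(image, params)
  vm <- large_vessel_mask(image, params, q_low, q_high, n_s, sigma)
  out <- remove_large_vessels(small_removed, vm, params)
  attr(out, "vessel_mask") <- vm
  out
}

#' Run the full leakage-quantification pipeline on a sequence
#'
#' Registers every frame to the first timepoint ([register_sequence()]),
#' extracts the vessel-free leakage image of each registered frame
#' ([extract_leakage()]) and quantifies the leakage time series over the
#' shared analysis ROI ([quantify_sequence()]).
#'
#' @param seq An [ffa_sequence()].
#' @param params An [opening_params()].
#' @param T_b,L_0 Reference-point parameters, see [reference_point()].
#' @param q_low,q_high,n_s,sigma Vessel segmentation parameters.
#' @param grid_step Resampling step in minutes.
#' @param pooled_otsu Use one sequence-wide leakage threshold; see
#'   [quantify_sequence()].
#' @param ... Passed to [register_pair()] via [register_sequence()].
#' @return A list of class `ffa_result`: `series` (a `leakage_series`
#'   tibble), `registration` (the [register_sequence()] result),
#'   `leakage_images` and `vessel_masks` per registered frame.
#' @export
run_pipeline <- function(seq, params = opening_params(), T_b = 20L,
                         L_0 = 30L, q_low = 0.90, q_high = 0.98, n_s = 2L,
                         sigma = 3, grid_step = 1, pooled_otsu = FALSE, ...) {
  reg <- register_sequence(seq, T_b, L_0, params, q_low, q_high, n_s,
                           sigma, ...)
  # leakage is extracted on the native (unresampled) frames and the leakage
  # images are then carried into the fixed coordinate frame, so the
  # morphological operators see identical noise statistics in every frame
  kept <- which(reg$ok)
  leaks_native <- lapply(seq$frames[kept], extract_leakage, params = params,
                         q_low = q_low, q_high = q_high, n_s = n_s,
                         sigma = sigma)
  fixed_dim <- dim(seq$frames[[1L]]$pixels)
  leaks <- Map(function(l, tr) {
    w <- warp(ffa_image(l$values, l$roi, l$time_min), tr, fixed_dim)
    out <- leakage_image(w$pixels, w$roi, w$time_min)
    attr(out, "vessel_mask") <- attr(l, "vessel_mask")
    out
  }, leaks_native, reg$transforms[kept])
  frames <- reg$registered$frames
  times <- vapply(frames, function(f) f$time_min, numeric(1))
  series <- quantify_sequence(leaks, times, analysis_roi = reg$analysis_roi,
                              grid_step = grid_step,
                              pooled_otsu = pooled_otsu)
  structure(list(series = series, registration = reg,
                 leakage_images = leaks,
                 vessel_masks = lapply(leaks, attr, "vessel_mask")),
            class = "ffa_result")
}

#' @export
print.ffa_result <- function(x, ...) {
  cat("<ffa_result>\n")
  print(x$registration)
  print(tidy.leakage_series(x$series))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `ffa_result`.
#' @method tidy ffa_result
#' @export
tidy.ffa_result <- function(x, ...) tidy.leakage_series(x$series)

#' @rdname run_pipeline
#' @param object An `ffa_result`.
#' @method glance ffa_result
#' @export
glance.ffa_result <- function(object, ...) glance.leakage_series(object$series)

#' @rdname run_pipeline
#' @method autoplot ffa_result
#' @export
autoplot.ffa_result <- function(object, ...) autoplot.leakage_series(object$series)
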