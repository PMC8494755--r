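#' Otsu threshold over a 256-bin histogram
#'
#' The threshold maximizing the between-class variance of a 256-bin
#' histogram spanning the value range; ties are broken towards the lower
#' threshold. The returned value is a bin edge, so `values >= T` assigns the
#' upper class to the foreground.
#'
#' @param values Numeric vector, matrix or sample of intensities with at
#'   least two distinct values.
#' @return The threshold, a single number.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L || min(v) == max(v)) stop("degenerate histogram")
  mn <- min(v)
  mx <- max(v)
  nb <- 256L
  bin <- pmin(floor((v - mn) / (mx - mn) * nb) + 1L, nb)
  counts <- as.numeric(tabulate(bin, nbins = nb))
  centers <- mn + (seq_len(nb) - 0.5) * (mx - mn) / nb
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * centers)
  n <- w0[nb]
  mt <- m0[nb]
  k <- seq_len(nb - 1L)
  valid <- w0[k] > 0 & w0[k] < n
  sb <- rep(-Inf, nb - 1L)
  sb[valid] <- (mt * w0[k][valid] - m0[k][valid] * n)^2 /
    (w0[k][valid] * (n - w0[k][valid]))
  kstar <- which.max(sb)    # which.max takes the first (lowest) maximizer
  mn + kstar * (mx - mn) / nb
}

#' Delineate the leakage region of one frame
#'
#' Applies [otsu_threshold()] to the within-ROI values of the leakage image
#' and returns the mask of in-ROI pixels at or above the threshold. A frame
#' without leakage contrast (degenerate histogram) yields an empty mask and
#' a warning.
#'
#' @param leak A [leakage_image()] (vessel-free leakage image).
#' @param analysis_roi Logical matrix: the shared analysis ROI.
#' @return `list(mask, threshold)`.
#' @export
leakage_mask <- function(leak, analysis_roi = leak$roi) {
  stopifnot(inherits(leak, "leakage_image"),
            identical(dim(analysis_roi), dim(leak$values)))
  t_val <- tryCatch(otsu_threshold(leak$values[analysis_roi]),
                    error = function(e) NA_real_)
  if (is.na(t_val)) {
    warning("no leakage contrast in frame; empty leakage mask")
    return(list(mask = array(FALSE, dim(leak$values)), threshold = NA_real_))
  }
  list(mask = (leak$values >= t_val) & analysis_roi, threshold = t_val)
}

series_means <- function(leak_images, analysis_roi) {
  vapply(leak_images, function(l) mean(l$values[analysis_roi]), numeric(1))
}

#' Relative fluorescein intensity series
#'
#' Mean leakage-image intensity over the analysis ROI, minus the first
#' frame's mean, so the first timepoint is exactly 0. Relative values are
#' used because the map from absolute intensity to fluorescein concentration
#' is unknown.
#'
#' @param leak_images List of registered [leakage_image()] objects, time
#'   ordered.
#' @param analysis_roi Logical matrix (shared ROI after registration).
#' @return Numeric vector, one value per frame, first element 0.
#' @export
relative_intensity_series <- function(leak_images, analysis_roi) {
  stopifnot(length(leak_images) >= 2L, sum(analysis_roi) > 0)
  m <- series_means(leak_images, analysis_roi)
  m - m[1L]
}

#' Leakage area fraction series
#'
#' Leakage-mask area divided by the analysis ROI area, per frame.
#'
#' @param masks List of logical leakage masks (subsets of the ROI).
#' @param analysis_roi Logical matrix.
#' @return Numeric vector in \[0, 1\].
#' @export
area_fraction_series <- function(masks, analysis_roi) {
  if (sum(analysis_roi) == 0) stop("empty analysis ROI")
  vapply(masks, function(m) sum(m) / sum(analysis_roi), numeric(1))
}

#' In-region leakage intensity series
#'
#' Sum of leakage-image intensities inside the leakage mask, divided by the
#' analysis ROI area. Reported alongside the maskless relative intensity;
#' the maskless version needs no thresholding step and is usually preferred.
#'
#' @param leak_images List of registered [leakage_image()] objects.
#' @param masks Aligned list of leakage masks.
#' @param analysis_roi Logical matrix.
#' @return Numeric vector, nonnegative.
#' @export
in_region_intensity_series <- function(leak_images, masks, analysis_roi) {
  stopifnot(length(leak_images) == length(masks), sum(analysis_roi) > 0)
  mapply(function(l, m) sum(l$values[m]) / sum(analysis_roi),
         leak_images, masks)
}

#' Resample a time series onto an equally spaced grid
#'
#' Piecewise-linear interpolation onto `seq(min(times), max(times),
#' by = grid_step)`; knots that fall on the grid are reproduced exactly and
#' no extrapolation is performed.
#'
#' @param times Strictly increasing times in minutes (>= 2 points).
#' @param values Values at `times`.
#' @param grid_step Grid spacing in minutes.
#' @param grid Optional explicit grid; must lie within `range(times)`.
#' @return A [tibble::tibble()] with columns `time_min` and `value`.
#' @export
resample_series <- function(times, values, grid_step = 1, grid = NULL) {
  stopifnot(length(times) >= 2L, length(times) == length(values),
            all(diff(times) > 0))
  if (is.null(grid)) grid <- seq(min(times), max(times), by = grid_step)
  if (any(grid < min(times) - 1e-9) || any(grid > max(times) + 1e-9)) {
    stop("grid point outside the observed time range (no extrapolation)")
  }
  tibble::tibble(time_min = grid,
                 value = stats::approx(times, values, xout = grid)$y)
}

#' Quantify a registered leakage sequence
#'
#' Computes the three leakage readouts per timepoint — relative fluorescein
#' intensity, Otsu-delineated leakage area over ROI area, and in-region
#' intensity over ROI area — together with the per-frame Otsu threshold, on
#' the native time grid and linearly resampled onto an equally spaced grid.
#'
#' The leakage threshold is computed per frame by default, matching the
#' single-frame delineation workflow. With `pooled_otsu = TRUE` one Otsu
#' threshold is computed from the pooled in-ROI values of all frames and
#' applied to every frame: for time-series area analysis this keeps the
#' delineation criterion comparable across timepoints, which per-frame
#' thresholds are not when early frames have weak leakage contrast.
#'
#' @param leak_images Time-ordered list of registered [leakage_image()]s.
#' @param times Acquisition times in minutes (same length).
#' @param analysis_roi Shared analysis ROI (intersection of registered ROIs).
#' @param grid_step Resampling step in minutes.
#' @param pooled_otsu Use one sequence-wide Otsu threshold instead of
#'   per-frame thresholds.
#' @return A tibble of class `leakage_series` with columns `time_min`,
#'   `rel_intensity`, `area_fraction`, `in_region_intensity`, `otsu_T`;
#'   attributes `resampled` (same quantities on the uniform grid) and
#'   `analysis_roi`.
#' @export
quantify_sequence <- function(leak_images, times,
                              analysis_roi = leak_images[[1L]]$roi,
                              grid_step = 1, pooled_otsu = FALSE) {
  stopifnot(length(leak_images) >= 2L, length(times) == length(leak_images),
            all(diff(times) > 0))
  if (pooled_otsu) {
    t_pool <- otsu_threshold(unlist(lapply(leak_images, function(l) {
      l$values[analysis_roi]
    })))
    masks <- lapply(leak_images, function(l) {
      (l$values >= t_pool) & analysis_roi
    })
    thr <- rep(t_pool, length(leak_images))
  } else {
    lm <- lapply(leak_images, leakage_mask, analysis_roi = analysis_roi)
    masks <- lapply(lm, `[[`, "mask")
    thr <- vapply(lm, `[[`, numeric(1), "threshold")
  }
  rel <- relative_intensity_series(leak_images, analysis_roi)
  area <- area_fraction_series(masks, analysis_roi)
  inreg <- in_region_intensity_series(leak_images, masks, analysis_roi)
  native <- tibble::tibble(time_min = times, rel_intensity = rel,
                           area_fraction = area,
                           in_region_intensity = inreg, otsu_T = thr)
  grid <- seq(min(times), max(times), by = grid_step)
  res <- tibble::tibble(
    time_min = grid,
    rel_intensity = resample_series(times, rel, grid = grid)$value,
    area_fraction = resample_series(times, area, grid = grid)$value,
    in_region_intensity = resample_series(times, inreg, grid = grid)$value)
  structure(native, resampled = res, analysis_roi = analysis_roi,
            masks = masks,
            class = c("leakage_series", class(native)))
}

#' @rdname quantify_sequence
#' @param x A `leakage_series`.
#' @param ... Unused.
#' @method tidy leakage_series
#' @export
tidy.leakage_series <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time_min", "rel_intensity",
                                 "area_fraction", "in_region_intensity",
                                 "otsu_T")])
}

#' @rdname quantify_sequence
#' @method glance leakage_series
#' @export
glance.leakage_series <- function(x, ...) {
  fit <- stats::lm(rel_intensity ~ time_min, data = x)
  tibble::tibble(n_frames = nrow(x),
                 t_span_min = diff(range(x$time_min)),
                 final_rel_intensity = x$rel_intensity[nrow(x)],
                 final_area_fraction = x$area_fraction[nrow(x)],
                 intensity_slope_per_min = unname(stats::coef(fit)[2L]))
}

#' Plot a leakage time series
#'
#' Line plots of the three leakage readouts against time.
#'
#' @param object A `leakage_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leakage_series
#' @export
autoplot.leakage_series <- function(object, ...) {
  df <- tidy.leakage_series(object)
  long <- tibble::tibble(
    time_min = rep(df$time_min, 3L),
    quantity = rep(c("relative intensity", "area fraction",
                     "in-region intensity"), each = nrow(df)),
    value = c(df$rel_intensity, df$area_fraction, df$in_region_intensity))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time after injection (min)", y = NULL)
}
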