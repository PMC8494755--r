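#' Relative difference against a reference value
#'
#' `|x - ref| / ref`, the agreement measure used for comparing method
#' quantifications with reference annotations. Note the definition is not
#' symmetric in its arguments: the second argument is the reference.
#'
#' @param x Measured value(s).
#' @param ref Reference value(s), strictly positive.
#' @return Relative difference(s) as fractions.
#' @export
relative_difference <- function(x, ref) {
  if (any(ref <= 0)) stop("reference values must be > 0")
  abs(x - ref) / ref
}

#' Agreement table between a method series and two reference annotations
#'
#' For each reference series (annotator), summarizes the relative difference
#' of the method series and of the other annotator's series against it as
#' mean +/- standard deviation over frames, plus the Pearson correlation per
#' pair. A constant pair has undefined correlation and is reported as `NA`.
#' Intensity comparisons are expected on unnormalized values so the first
#' frame does not degenerate to zero for every series.
#'
#' @param method Numeric series from the method.
#' @param ref1,ref2 Reference series (e.g. from two annotators), aligned
#'   with `method` and strictly positive.
#' @return A [tibble::tibble()] with columns `reference`, `series`,
#'   `mean_rel_diff`, `sd_rel_diff`, `pearson`.
#' @export
agreement_table <- function(method, ref1, ref2) {
  n <- length(method)
  if (length(ref1) != n || length(ref2) != n) {
    stop("series lengths differ")
  }
  series <- list(method = method, ref1 = ref1, ref2 = ref2)
  refs <- list(ref1 = ref1, ref2 = ref2)
  rows <- list()
  for (rn in names(refs)) {
    for (sn in names(series)) {
      rd <- relative_difference(series[[sn]], refs[[rn]])
      s_a <- stats::sd(series[[sn]])
      s_b <- stats::sd(refs[[rn]])
      pe <- if (is.na(s_a) || is.na(s_b) || s_a == 0 || s_b == 0) {
        NA_real_
      } else {
        stats::cor(series[[sn]], refs[[rn]])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reference = rn, series = sn,
        mean_rel_diff = mean(rd), sd_rel_diff = stats::sd(rd), pearson = pe)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate leakage quantifications against annotation masks
#'
#' Computes, per frame, the leakage fluorescence intensity (sum of
#' leakage-image values inside a mask; set `raw_pixels = TRUE` to sum the
#' registered raw frame instead) and the leakage area, for the method's
#' masks and for two annotators' masks, then summarizes each quantity with
#' [agreement_table()].
#'
#' @param leak_images Registered [leakage_image()] list (and, if
#'   `raw_pixels`, matching raw frames via `raw_images`).
#' @param method_masks,g1_masks,g2_masks Aligned lists of logical masks.
#' @param raw_pixels Sum raw frame intensities instead of leakage-image
#'   intensities.
#' @param raw_images Raw [ffa_image()] list, required when `raw_pixels`.
#' @return List with `intensity` and `area` agreement tibbles plus the
#'   per-frame quantity tibble `values`.
#' @export
evaluate_annotations <- function(leak_images, method_masks, g1_masks,
                                 g2_masks, raw_pixels = FALSE,
                                 raw_images = NULL) {
  n <- length(leak_images)
  stopifnot(length(method_masks) == n, length(g1_masks) == n,
            length(g2_masks) == n)
  grids <- if (raw_pixels) {
    stopifnot(!is.null(raw_images), length(raw_images) == n)
    lapply(raw_images, function(f) f$pixels)
  } else {
    lapply(leak_images, function(l) l$values)
  }
  isum <- function(masks) {
    mapply(function(g, m) sum(g[m]), grids, masks)
  }
  asum <- function(masks) vapply(masks, sum, numeric(1))
  vals <- tibble::tibble(
    frame = seq_len(n),
    L = isum(method_masks), L_g1 = isum(g1_masks), L_g2 = isum(g2_masks),
    A = asum(method_masks), A_g1 = asum(g1_masks), A_g2 = asum(g2_masks))
  list(intensity = agreement_table(vals$L, vals$L_g1, vals$L_g2),
       area = agreement_table(vals$A, vals$A_g1, vals$A_g2),
       values = vals)
}

#' Read an annotation mask from a 0/255 PNG
#'
#' @param path PNG path; any strictly positive pixel is foreground.
#' @return Logical matrix.
#' @export
read_annotation_mask <- function(path) {
  read_gray(path)$pixels > 0
}
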