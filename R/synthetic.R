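#' Specification of a synthetic FFA phantom
#'
#' Describes an FFA-like phantom eye with full ground truth: a dark frame
#' with a circular bright field of view, a branching tree of bright tubular
#' vessels converging on an optic-disk point, smooth compactly supported
#' leakage blobs whose amplitude and support grow over timepoints, additive
#' Gaussian noise, and an unknown rigid jitter per timepoint. Blob profiles
#' are raised cosines, so the "true support" used by area-recovery tests is
#' well defined even though real leakage has no sharp boundary.
#'
#' @param size Frame side length in pixels.
#' @param roi_radius Field-of-view disk radius in pixels.
#' @param roi_center Disk center `c(row, col)`; frame center by default.
#' @param n_primaries Number of primary vessels radiating from the
#'   convergence point.
#' @param branch_depth Branching depth (0 = unbranched primaries).
#' @param diameter_range Vessel diameter range `c(min, max)` in pixels;
#'   primaries start at the maximum and children taper.
#' @param tortuosity Standard deviation (radians) of the per-step heading
#'   perturbation of vessel centerlines; 0 gives straight vessels. The
#'   default keeps the gentle curvature of retinal vessels, whose course
#'   stays locally straight at the scale of a line-fit window.
#' @param vessel_intensity Peak vessel brightness above background.
#' @param background Background level inside the field of view.
#' @param times Acquisition times in minutes.
#' @param n_blobs Number of leakage blobs.
#' @param amplitudes Per-timepoint leakage amplitude series A_t, expressed
#'   as the field-of-view-mean intensity contributed by the blobs (the blob
#'   field is normalized so its in-ROI mean equals A_t); default linear from
#'   1 to 8.
#' @param blob_radius0 Baseline blob support radius in pixels.
#' @param growth Support-radius growth factor per timepoint (1 = constant
#'   support).
#' @param jitter_max_px Maximum rigid translation magnitude per timepoint.
#' @param jitter_max_deg Maximum rigid rotation per timepoint (degrees).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param convergence_offset Offset `c(row, col)` of the vessel convergence
#'   point from the ROI center; default shifts it towards the nasal side as
#'   in fundus images.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 512L, roi_radius = round(0.45 * size),
                         roi_center = c((size + 1) / 2, (size + 1) / 2),
                         n_primaries = 6L, branch_depth = 2L,
                         diameter_range = c(2, 8), tortuosity = 0.05,
                         vessel_intensity = 120, background = 20,
                         times = c(1, 3, 5, 7, 9), n_blobs = 3L,
                         amplitudes = NULL,
                         blob_radius0 = round(0.08 * size), growth = 1.15,
                         jitter_max_px = 25, jitter_max_deg = 8,
                         noise_sd = 4,
                         convergence_offset = c(0, -round(0.20 * roi_radius))) {
  stopifnot(size >= 64, roi_radius > 8, n_primaries >= 1,
            branch_depth >= 0, all(diameter_range > 0),
            length(times) >= 2, all(diff(times) > 0),
            jitter_max_px >= 0, jitter_max_deg >= 0, noise_sd >= 0)
  if (is.null(amplitudes)) {
    amplitudes <- seq(1, 8, length.out = length(times))
  }
  stopifnot(length(amplitudes) == length(times))
  structure(list(size = as.integer(size), roi_radius = roi_radius,
                 roi_center = roi_center, n_primaries = as.integer(n_primaries),
                 branch_depth = as.integer(branch_depth),
                 diameter_range = diameter_range, tortuosity = tortuosity,
                 vessel_intensity = vessel_intensity, background = background,
                 times = times, n_blobs = as.integer(n_blobs),
                 amplitudes = amplitudes, blob_radius0 = blob_radius0,
                 growth = growth, jitter_max_px = jitter_max_px,
                 jitter_max_deg = jitter_max_deg, noise_sd = noise_sd,
                 convergence_offset = convergence_offset),
            class = "phantom_spec")
}

# Grow the centerline segment list of the vessel tree (RNG already seeded).
tree_segments <- function(spec) {
  cp <- spec$roi_center + spec$convergence_offset
  dmin <- spec$diameter_range[1L]
  dmax <- spec$diameter_range[2L]
  segs <- list()
  grow <- function(p0, heading, len, diam, depth) {
    step <- max(8, len / 8)
    n_steps <- max(2L, ceiling(len / step))
    pts <- matrix(0, n_steps + 1L, 2L)
    pts[1L, ] <- p0
    for (i in seq_len(n_steps)) {
      heading <- heading + stats::rnorm(1L, 0, spec$tortuosity)
      pts[i + 1L, ] <- pts[i, ] + step * c(sin(heading), cos(heading))
    }
    for (i in seq_len(n_steps)) {
      segs[[length(segs) + 1L]] <<- list(p0 = pts[i, ], p1 = pts[i + 1L, ],
                                         diam = diam)
    }
    if (depth < spec$branch_depth) {
      at <- sample(seq(max(2L, ceiling(n_steps / 2)), n_steps + 1L), 1L)
      side <- sample(c(-1, 1), 1L)
      # acute branching keeps daughters on a roughly radial outward course,
      # as in the retinal vasculature converging on the optic disk
      grow(pts[at, ], heading + side * stats::runif(1L, 0.25, 0.5),
           len * 0.6, max(dmin, diam * 0.65), depth + 1L)
    }
    pts[n_steps + 1L, ]
  }
  for (k in seq_len(spec$n_primaries)) {
    ang <- 2 * pi * (k - 1) / spec$n_primaries +
      stats::runif(1L, -0.5, 0.5) * pi / spec$n_primaries
    grow(cp, ang, 0.85 * spec$roi_radius, dmax, 0L)
  }
  list(segments = segs, convergence_point = cp)
}

render_tree <- function(spec, tree) {
  n <- spec$size
  diams <- vapply(tree$segments, `[[`, numeric(1), "diam")
  buckets <- split(tree$segments, round(diams))
  profile <- matrix(0, n, n)
  vmask <- matrix(FALSE, n, n)
  cl <- matrix(FALSE, n, n)
  for (b in names(buckets)) {
    d <- as.numeric(b)
    m <- matrix(FALSE, n, n)
    for (s in buckets[[b]]) {
      px <- digital_segment(round(s$p0), round(s$p1))
      keep <- px[, 1L] >= 1 & px[, 1L] <= n & px[, 2L] >= 1 & px[, 2L] <= n
      m[px[keep, , drop = FALSE]] <- TRUE
    }
    if (!any(m)) next
    dist <- EBImage::distmap(1 - m)
    profile <- pmax(profile, exp(-log(2) * (2 * dist / d)^2))
    vmask <- vmask | dist <= d / 2
    cl <- cl | m
  }
  list(profile = profile, vessel_mask = vmask, centerlines = cl)
}

#' Generate a synthetic vessel tree
#'
#' Renders the branching tree of bright tubular vessels (Gaussian
#' cross-section, half maximum at the nominal vessel radius) converging on
#' the phantom's optic-disk point. Fully deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed fixing every random draw.
#' @return List with `vessel_image` (intensities), `vessel_mask`,
#'   `centerlines` and `convergence_point`.
#' @export
generate_vessel_tree <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  tree <- with_seed(seed, tree_segments(spec))
  rend <- render_tree(spec, tree)
  cp <- tree$convergence_point
  if (cp[1L] < 1 || cp[1L] > spec$size || cp[2L] < 1 || cp[2L] > spec$size) {
    stop("convergence point outside the frame")
  }
  list(vessel_image = spec$vessel_intensity * rend$profile,
       vessel_mask = rend$vessel_mask, centerlines = rend$centerlines,
       convergence_point = cp)
}

#' Generate a synthetic FFA sequence with ground truth
#'
#' Composites background, vessel tree and growing leakage blobs in a fixed
#' "retina" coordinate frame, then forms each timepoint's frame by sampling
#' the retina through the true rigid jitter transform (frame 0 has identity
#' jitter), applying the static circular camera aperture, and adding noise.
#' The stored truth transforms map each frame's coordinates to the
#' first-frame (retina) coordinates, i.e. they are exactly what registration
#' is asked to recover.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return An object of class `ffa_phantom`: `sequence` (an
#'   [ffa_sequence()]), `truth` (list with `transforms`, `support_masks`,
#'   `half_support_masks`, `amplitudes`, `support_fraction`, `vessel_mask`,
#'   `centerlines`, `convergence_point`) and `spec`.
#' @export
generate_sequence <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  n_t <- length(spec$times)
  out <- with_seed(seed, {
    tree <- tree_segments(spec)
    rend <- render_tree(spec, tree)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    disk <- (rows - spec$roi_center[1L])^2 +
      (cols - spec$roi_center[2L])^2 <= spec$roi_radius^2
    # blob centers in the retina frame, inside the field of view
    centers <- matrix(0, spec$n_blobs, 2L)
    for (b in seq_len(spec$n_blobs)) {
      ang <- stats::runif(1L, 0, 2 * pi)
      rad <- stats::runif(1L, 0.15, 0.55) * spec$roi_radius
      centers[b, ] <- spec$roi_center + rad * c(sin(ang), cos(ang))
    }
    radii0 <- stats::runif(spec$n_blobs, 0.8, 1.2) * spec$blob_radius0
    transforms <- vector("list", n_t)
    frames <- vector("list", n_t)
    support <- vector("list", n_t)
    half_support <- vector("list", n_t)
    support_fraction <- numeric(n_t)
    vessel_img <- spec$vessel_intensity * rend$profile
    grid <- cbind(as.vector(rows), as.vector(cols))
    for (i in seq_len(n_t)) {
      leak <- matrix(0, n, n)
      supp <- matrix(FALSE, n, n)
      half <- matrix(FALSE, n, n)
      for (b in seq_len(spec$n_blobs)) {
        rb <- radii0[b] * spec$growth^(i - 1L)
        dist <- sqrt((rows - centers[b, 1L])^2 + (cols - centers[b, 2L])^2)
        inside <- dist < rb
        leak[inside] <- leak[inside] +
          0.5 * (1 + cos(pi * dist[inside] / rb))
        supp <- supp | inside
        half <- half | (dist < rb / 2)
      }
      # A_t is the programmed field-of-view-mean leakage contribution: the
      # blob field is normalized so its in-ROI mean equals A_t exactly, so
      # peak brightness and support area both grow over time (as leaking
      # dye accumulates and spreads) while the integrated signal is A_t
      leak <- leak * (spec$amplitudes[i] * sum(disk) / sum(leak[disk]))
      clean <- spec$background + vessel_img + leak
      if (i == 1L) {
        transforms[[i]] <- rigid_transform(0, c(0, 0), spec$roi_center)
        px <- clean
      } else {
        ang <- stats::runif(1L, -1, 1) * spec$jitter_max_deg * pi / 180
        tdir <- stats::runif(1L, 0, 2 * pi)
        tmag <- stats::runif(1L, 0, spec$jitter_max_px)
        transforms[[i]] <- rigid_transform(ang,
                                           tmag * c(sin(tdir), cos(tdir)),
                                           spec$roi_center)
        src <- transform_points(transforms[[i]], grid)
        v <- bilinear_sample(clean, src[, 1L], src[, 2L],
                             fill = spec$background)
        px <- matrix(as.numeric(v), n, n)
      }
      px[!disk] <- 1
      px <- px + stats::rnorm(n * n, 0, spec$noise_sd)
      px[px < 0] <- 0
      frames[[i]] <- ffa_image(px, roi = disk, time_min = spec$times[i])
      support[[i]] <- supp
      half_support[[i]] <- half
      support_fraction[i] <- sum(supp & disk) / sum(disk)
    }
    list(sequence = ffa_sequence(frames, eye_id = sprintf("phantom-%d", seed)),
         truth = list(transforms = transforms, support_masks = support,
                      half_support_masks = half_support,
                      amplitudes = spec$amplitudes,
                      support_fraction = support_fraction,
                      vessel_mask = rend$vessel_mask,
                      centerlines = rend$centerlines,
                      convergence_point = tree$convergence_point,
                      roi_mask = disk))
  })
  structure(c(out, list(spec = spec)), class = "ffa_phantom")
}

#' @export
print.ffa_phantom <- function(x, ...) {
  cat(sprintf("<ffa_phantom> %dx%d, %d timepoints, %d blobs, jitter <= %.0f px / %.0f deg\n",
              x$spec$size, x$spec$size, length(x$spec$times),
              x$spec$n_blobs, x$spec$jitter_max_px, x$spec$jitter_max_deg))
  invisible(x)
}

#' Perturb an annotation mask
#'
#' Models inter-annotator variability in delineating a leakage border:
#' shifts the mask boundary outward (`radius > 0`, dilation) or inward
#' (`radius < 0`, erosion) in the signed-distance sense and adds a seeded,
#' spatially smooth perturbation to the boundary position.
#'
#' @param mask Logical matrix.
#' @param radius Signed boundary shift in pixels.
#' @param boundary_noise Standard deviation (pixels) of the smooth boundary
#'   perturbation field.
#' @param seed Integer seed for the perturbation field.
#' @return Perturbed logical mask.
#' @export
perturb_annotation <- function(mask, radius = 0, boundary_noise = 0,
                               seed = 1L) {
  stopifnot(is.logical(mask))
  if (radius == 0 && boundary_noise == 0) return(mask)
  sd_in <- EBImage::distmap(mask * 1)
  sd_out <- EBImage::distmap((!mask) * 1)
  signed <- ifelse(mask, sd_in, -sd_out)
  eps <- 0
  if (boundary_noise > 0) {
    z <- with_seed(seed,
                   matrix(stats::rnorm(length(mask)), nrow(mask), ncol(mask)))
    z <- EBImage::gblur(z, sigma = 4)
    eps <- boundary_noise * z / stats::sd(z)
  }
  (signed + radius + eps) > 0
}
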