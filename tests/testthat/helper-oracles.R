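# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's computational paths (EBImage
# morphology, igraph labeling, vectorized Otsu).

reflect_idx <- function(n, p) c(rev(seq_len(p)), seq_len(n), n - seq_len(p) + 1)

# Grayscale opening by explicit shift-and-min / shift-and-max over the
# structuring-element offsets, on a mirror-padded image.
oracle_gray_open <- function(values, se) {
  nr <- nrow(values); nc <- ncol(values)
  anchor <- c(nrow(se) %/% 2 + 1, ncol(se) %/% 2 + 1)
  offs <- which(se, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - anchor[1]
  offs[, 2] <- offs[, 2] - anchor[2]
  kr <- max(abs(offs[, 1])); kc <- max(abs(offs[, 2]))
  pr <- 2 * kr + 1; pc <- 2 * kc + 1
  p <- values[reflect_idx(nr, pr), reflect_idx(nc, pc)]
  er_nr <- nr + 2 * kr; er_nc <- nc + 2 * kc
  er <- matrix(Inf, er_nr, er_nc)
  for (k in seq_len(nrow(offs))) {
    er <- pmin(er, p[(pr - kr + 1 + offs[k, 1]):(pr - kr + er_nr + offs[k, 1]),
                    (pc - kc + 1 + offs[k, 2]):(pc - kc + er_nc + offs[k, 2])])
  }
  di <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(offs))) {
    di <- pmax(di, er[(kr + 1 - offs[k, 1]):(kr + nr - offs[k, 1]),
                      (kc + 1 - offs[k, 2]):(kc + nc - offs[k, 2])])
  }
  di
}

oracle_small_vessel_removal <- function(values, l_sv, n_angles = 8) {
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  Reduce(pmin, lapply(angles, function(a) {
    oracle_gray_open(values, line_structuring_element(l_sv, a))
  }))
}

oracle_large_vessel_enhancement <- function(values, l_lv, n_angles = 8) {
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  op <- lapply(angles, function(a) {
    oracle_gray_open(values, line_structuring_element(l_lv, a))
  })
  perp <- ((seq_len(n_angles) - 1 + n_angles / 2) %% n_angles) + 1
  Reduce(pmax, Map(function(i, j) op[[i]] - op[[j]], seq_len(n_angles), perp))
}

# Queue-based flood fill over 8-connectivity.
oracle_flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- rr + (cc - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

oracle_hysteresis <- function(values, t_low, t_high) {
  lab <- oracle_flood_components(values >= t_low)
  keep <- unique(lab[values >= t_high])
  keep <- keep[keep > 0]
  array(lab %in% keep, dim(values))
}

# Exhaustive Otsu: loop over the 255 candidate splits of a 256-bin
# histogram computing class weights and means directly.
oracle_otsu <- function(v) {
  mn <- min(v); mx <- max(v)
  nb <- 256L
  bin <- pmin(floor((v - mn) / (mx - mn) * nb) + 1, nb)
  centers <- mn + (seq_len(nb) - 0.5) * (mx - mn) / nb
  best_k <- NA; best <- -Inf
  for (k in 1:(nb - 1)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(centers[bin[in0]])
    mu1 <- mean(centers[bin[!in0]])
    sb <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_k <- k }
  }
  mn + best_k * (mx - mn) / nb
}

# A filled disk mask.
disk_mask <- function(n, center, radius) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# Shared test-scale phantom conditions: 256 px frames with pipeline
# parameters matched to that scale (see the methods vignette).
test_spec <- function(...) {
  args <- list(size = 256, roi_radius = 115, blob_radius0 = 20)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# 4-connected flood fill (background components; complements the
# 8-connected foreground convention)
oracle_flood4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc <- c + d[2L]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- rr + (cc - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}
test_params <- function() opening_params(15, 17)
test_pipeline_args <- function() list(T_b = 10, L_0 = 15, n_s = 3)
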