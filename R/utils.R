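# Internal helpers shared across the pipeline: reflect padding, 8-connected
# component labeling, bilinear sampling and line rasterization. All pixel
# coordinates are (row, col), 1-based in R code, row increasing downward.

# Pad a matrix by (pr, pc) on each side with mirror (edge-inclusive) reflection.
pad_reflect <- function(m, pr, pc = pr) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (pr >= nr || pc >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(pr)), seq_len(nr), nr - seq_len(pr) + 1L)
  ci <- c(rev(seq_len(pc)), seq_len(nc), nc - seq_len(pc) + 1L)
  m[ri, ci, drop = FALSE]
}

unpad <- function(m, pr, pc, nr, nc) {
  m[(pr + 1L):(pr + nr), (pc + 1L):(pc + nc), drop = FALSE]
}

# 8-connected labeling of a logical matrix via the pixel adjacency graph.
# Returns an integer matrix, 0 = background, components numbered from 1.
label8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0)
  to <- integer(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + d[1L]
    cc <- c + d[2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    nb <- pos[cbind(rr[ok], cc[ok])]
    sel <- nb > 0L
    from <- c(from, seq_along(idx)[ok][sel])
    to <- c(to, nb[sel])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# Count of TRUE 8-neighbors for every pixel of a logical matrix.
neighbor_count8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  s <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  s
}

# Bilinear sampling of matrix m at fractional (r, c) positions.
# Out-of-range positions return `fill` and are reported via attr "inside".
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  inside <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  r0 <- pmin(pmax(floor(r), 1), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  fr[!inside] <- 0
  fc[!inside] <- 0
  i00 <- cbind(r0, c0)
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[cbind(r0 + 1L, c0)] +
    (1 - fr) * fc * m[cbind(r0, c0 + 1L)] +
    fr * fc * m[cbind(r0 + 1L, c0 + 1L)]
  v[!inside] <- fill
  attr(v, "inside") <- inside
  v
}

# Nearest-neighbor sampling (used for masks).
nearest_sample <- function(m, r, c, fill = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- round(r)
  ci <- round(c)
  inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & is.finite(ri) & is.finite(ci)
  out <- rep(fill, length(r))
  out[inside] <- m[cbind(ri[inside], ci[inside])]
  out
}

# Rasterize the full line through `point` along unit direction `dir`
# (both (row, col)) clipped to an nr x nc frame. One pixel per step of the
# major axis. Returns linear (column-major) indices.
rasterize_line <- function(point, dir, nr, nc) {
  if (abs(dir[2L]) >= abs(dir[1L])) {
    cc <- seq_len(nc)
    rr <- round(point[1L] + (cc - point[2L]) * dir[1L] / dir[2L])
    keep <- rr >= 1 & rr <= nr
    rr <- rr[keep]
    cc <- cc[keep]
  } else {
    rr <- seq_len(nr)
    cc <- round(point[2L] + (rr - point[1L]) * dir[2L] / dir[1L])
    keep <- cc >= 1 & cc <= nc
    rr <- rr[keep]
    cc <- cc[keep]
  }
  as.integer(rr + (cc - 1) * nr)
}

# Bresenham-style digital segment between two (row, col) endpoints, inclusive.
digital_segment <- function(p0, p1) {
  dr <- p1[1L] - p0[1L]
  dc <- p1[2L] - p0[2L]
  n <- max(abs(dr), abs(dc))
  if (n == 0) return(matrix(p0, 1L, 2L))
  t <- 0:n
  cbind(round(p0[1L] + t * dr / n), round(p0[2L] + t * dc / n))
}

# Jaccard index of two logical masks.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Run an expression with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  expr
}
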