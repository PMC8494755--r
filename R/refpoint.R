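#' Skeletonize a binary vessel mask
#'
#' Topology-preserving Zhang-Suen thinning to a 1-pixel-wide, 8-connected
#' medial axis. An empty mask yields an empty skeleton.
#'
#' @param mask Logical matrix.
#' @return Logical matrix, the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  sk <- mask > 0
  if (!any(sk)) return(sk)
  nr <- nrow(sk)
  nc <- ncol(sk)
  shift <- function(m, dr, dc) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  repeat {
    removed_any <- FALSE
    for (sub in 1:2) {
      # clockwise neighbors starting north
      p2 <- shift(sk, -1L, 0L);  p3 <- shift(sk, -1L, 1L)
      p4 <- shift(sk, 0L, 1L);   p5 <- shift(sk, 1L, 1L)
      p6 <- shift(sk, 1L, 0L);   p7 <- shift(sk, 1L, -1L)
      p8 <- shift(sk, 0L, -1L);  p9 <- shift(sk, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- sk & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        sk[del] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

#' Vessel skeleton graph
#'
#' Represents a 1-pixel-wide skeleton as a graph: bifurcations (skeleton
#' pixels with at least three 8-neighbors) and terminations (exactly one
#' neighbor) become nodes, and each edge carries the ordered medial-axis
#' pixel chain connecting its two nodes, endpoints included. Thinning
#' produces small blocks of mutually adjacent bifurcation pixels; each such
#' 8-connected cluster is merged into a single node located at the member
#' pixel nearest the cluster centroid. A closed loop without any node is
#' represented as one cyclic edge anchored at its smallest-scan-order pixel.
#'
#' @param skeleton Logical matrix, a thinned skeleton.
#' @return An object of class `vessel_graph` with fields `nodes` (data frame
#'   `id`, `row`, `col`, `type`), `node_pixels` (list of linear pixel indices
#'   per node), `edges` (list of `list(from, to, chain)` where `chain` is a
#'   two-column (row, col) matrix) and `dim`.
#' @export
build_graph <- function(skeleton) {
  stopifnot(is.logical(skeleton))
  nr <- nrow(skeleton)
  nc <- ncol(skeleton)
  deg <- neighbor_count8(skeleton)
  node_px <- skeleton & (deg == 1L | deg >= 3L)
  node_id <- matrix(0L, nr, nc)
  nodes <- list()
  node_pixels <- list()
  add_node <- function(pixels, type) {
    id <- length(nodes) + 1L
    rr <- ((pixels - 1L) %% nr) + 1L
    cc <- ((pixels - 1L) %/% nr) + 1L
    cen <- c(mean(rr), mean(cc))
    best <- which.min((rr - cen[1])^2 + (cc - cen[2])^2)
    nodes[[id]] <<- data.frame(id = id, row = rr[best], col = cc[best],
                               type = type)
    node_pixels[[id]] <<- pixels
    node_id[pixels] <<- id
    id
  }
  bif <- skeleton & deg >= 3L
  if (any(bif)) {
    lab <- label8(bif)
    for (l in seq_len(max(lab))) add_node(which(lab == l), "bifurcation")
  }
  for (p in which(skeleton & deg == 1L)) add_node(p, "termination")

  edges <- list()
  edge_keys <- new.env(hash = TRUE)
  add_edge <- function(from, to, chain_idx) {
    key <- paste(min(chain_idx[1], chain_idx[length(chain_idx)]),
                 max(chain_idx[1], chain_idx[length(chain_idx)]),
                 length(chain_idx),
                 chain_idx[min(2L, length(chain_idx))] +
                   chain_idx[max(1L, length(chain_idx) - 1L)],
                 sep = ":")
    if (!is.null(edge_keys[[key]])) return(invisible())
    edge_keys[[key]] <- TRUE
    rr <- ((chain_idx - 1L) %% nr) + 1L
    cc <- ((chain_idx - 1L) %/% nr) + 1L
    edges[[length(edges) + 1L]] <<- list(from = from, to = to,
                                         chain = cbind(row = rr, col = cc))
  }
  nbrs_of <- function(p) {
    r <- ((p - 1L) %% nr) + 1L
    c <- ((p - 1L) %/% nr) + 1L
    rs <- r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    cs <- c + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    ok <- rs >= 1L & rs <= nr & cs >= 1L & cs <= nc
    q <- rs[ok] + (cs[ok] - 1L) * nr
    q[skeleton[q]]
  }
  visited <- matrix(FALSE, nr, nc)
  for (id in seq_along(nodes)) {
    for (p in node_pixels[[id]]) {
      for (q in nbrs_of(p)) {
        if (node_id[q] == id) next
        if (node_id[q] > 0L) {           # direct node-to-node adjacency
          add_edge(id, node_id[q], c(p, q))
          next
        }
        if (visited[q]) next
        chain <- c(p, q)
        visited[q] <- TRUE
        prev <- p
        cur <- q
        repeat {
          cand <- setdiff(nbrs_of(cur), c(prev, chain))
          nid <- cand[node_id[cand] > 0L]
          if (length(nid)) {
            # prefer a 4-adjacent node pixel, then scan order
            d4 <- abs(((nid - 1L) %% nr) + 1L - (((cur - 1L) %% nr) + 1L)) +
              abs(((nid - 1L) %/% nr) - ((cur - 1L) %/% nr))
            nxt <- nid[order(d4, nid)][1L]
            chain <- c(chain, nxt)
            add_edge(id, node_id[nxt], chain)
            break
          }
          if (length(cand) == 0L) {      # dead end (thinning artifact)
            add_edge(id, node_id[p], chain)
            break
          }
          # prefer 4-adjacent continuation for 8-connected chains
          d4 <- abs(((cand - 1L) %% nr) + 1L - (((cur - 1L) %% nr) + 1L)) +
            abs(((cand - 1L) %/% nr) - ((cur - 1L) %/% nr))
          nxt <- cand[order(d4, cand)][1L]
          chain <- c(chain, nxt)
          visited[nxt] <- TRUE
          prev <- cur
          cur <- nxt
        }
      }
    }
  }
  # pure cycles: skeleton pixels not yet part of any node or traced chain
  left <- skeleton & !visited & node_id == 0L
  if (any(left)) {
    lab <- label8(left)
    for (l in seq_len(max(lab))) {
      comp <- which(lab == l)
      if (!all(deg[comp] == 2L)) next
      anchor <- min(comp)
      id <- add_node(anchor, "cycle")
      chain <- anchor
      prev <- anchor
      cur <- nbrs_of(anchor)[1L]
      while (cur != anchor) {
        chain <- c(chain, cur)
        cand <- setdiff(nbrs_of(cur), prev)
        prev <- cur
        cur <- cand[1L]
      }
      chain <- c(chain, anchor)
      rr <- ((chain - 1L) %% nr) + 1L
      cc <- ((chain - 1L) %/% nr) + 1L
      edges[[length(edges) + 1L]] <- list(from = id, to = id,
                                          chain = cbind(row = rr, col = cc))
    }
  }
  nodes_df <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = integer(0), row = integer(0), col = integer(0),
               type = character(0))
  structure(list(nodes = nodes_df, node_pixels = node_pixels, edges = edges,
                 dim = c(nr, nc)),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes (%d bifurcations, %d terminations), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "bifurcation"),
              sum(x$nodes$type == "termination"), length(x$edges)))
  invisible(x)
}

graph_to_skeleton <- function(graph) {
  sk <- matrix(FALSE, graph$dim[1L], graph$dim[2L])
  for (px in graph$node_pixels) sk[px] <- TRUE
  for (e in graph$edges) sk[e$chain] <- TRUE
  sk
}

node_degrees <- function(graph) {
  d <- integer(nrow(graph$nodes))
  for (e in graph$edges) {
    d[e$from] <- d[e$from] + 1L
    d[e$to] <- d[e$to] + 1L
  }
  d
}

#' Prune short terminal branches of a vessel graph
#'
#' Repeatedly deletes terminal edges (edges with a degree-1 endpoint) whose
#' pixel chains are shorter than `T_b`, re-deriving node degrees between
#' passes, until no such branch remains; removing a branch can expose new
#' short branches, which are removed in later passes. Junction nodes whose
#' degree drops to 2 are absorbed, merging their two incident edges into one
#' chain. Non-terminal edges are never deleted.
#'
#' @param graph A [build_graph()] result.
#' @param T_b Minimum chain length (pixel count) for a terminal branch to
#'   survive; `T_b = 0` leaves the graph unchanged.
#' @return A pruned `vessel_graph`.
#' @export
prune <- function(graph, T_b) {
  stopifnot(inherits(graph, "vessel_graph"), T_b >= 0)
  repeat {
    deg <- node_degrees(graph)
    short <- which(vapply(graph$edges, function(e) {
      e$from != e$to && (deg[e$from] == 1L || deg[e$to] == 1L) &&
        nrow(e$chain) < T_b
    }, logical(1)))
    if (length(short) == 0L) break
    sk <- graph_to_skeleton(graph)
    nr <- graph$dim[1L]
    for (i in short) {
      e <- graph$edges[[i]]
      deg_from <- deg[e$from]
      keep_end <- if (deg_from == 1L) e$to else e$from
      idx <- e$chain[, 1L] + (e$chain[, 2L] - 1L) * nr
      drop <- setdiff(idx, graph$node_pixels[[keep_end]])
      sk[drop] <- FALSE
    }
    # re-thin: junction-cluster pixels kept from a removed branch can leave
    # redundant (non-medial) pixels that would masquerade as bifurcations
    graph <- build_graph(skeletonize(sk))
  }
  graph
}

#' Local total-least-squares line fit along a skeleton chain
#'
#' Fits a straight line to the chain pixels within Euclidean distance `L_0`
#' of the chain point at index `i`: the line passes through the centroid of
#' the in-window points along their principal axis. Total least squares is
#' used so vertical vessels are handled like any other orientation.
#'
#' @param chain Two-column (row, col) matrix of ordered chain pixels.
#' @param i Index of the window center within `chain`.
#' @param L_0 Window radius in pixels.
#' @return `list(point, dir)` with the centroid and unit direction, or
#'   `NULL` if fewer than 2 distinct points fall inside the window.
#' @export
fit_local_line <- function(chain, i, L_0) {
  d2 <- (chain[, 1L] - chain[i, 1L])^2 + (chain[, 2L] - chain[i, 2L])^2
  w <- chain[d2 <= L_0^2, , drop = FALSE]
  w <- unique(w)
  if (nrow(w) < 2L) return(NULL)
  cen <- colMeans(w)
  a <- mean((w[, 1L] - cen[1L])^2)
  cvar <- mean((w[, 2L] - cen[2L])^2)
  b <- mean((w[, 1L] - cen[1L]) * (w[, 2L] - cen[2L]))
  ang <- 0.5 * atan2(2 * b, a - cvar)
  dir <- c(cos(ang), sin(ang))
  list(point = unname(cen), dir = dir)
}

#' Accumulator voting for the vessel convergence point
#'
#' For every chain pixel of every edge (optionally strided), fits the local
#' line ([fit_local_line()]) and rasterizes the full line, clipped to the
#' frame, into an accumulator array, adding one vote per covered pixel.
#' Straight vessel segments oriented towards the optic disk all cast votes
#' through it, so the accumulator maximum marks the convergence point.
#'
#' @param graph A pruned [build_graph()] result.
#' @param L_0 Line-fit window radius in pixels.
#' @param shape Accumulator dimensions, default the graph's frame size.
#' @param stride Vote from every `stride`-th chain pixel (default 1 = all).
#' @return Integer accumulator matrix with attribute `total_votes`, the sum
#'   of in-frame rasterized line lengths.
#' @export
vote <- function(graph, L_0, shape = graph$dim, stride = 1L) {
  stopifnot(inherits(graph, "vessel_graph"), L_0 > 0, stride >= 1L)
  nr <- shape[1L]
  nc <- shape[2L]
  if (length(graph$edges) == 0L) {
    warning("empty vessel graph: zero accumulator")
    a <- matrix(0L, nr, nc)
    attr(a, "total_votes") <- 0L
    return(a)
  }
  all_idx <- vector("list", length(graph$edges))
  for (k in seq_along(graph$edges)) {
    chain <- graph$edges[[k]]$chain
    picks <- seq(1L, nrow(chain), by = stride)
    lines_idx <- vector("list", length(picks))
    for (m in seq_along(picks)) {
      fit <- fit_local_line(chain, picks[m], L_0)
      if (is.null(fit)) next
      lines_idx[[m]] <- rasterize_line(fit$point, fit$dir, nr, nc)
    }
    all_idx[[k]] <- unlist(lines_idx)
  }
  idx <- unlist(all_idx)
  a <- matrix(tabulate(idx, nbins = nr * nc), nr, nc)
  attr(a, "total_votes") <- length(idx)
  a
}

# Morphological closing (5-px disc) plus removal of components smaller than
# min_size pixels: cleans a noisy hysteresis mask ahead of thinning.
condition_mask <- function(mask, min_size = 20L, close_size = 5L) {
  k <- EBImage::makeBrush(close_size, "disc")
  p <- pad_reflect(mask * 1, close_size)
  cm <- EBImage::erode(EBImage::dilate(p, k), k)
  cm <- unpad(cm, close_size, close_size, nrow(mask), ncol(mask)) > 0
  lab <- label8(cm)
  if (max(lab) == 0L) return(cm)
  sz <- tabulate(lab[lab > 0L])
  matrix(lab %in% which(sz >= min_size), nrow(mask), ncol(mask))
}

#' Detect the vessel-convergence reference point
#'
#' Composes [large_vessel_mask()], [skeletonize()], [build_graph()],
#' [prune()] and [vote()], then returns the position of the maximum of the
#' Gaussian-smoothed accumulator. Raw vote maxima are rasterization
#' sensitive, and the lines fitted along one vessel cross the optic disk in
#' a fan a few pixels wide; `accumulator_sd` should roughly match that fan
#' so the smoothed peak integrates it.
#' Ties are broken by scan order (smallest row,
#' then smallest column). The point is stable across timepoints of one eye
#' and is used to initialize registration.
#'
#' @param image An [ffa_image()].
#' @param T_b Branch-pruning threshold in pixels.
#' @param L_0 Line-fit window radius in pixels.
#' @param params,q_low,q_high,n_s,sigma Passed to [large_vessel_mask()].
#' @param stride Passed to [vote()].
#' @param accumulator_sd Standard deviation (pixels) of the Gaussian
#'   smoothing applied to the accumulator before taking the maximum.
#' @return Numeric `c(row, col)` with attribute `votes` (the smoothed
#'   accumulator value at the maximum).
#' @export
reference_point <- function(image, T_b = 20L, L_0 = 30L,
                            params = opening_params(), q_low = 0.90,
                            q_high = 0.98, n_s = 2L, sigma = 3,
                            stride = 1L, accumulator_sd = 4) {
  mask <- large_vessel_mask(image, params, q_low, q_high, n_s, sigma)
  if (!any(mask)) stop("reference point unavailable")
  # condition the binary mask before thinning: close noise pits (which
  # thinning would turn into spurious loops and spurs) and drop specks
  # smaller than the pruning scale
  mask <- condition_mask(mask, min_size = T_b)
  sk <- skeletonize(mask)
  g <- build_graph(sk)
  if (length(g$edges) == 0L) stop("reference point unavailable")
  g <- prune(g, T_b)
  if (length(g$edges) == 0L) stop("reference point unavailable")
  a <- suppressWarnings(vote(g, L_0))
  if (attr(a, "total_votes") == 0L) stop("reference point unavailable")
  as_smooth <- EBImage::gblur(a, sigma = accumulator_sd)
  mx <- max(as_smooth)
  cand <- which(as_smooth == mx)
  rr <- ((cand - 1L) %% nrow(a)) + 1L
  cc <- ((cand - 1L) %/% nrow(a)) + 1L
  pick <- order(rr, cc)[1L]
  structure(c(row = rr[pick], col = cc[pick]), votes = mx)
}
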