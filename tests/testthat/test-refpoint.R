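test_that("thinning produces 1-px skeletons preserving topology", {
  # solid bar thins to a single-pixel line
  bar <- matrix(FALSE, 20, 60)
  bar[8:12, 6:55] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(sk[!bar] == FALSE))
  expect_equal(max(oracle_flood_components(sk)), 1L)
  expect_true(all(ffaleak:::neighbor_count8(sk)[sk] <= 2))
  expect_gte(diff(range(which(sk, arr.ind = TRUE)[, 2])), 40)
  # a single pixel is its own skeleton
  px <- matrix(FALSE, 5, 5)
  px[3, 3] <- TRUE
  expect_identical(skeletonize(px), px)
  # annulus: one component and the hole survives (Euler check via labeling)
  n <- 41
  r <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, `+`))
  ann <- r >= 8 & r <= 14
  ska <- skeletonize(ann)
  expect_equal(max(oracle_flood_components(ska)), 1L)
  # the interior background stays disconnected from the exterior
  # (4-connected background, dual to the 8-connected foreground)
  bg <- oracle_flood4(!ska)
  expect_gte(max(bg), 2L)
  expect_false(bg[21, 21] == bg[1, 1])
  expect_false(any(skeletonize(matrix(FALSE, 4, 4))))
})

test_that("the skeleton graph encodes nodes, chains and degenerate loops", {
  # straight line: 2 terminations, one 50-px chain
  ln <- matrix(FALSE, 30, 60)
  ln[15, 5:54] <- TRUE
  g <- build_graph(ln)
  expect_equal(nrow(g$nodes), 2L)
  expect_true(all(g$nodes$type == "termination"))
  expect_length(g$edges, 1L)
  expect_equal(nrow(g$edges[[1]]$chain), 50L)
  # chain endpoints are the node pixels
  ends <- g$edges[[1]]$chain[c(1, 50), ]
  expect_setequal(ends[, 2], g$nodes$col)
  # plus shape: one bifurcation cluster, four terminations, four edges
  pl <- matrix(FALSE, 41, 41)
  pl[21, 6:36] <- TRUE
  pl[6:36, 21] <- TRUE
  g2 <- build_graph(pl)
  expect_equal(sum(g2$nodes$type == "bifurcation"), 1L)
  expect_equal(sum(g2$nodes$type == "termination"), 4L)
  expect_length(g2$edges, 4L)
  # node-free loop becomes a single cyclic edge at an anchor pixel
  # (diamond ring: every pixel has exactly two 8-neighbors)
  ring <- matrix(FALSE, 15, 15)
  rc <- which(matrix(TRUE, 15, 15), arr.ind = TRUE)
  ring[rc[abs(rc[, 1] - 8) + abs(rc[, 2] - 8) == 5, ]] <- TRUE
  g3 <- build_graph(ring)
  expect_length(g3$edges, 1L)
  expect_equal(g3$edges[[1]]$from, g3$edges[[1]]$to)
  expect_equal(g3$nodes$type, "cycle")
})

test_that("pruning removes short branches iteratively and is idempotent", {
  y <- matrix(FALSE, 40, 40)
  y[20, 3:38] <- TRUE
  y[17:19, 26:28][cbind(3:1, 1:3)] <- TRUE   # 3-px spur
  g <- build_graph(y)
  expect_length(g$edges, 3L)
  expect_identical(ffaleak:::graph_to_skeleton(prune(g, 0)),
                   ffaleak:::graph_to_skeleton(g))
  gp <- prune(g, 10)
  # spur gone and the two long edges merged through the old junction
  expect_length(gp$edges, 1L)
  expect_gte(nrow(gp$edges[[1]]$chain), 34L)
  expect_identical(ffaleak:::graph_to_skeleton(prune(gp, 10)),
                   ffaleak:::graph_to_skeleton(gp))
  # cascading stubs need several passes
  z <- matrix(FALSE, 40, 80)
  z[20, 5:70] <- TRUE
  z[15:19, 30] <- TRUE
  z[14, 31] <- TRUE
  gz <- prune(build_graph(z), 8)
  expect_length(gz$edges, 1L)
  expect_equal(nrow(gz$nodes), 2L)
})

test_that("local total-least-squares line fits handle every orientation", {
  horiz <- cbind(rep(10, 11), 5:15)
  f <- fit_local_line(horiz, 6, 5)
  expect_equal(abs(f$dir), c(0, 1))
  expect_equal(f$point[1], 10)
  vert <- cbind(5:15, rep(3, 11))
  fv <- fit_local_line(vert, 6, 5)
  expect_equal(abs(fv$dir), c(1, 0))
  diag <- cbind(1:11, 1:11)
  fd <- fit_local_line(diag, 6, 5)
  expect_equal(abs(fd$dir), c(1, 1) / sqrt(2), tolerance = 1e-9)
  # arc of radius 3 L0: fitted line within 10 degrees of the tangent
  L0 <- 10
  rad <- 3 * L0
  th <- seq(-0.5, 0.5, length.out = 200)
  arc <- cbind(100 + rad * sin(th), 100 + rad * (1 - cos(th)))
  fa <- fit_local_line(arc, 100, L0)
  tangent <- c(1, 0)
  ang <- acos(abs(sum(fa$dir * tangent)))
  expect_lt(ang, 10 * pi / 180)
  # fewer than two in-window points: no line
  expect_null(fit_local_line(cbind(c(1, 50), c(1, 50)), 1, 2))
})

test_that("voting concentrates where supporting lines cross", {
  # one straight chain: accumulator maximal and flat along its own line
  ln <- matrix(FALSE, 60, 60)
  ln[30, 10:50] <- TRUE
  g <- build_graph(ln)
  a <- vote(g, 8, shape = c(60, 60))
  expect_equal(attr(a, "total_votes"), sum(a))
  expect_true(all(a[30, ] == max(a)))
  expect_true(all(a[-30, ] == 0))
  # two crossing chains: argmax at the crossing
  x2 <- matrix(FALSE, 200, 200)
  x2[100, 20:80] <- TRUE          # horizontal, supporting line row 100
  x2[20:80, 100] <- TRUE          # vertical, supporting line col 100
  a2 <- vote(build_graph(x2), 10, shape = c(200, 200))
  peak <- which(a2 == max(a2), arr.ind = TRUE)
  expect_lt(sqrt(sum((peak[1, ] - c(100, 100))^2)), 1.5)
  # spoke phantom: six radial 1-px chains converge on a common center
  spokes <- matrix(FALSE, 201, 201)
  for (th in (0:5) * pi / 3 + 0.2) {
    seg <- ffaleak:::digital_segment(
      round(c(101, 101) + 12 * c(sin(th), cos(th))),
      round(c(101, 101) + 85 * c(sin(th), cos(th))))
    spokes[seg] <- TRUE
  }
  a3 <- vote(build_graph(spokes), 15)
  peak3 <- which(a3 == max(a3), arr.ind = TRUE)
  expect_lte(sqrt(sum((peak3[1, ] - c(101, 101))^2)), 2)
  # empty graph: zero accumulator with a warning
  ge <- build_graph(matrix(FALSE, 10, 10))
  expect_warning(ae <- vote(ge, 5, shape = c(10, 10)), "empty")
  expect_equal(sum(ae), 0)
})

test_that("the reference point lands on the phantom convergence point", {
  sp <- test_spec()
  ph <- generate_sequence(sp, seed = 52)
  f1 <- ph$sequence$frames[[1]]
  args <- test_pipeline_args()
  rp <- reference_point(f1, T_b = args$T_b, L_0 = args$L_0,
                        params = test_params(), n_s = args$n_s)
  expect_lt(sqrt(sum((rp - ph$truth$convergence_point)^2)), 5)
  # translation equivariance: shift the frame content by whole pixels
  dr <- 20; dc <- -10
  shifted <- matrix(1, 256, 256)
  shifted[(1 + dr):256, 1:(256 + dc)] <- f1$pixels[1:(256 - dr), (1 - dc):256]
  roi_s <- matrix(FALSE, 256, 256)
  roi_s[(1 + dr):256, 1:(256 + dc)] <- f1$roi[1:(256 - dr), (1 - dc):256]
  rp2 <- reference_point(ffa_image(shifted, roi_s), T_b = args$T_b,
                         L_0 = args$L_0, params = test_params(), n_s = args$n_s)
  expect_lt(max(abs((rp2 - rp) - c(dr, dc))), 2 + 1e-9)
  # a vessel-free frame has no reference point
  blank <- ffa_image(matrix(5, 128, 128) + rep(0, 128 * 128),
                     disk_mask(128, c(64, 64), 55))
  expect_error(
    suppressWarnings(reference_point(blank, params = opening_params(5, 9))),
    "reference point unavailable")
})
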