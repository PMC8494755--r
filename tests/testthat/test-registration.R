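test_that("rigid transforms compose, invert and initialize correctly", {
  t1 <- rigid_transform(0.3, c(5, -2), c(100, 120))
  pts <- cbind(runif(20, 1, 200), runif(20, 1, 200))
  # inverse maps back to the identity
  back <- transform_points(invert_transform(t1), transform_points(t1, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  # composition agrees with sequential application
  t2 <- rigid_transform(-0.1, c(-3, 7), c(50, 60))
  comp <- compose_transforms(t2, t1)
  expect_lt(max(abs(transform_points(comp, pts) -
                      transform_points(t2, transform_points(t1, pts)))), 1e-6)
  # pure translation is vector addition
  tt <- rigid_transform(0, c(4, -9), c(0, 0))
  expect_equal(transform_points(tt, c(10, 10)), c(14, 1))
  # reference-point initialization
  init <- initial_transform(c(120, 200), c(100, 210))
  expect_equal(init$translation, c(-20, 10))
  expect_equal(init$angle, 0)
  expect_equal(transform_points(init, c(120, 200)), c(100, 210))
})

test_that("warping is exact for the identity and consistent under round trips", {
  set.seed(61)
  n <- 96
  base <- matrix(0, n, n)
  for (k in 1:6) {   # smooth random phantom
    base <- base + outer(sin(runif(1, 0, 2) * seq_len(n) / 9 + runif(1, 0, 6)),
                         cos(runif(1, 0, 2) * seq_len(n) / 9 + runif(1, 0, 6)))
  }
  base <- 50 + 20 * base
  base[base < 0] <- 0
  roi <- disk_mask(n, c(48, 48), 40)
  img <- ffa_image(base, roi)
  idw <- warp(img, rigid_transform(0, c(0, 0), c(48, 48)))
  expect_identical(idw$pixels, img$pixels)
  # +3 then -3 rows returns the original away from the border
  w1 <- warp(img, rigid_transform(0, c(3, 0), c(48, 48)))
  w2 <- warp(ffa_image(w1$pixels, w1$roi), rigid_transform(0, c(-3, 0), c(48, 48)))
  core <- w2$roi & roi
  expect_lt(max(abs(w2$pixels[core] - img$pixels[core])),
            0.01 * diff(range(base)))
  # ROI area preserved within 2% under pure rotation
  wr <- warp(img, rigid_transform(10 * pi / 180, c(0, 0), c(48, 48)))
  expect_lt(abs(sum(wr$roi) - sum(roi)) / sum(roi), 0.02)
})

test_that("pairwise registration recovers imposed motions", {
  set.seed(62)
  ph <- generate_sequence(test_spec(times = c(1, 3), jitter_max_px = 0,
                                    jitter_max_deg = 0), seed = 63)
  fixed <- ph$sequence$frames[[1]]
  cen <- c(128, 128)
  # identical frames: identity within 0.1 px / 0.1 degree
  r0 <- register_pair(fixed, fixed,
                      rigid_transform(0, c(0, 0), cen))
  expect_lt(max(abs(r0$translation)), 0.1)
  expect_lt(abs(r0$angle) * 180 / pi, 0.1)
  # known shift
  tshift <- rigid_transform(0, c(7, -4), cen)
  moving <- warp(fixed, invert_transform(tshift))
  rs <- register_pair(fixed, moving, rigid_transform(0, c(0, 0), cen))
  expect_lt(max(abs(rs$translation - c(7, -4))), 0.5)
  # known rotation about the ROI center
  trot <- rigid_transform(5 * pi / 180, c(0, 0), cen)
  moving2 <- warp(fixed, invert_transform(trot))
  rr <- register_pair(fixed, moving2, rigid_transform(0, c(0, 0), cen))
  expect_lt(abs(rr$angle - 5 * pi / 180) * 180 / pi, 0.5)
  # metric never decreases from its initial value
  expect_gte(attr(rs, "metric_final"), attr(rs, "metric_init"))
  expect_gte(attr(rr, "metric_final"), attr(rr, "metric_init"))
  # disjoint fields of view are rejected
  off <- rigid_transform(0, c(500, 500), cen)
  expect_error(register_pair(fixed, moving, off), "out of field")
})

test_that("inverse consistency holds on a jittered pair", {
  ph <- generate_sequence(test_spec(times = c(1, 3)), seed = 64)
  a <- ph$sequence$frames[[1]]
  b <- ph$sequence$frames[[2]]
  cen <- c(128, 128)
  tab <- register_pair(a, b, rigid_transform(0, c(0, 0), cen))
  tba <- register_pair(b, a, rigid_transform(0, c(0, 0), cen))
  comp <- compose_transforms(tab, tba)
  pts <- cbind(runif(20, 80, 180), runif(20, 80, 180))
  expect_lt(max(sqrt(rowSums((transform_points(comp, pts) - pts)^2))), 1)
  expect_lt(abs(comp$angle) * 180 / pi, 1)
})

test_that("sequence registration aligns to the first frame and intersects ROIs", {
  # identical frames register to the identity
  sp <- test_spec(times = c(1, 3, 5), jitter_max_px = 0, jitter_max_deg = 0,
                  noise_sd = 0, amplitudes = c(3, 3, 3), growth = 1)
  ph <- generate_sequence(sp, seed = 65)
  args <- test_pipeline_args()
  reg <- register_sequence(ph$sequence, T_b = args$T_b, L_0 = args$L_0,
                           params = test_params(), n_s = args$n_s)
  expect_true(all(reg$ok))
  for (k in 2:3) {
    expect_lt(max(abs(reg$transforms[[k]]$translation)), 0.2)
    expect_lt(abs(reg$transforms[[k]]$angle) * 180 / pi, 0.2)
  }
  expect_identical(reg$analysis_roi,
                   Reduce(`&`, lapply(reg$registered$frames, function(f) f$roi)))
  # a jittered sequence recovers the programmed motions
  ph2 <- generate_sequence(test_spec(times = c(1, 5, 9)), seed = 66)
  reg2 <- suppressWarnings(
    register_sequence(ph2$sequence, T_b = args$T_b, L_0 = args$L_0,
                      params = test_params(), n_s = args$n_s))
  probe <- cbind(rep(c(80, 128, 176), 3), rep(c(80, 128, 176), each = 3))
  for (k in 2:3) {
    expect_true(reg2$ok[k])
    err <- sqrt(rowSums((transform_points(ph2$truth$transforms[[k]], probe) -
                           transform_points(reg2$transforms[[k]], probe))^2))
    expect_lt(max(err), 1)
    expect_lt(abs(reg2$transforms[[k]]$angle -
                    ph2$truth$transforms[[k]]$angle) * 180 / pi, 1)
  }
})
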