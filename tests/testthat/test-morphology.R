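test_that("line structuring elements follow the integer line-drawing rule", {
  expect_identical(line_structuring_element(5, 0), matrix(TRUE, 1, 5))
  expect_identical(line_structuring_element(5, pi / 2), matrix(TRUE, 5, 1))
  d <- line_structuring_element(7, pi / 4)
  expect_equal(sum(d), 7)
  # point symmetry about the center (180-degree rotation invariance)
  expect_identical(d, d[rev(seq_len(nrow(d))), rev(seq_len(ncol(d))),
                        drop = FALSE])
  for (a in runif(10, 0, pi)) {
    se <- line_structuring_element(9, a)
    expect_equal(sum(se), 9)
    expect_identical(se, se[rev(seq_len(nrow(se))), rev(seq_len(ncol(se))),
                            drop = FALSE])
  }
  expect_error(line_structuring_element(4, 0), "odd")
  expect_error(line_structuring_element(-3, 0), "odd")
})

test_that("oriented openings match the brute-force sliding-window oracle", {
  set.seed(11)
  for (i in 1:4) {
    img <- matrix(runif(48 * 48, 0, 100), 48, 48)
    for (a in c(0, pi / 8, 3 * pi / 8, 5 * pi / 8)) {
      se <- line_structuring_element(11, a)
      expect_identical(ffaleak:::gray_open(img, se), oracle_gray_open(img, se))
    }
  }
})

test_that("small-vessel removal erases thin lines and preserves broad structure", {
  roi <- matrix(TRUE, 64, 64)
  # constant image is a fixed point of any opening
  cst <- ffa_image(matrix(5, 64, 64) + 0, roi)
  expect_equal(remove_small_vessels(cst, opening_params(5, 9))$values,
               matrix(5, 64, 64))
  # 1-px bright line vanishes completely
  m <- matrix(10, 64, 64)
  m[32, ] <- 100
  out <- remove_small_vessels(ffa_image(m, roi), opening_params(15, 31))
  expect_equal(out$values[32, ], rep(10, 64))
  expect_identical(out$values,
                   oracle_small_vessel_removal(m, 15))
  # disk wider than the element survives in its interior
  dm <- disk_mask(64, c(32, 32), 20.5)
  md <- ifelse(dm, 80, 10)
  outd <- remove_small_vessels(ffa_image(md, roi), opening_params(15, 31))
  interior <- disk_mask(64, c(32, 32), 13)
  expect_true(all(outd$values[interior] == 80))
  # anti-extensivity everywhere
  expect_true(all(outd$values <= md))
})

test_that("directional residues are antisymmetric on an oriented bar", {
  roi <- matrix(TRUE, 64, 64)
  p <- opening_params(5, 21)
  cst <- ffa_image(matrix(7, 64, 64) + 0, roi)
  expect_equal(directional_residue(cst, 0, p), matrix(0, 64, 64))
  m <- matrix(10, 64, 64)
  m[, 30:34] <- 100
  fi <- ffa_image(m, roi)
  expect_equal(directional_residue(fi, pi / 2, p)[32, 32], 90)
  expect_equal(directional_residue(fi, 0, p)[32, 32], -90)
  ev <- enhance_large_vessels(fi, p)
  expect_equal(ev$values[32, 32], 90)
  expect_identical(ev$values, oracle_large_vessel_enhancement(m, 21))
})

test_that("the large-vessel enhancement is nonnegative and suppresses blobs", {
  set.seed(12)
  p <- opening_params(5, 9)
  roi <- matrix(TRUE, 48, 48)
  for (i in 1:5) {
    img <- ffa_image(matrix(runif(48 * 48, 0, 50), 48, 48), roi)
    expect_gte(min(enhance_large_vessels(img, p)$values), 0)
  }
  # isotropic Gaussian blob with FWHM = 4 l_lv barely responds
  n <- 96
  r2 <- outer((1:n - 48)^2, (1:n - 48)^2, `+`)
  fwhm <- 4 * 9
  blob <- 100 * exp(-log(2) * 4 * r2 / fwhm^2)
  ev <- enhance_large_vessels(ffa_image(blob, matrix(TRUE, n, n)), p)
  # residual curvature response of the discrete openings stays an order of
  # magnitude below the response to an oriented bar of the same peak (90)
  expect_lt(max(ev$values), 0.1 * 100)
  expect_identical(ev$values, oracle_large_vessel_enhancement(blob, 9))
})

test_that("90-degree rotation of the input rotates the enhancement", {
  set.seed(13)
  img <- matrix(runif(40 * 40, 0, 60), 40, 40)
  p <- opening_params(5, 9)
  rot90 <- function(m) t(m)[ncol(m):1, ]
  a <- enhance_large_vessels(ffa_image(rot90(img), matrix(TRUE, 40, 40)), p)
  b <- enhance_large_vessels(ffa_image(img, matrix(TRUE, 40, 40)), p)
  expect_equal(a$values, rot90(b$values))
})

test_that("large-vessel removal infills with the local background level", {
  p <- opening_params(5, 21)
  n <- 64
  plateau <- matrix(10, n, n)
  plateau[disk_mask(n, c(32, 32), 25)] <- 80
  ridge <- matrix(FALSE, n, n)
  ridge[30:34, 20:44] <- TRUE
  img <- plateau
  img[ridge] <- 200
  small_removed <- leakage_image(img, matrix(TRUE, n, n))
  out <- remove_large_vessels(small_removed, ridge, p)
  # outside the mask untouched; inside within +-5 of the plateau
  expect_identical(out$values[!ridge], img[!ridge])
  expect_true(all(abs(out$values[ridge] - 80) <= 5))
  # empty mask is the identity; all-true mask is an error
  expect_identical(remove_large_vessels(small_removed,
                                        matrix(FALSE, n, n), p)$values, img)
  expect_error(remove_large_vessels(small_removed, matrix(TRUE, n, n), p),
               "entire image")
})
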