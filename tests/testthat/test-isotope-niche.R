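test_that("lipid normalization triggers strictly above C:N = 3.5", {
  df <- data.frame(delta13C = c(-19, -19, -19), c_to_n = c(3.0, 3.5, 4.0))
  out <- lipid_correct(df)
  expect_equal(out$delta13C, c(-19, -19, -19 - 3.32 + 0.99 * 4))
  expect_equal(out$corrected, c(FALSE, FALSE, TRUE))
  expect_error(lipid_correct(data.frame(delta13C = -19, c_to_n = 0)),
               "positive")
})

test_that("SEA closed forms and the small-sample correction are exact", {
  e1 <- standard_ellipse(c(0, 0), diag(2))
  expect_equal(e1$SEA, pi)
  e2 <- standard_ellipse(c(0, 0), diag(c(4, 1)))
  expect_equal(e2$SEA, 2 * pi)
  set.seed(31)
  pts <- MASS::mvrnorm(10, c(0, 0), diag(2))
  f <- fit_standard_ellipse(pts)
  expect_equal(f$SEA_C / f$SEA, 9 / 8)
  expect_error(fit_standard_ellipse(pts[1:2, ]), "3 points")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_standard_ellipse(line), "collinear")
  expect_error(standard_ellipse(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("SEA of a large standard-normal sample approaches pi", {
  set.seed(32)
  pts <- MASS::mvrnorm(20000, c(0, 0), diag(2))
  f <- fit_standard_ellipse(pts)
  expect_equal(f$SEA, pi, tolerance = 0.05)
})

test_that("SEA is rotation invariant and scales quadratically", {
  set.seed(33)
  pts <- MASS::mvrnorm(200, c(1, -18), matrix(c(0.5, 0.2, 0.2, 0.8), 2))
  f <- fit_standard_ellipse(pts)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(fit_standard_ellipse(pts %*% R)$SEA, f$SEA)
  expect_equal(fit_standard_ellipse(3 * pts)$SEA, 9 * f$SEA)
})

test_that("SEA_B posterior is reproducible and consistent with ML", {
  set.seed(34)
  pts <- MASS::mvrnorm(500, c(-19, 9), matrix(c(0.4, 0.1, 0.1, 0.3), 2))
  a <- sea_b_posterior(pts, draws = 4000, seed = 11)
  b <- sea_b_posterior(pts, draws = 4000, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ci, b$ci)
  expect_lt(abs(a$mean - a$ml$SEA) / a$ml$SEA, 0.05)
  expect_equal(formals(sea_b_posterior)$draws, 10000)
  expect_error(sea_b_posterior(pts[1:2, ]), "3 points")
})

test_that("ellipse overlap endpoints: identity, separation, containment", {
  A <- standard_ellipse(c(0, 0), diag(2))
  same <- ellipse_overlap(A, A)
  expect_equal(same$pct_a, 100)
  expect_equal(same$pct_b, 100)
  B <- standard_ellipse(c(100, 0), diag(2))
  far <- ellipse_overlap(A, B)
  expect_equal(far$pct_a, 0)
  expect_equal(far$pct_b, 0)
  # area-1 ellipse centred inside an area-4 ellipse: 100% / 25%
  small <- standard_ellipse(c(0, 0), diag(1 / pi, 2))
  big <- standard_ellipse(c(0.1, 0), diag(4 / pi, 2))
  ov <- ellipse_overlap(small, big)
  expect_equal(ov$pct_a, 100)
  expect_equal(ov$pct_b, 25)
  expect_lte(ov$intersection, min(ov$area_a, ov$area_b))
})

test_that("grid and Monte-Carlo overlap agree on partially overlapping pairs", {
  set.seed(35)
  for (i in 1:10) {
    A <- standard_ellipse(rnorm(2, sd = 0.3),
                          crossprod(matrix(rnorm(4, sd = 0.8), 2)) + diag(0.3, 2))
    B <- standard_ellipse(rnorm(2, sd = 0.3),
                          crossprod(matrix(rnorm(4, sd = 0.8), 2)) + diag(0.3, 2))
    g <- ellipse_overlap(A, B, method = "grid")
    mc <- ellipse_overlap(A, B, method = "montecarlo", n_mc = 2e5, seed = i)
    denom <- max(g$intersection, 1e-9)
    expect_lt(abs(g$intersection - mc$intersection) / denom, 0.02)
  }
})

test_that("posterior overlap intervals bracket the point estimate", {
  set.seed(36)
  pa <- MASS::mvrnorm(40, c(-19, 9), diag(c(0.4, 0.3)))
  pb <- MASS::mvrnorm(40, c(-18.7, 9.3), diag(c(0.5, 0.3)))
  res <- ellipse_overlap_posterior(pa, pb, n_draws = 60, seed = 12)
  expect_true(res$ci_pct_a[1] <= res$estimate$pct_a + 5)
  expect_true(res$ci_pct_a[2] >= res$estimate$pct_a - 5)
  expect_true(all(res$ci_pct_b >= 0 & res$ci_pct_b <= 100))
})
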