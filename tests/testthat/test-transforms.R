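test_that("compose_affine builds S R Sh T in the printed factor order", {
  expect_equal(compose_affine(affine_params())$m, diag(3))

  tr <- compose_affine(affine_params(x_0 = 3, y_0 = -2))
  expect_equal(tr$m[, 3], c(3, -2, 1))
  expect_equal(tr$kind, "affine")

  # s = (2, 1), theta = pi/2: hand-multiplying the four factors sends
  # (0, 1) to (-2, 0)
  A <- compose_affine(affine_params(s_x = 2, s_y = 1, theta = pi / 2))
  expect_points_close(apply_transform(A, c(0, 1)), c(-2, 0), tol = 1e-12)

  expect_error(affine_params(s_x = 0), "positive")
  expect_error(affine_params(s_y = -1), "positive")
})

test_that("apply_transform follows the homogeneous evaluation rule", {
  pts <- cbind(runif(5, -10, 10), runif(5, -10, 10))
  expect_equal(apply_transform(identity_transform(), pts), as_points(pts))

  # hand-evaluated worked example: z_t = 1.6, x_t = 100, y_t = 130
  expect_points_close(apply_transform(worked_H(), c(100, 100)),
                      c(62.5, 81.25), tol = 1e-12)

  # affine subcase keeps z_t = 1: results equal the linear evaluation
  A <- compose_affine(affine_params(s_x = 1.3, theta = 0.4, a_x = 0.1,
                                    x_0 = 2, y_0 = -1))
  lin <- t(A$m[1:2, 1:2] %*% t(as_points(pts))) +
    matrix(A$m[1:2, 3], 5, 2, byrow = TRUE)
  expect_points_close(apply_transform(A, pts), lin, tol = 1e-9)

  # a point mapped to the horizon line is a degenerate projection
  Hbad <- transform_matrix(matrix(c(1, 0, 0, 0, 1, 0, -0.01, 0, 1), 3, 3,
                                  byrow = TRUE))
  expect_error(apply_transform(Hbad, c(100, 0)), "index 1")
})

test_that("invert_transform round-trips points and matrices", {
  expect_equal(invert_transform(identity_transform())$m, diag(3))

  H <- worked_H()
  expect_points_close(apply_transform(invert_transform(H), c(62.5, 81.25)),
                      c(100, 100), tol = 1e-9)

  tr <- compose_affine(affine_params(x_0 = 3, y_0 = -2))
  expect_equal(invert_transform(tr)$m[, 3], c(-3, 2, 1))

  expect_equal(invert_transform(invert_transform(H))$m, H$m, tolerance = 1e-9)
})

test_that("projective transform invariants hold on random instances", {
  set.seed(42)
  for (k in 1:20) {
    A <- random_homography(); B <- random_homography()
    pts <- cbind(runif(6, -2, 2), runif(6, -2, 2))
    # composition consistency
    expect_points_close(apply_transform(compose_transforms(A, B), pts),
                        apply_transform(A, apply_transform(B, pts)),
                        tol = 1e-9)
    # projective scale invariance: scaling all entries changes nothing
    expect_points_close(apply_transform(transform_matrix(3.7 * A$m), pts),
                        apply_transform(A, pts), tol = 1e-9)
  }
  # affine closure
  for (k in 1:10) {
    p <- affine_params(s_x = runif(1, 0.5, 2), s_y = runif(1, 0.5, 2),
                       theta = runif(1, -pi, pi), a_x = runif(1, -0.3, 0.3),
                       a_y = runif(1, -0.3, 0.3), x_0 = rnorm(1), y_0 = rnorm(1))
    expect_equal(compose_affine(p)$m[3, 1:2], c(0, 0))
  }
})

test_that("warp_image resamples exactly on trivial transforms", {
  set.seed(7)
  img <- matrix(runif(30 * 40), 30, 40)
  expect_equal(warp_image(img, identity_transform()), img)

  sh <- compose_affine(affine_params(x_0 = 5))  # shift +5 columns
  w <- warp_image(img, sh, fill = -1)
  expect_equal(w[, 6:40], img[, 1:35])
  expect_true(all(w[, 1:5] == -1))

  expect_error(warp_image(matrix(numeric(0), 0, 0), identity_transform()),
               "non-empty")
})

test_that("warp by H then by H^-1 returns the image away from borders", {
  set.seed(8)
  # smooth image: sum of broad Gaussians so interpolation error is small
  n <- 64
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), times = n), n, n)
  img <- 0.5 + 0.3 * exp(-((xg - 20)^2 + (yg - 28)^2) / 60) -
    0.25 * exp(-((xg - 44)^2 + (yg - 40)^2) / 90)
  H <- transform_matrix(matrix(c(1.05, 0.04, 2, -0.03, 0.97, 3,
                                 1e-4, -8e-5, 1), 3, 3, byrow = TRUE))
  back <- warp_image(warp_image(img, H), invert_transform(H))
  core <- 9:(n - 8)
  err <- mean(abs(back[core, core] - img[core, core]))
  expect_lt(err / diff(range(img)), 0.02)
})

test_that("transforms serialise to row-major JSON and back", {
  H <- worked_H()
  js <- write_transform_json(H)
  expect_match(js, "homography")
  H2 <- read_transform_json(js)
  expect_equal(H2$m, H$m)
  expect_equal(H2$kind, "homography")

  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(compose_affine(affine_params(x_0 = 1)), f)
  expect_equal(read_transform_json(f)$kind, "affine")
})

test_that("transform_matrix validates its invariants", {
  expect_error(transform_matrix(matrix(0, 3, 3)), "zero bottom-right|singular")
  expect_error(transform_matrix(matrix(c(1, 0, 0, 2, 0, 0, 3, 0, 1), 3, 3)),
               "singular")
  m <- diag(3); m[3, 1] <- 0.1
  expect_error(transform_matrix(m, "affine"), "projective terms")
  # normalisation: any overall scale is divided out
  expect_equal(transform_matrix(2 * diag(3))$m, diag(3))
})
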