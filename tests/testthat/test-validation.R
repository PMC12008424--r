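test_that("mae is the mean Euclidean displacement", {
  P <- make_lattice_model(3, 3)$points
  expect_equal(mae(P, P), 0)
  expect_equal(mae(sweep(P, 2, c(0.3, 0.4), "+"), P), 0.5)

  set.seed(4)
  Q <- P + matrix(rnorm(18), 9, 2)
  # direct summation oracle
  want <- 0
  for (i in 1:9) want <- want + sqrt(sum((Q[i, ] - P[i, ])^2))
  expect_equal(mae(Q, P), want / 9)
  expect_error(mae(P, P[1:3, ]), "equal lengths")
})

test_that("oks is the mean Gaussian keypoint similarity", {
  P <- make_lattice_model(2, 2)$points
  cfg <- metric_config()
  expect_equal(oks(P, P, cfg), 1)

  # single point displaced by s * kappa * sqrt(2): kernel value exp(-1)
  d <- cfg$oks_scale * cfg$oks_kappa * sqrt(2)
  one <- rbind(c(0, 0))
  expect_equal(oks(rbind(c(d, 0)), one, cfg), exp(-1), tolerance = 1e-12)

  # large displacements drive the similarity to zero
  expect_lt(oks(P + 100, P, cfg), 1e-10)
})

test_that("recall_at_oks counts threshold exceedances", {
  expect_equal(recall_at_oks(rep(1, 10), 0.95), 1)
  expect_equal(recall_at_oks(rep(0.5, 10), 0.95), 0)
  expect_equal(recall_at_oks(c(rep(0.99, 5), rep(0.5, 5)), 0.95), 0.5)
  expect_error(recall_at_oks(numeric(0)), "non-empty")
})

test_that("random_homography honours magnitudes and stays invertible", {
  zero <- homography_magnitude(0, 0, 0, 0, 0)
  expect_equal(random_homography(zero)$m, diag(3))

  set.seed(10); H1 <- random_homography()
  set.seed(10); H2 <- random_homography()
  expect_identical(H1$m, H2$m)

  set.seed(11)
  corners <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  for (k in 1:2000) {
    H <- random_homography(extent = 6)
    expect_gt(abs(det(H$m)), 1e-12)
    z <- H$m[3, 1] * corners[, 1] + H$m[3, 2] * corners[, 2] + 1
    expect_true(all(z > 0))
  }
})

test_that("zero-noise sweep reconstructs the model exactly in every sample", {
  r <- run_noise_sweep(sweep_config(noise_stds = 0, point_counts = c(4, 9),
                                    n_samples = 200, seed = 2))
  expect_true(all(r$samples$oks == 1))
  expect_lt(max(r$samples$mae), 1e-6)
  expect_equal(r$summary$recall, c(1, 1))
})

test_that("mean MAE grows with noise at fixed point count", {
  r <- run_noise_sweep(sweep_config(noise_stds = c(0, 0.02, 0.05, 0.08),
                                    point_counts = 4, n_samples = 1000,
                                    seed = 6))
  m <- r$summary$mae_mean[order(r$summary$noise_std)]
  expect_true(all(diff(m) > 0))
})

test_that("H is recovered entrywise under small noise with 9+ points", {
  set.seed(13)
  Pm <- make_lattice_model(3, 3)$points
  ok <- 0
  for (k in 1:300) {
    H <- random_homography(extent = 3)
    Pe <- apply_transform(H, Pm) + matrix(rnorm(18, sd = 0.02), 9, 2)
    est <- estimate_homography_lmeds(Pm, Pe, lmeds_config(n_samples = 500,
                                                          seed = k))
    if (max(abs(est$H$m - H$m)) < 0.05) ok <- ok + 1
  }
  expect_gte(ok / 300, 0.95)
})

test_that("sweeps are bitwise reproducible under a fixed seed", {
  cfg <- sweep_config(noise_stds = c(0, 0.05), point_counts = c(4, 9),
                      n_samples = 50, seed = 123)
  r1 <- run_noise_sweep(cfg)
  r2 <- run_noise_sweep(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$summary, r2$summary)
})

test_that("render_fixture stamps spots at the transformed anchor positions", {
  model <- make_lattice_model(3, 3)
  H <- pixel_scale_H(20, c(15, 15), g = 0, h = 0)
  fx <- render_fixture(model, H, size = c(90, 90))
  # darkest pixels sit at the anchor positions (pixel-centre resolution)
  for (i in seq_len(9)) {
    p <- round(fx$anchors_image[i, ])
    patch <- fx$image[(p[2] - 2):(p[2] + 4) + 1, (p[1] - 2):(p[1] + 4) + 1]
    expect_equal(unname(which(patch == min(patch), arr.ind = TRUE)[1, ]),
                 c(3, 3))
  }

  f1 <- render_fixture(model, H, size = c(90, 90), noise_sd = 0.05, seed = 8)
  f2 <- render_fixture(model, H, size = c(90, 90), noise_sd = 0.05, seed = 8)
  expect_identical(f1$image, f2$image)

  expect_error(render_fixture(model, pixel_scale_H(60, c(5, 5)),
                              size = c(64, 64)),
               "outside canvas")
})

test_that("fixture rendering closes the loop with keypoint detection", {
  model <- make_lattice_model(4, 4)
  H <- pixel_scale_H(16, c(14, 14))
  fx <- render_fixture(model, H, size = c(92, 92), noise_sd = 0.02, seed = 3)
  det <- detect_dark_keypoints(fx$image, detection_config(min_separation = 5))
  dmin <- apply(fx$anchors_image, 1, function(p) {
    min(sqrt((det[, 1] - p[1])^2 + (det[, 2] - p[2])^2))
  })
  expect_lt(max(dmin), 0.5)
})
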