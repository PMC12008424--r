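test_that("vote scores reproduce the worked lattice and error cases", {
  # centre of a 3x3 unit lattice: four axial neighbours in range -> +4
  lat <- make_lattice_model(3, 3)
  vr <- vote_filter(lat$points, vote_config(1))
  centre <- which(lat$points[, 1] == 1 & lat$points[, 2] == 1)
  expect_identical(vr$scores[centre], 4L)
  expect_equal(nrow(vr$removed), 0)

  # constructed error case: one in-range neighbour, three off-spacing -> -2
  pts <- rbind(c(0, 0), c(1, 0), c(0.3, 0), c(0, 0.4), c(-0.5, 0))
  vr2 <- vote_filter(pts, vote_config(1, radius = 1.2))
  expect_identical(vr2$scores[1], -2L)
  expect_true(1 %in% setdiff(seq_len(5), vr2$kept_idx))

  # isolated point: no candidates, score 0, kept
  vr3 <- vote_filter(rbind(c(0, 0)), vote_config(1))
  expect_identical(vr3$scores, 0L)
  expect_equal(nrow(vr3$kept), 1)
})

test_that("vote conservation and perfect-lattice soundness", {
  for (n in 3:6) {
    lat <- make_lattice_model(n, n)
    vr <- vote_filter(lat$points, vote_config(1))
    expect_equal(nrow(vr$kept) + nrow(vr$removed), n * n)
    expect_equal(nrow(vr$removed), 0)
    # stability: re-running on the kept set removes nothing further
    vr2 <- vote_filter(vr$kept, vote_config(1))
    expect_equal(nrow(vr2$removed), 0)
  }
})

test_that("midpoint spurious points are removed, lattice points kept", {
  set.seed(5)
  for (n in 4:6) {
    lat <- make_lattice_model(n, n)$points
    k <- 3
    # spurious points midway between horizontally adjacent sites
    rows <- sample(which(lat[, 1] < n - 1), k)
    spur <- lat[rows, ] + matrix(c(0.5, 0), k, 2, byrow = TRUE)
    all_pts <- rbind(lat, spur)
    vr <- vote_filter(all_pts, vote_config(1))
    expect_setequal(setdiff(seq_len(nrow(all_pts)), vr$kept_idx),
                    nrow(lat) + seq_len(k))
  }
})

test_that("pair_points gates, claims greedily, and matches the brute-force oracle", {
  lat <- make_lattice_model(3, 3)$points
  ps <- pair_points(lat, lat, gate = 0.5)
  expect_equal(ps$pairs$model, ps$pairs$extracted)
  expect_equal(ps$pairs$distance, rep(0, 9))

  # an extracted outlier far from everything stays unpaired
  ps2 <- pair_points(lat, rbind(lat, c(9, 9)), gate = 0.5)
  expect_equal(ps2$unpaired_extracted, 10)

  # oracle: iteratively claim the globally closest free pair
  oracle_pairs <- function(A, B, gate) {
    d <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                             nrow(A) + seq_len(nrow(B)), drop = FALSE]
    out <- NULL
    repeat {
      if (all(!is.finite(d)) || min(d) > gate) break
      ij <- which(d == min(d), arr.ind = TRUE)
      ij <- ij[order(ij[, 1]), , drop = FALSE][1, ]
      out <- rbind(out, ij)
      d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
    }
    out[order(out[, 1]), , drop = FALSE]
  }
  set.seed(11)
  for (k in 1:5) {
    A <- cbind(runif(50, 0, 10), runif(50, 0, 10))
    B <- A + matrix(rnorm(100, sd = 0.15), 50, 2)
    got <- pair_points(A, B, gate = 0.6)$pairs
    want <- oracle_pairs(A, B, 0.6)
    expect_equal(as.matrix(got[order(got$model), c("model", "extracted")]),
                 want, ignore_attr = TRUE)
  }
})

test_that("greedy pairing is assignment-optimal in the registration regime", {
  # small perturbed-lattice instances vs exhaustive minimum-cost assignment
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  set.seed(21)
  for (k in 1:5) {
    A <- make_lattice_model(3, 2)$points
    B <- A + matrix(rnorm(12, sd = 0.1), 6, 2)
    got <- pair_points(A, B, gate = 0.45)$pairs
    expect_equal(nrow(got), 6)
    got_sum <- sum(got$distance)
    best <- min(vapply(perms(1:6), function(p) {
      sum(sqrt(rowSums((A - B[p, , drop = FALSE])^2)))
    }, numeric(1)))
    expect_lte(got_sum, best + 1e-12)
  }
})

test_that("place_model recovers known translations within one grid step", {
  lat <- make_lattice_model(4, 4)
  fixed <- affine_params()

  # exact copy: translation (0, 0) modulo the lattice
  rm0 <- place_model(lat, fixed, lat$points)
  expect_equal(nrow(rm0$pairs$pairs), 16)
  expect_lt(max(rm0$pairs$pairs$distance), 1 / 50 * sqrt(2) + 1e-9)

  # known sub-cell shift
  shift <- c(0.31, -0.22)
  rm1 <- place_model(lat, fixed, sweep(lat$points, 2, shift, "+"))
  # recovered placement reproduces the shift modulo one lattice cell
  resid <- (rbind(c(rm1$affine$x_0, rm1$affine$y_0)) - rbind(shift)) %% 1
  resid <- pmin(resid, 1 - resid)
  expect_lt(max(resid), 1 / 50 + 1e-9)
  # oracle: a finer exhaustive grid cannot do meaningfully better
  fine <- place_model(lat, fixed, sweep(lat$points, 2, shift, "+"),
                      grid_step = 1 / 200)
  expect_lte(fine$objective, rm1$objective + 1e-9)

  # placements that never approach P_e fail
  expect_error(place_model(lat, fixed, rbind(c(500, 500), c(501, 500)),
                           search = list(tx = 0:3, ty = 0:3)),
               "placement failure|no pairs")
  expect_error(place_model(lat, fixed, lat$points,
                           search = list(tx = numeric(0), ty = numeric(0))),
               "empty translation search grid")
})

test_that("placement works for polygon models over the bounding box", {
  poly <- make_polygon_model(rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40)))
  P_e <- sweep(poly$points, 2, c(13.4, 27.1), "+")
  rm <- place_model(poly, affine_params(), P_e, grid_step = 1, gate = 2)
  expect_equal(nrow(rm$pairs$pairs), 4)
  expect_lt(max(rm$pairs$pairs$distance), sqrt(2) + 1e-9)
})

test_that("vote_config validates its window", {
  expect_error(vote_config(1, tol_low = 1.2), "tol_low")
  expect_error(vote_config(1, radius = 0.5), "radius")
  expect_error(vote_config(0), "positive")
})
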