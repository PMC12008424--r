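#' Least-median-of-squares configuration
#'
#' @param n_samples number of random 4-pair minimal subsets to draw (>= 1).
#'   Ignored when exactly 4 pairs are supplied (direct solve).
#' @param refine if `TRUE`, after the best minimal model is found the
#'   homography is re-solved in the least-squares sense on its inliers.
#' @param inlier_k inlier threshold multiplier on the robust scale
#'   `1.4826 * (1 + 5 / (n - 4)) * sqrt(median squared residual)`.
#' @param seed optional integer; when set, subset sampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @return list of class `lmeds_config`.
#' @export
lmeds_config <- function(n_samples = 1000, refine = TRUE, inlier_k = 2.5,
                         seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (inlier_k <= 0) stop("inlier_k must be positive")
  structure(list(n_samples = as.integer(n_samples), refine = isTRUE(refine),
                 inlier_k = inlier_k, seed = seed),
            class = "lmeds_config")
}

# Run expr with a local RNG seed, preserving the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hartley normalisation: translate centroid to origin, scale RMS radius to
# sqrt(2). Returns the 3x3 conditioning matrix.
.hartley_matrix <- function(pts) {
  ctr <- colMeans(pts)
  rms <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  s <- if (rms < 1e-12) 1 else sqrt(2) / rms
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Direct linear transform for the homography src -> dst, with Hartley
# normalisation. Exact 8x8 solve for 4 pairs, SVD least squares otherwise.
# Returns a 3x3 matrix or NULL on degeneracy.
.solve_dlt <- function(src, dst) {
  n <- nrow(src)
  Ts <- .hartley_matrix(src); Td <- .hartley_matrix(dst)
  s <- t(Ts %*% rbind(t(src), 1))[, 1:2, drop = FALSE]
  d <- t(Td %*% rbind(t(dst), 1))[, 1:2, drop = FALSE]
  x <- s[, 1]; y <- s[, 2]; u <- d[, 1]; v <- d[, 2]
  zero <- numeric(n); one <- rep(1, n)
  M <- rbind(
    cbind(x, y, one, zero, zero, zero, -u * x, -u * y, -u),
    cbind(zero, zero, zero, x, y, one, -v * x, -v * y, -v))
  if (n == 4) {
    A <- M[, 1:8, drop = FALSE]; b <- -M[, 9]
    h8 <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(h8) || any(!is.finite(h8))) return(NULL)
    Hn <- matrix(c(h8, 1), 3, 3, byrow = TRUE)
  } else {
    sv <- tryCatch(svd(M, nu = 0, nv = 9), error = function(e) NULL)
    if (is.null(sv)) return(NULL)
    h <- sv$v[, 9]
    Hn <- matrix(h, 3, 3, byrow = TRUE)
  }
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12 || abs(det(H)) < 1e-12) return(NULL)
  H / H[3, 3]
}

# Squared reprojection distances of H applied to src against dst.
.sq_residuals <- function(H, src, dst) {
  h <- H %*% rbind(t(src), 1)
  z <- h[3, ]
  bad <- abs(z) < 1e-12
  r <- (h[1, ] / z - dst[, 1])^2 + (h[2, ] / z - dst[, 2])^2
  r[bad] <- Inf
  r
}

.collinear3 <- function(p, tol = 1e-9) {
  # TRUE if any 3 of the 4 points are collinear (twice-area test)
  tri <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (k in 1:4) {
    a <- p[tri[k, 1], ]; b <- p[tri[k, 2], ]; c <- p[tri[k, 3], ]
    ar <- abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (ar < tol) return(TRUE)
  }
  FALSE
}

#' Robust homography estimation by least median of squares
#'
#' Estimates the homography `H` with `dst ~ H (x) src` from point
#' correspondences. Random minimal subsets of 4 pairs are solved exactly by
#' the normalised direct linear transform; each candidate is scored by the
#' median squared reprojection error over all pairs and the minimiser is
#' kept. LMedS tolerates up to ~50% gross outliers: wrong pairings influence
#' the median hardly at all. With exactly 4 pairs sampling is skipped and
#' the interpolating homography is returned. If `cfg$refine` is set, the
#' model is re-solved in the least-squares sense on the inliers (residual
#' at most `inlier_k` times the robust scale).
#'
#' @param src,dst matched point matrices (model-placed points and extracted
#'   points), equal row counts, at least 4 rows.
#' @param cfg [lmeds_config()].
#' @return list of class `estimation_result`: `H` (`anchor_transform`),
#'   `residuals` (per-pair reprojection distances), `inlier_mask`,
#'   `median_sq_residual`, `robust_scale`.
#' @export
estimate_homography_lmeds <- function(src, dst, cfg = lmeds_config()) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal row counts")
  n <- nrow(src)
  if (n < 4) stop(sprintf("insufficient data: need >= 4 pairs, got %d", n))

  finish <- function(H) {
    r2 <- .sq_residuals(H, src, dst)
    med <- stats::median(r2)
    # Robust scale from the floor((n+4)/2)-th ordered residual rather than
    # the plain median: a homography interpolates 4 pairs exactly, so for
    # small n the median sits on the first free residual and the subset
    # search drives it arbitrarily low (Rousseeuw's finite-sample order
    # statistic, with the usual 1.4826 (1 + 5/(n-4)) consistency factor).
    k <- min(n, floor((n + 4) / 2))
    rk <- sort(r2, partial = k)[k]
    scale <- 1.4826 * (1 + 5 / max(n - 4, 1)) * sqrt(rk)
    inl <- sqrt(r2) <= max(cfg$inlier_k * scale, 1e-9)
    structure(list(H = transform_matrix(H, "homography"),
                   residuals = sqrt(r2), inlier_mask = inl,
                   median_sq_residual = med, robust_scale = scale),
              class = "estimation_result")
  }

  if (n == 4) {
    if (.collinear3(src) || .collinear3(dst)) stop("degenerate configuration: 3 collinear points")
    H <- .solve_dlt(src, dst)
    if (is.null(H)) stop("degenerate configuration: homography solve failed")
    return(finish(H))
  }

  # The sampling loop runs entirely in Hartley-normalised coordinates
  # (conditioning matrices computed once from the full sets); the median
  # ranking is invariant under the similarity normalisation of dst, so the
  # best subset can be selected there and denormalised once.
  Ts <- .hartley_matrix(src); Td <- .hartley_matrix(dst)
  sn <- t(Ts %*% rbind(t(src), 1)); dn <- t(Td %*% rbind(t(dst), 1))
  x <- sn[, 1]; y <- sn[, 2]; u <- dn[, 1]; v <- dn[, 2]
  A8 <- matrix(0, 8, 8); b8 <- numeric(8)
  solve_subset <- function(idx) {
    xs <- x[idx]; ys <- y[idx]; us <- u[idx]; vs <- v[idx]
    A8[1:4, 1] <<- xs; A8[1:4, 2] <<- ys; A8[1:4, 3] <<- 1
    A8[1:4, 4:6] <<- 0
    A8[1:4, 7] <<- -us * xs; A8[1:4, 8] <<- -us * ys
    A8[5:8, 1:3] <<- 0
    A8[5:8, 4] <<- xs; A8[5:8, 5] <<- ys; A8[5:8, 6] <<- 1
    A8[5:8, 7] <<- -vs * xs; A8[5:8, 8] <<- -vs * ys
    b8[1:4] <<- us; b8[5:8] <<- vs
    h <- tryCatch(solve(A8, b8), error = function(e) NULL)
    if (is.null(h) || any(!is.finite(h))) return(NULL)
    h
  }
  med_sq <- function(h) {
    z <- h[7] * x + h[8] * y + 1
    ru <- (h[1] * x + h[2] * y + h[3]) / z - u
    rv <- (h[4] * x + h[5] * y + h[6]) / z - v
    r <- ru * ru + rv * rv
    r[abs(z) < 1e-12] <- Inf
    stats::median(r)
  }
  res <- with_local_seed(cfg$seed, {
    best <- NULL; best_med <- Inf
    tries <- 0L; draws <- 0L
    while (draws < cfg$n_samples && tries < 20L * cfg$n_samples) {
      tries <- tries + 1L
      idx <- sample.int(n, 4)
      h <- solve_subset(idx)
      if (is.null(h)) next
      draws <- draws + 1L
      med <- med_sq(h)
      if (med < best_med) { best_med <- med; best <- h }
    }
    list(best = best, draws = draws)
  })
  if (is.null(res$best)) stop("degenerate configuration: all sampled subsets failed")

  h <- res$best
  Hn <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  Hbest <- solve(Td) %*% Hn %*% Ts
  if (abs(Hbest[3, 3]) < 1e-12) stop("degenerate configuration: homography at infinity")
  out <- finish(Hbest / Hbest[3, 3])
  # The minimal-subset winner interpolates its 4 points exactly, so its
  # median residual -- and hence the robust scale -- is biased low and the
  # first inlier set is too small. Iterate: least-squares DLT on the current
  # inliers, re-score all pairs against the refined model, re-derive the
  # scale and inlier set, until the set stabilises. Gross outliers keep
  # residuals far above the scale and stay excluded throughout.
  if (cfg$refine) {
    prev <- out$inlier_mask
    for (it in 1:5) {
      if (sum(prev) < 4) break
      Hr <- .solve_dlt(src[prev, , drop = FALSE], dst[prev, , drop = FALSE])
      if (is.null(Hr)) break
      out <- finish(Hr)
      if (identical(out$inlier_mask, prev)) break
      prev <- out$inlier_mask
    }
  }
  out
}

#' Reconstruct model-frame points from extracted points
#'
#' Inverts the registration chain: extracted image points are mapped back
#' through the estimated homography and the affine placement,
#' `P_t = A^-1 (H^-1 P_e)`, landing in model units on the absolute scale of
#' the structure model.
#'
#' @param A affine placement (`anchor_transform`).
#' @param H estimated homography (`anchor_transform`).
#' @param P_e extracted points in image coordinates.
#' @return point matrix in model units.
#' @export
reconstruct_points <- function(A, H, P_e) {
  apply_transform(invert_transform(A), apply_transform(invert_transform(H), P_e))
}
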