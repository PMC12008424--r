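#' Vote-filter configuration
#'
#' Controls the neighbour-distance vote rule used to remove extracted points
#' inconsistent with the known spacing of a periodic lattice.
#'
#' @param unit_length expected inter-structure distance L, in the frame of
#'   the filtered points.
#' @param radius candidate-neighbourhood radius; default `1.3 * L` captures
#'   the four axial neighbours of a square lattice and excludes diagonals.
#' @param tol_low,tol_high acceptance window multipliers of L; a candidate
#'   at distance within `[tol_low * L, tol_high * L]` counts +1, otherwise
#'   -1.
#' @return list of class `vote_config`.
#' @export
vote_config <- function(unit_length, radius = 1.3 * unit_length,
                        tol_low = 0.9, tol_high = 1.1) {
  if (unit_length <= 0) stop("unit_length must be positive")
  if (!(tol_low > 0 && tol_low < 1 && tol_high > 1)) {
    stop("need 0 < tol_low < 1 < tol_high")
  }
  if (radius < tol_high * unit_length) {
    stop("radius must be at least tol_high * unit_length")
  }
  structure(list(unit_length = unit_length, radius = radius,
                 tol_low = tol_low, tol_high = tol_high),
            class = "vote_config")
}

#' Vote-based outlier filtering of a periodic point cloud
#'
#' Each point serves in turn as a vote target; all other points within
#' `cfg$radius` are candidates. The target's score gains +1 per candidate
#' whose distance lies in `[tol_low * L, tol_high * L]` and loses 1
#' otherwise. Points with a negative score are removed; isolated points (no
#' candidates) score 0 and are kept. An interior point of a perfect square
#' lattice scores +4 from its axial neighbours; a spurious midpoint typically
#' scores -2.
#'
#' @param pts point matrix.
#' @param cfg [vote_config()].
#' @return list of class `vote_result`: `scores` (integer per input point),
#'   `kept`, `removed` (point matrices), `kept_idx`.
#' @export
vote_filter <- function(pts, cfg) {
  pts <- as_points(pts)
  stopifnot(inherits(cfg, "vote_config"), nrow(pts) >= 1)
  n <- nrow(pts)
  scores <- integer(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(pts))
    lo <- cfg$tol_low * cfg$unit_length
    hi <- cfg$tol_high * cfg$unit_length
    for (i in seq_len(n)) {
      di <- d[i, -i]
      cand <- di[di <= cfg$radius]
      if (length(cand)) {
        scores[i] <- sum(ifelse(cand >= lo & cand <= hi, 1L, -1L))
      }
    }
  }
  keep <- scores >= 0
  structure(list(scores = scores,
                 kept = pts[keep, , drop = FALSE],
                 removed = pts[!keep, , drop = FALSE],
                 kept_idx = which(keep)),
            class = "vote_result")
}

#' Pair model points with extracted points under a distance gate
#'
#' Greedy one-to-one assignment by ascending distance: among all
#' (model, extracted) pairs with distance at most `gate`, repeatedly claim
#' the closest pair whose members are both still free. Ties are broken by
#' the lower model index. Exact nearest-neighbour distances are computed
#' over the full cross-distance matrix (the point sets in this setting are
#' small).
#'
#' @param P_m_placed placed model points (P_m').
#' @param P_e extracted points.
#' @param gate maximum pairing distance (> 0).
#' @return list of class `pair_set` with `pairs` (data.frame: `model`,
#'   `extracted`, `distance`), `unpaired_model`, `unpaired_extracted`, `gate`.
#' @export
pair_points <- function(P_m_placed, P_e, gate) {
  P_m_placed <- as_points(P_m_placed); P_e <- as_points(P_e)
  if (gate <= 0) stop("gate must be positive")
  nm <- nrow(P_m_placed); ne <- nrow(P_e)
  d <- outer(rowSums(P_m_placed^2), rep(1, ne)) +
       outer(rep(1, nm), rowSums(P_e^2)) -
       2 * P_m_placed %*% t(P_e)
  d <- sqrt(pmax(d, 0))
  cand <- which(d <= gate, arr.ind = TRUE)
  res <- data.frame(model = integer(0), extracted = integer(0),
                    distance = numeric(0))
  if (nrow(cand)) {
    ord <- order(d[cand], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    used_m <- logical(nm); used_e <- logical(ne)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_m[i] && !used_e[j]) {
        used_m[i] <- TRUE; used_e[j] <- TRUE
        res <- rbind(res, data.frame(model = i, extracted = j,
                                     distance = d[i, j]))
      }
    }
  }
  structure(list(pairs = res,
                 unpaired_model = setdiff(seq_len(nm), res$model),
                 unpaired_extracted = setdiff(seq_len(ne), res$extracted),
                 gate = gate),
            class = "pair_set")
}

#' Place the model near the extracted points by brute-force translation
#'
#' The non-translational affine parameters (scale, rotation, shear) are
#' assumed known from prior knowledge of the structure and the experimental
#' setup; only the translation `(x_0, y_0)` is optimised, by exhaustive
#' evaluation on a grid. For lattice models the grid covers one primitive
#' cell (translation is only identifiable modulo the lattice); for polygon
#' models it covers the bounding box of `P_e` expanded by the model extent.
#' The placement objective is the median nearest-neighbour distance from the
#' placed model points to `P_e`, which is robust to missing detections.
#'
#' @param model `anchor_model`.
#' @param fixed [affine_params()] with the known scale/rotation/shear
#'   (its translation entries are ignored).
#' @param P_e extracted points (non-empty).
#' @param grid_step translation grid step in P_e-frame units; default
#'   `L_image / 50` where `L_image` is the placed unit length.
#' @param gate pairing gate passed to [pair_points()]; default
#'   `0.35 * L_image`.
#' @param search optional explicit translation grid, a list with numeric
#'   vectors `tx`, `ty` of image-frame offsets (evaluated as their cross
#'   product); overrides the automatic grid.
#' @return list of class `rough_match`: `affine` (optimised
#'   `affine_params`), `placed_model` (P_m'), `pairs` ([pair_points()]
#'   result), `objective`.
#' @export
place_model <- function(model, fixed, P_e, grid_step = NULL, gate = NULL,
                        search = NULL) {
  stopifnot(inherits(model, "anchor_model"))
  if (!inherits(fixed, "affine_params")) fixed <- do.call(affine_params, fixed)
  P_e <- as_points(P_e)
  if (nrow(P_e) == 0) stop("P_e must be non-empty")

  base_par <- fixed; base_par$x_0 <- 0; base_par$y_0 <- 0
  A0 <- compose_affine(base_par)
  P0 <- apply_transform(A0, model$points)
  L_img <- model$unit_length * sqrt(fixed$s_x * fixed$s_y)
  if (is.null(grid_step)) grid_step <- L_img / 50
  if (is.null(gate)) gate <- 0.35 * L_img

  if (!is.null(search)) {
    if (!length(search$tx) || !length(search$ty)) stop("empty translation search grid")
    fr <- expand.grid(tx = search$tx, ty = search$ty)
    tx <- fr$tx; ty <- fr$ty
  } else if (!is.null(model$basis)) {
    # one primitive cell, in the placed frame
    b1 <- apply_transform(A0, rbind(model$unit_length * model$basis[1, ])) -
          apply_transform(A0, rbind(c(0, 0)))
    b2 <- apply_transform(A0, rbind(model$unit_length * model$basis[2, ])) -
          apply_transform(A0, rbind(c(0, 0)))
    # centre the finite model block on the extracted cloud, then search one
    # primitive cell around that alignment (translation is only identifiable
    # modulo the lattice, but the block must overlap the detections)
    origin <- colMeans(P_e) - colMeans(P0)
    f1 <- seq(-0.5, 0.5, by = grid_step / sqrt(sum(b1^2)))
    f2 <- seq(-0.5, 0.5, by = grid_step / sqrt(sum(b2^2)))
    fr <- expand.grid(f1 = f1, f2 = f2)
    tx <- origin[1] + fr$f1 * b1[1] + fr$f2 * b2[1]
    ty <- origin[2] + fr$f1 * b1[2] + fr$f2 * b2[2]
  } else {
    lo <- apply(P_e, 2, min) - (apply(P0, 2, max) - apply(P0, 2, min))
    hi <- apply(P_e, 2, max)
    tx0 <- seq(lo[1] - min(P0[, 1]), hi[1] - min(P0[, 1]), by = grid_step)
    ty0 <- seq(lo[2] - min(P0[, 2]), hi[2] - min(P0[, 2]), by = grid_step)
    fr <- expand.grid(tx = tx0, ty = ty0)
    tx <- fr$tx; ty <- fr$ty
  }
  if (!length(tx)) stop("empty translation search grid")

  # objective: median NN distance from placed model to P_e, per translation
  obj <- .placement_objective(P0, P_e, tx, ty)
  best <- which.min(obj)
  if (!is.finite(obj[best])) stop("placement failure: no candidate near any model point")

  # the affine translation acts pre-rotation (A = S R Sh T); recover the
  # model-frame translation giving the chosen image-frame offset
  M <- A0$m[1:2, 1:2]
  t_model <- solve(M, c(tx[best], ty[best]))
  opt <- fixed; opt$x_0 <- t_model[1]; opt$y_0 <- t_model[2]
  A <- compose_affine(opt)
  placed <- apply_transform(A, model$points)
  pairs <- pair_points(placed, P_e, gate)
  if (nrow(pairs$pairs) == 0) stop("placement failure: no pairs within gate")
  structure(list(affine = opt, placed_model = placed, pairs = pairs,
                 objective = obj[best]),
            class = "rough_match")
}

# median over model points of min distance to P_e, for each (tx, ty)
.placement_objective <- function(P0, P_e, tx, ty) {
  nm <- nrow(P0)
  vapply(seq_along(tx), function(k) {
    px <- P0[, 1] + tx[k]; py <- P0[, 2] + ty[k]
    dmin <- vapply(seq_len(nm), function(i) {
      min((P_e[, 1] - px[i])^2 + (P_e[, 2] - py[i])^2)
    }, numeric(1))
    stats::median(sqrt(dmin))
  }, numeric(1))
}
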