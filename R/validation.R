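#' Keypoint accuracy metrics
#'
#' `mae()` is the mean Euclidean distance between corresponding points, in
#' model units. `oks()` is the mean per-point Gaussian similarity
#' `exp(-d^2 / (2 s^2 kappa^2))` (object keypoint similarity with a uniform
#' per-point falloff), in `(0, 1]`. `recall_at_oks()` is the fraction of
#' per-sample OKS values strictly exceeding a threshold.
#'
#' @param P_t reconstructed points.
#' @param P_m reference model points, same length and order.
#' @return `mae`: non-negative scalar in model units.
#' @export
mae <- function(P_t, P_m) {
  P_t <- as_points(P_t); P_m <- as_points(P_m)
  if (nrow(P_t) != nrow(P_m)) stop("point sets must have equal lengths")
  mean(sqrt(rowSums((P_t - P_m)^2)))
}

#' Metric configuration for OKS
#'
#' @param oks_scale spatial scale `s` in model units (default the unit
#'   length, 1).
#' @param oks_kappa per-point falloff constant `kappa`.
#' @param oks_threshold recall cutoff in `(0, 1]`.
#' @return list of class `metric_config`.
#' @export
metric_config <- function(oks_scale = 1, oks_kappa = 0.5, oks_threshold = 0.95) {
  if (oks_scale <= 0 || oks_kappa <= 0) stop("oks_scale and oks_kappa must be positive")
  if (oks_threshold <= 0 || oks_threshold > 1) stop("oks_threshold must be in (0, 1]")
  structure(list(oks_scale = oks_scale, oks_kappa = oks_kappa,
                 oks_threshold = oks_threshold),
            class = "metric_config")
}

#' @rdname mae
#' @param cfg [metric_config()].
#' @return `oks`: scalar in `(0, 1]`.
#' @export
oks <- function(P_t, P_m, cfg = metric_config()) {
  P_t <- as_points(P_t); P_m <- as_points(P_m)
  if (nrow(P_t) != nrow(P_m)) stop("point sets must have equal lengths")
  d2 <- rowSums((P_t - P_m)^2)
  mean(exp(-d2 / (2 * cfg$oks_scale^2 * cfg$oks_kappa^2)))
}

#' @rdname mae
#' @param oks_values numeric vector of per-sample OKS values.
#' @param threshold recall cutoff.
#' @return `recall_at_oks`: fraction in `[0, 1]`.
#' @export
recall_at_oks <- function(oks_values, threshold = 0.95) {
  if (!length(oks_values)) stop("oks_values must be non-empty")
  mean(oks_values > threshold)
}

#' Homography perturbation magnitudes
#'
#' Magnitudes of the independent perturbations applied to the identity when
#' drawing a random homography: scale factors uniform in `1 +/- sigma_s`,
#' rotation uniform in `+/- sigma_theta` radians, shear in `+/- sigma_a`,
#' translation in `+/- sigma_t` model units, projective terms `g, h` in
#' `+/- sigma_p` per model unit.
#'
#' @param sigma_s,sigma_theta,sigma_a,sigma_t,sigma_p non-negative magnitudes.
#' @return list of class `homography_magnitude`.
#' @export
homography_magnitude <- function(sigma_s = 0.1, sigma_theta = 0.1,
                                 sigma_a = 0.05, sigma_t = 0.5,
                                 sigma_p = 0.01) {
  v <- c(sigma_s, sigma_theta, sigma_a, sigma_t, sigma_p)
  if (any(v < 0)) stop("magnitudes must be non-negative")
  structure(list(sigma_s = sigma_s, sigma_theta = sigma_theta,
                 sigma_a = sigma_a, sigma_t = sigma_t, sigma_p = sigma_p),
            class = "homography_magnitude")
}

#' Draw a random homography as a perturbation of the identity
#'
#' Scale, rotation, shear and translation are composed as an affine matrix
#' (same factor order as [compose_affine()]) and the projective terms are
#' set independently. Draws are rejected (and resampled, up to 100 tries)
#' unless the matrix is invertible and the homogeneous `z` stays positive
#' over `extent` model units in each direction, so the lattice never crosses
#' the horizon line.
#'
#' @param mag [homography_magnitude()].
#' @param extent half-extent (model units) over which positivity of `z` is
#'   enforced.
#' @return `anchor_transform` of kind `"homography"`.
#' @export
random_homography <- function(mag = homography_magnitude(), extent = 8) {
  stopifnot(inherits(mag, "homography_magnitude"))
  for (try in seq_len(100)) {
    par <- affine_params(
      s_x = 1 + stats::runif(1, -mag$sigma_s, mag$sigma_s),
      s_y = 1 + stats::runif(1, -mag$sigma_s, mag$sigma_s),
      theta = stats::runif(1, -mag$sigma_theta, mag$sigma_theta),
      a_x = stats::runif(1, -mag$sigma_a, mag$sigma_a),
      a_y = stats::runif(1, -mag$sigma_a, mag$sigma_a),
      x_0 = stats::runif(1, -mag$sigma_t, mag$sigma_t),
      y_0 = stats::runif(1, -mag$sigma_t, mag$sigma_t))
    m <- compose_affine(par)$m
    m[3, 1] <- stats::runif(1, -mag$sigma_p, mag$sigma_p)
    m[3, 2] <- stats::runif(1, -mag$sigma_p, mag$sigma_p)
    corners <- rbind(c(-extent, -extent), c(extent, -extent),
                     c(-extent, extent), c(extent, extent))
    z <- m[3, 1] * corners[, 1] + m[3, 2] * corners[, 2] + 1
    if (all(z > 0.05) && abs(det(m)) > 1e-12) {
      return(transform_matrix(m, "homography"))
    }
  }
  stop("failed to draw an invertible homography in 100 tries")
}

#' Sweep configuration for the Monte-Carlo accuracy study
#'
#' @param noise_stds Gaussian detection-noise standard deviations (model
#'   units), each >= 0.
#' @param point_counts anchor-point counts; each must be a perfect square
#'   (square lattices), >= 4.
#' @param n_samples Monte-Carlo repetitions per condition.
#' @param magnitude [homography_magnitude()] for the random draw.
#' @param seed RNG seed for the whole sweep.
#' @param lmeds_n_samples LMedS subset draws per estimate for point counts
#'   above 4 (4-point conditions solve directly).
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(noise_stds = seq(0, 0.1, by = 0.01),
                         point_counts = c(4, 9, 16, 25, 36, 49),
                         n_samples = 10000,
                         magnitude = homography_magnitude(),
                         seed = 1, lmeds_n_samples = 64) {
  if (any(noise_stds < 0)) stop("noise_stds must be >= 0")
  if (any(point_counts < 4)) stop("point_counts must be >= 4")
  if (any(sqrt(point_counts) %% 1 != 0)) stop("point_counts must be perfect squares")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(noise_stds = noise_stds, point_counts = as.integer(point_counts),
                 n_samples = as.integer(n_samples), magnitude = magnitude,
                 seed = seed, lmeds_n_samples = as.integer(lmeds_n_samples)),
            class = "sweep_config")
}

#' Monte-Carlo validation of registration accuracy under detection noise
#'
#' For every (noise std, point count) condition, repeats `n_samples` times:
#' build a square lattice of model anchor points (unit length 1), draw a
#' random homography `H_true`, transform the lattice, add i.i.d. Gaussian
#' noise per coordinate in the transformed (image) frame, estimate `H_est`
#' from the (model, noisy) pairs with the LMedS solver, reconstruct
#' `P_t = H_est^-1 (x) P_e_clean` (the noise-free transformed positions,
#' because rectification warps the underlying image, not the noisy
#' detections), and record `MAE(P_t, P_m)` and `OKS(P_t, P_m)`. A failed
#' estimation is recorded as MAE = Inf, OKS = 0.
#'
#' @param cfg [sweep_config()].
#' @param metric [metric_config()].
#' @return list of class `sweep_result`: `samples` (data.frame with columns
#'   `noise_std`, `point_count`, `sample`, `mae`, `oks`, `failed`) and
#'   `summary` (per-condition mean/median/quartile MAE and
#'   `recall` = fraction of samples with OKS above the threshold).
#' @export
run_noise_sweep <- function(cfg = sweep_config(), metric = metric_config()) {
  stopifnot(inherits(cfg, "sweep_config"), inherits(metric, "metric_config"))
  with_local_seed(cfg$seed, {
    rows <- vector("list", length(cfg$noise_stds) * length(cfg$point_counts))
    k <- 0L
    for (pc in cfg$point_counts) {
      nside <- as.integer(sqrt(pc))
      P_m <- make_lattice_model(nside, nside)$points
      lcfg <- lmeds_config(n_samples = cfg$lmeds_n_samples, refine = TRUE)
      mae_v <- numeric(cfg$n_samples); oks_v <- numeric(cfg$n_samples)
      for (ns in cfg$noise_stds) {
        fail_v <- logical(cfg$n_samples)
        for (s in seq_len(cfg$n_samples)) {
          H_true <- random_homography(cfg$magnitude, extent = nside)
          P_clean <- apply_transform(H_true, P_m)
          P_noisy <- P_clean + matrix(stats::rnorm(2 * pc, sd = ns), pc, 2)
          est <- tryCatch(estimate_homography_lmeds(P_m, P_noisy, lcfg),
                          error = function(e) NULL)
          if (is.null(est)) {
            mae_v[s] <- Inf; oks_v[s] <- 0; fail_v[s] <- TRUE
          } else {
            P_t <- tryCatch(apply_transform(invert_transform(est$H), P_clean),
                            error = function(e) NULL)
            if (is.null(P_t)) {
              mae_v[s] <- Inf; oks_v[s] <- 0; fail_v[s] <- TRUE
            } else {
              mae_v[s] <- mae(P_t, P_m)
              oks_v[s] <- oks(P_t, P_m, metric)
            }
          }
        }
        k <- k + 1L
        rows[[k]] <- data.frame(noise_std = ns, point_count = pc,
                                sample = seq_len(cfg$n_samples),
                                mae = mae_v, oks = oks_v, failed = fail_v)
      }
    }
    samples <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(samples, list(samples$noise_std, samples$point_count), drop = TRUE), function(g) {
      q <- stats::quantile(g$mae[is.finite(g$mae)], c(0.25, 0.5, 0.75),
                           names = FALSE)
      data.frame(noise_std = g$noise_std[1], point_count = g$point_count[1],
                 mae_mean = mean(g$mae[is.finite(g$mae)]),
                 mae_q1 = q[1], mae_median = q[2], mae_q3 = q[3],
                 recall = recall_at_oks(g$oks, metric$oks_threshold),
                 n_failed = sum(g$failed))
    }))
    rownames(agg) <- NULL
    agg <- agg[order(agg$point_count, agg$noise_std), ]
    structure(list(samples = samples, summary = agg,
                   config = cfg, metric = metric),
              class = "sweep_result")
  })
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %d conditions x %d samples>\n",
              nrow(x$summary), x$config$n_samples))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render a synthetic microscopy fixture with known ground truth
#'
#' Renders dark Gaussian wells at the image positions of the model's anchor
#' points under a known homography `H_true` (which maps model units to pixel
#' coordinates, including the pixel scale), optionally bright Gaussian spots
#' at template sub-feature positions (omitting a caller-specified defect
#' list), plus additive Gaussian pixel noise. Spots are rendered directly at
#' the transformed centres so the ground-truth coordinates are exact.
#'
#' @param model `anchor_model`.
#' @param H_true `anchor_transform` mapping model to pixel coordinates.
#' @param size image `(rows, cols)`.
#' @param template optional `unit_cell_template`; its sub-features are
#'   rendered bright for every cell origin in `cell_origins`.
#' @param cell_origins model-frame cell origins at which to stamp the
#'   template (point matrix); default the model's anchor points when a
#'   template is given.
#' @param defects optional data.frame with columns `cell` (row index into
#'   `cell_origins`) and `subfeature` (index into the template order);
#'   those spots are left unrendered (defect sites).
#' @param spot_sigma Gaussian spot width, pixels.
#' @param amplitude spot amplitude relative to the 0.5 background.
#' @param noise_sd additive pixel-noise standard deviation; the fixture SNR
#'   is `amplitude / noise_sd`.
#' @param seed optional seed for the pixel noise.
#' @return list of class `fixture`: `image` (matrix in `[0, 1]`),
#'   `anchors_image` (true anchor centres, pixel coords), `subfeatures_image`
#'   (data.frame with `cell`, `subfeature`, `x`, `y`, `present`), `H_true`,
#'   `defects`.
#' @export
render_fixture <- function(model, H_true, size = c(96, 96), template = NULL,
                           cell_origins = NULL, defects = NULL,
                           spot_sigma = 1.6, amplitude = 0.4,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "anchor_model"), inherits(H_true, "anchor_transform"))
  anchors <- apply_transform(H_true, model$points)
  nr <- size[1]; nc <- size[2]
  inb <- anchors[, 1] >= 1 & anchors[, 1] <= nc - 2 &
         anchors[, 2] >= 1 & anchors[, 2] <= nr - 2
  if (!all(inb)) {
    stop(sprintf("anchor points outside canvas under H_true: %s",
                 paste(which(!inb), collapse = ", ")))
  }
  img <- matrix(0.5, nr, nc)
  xg <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  stamp <- function(img, px, py, amp) {
    img + amp * exp(-((xg - px)^2 + (yg - py)^2) / (2 * spot_sigma^2))
  }
  for (i in seq_len(nrow(anchors))) {
    img <- stamp(img, anchors[i, 1], anchors[i, 2], -amplitude)
  }
  sub_df <- NULL
  if (!is.null(template)) {
    if (is.null(cell_origins)) cell_origins <- model$points
    cell_origins <- as_points(cell_origins)
    recs <- list()
    for (ci in seq_len(nrow(cell_origins))) {
      pos <- apply_transform(H_true,
               sweep(template$subfeature_offsets, 2, cell_origins[ci, ], "+"))
      for (si in seq_len(nrow(pos))) {
        absent <- !is.null(defects) &&
          any(defects$cell == ci & defects$subfeature == si)
        if (!absent) img <- stamp(img, pos[si, 1], pos[si, 2], amplitude)
        recs[[length(recs) + 1]] <- data.frame(cell = ci, subfeature = si,
                                               x = pos[si, 1], y = pos[si, 2],
                                               present = !absent)
      }
    }
    sub_df <- do.call(rbind, recs)
  }
  if (noise_sd > 0) {
    img <- img + with_local_seed(seed, matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc))
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, anchors_image = anchors,
                 subfeatures_image = sub_df, H_true = H_true,
                 defects = defects),
            class = "fixture")
}
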