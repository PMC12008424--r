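#' End-to-end anchor-point registration
#'
#' Runs the two-stage workflow: (optional) keypoint extraction from an
#' image, vote filtering of the point cloud (periodic lattice models only),
#' brute-force placement of the model, gated nearest-neighbour pairing,
#' robust homography estimation by LMedS, and absolute-scale reconstruction
#' `P_t = A^-1 H^-1 P_e`. Accuracy of the reconstruction against the model
#' anchors is summarised by MAE and OKS.
#'
#' If fewer than 4 pairs survive, the pairing gate is relaxed once by a
#' factor 1.5 (status `"degraded"` when that rescue is used). Unrecoverable
#' failures return a result with status `"failed"` and a `reason` rather
#' than throwing.
#'
#' @param x either an extracted point matrix (image coordinates) or a
#'   numeric image matrix (then `detection` is used to extract points).
#' @param model `anchor_model`.
#' @param fixed [affine_params()] carrying the known scale / rotation /
#'   shear of the placement (translation entries ignored).
#' @param detection [detection_config()] used when `x` is an image.
#' @param vote apply the vote filter (default: only for lattice models).
#' @param vote_cfg optional [vote_config()]; defaults to the placed unit
#'   length with the standard `[0.9 L, 1.1 L]` window.
#' @param gate pairing gate; default `0.35` of the placed unit length.
#' @param grid_step translation search step; default placed unit length / 50.
#' @param lmeds [lmeds_config()].
#' @param metric [metric_config()].
#' @return list of class `registration_result`: `affine` (optimised
#'   `affine_params`), `A`, `H` (`anchor_transform`s), `P_e_used`, `pairs`,
#'   `P_t` (model units, one row per pair), `model_idx` (model row of each
#'   reconstructed point), `mae`, `oks`, `status` (`ok` / `degraded` /
#'   `failed`), `reason`, `model`.
#' @export
register <- function(x, model, fixed = affine_params(),
                     detection = detection_config(), vote = NULL,
                     vote_cfg = NULL, gate = NULL, grid_step = NULL,
                     lmeds = lmeds_config(), metric = metric_config()) {
  stopifnot(inherits(model, "anchor_model"))
  if (!inherits(fixed, "affine_params")) fixed <- do.call(affine_params, fixed)
  fail <- function(reason) {
    structure(list(affine = fixed, A = NULL, H = NULL, P_e_used = NULL,
                   pairs = NULL, P_t = NULL, model_idx = integer(0),
                   mae = NA_real_, oks = NA_real_, status = "failed",
                   reason = reason, model = model),
              class = "registration_result")
  }

  # a two-column matrix is taken as an extracted point set, anything else
  # as an image to run detection on
  P_e <- if (!is.null(dim(x)) && ncol(x) == 2) as_points(x) else
    detect_dark_keypoints(as.matrix(x), detection)
  if (nrow(P_e) == 0) return(fail("no extracted points"))

  L_img <- model$unit_length * sqrt(fixed$s_x * fixed$s_y)
  if (is.null(vote)) vote <- !is.null(model$basis)
  if (isTRUE(vote)) {
    if (is.null(vote_cfg)) vote_cfg <- vote_config(L_img)
    vres <- vote_filter(P_e, vote_cfg)
    P_e <- vres$kept
    if (nrow(P_e) == 0) return(fail("vote filter removed every point"))
  }
  if (is.null(gate)) gate <- 0.35 * L_img

  rough <- tryCatch(place_model(model, fixed, P_e, grid_step = grid_step,
                                gate = gate),
                    error = function(e) conditionMessage(e))
  if (is.character(rough)) return(fail(paste("placement:", rough)))

  status <- "ok"
  pairs <- rough$pairs
  if (nrow(pairs$pairs) < 4) {
    pairs <- pair_points(rough$placed_model, P_e, gate * 1.5)
    status <- "degraded"
    message("register: fewer than 4 pairs; pairing gate relaxed by 1.5x")
    if (nrow(pairs$pairs) < 4) return(fail("fewer than 4 pairs even after gate relaxation"))
  }

  A <- compose_affine(rough$affine)
  src <- rough$placed_model[pairs$pairs$model, , drop = FALSE]
  dst <- P_e[pairs$pairs$extracted, , drop = FALSE]
  est <- tryCatch(estimate_homography_lmeds(src, dst, lmeds),
                  error = function(e) conditionMessage(e))
  if (is.character(est)) return(fail(paste("estimation:", est)))

  P_t <- tryCatch(reconstruct_points(A, est$H, dst),
                  error = function(e) conditionMessage(e))
  if (is.character(P_t)) return(fail(paste("reconstruction:", P_t)))

  ref <- model$points[pairs$pairs$model, , drop = FALSE]
  structure(list(affine = rough$affine, A = A, H = est$H, P_e_used = P_e,
                 pairs = pairs, estimation = est, P_t = P_t,
                 model_idx = pairs$pairs$model,
                 mae = mae(P_t, ref), oks = oks(P_t, ref, metric),
                 status = status, reason = NULL, model = model),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: status %s>\n", x$status))
  if (x$status == "failed") {
    cat("  reason:", x$reason, "\n")
  } else {
    cat(sprintf("  pairs: %d   MAE: %.4g   OKS: %.4g\n",
                nrow(x$pairs$pairs), x$mae, x$oks))
  }
  invisible(x)
}

#' Rectify an image to the absolute model scale
#'
#' Warps the image by the inverse of the estimated chain `H A` composed
#' with a model-to-pixel scaling, so that after warping every model anchor
#' sits at pixel `pixels_per_unit * model_coordinate + margin` on an exact
#' undistorted grid; non-linear drift and creep distortion captured by `H`
#' is thereby removed.
#'
#' @param img image matrix.
#' @param result successful `registration_result`.
#' @param pixels_per_unit output pixels per model unit length.
#' @param margin border margin in output pixels.
#' @param out_shape output `(rows, cols)`; default sized to the model
#'   extent plus margins.
#' @param fill fill value for out-of-bounds samples.
#' @return warped image matrix with attributes `transform` (the full
#'   input-to-output `anchor_transform`) and `anchors_px` (ideal anchor
#'   positions in the output).
#' @export
rectify <- function(img, result, pixels_per_unit, margin = pixels_per_unit,
                    out_shape = NULL, fill = 0) {
  stopifnot(inherits(result, "registration_result"))
  if (result$status == "failed") stop("cannot rectify a failed registration")
  M <- compose_transforms(result$H, result$A)      # model -> image
  scale_T <- transform_matrix(matrix(c(pixels_per_unit, 0, margin,
                                       0, pixels_per_unit, margin,
                                       0, 0, 1), 3, 3, byrow = TRUE))
  T <- compose_transforms(scale_T, invert_transform(M))  # image -> output
  anchors_px <- apply_transform(scale_T, result$model$points)
  if (is.null(out_shape)) {
    out_shape <- c(ceiling(max(anchors_px[, 2]) + margin) + 1,
                   ceiling(max(anchors_px[, 1]) + margin) + 1)
  }
  out <- warp_image(img, T, out_shape = out_shape, fill = fill)
  attr(out, "transform") <- T
  attr(out, "anchors_px") <- anchors_px
  out
}

#' Locate unit-cell sub-features and encode them as binary vectors
#'
#' For every complete unit cell whose defining anchors were matched during
#' registration, projects the template sub-features into the image with the
#' estimated `A` and `H`, classifies each projected site by pixel values,
#' and emits the cell's ordered binary feature vector (1 = present/adatom,
#' 0 = absent/defect). Cells with any projected sub-feature outside the
#' image are skipped (with a reason recorded), never extrapolated.
#'
#' @param img image matrix the registration was computed on.
#' @param result successful `registration_result`.
#' @param template `unit_cell_template`.
#' @param window classification patch half-width (pixels).
#' @param threshold classification threshold; the default
#'   `median(img) + 0.1 * dynamic range` separates bright sub-feature spots
#'   from background robustly even when a frame has no defects at all (a
#'   patch-statistics midpoint would split such a frame in half).
#' @param anchor_tol tolerance (model units) for deciding that a cell
#'   anchor coincides with a matched model anchor.
#' @return list of class `cell_features`: `cells` (list with `cell_id`
#'   lattice index, `origin_index`, `vector`, `anchor_image_pos`),
#'   `skipped` (data.frame of skipped origins and reasons).
#' @export
localize_and_encode <- function(img, result, template, window = 2,
                                threshold = NULL, anchor_tol = 1e-6) {
  stopifnot(inherits(result, "registration_result"),
            inherits(template, "unit_cell_template"))
  if (result$status == "failed") stop("registration failed; nothing to encode")
  img <- as.matrix(img)
  model <- result$model
  if (is.null(threshold)) {
    threshold <- stats::median(img) + 0.1 * diff(range(img))
  }
  matched <- model$points[unique(result$model_idx), , drop = FALSE]
  near_matched <- function(p) {
    any(sqrt((matched[, 1] - p[1])^2 + (matched[, 2] - p[2])^2) <= anchor_tol)
  }
  nr <- nrow(img); nc <- ncol(img)
  cells <- list(); skipped <- list()
  for (oi in seq_len(nrow(model$points))) {
    origin <- model$points[oi, ]
    anchors <- sweep(template$cell_anchor_offsets * model$unit_length, 2,
                     origin, "+")
    if (!all(apply(anchors, 1, near_matched))) {
      skipped[[length(skipped) + 1]] <- data.frame(origin_index = oi,
                                                   reason = "cell anchors not all matched")
      next
    }
    pos <- project_subfeatures(template, result$A, result$H,
                               cell_origin = origin)
    if (any(pos[, 1] < window | pos[, 1] > nc - 1 - window |
            pos[, 2] < window | pos[, 2] > nr - 1 - window)) {
      skipped[[length(skipped) + 1]] <- data.frame(origin_index = oi,
                                                   reason = "projected sub-feature outside image")
      next
    }
    lab <- classify_sites(img, pos, window = window, threshold = threshold)
    cell_id <- if (!is.null(model$basis)) {
      as.integer(round(solve(t(model$basis), origin / model$unit_length)))
    } else c(oi, 0L)
    cells[[length(cells) + 1]] <- list(
      cell_id = cell_id, origin_index = oi,
      vector = as.integer(lab$label == "present"),
      anchor_image_pos = apply_transform(result$H,
        apply_transform(result$A, rbind(origin)))[1, ])
  }
  structure(list(cells = cells,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL),
            class = "cell_features")
}

#' Match unit cells across two frames by their feature vectors
#'
#' Candidate matches are cells with identical binary vectors; the returned
#' set is the one consistent with a single lattice translation (vector
#' equality plus agreement of relative cell offsets), chosen to maximise
#' the number of matched cells. If no translation is uniquely best (e.g.
#' every cell carries the same vector), an empty result with a diagnostic
#' is returned.
#'
#' @param cells_a,cells_b `cell_features` objects (or their `cells` lists).
#' @return list of class `frame_match`: `matches` (data.frame `cell_a`,
#'   `cell_b` origin indices, `score` = Hamming distance, always 0),
#'   `translation` (lattice offset b - a), `diagnostic`.
#' @export
match_frames <- function(cells_a, cells_b) {
  ca <- if (inherits(cells_a, "cell_features")) cells_a$cells else cells_a
  cb <- if (inherits(cells_b, "cell_features")) cells_b$cells else cells_b
  if (!length(ca) || !length(cb)) stop("both frames must contain cells")
  key <- function(cl) paste(cl$vector, collapse = "")
  ida <- t(vapply(ca, function(cl) as.numeric(cl$cell_id), numeric(2)))
  idb <- t(vapply(cb, function(cl) as.numeric(cl$cell_id), numeric(2)))
  ka <- vapply(ca, key, character(1)); kb <- vapply(cb, key, character(1))
  if (length(unique(c(ka, kb))) < 2) {
    return(structure(list(matches = NULL, translation = NULL,
                          diagnostic = paste("ambiguous: all cells carry the",
                                             "same feature vector")),
                     class = "frame_match"))
  }
  # tally candidate translations over vector-identical pairs
  trans <- list()
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    if (ka[i] == kb[j]) {
      t_ij <- idb[j, ] - ida[i, ]
      trans[[length(trans) + 1]] <- t_ij
    }
  }
  if (!length(trans)) {
    return(structure(list(matches = NULL, translation = NULL,
                          diagnostic = "no vector-identical cell pairs"),
                     class = "frame_match"))
  }
  tm <- unique(do.call(rbind, trans))
  count_for <- function(tv) {
    sum(vapply(seq_along(ca), function(i) {
      j <- which(idb[, 1] == ida[i, 1] + tv[1] & idb[, 2] == ida[i, 2] + tv[2])
      length(j) == 1 && kb[j] == ka[i]
    }, logical(1)))
  }
  counts <- apply(tm, 1, count_for)
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    return(structure(list(matches = NULL, translation = NULL,
                          diagnostic = sprintf(
                            "ambiguous: %d translations tie at %d consistent matches",
                            length(best), max(counts))),
                     class = "frame_match"))
  }
  tv <- tm[best, ]
  rows <- list()
  for (i in seq_along(ca)) {
    j <- which(idb[, 1] == ida[i, 1] + tv[1] & idb[, 2] == ida[i, 2] + tv[2])
    if (length(j) == 1 && kb[j] == ka[i]) {
      rows[[length(rows) + 1]] <- data.frame(cell_a = ca[[i]]$origin_index,
                                             cell_b = cb[[j]]$origin_index,
                                             score = 0L)
    }
  }
  structure(list(matches = do.call(rbind, rows), translation = tv,
                 diagnostic = NULL),
            class = "frame_match")
}

#' Pixelwise difference map and dark-signal change of registered images
#'
#' Both images must already be registered to the same model frame. The map
#' is `b - a` pixelwise. The change statistic integrates the dark signal
#' `S = sum(max(0, baseline - intensity))` over each image, with the
#' baseline defaulting to the Otsu threshold of the first image, and
#' reports `fraction_change = (S_b - S_a) / S_a` (negative when dark
#' features shrink, e.g. an overall reduction in absorbing material).
#'
#' @param img_a,img_b equally shaped image matrices.
#' @param baseline dark-signal baseline; default Otsu threshold of `img_a`.
#' @param mask optional logical matrix restricting the analysis region.
#' @return list: `map` (matrix `b - a`), `fraction_change`, `S_a`, `S_b`,
#'   `baseline`.
#' @export
difference_map <- function(img_a, img_b, baseline = NULL, mask = NULL) {
  img_a <- as.matrix(img_a); img_b <- as.matrix(img_b)
  if (!identical(dim(img_a), dim(img_b))) stop("images must have equal shape")
  if (is.null(baseline)) {
    rng <- range(img_a)
    baseline <- if (diff(rng) < 1e-9) rng[1] else
      EBImage::otsu(EBImage::Image((img_a - rng[1]) / diff(rng)), range = c(0, 1)) *
        diff(rng) + rng[1]
  }
  if (is.null(mask)) mask <- TRUE
  S_a <- sum(pmax(0, baseline - img_a)[mask])
  S_b <- sum(pmax(0, baseline - img_b)[mask])
  fc <- if (S_a > 0) (S_b - S_a) / S_a else if (S_b == 0) 0 else NaN
  list(map = img_b - img_a, fraction_change = fc, S_a = S_a, S_b = S_b,
       baseline = baseline)
}

#' Intensity profile along a line segment
#'
#' Bilinearly samples the image at unit-pixel spacing along the segment
#' `p0 -> p1`, averaging across `width` parallel lines offset
#' perpendicularly at unit-pixel spacing (centred on the segment).
#'
#' @param img image matrix.
#' @param p0,p1 segment endpoints, 0-based pixel coordinates.
#' @param width number of perpendicular offsets averaged (odd integer).
#' @return data.frame with `t` (distance along the segment, pixels) and
#'   `value`.
#' @export
line_profile <- function(img, p0, p1, width = 1) {
  img <- as.matrix(img)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  nr <- nrow(img); nc <- ncol(img)
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > nc - 1 || p[2] < 0 || p[2] > nr - 1) {
      stop("segment endpoints must lie inside the image")
    }
  }
  if (width < 1 || width %% 2 == 0) stop("width must be a positive odd integer")
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2, floor(len) + 1)
  t <- seq(0, len, length.out = n)
  u <- if (len > 0) (p1 - p0) / len else c(1, 0)
  v <- c(-u[2], u[1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  acc <- 0
  for (o in offs) {
    xs <- p0[1] + t * u[1] + o * v[1]
    ys <- p0[2] + t * u[2] + o * v[2]
    acc <- acc + bilinear_sample(img, xs, ys, fill = NA)
  }
  data.frame(t = t, value = acc / width)
}
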