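#' Detection configuration
#'
#' @param blur_sigma Gaussian pre-smoothing width in pixels (>= 0).
#' @param intensity_filter `"below_mean"` keeps only keypoints whose
#'   smoothed intensity lies below the global image mean (dark features,
#'   e.g. corner holes), `"above_mean"` the converse, `"none"` disables the
#'   filter.
#' @param min_separation minimum distance between detections in pixels; of
#'   any conflicting pair the stronger (darker) detection is kept.
#' @param detector `"blob"` (difference-of-Gaussian extrema with sub-pixel
#'   refinement, the default) or `"sift_like"` (same detector, more scale
#'   levels).
#' @param response_threshold minimum difference-of-Gaussian response, as a
#'   fraction of the image dynamic range, for a candidate to count.
#' @param polarity for [detect_square_corners()]: whether the sought region
#'   is `"bright"` or `"dark"` against the background.
#' @param min_area_frac minimum fraction of the image a detected region must
#'   cover before square fitting succeeds.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(blur_sigma = 1.0,
                             intensity_filter = c("below_mean", "above_mean", "none"),
                             min_separation = 2,
                             detector = c("blob", "sift_like"),
                             response_threshold = 0.05,
                             polarity = c("bright", "dark"),
                             min_area_frac = 0.01) {
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (min_separation < 0) stop("min_separation must be >= 0")
  structure(list(blur_sigma = blur_sigma,
                 intensity_filter = match.arg(intensity_filter),
                 min_separation = min_separation,
                 detector = match.arg(detector),
                 response_threshold = response_threshold,
                 polarity = match.arg(polarity),
                 min_area_frac = min_area_frac),
            class = "detection_config")
}

.gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  # EBImage's kernel needs odd radius >= 2*sigma; pad-safe for small images
  as.matrix(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
}

#' Detect dark blob keypoints with sub-pixel accuracy
#'
#' Scale-robust detector for dark, roughly isotropic features (corner holes,
#' vacancies): the image is inverted, a difference-of-Gaussian scale stack
#' is built, spatial local maxima above a response threshold are collected
#' across scales, and each detection is refined to sub-pixel position by a
#' quadratic fit to the response surface. With
#' `intensity_filter = "below_mean"` only points whose smoothed intensity is
#' below the global mean survive, and detections closer than
#' `min_separation` are reduced to the strongest.
#'
#' @param img numeric image matrix in `[0, 1]`.
#' @param cfg [detection_config()].
#' @return point matrix (0-based pixel coordinates `x`, `y`) with a `score`
#'   attribute; may have zero rows.
#' @export
detect_dark_keypoints <- function(img, cfg = detection_config()) {
  img <- as.matrix(img)
  if (!length(img)) stop("image must be non-empty")
  rng <- diff(range(img))
  empty <- function() {
    out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    attr(out, "score") <- numeric(0)
    out
  }
  if (rng < 1e-12) return(empty())

  work <- (max(img) - img) / rng  # dark features become bright
  n_scales <- if (cfg$detector == "sift_like") 7L else 4L
  s0 <- max(cfg$blur_sigma, 0.8)
  sigmas <- s0 * sqrt(2)^(seq_len(n_scales) - 1)
  blurred <- lapply(sigmas, function(s) .gblur(work, s))
  dogs <- lapply(seq_len(n_scales - 1), function(i) blurred[[i]] - blurred[[i + 1]])

  nr <- nrow(img); nc <- ncol(img)
  cand <- list()
  for (li in seq_along(dogs)) {
    D <- dogs[[li]]
    if (nr < 3 || nc < 3) next
    C <- D[2:(nr - 1), 2:(nc - 1)]
    ismax <- C > D[1:(nr - 2), 2:(nc - 1)] & C > D[3:nr, 2:(nc - 1)] &
             C > D[2:(nr - 1), 1:(nc - 2)] & C > D[2:(nr - 1), 3:nc] &
             C >= D[1:(nr - 2), 1:(nc - 2)] & C >= D[1:(nr - 2), 3:nc] &
             C >= D[3:nr, 1:(nc - 2)] & C >= D[3:nr, 3:nc] &
             C > cfg$response_threshold
    hit <- which(ismax, arr.ind = TRUE)
    if (nrow(hit)) {
      cand[[length(cand) + 1]] <- data.frame(
        row = hit[, 1] + 1L, col = hit[, 2] + 1L, level = li,
        resp = C[hit])
    }
  }
  if (!length(cand)) return(empty())
  cand <- do.call(rbind, cand)
  # per pixel keep the best-responding scale
  cand <- cand[order(-cand$resp), ]
  cand <- cand[!duplicated(paste(cand$row, cand$col)), ]

  # sub-pixel quadratic refinement on the winning DoG level
  refine <- function(row, col, level) {
    D <- dogs[[level]]
    p <- D[(row - 1):(row + 1), (col - 1):(col + 1)]
    gx <- (p[2, 3] - p[2, 1]) / 2; gy <- (p[3, 2] - p[1, 2]) / 2
    hxx <- p[2, 3] - 2 * p[2, 2] + p[2, 1]
    hyy <- p[3, 2] - 2 * p[2, 2] + p[1, 2]
    hxy <- (p[3, 3] - p[3, 1] - p[1, 3] + p[1, 1]) / 4
    det_h <- hxx * hyy - hxy^2
    off <- c(0, 0)
    if (abs(det_h) > 1e-12) {
      off <- -solve(matrix(c(hxx, hxy, hxy, hyy), 2, 2), c(gx, gy))
      off <- pmin(pmax(off, -0.6), 0.6)
    }
    c(col - 1 + off[1], row - 1 + off[2])  # 0-based (x, y)
  }
  pos <- t(mapply(refine, cand$row, cand$col, cand$level))

  # intensity filter on the smoothed image
  sm <- blurred[[1]] * -rng + max(img)  # undo inversion: smoothed original
  vals <- sm[cbind(cand$row, cand$col)]
  keep <- switch(cfg$intensity_filter,
                 below_mean = vals < mean(sm),
                 above_mean = vals > mean(sm),
                 none = rep(TRUE, length(vals)))
  pos <- pos[keep, , drop = FALSE]
  resp <- cand$resp[keep]

  # non-maximum suppression at min_separation, strongest first
  if (nrow(pos) && cfg$min_separation > 0) {
    ord <- order(-resp)
    pos <- pos[ord, , drop = FALSE]; resp <- resp[ord]
    taken <- logical(nrow(pos))
    for (i in seq_len(nrow(pos))) {
      if (taken[i]) next
      if (i < nrow(pos)) {
        d <- sqrt((pos[(i + 1):nrow(pos), 1] - pos[i, 1])^2 +
                  (pos[(i + 1):nrow(pos), 2] - pos[i, 2])^2)
        taken[(i + 1):nrow(pos)][d < cfg$min_separation] <- TRUE
      }
    }
    pos <- pos[!taken, , drop = FALSE]; resp <- resp[!taken]
  }
  colnames(pos) <- c("x", "y")
  attr(pos, "score") <- resp
  pos
}

# Minimum-area enclosing rectangle of a point set (rotating calipers over
# the convex hull). Returns a 4x2 corner matrix.
.min_area_rect <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    e <- hull[i %% n + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2)); if (len < 1e-12) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (area < best_area) {
      best_area <- area
      cu <- c(min(pu), max(pu)); cv <- c(min(pv), max(pv))
      best <- rbind(cu[1] * u + cv[1] * v, cu[2] * u + cv[1] * v,
                    cu[2] * u + cv[2] * v, cu[1] * u + cv[2] * v)
    }
  }
  best
}

#' Detect the corners of a dominant square/rectangular region
#'
#' Pipeline: Gaussian blur, Otsu binarisation, largest connected foreground
#' component, minimum-area rectangle fit. Corners are returned
#' counterclockwise starting with the corner nearest the image origin; the
#' component centroid is attached as the `"centroid"` attribute.
#'
#' @param img numeric image matrix in `[0, 1]`.
#' @param cfg [detection_config()]; `polarity` selects whether the region is
#'   brighter or darker than its surroundings, `min_area_frac` the minimum
#'   area fraction the component must cover.
#' @return 4x2 corner matrix (0-based pixel coordinates) with attribute
#'   `centroid`.
#' @export
detect_square_corners <- function(img, cfg = detection_config()) {
  img <- as.matrix(img)
  if (!length(img)) stop("image must be non-empty")
  sm <- .gblur(img, cfg$blur_sigma)
  if (diff(range(sm)) < 1e-9) stop("detection failure: image has no contrast")
  smn <- (sm - min(sm)) / diff(range(sm))
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  fg <- if (cfg$polarity == "bright") smn > thr else smn < thr
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) < 1) stop("detection failure: no foreground component")
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < cfg$min_area_frac * length(img)) {
    stop(sprintf("detection failure: largest component covers %.4f < %.4f of the image",
                 sizes[big] / length(img), cfg$min_area_frac))
  }
  px <- which(lab == big, arr.ind = TRUE)  # row, col (1-based)
  pts <- cbind(x = px[, 2] - 1, y = px[, 1] - 1)
  corners <- .min_area_rect(pts)
  # canonical order: counterclockwise, starting nearest the origin
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  corners <- corners[order(ang), , drop = FALSE]
  start <- which.min(rowSums(corners^2))
  if (start > 1) corners <- corners[c(start:4, 1:(start - 1)), , drop = FALSE]
  colnames(corners) <- c("x", "y")
  attr(corners, "centroid") <- c(x = mean(pts[, 1]), y = mean(pts[, 2]))
  corners
}

#' Classify sites as present (adatom) or absent (defect) by pixel values
#'
#' Samples the mean intensity of a `(2 * window + 1)^2` patch around each
#' point (patches are clipped at image borders) and labels the site
#' `present` when the sample reaches the classification threshold. The
#' default threshold is the midpoint of the 10th and 90th percentiles of
#' the sampled patch means, so it adapts to image contrast; on a constant
#' image every sample equals the threshold and all sites are labelled
#' `present` (ties go to present).
#'
#' @param img numeric image matrix.
#' @param pts point matrix (0-based pixel coordinates).
#' @param window patch half-width in pixels.
#' @param threshold classification threshold; `NULL` for the adaptive
#'   default.
#' @return data.frame with columns `index`, `label` (factor
#'   present/absent), `intensity`.
#' @export
classify_sites <- function(img, pts, window = 2, threshold = NULL) {
  img <- as.matrix(img); pts <- as_points(pts)
  nr <- nrow(img); nc <- ncol(img)
  out_of_bounds <- which(pts[, 1] < 0 | pts[, 1] > nc - 1 |
                         pts[, 2] < 0 | pts[, 2] > nr - 1)
  if (length(out_of_bounds)) {
    stop(sprintf("point(s) outside image bounds at index %s",
                 paste(out_of_bounds, collapse = ", ")))
  }
  vals <- vapply(seq_len(nrow(pts)), function(i) {
    cx <- round(pts[i, 1]); cy <- round(pts[i, 2])
    xs <- max(0, cx - window):min(nc - 1, cx + window)
    ys <- max(0, cy - window):min(nr - 1, cy + window)
    mean(img[ys + 1, xs + 1])
  }, numeric(1))
  if (is.null(threshold)) {
    q <- stats::quantile(vals, c(0.1, 0.9), names = FALSE)
    threshold <- mean(q)
  }
  data.frame(index = seq_len(nrow(pts)),
             label = factor(ifelse(vals >= threshold, "present", "absent"),
                            levels = c("present", "absent")),
             intensity = vals)
}
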