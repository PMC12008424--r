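#' Planar projective transforms
#'
#' Transforms are stored as 3x3 matrices acting on homogeneous coordinates
#' (x, y, 1), normalised so that the bottom-right element equals 1. An
#' `"affine"` transform additionally has zero projective terms (third row
#' `(0, 0, 1)`); a `"homography"` may carry non-zero projective terms and
#' models perspective-like distortion with 8 degrees of freedom.
#'
#' Coordinate convention used throughout the package: `x` is the column
#' index, `y` the row index, origin at the centre of the top-left pixel,
#' 0-based. Point sets are numeric matrices with columns `x`, `y`.
#'
#' @param m numeric 3x3 matrix; it is rescaled so `m[3, 3] == 1`.
#' @param kind `"affine"` or `"homography"`. If omitted, inferred from the
#'   third row.
#' @return An object of class `anchor_transform`.
#' @export
transform_matrix <- function(m, kind = NULL) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)) || any(!is.finite(m))) {
    stop("transform matrix must be a finite numeric 3x3 matrix")
  }
  if (abs(m[3, 3]) < 1e-12) {
    stop("transform matrix has (near-)zero bottom-right element; cannot normalise")
  }
  m <- m / m[3, 3]
  if (abs(det(m)) < 1e-12) {
    stop("transform matrix is singular (|det| < 1e-12)")
  }
  if (is.null(kind)) {
    kind <- if (all(abs(m[3, 1:2]) == 0)) "affine" else "homography"
  }
  kind <- match.arg(kind, c("affine", "homography"))
  if (kind == "affine" && any(abs(m[3, 1:2]) > 1e-12)) {
    stop("kind = \"affine\" but projective terms m[3, 1:2] are non-zero")
  }
  structure(list(m = unname(m), kind = kind), class = "anchor_transform")
}

#' @export
print.anchor_transform <- function(x, ...) {
  cat(sprintf("<anchor_transform: %s>\n", x$kind))
  print(round(x$m, 6))
  invisible(x)
}

#' Identity transform
#' @param kind transform kind tag.
#' @return identity `anchor_transform`.
#' @export
identity_transform <- function(kind = "affine") transform_matrix(diag(3), kind)

#' Affine parameter set
#'
#' Parameters of the affine placement matrix: per-axis scaling `s_x`, `s_y`,
#' rotation `theta` (radians), shearing `a_x`, `a_y`, and translation
#' `x_0`, `y_0` in target-frame units.
#'
#' @param s_x,s_y scale factors, must be positive.
#' @param theta rotation angle in radians.
#' @param a_x,a_y shear factors.
#' @param x_0,y_0 translation.
#' @return list of class `affine_params`.
#' @export
affine_params <- function(s_x = 1, s_y = 1, theta = 0, a_x = 0, a_y = 0,
                          x_0 = 0, y_0 = 0) {
  vals <- c(s_x = s_x, s_y = s_y, theta = theta, a_x = a_x, a_y = a_y,
            x_0 = x_0, y_0 = y_0)
  if (any(!is.finite(vals))) stop("affine parameters must be finite")
  if (s_x <= 0 || s_y <= 0) stop("scale factors s_x, s_y must be positive")
  structure(as.list(vals), class = "affine_params")
}

#' Compose the affine placement matrix from its factor parameters
#'
#' Builds `A = S(s_x, s_y) %*% R(theta) %*% Sh(a_x, a_y) %*% T(x_0, y_0)`,
#' i.e. scaling, rotation, shearing and translation multiplied in that fixed
#' left-to-right order. Because translation is the right-most factor it acts
#' in pre-rotation (model-frame) coordinates.
#'
#' @param params an [affine_params()] object (or plain list with the same
#'   fields).
#' @return `anchor_transform` of kind `"affine"`.
#' @export
compose_affine <- function(params) {
  if (!inherits(params, "affine_params")) params <- do.call(affine_params, params)
  S <- diag(c(params$s_x, params$s_y, 1))
  R <- matrix(c(cos(params$theta), -sin(params$theta), 0,
                sin(params$theta),  cos(params$theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  Sh <- matrix(c(1, params$a_x, 0,
                 params$a_y, 1, 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Tr <- matrix(c(1, 0, params$x_0,
                 0, 1, params$y_0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  transform_matrix(S %*% R %*% Sh %*% Tr, "affine")
}

#' Coerce to an n x 2 point matrix
#' @param pts matrix or data.frame with x/y columns, or length-2 vector.
#' @return numeric matrix with columns `x`, `y`.
#' @export
as_points <- function(pts) {
  if (is.data.frame(pts)) {
    stopifnot(all(c("x", "y") %in% names(pts)))
    pts <- cbind(pts$x, pts$y)
  }
  if (is.null(dim(pts))) {
    if (length(pts) != 2) stop("a bare vector point must have length 2")
    pts <- matrix(pts, 1, 2)
  }
  pts <- as.matrix(pts)
  if (ncol(pts) < 2) stop("points must have two coordinate columns")
  pts <- pts[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) stop("point coordinates must be finite")
  colnames(pts) <- c("x", "y")
  unname(pts) -> m
  colnames(m) <- c("x", "y")
  m
}

#' Apply a projective transform to points
#'
#' Each point `(x, y)` is lifted to homogeneous coordinates, multiplied by the
#' transform matrix, and de-homogenised: `(x_t, y_t, z_t) = m (x, y, 1)'`,
#' returning `(x_t / z_t, y_t / z_t)`. Point order is preserved.
#'
#' @param T `anchor_transform` (or plain 3x3 matrix).
#' @param pts point matrix (see [as_points()]).
#' @return transformed point matrix, same number of rows.
#' @export
apply_transform <- function(T, pts) {
  m <- if (inherits(T, "anchor_transform")) T$m else transform_matrix(T)$m
  pts <- as_points(pts)
  h <- m %*% rbind(t(pts), 1)
  z <- h[3, ]
  bad <- which(abs(z) < 1e-12)
  if (length(bad)) {
    stop(sprintf("degenerate projection (point at infinity) at index %s",
                 paste(bad, collapse = ", ")))
  }
  out <- cbind(h[1, ] / z, h[2, ] / z)
  colnames(out) <- c("x", "y")
  out
}

#' Invert a transform
#'
#' Returns the inverse matrix rescaled so its bottom-right element is 1, so
#' that entrywise comparisons between transforms remain meaningful.
#'
#' @param T `anchor_transform`.
#' @return `anchor_transform` of the same kind.
#' @export
invert_transform <- function(T) {
  stopifnot(inherits(T, "anchor_transform"))
  inv <- tryCatch(solve(T$m), error = function(e) stop("transform is singular"))
  transform_matrix(inv, T$kind)
}

#' Compose two transforms
#'
#' `compose_transforms(A, B)` returns the transform equivalent to applying
#' `B` first and then `A`.
#'
#' @param A,B `anchor_transform` objects.
#' @return composed `anchor_transform`.
#' @export
compose_transforms <- function(A, B) {
  stopifnot(inherits(A, "anchor_transform"), inherits(B, "anchor_transform"))
  kind <- if (A$kind == "affine" && B$kind == "affine") "affine" else "homography"
  transform_matrix(A$m %*% B$m, kind)
}

#' Warp an image by a projective transform
#'
#' The output pixel at 0-based coordinates `(x, y)` samples the input image at
#' `apply_transform(invert_transform(T), (x, y))` with bilinear interpolation;
#' samples falling outside the input take `fill`. `T` maps input coordinates
#' to output coordinates.
#'
#' @param img numeric matrix, rows = y, cols = x, values typically in `[0, 1]`.
#' @param T `anchor_transform` mapping input to output coordinates.
#' @param out_shape integer `(rows, cols)` of the output; default `dim(img)`.
#' @param fill scalar used for out-of-bounds samples.
#' @return numeric matrix of dimension `out_shape`.
#' @export
warp_image <- function(img, T, out_shape = dim(img), fill = 0) {
  img <- as.matrix(img)
  if (length(img) == 0 || any(dim(img) < 1)) stop("image must be non-empty")
  if (length(out_shape) != 2 || any(out_shape < 1)) stop("invalid output shape")
  out_shape <- as.integer(out_shape)
  Tinv <- invert_transform(if (inherits(T, "anchor_transform")) T else transform_matrix(T))
  nr <- out_shape[1]; nc <- out_shape[2]
  # all output pixel centres, 0-based (x = col, y = row)
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  src <- apply_transform(Tinv, cbind(gx, gy))
  bilinear_sample(img, src[, 1], src[, 2], fill = fill, out_dim = c(nr, nc))
}

# Vectorised bilinear sampling of img at 0-based (x, y); out-of-bounds -> fill.
bilinear_sample <- function(img, x, y, fill = 0, out_dim = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp corner indices; validity decided on the un-clamped sample position
  inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  xi0 <- pmin(pmax(x0, 0), nc - 1); yi0 <- pmin(pmax(y0, 0), nr - 1)
  xi1 <- pmin(xi0 + 1, nc - 1);     yi1 <- pmin(yi0 + 1, nr - 1)
  idx <- function(yy, xx) yy + 1L + nr * xx  # column-major linear index
  v <- (1 - fx) * (1 - fy) * img[idx(yi0, xi0)] +
       fx       * (1 - fy) * img[idx(yi0, xi1)] +
       (1 - fx) * fy       * img[idx(yi1, xi0)] +
       fx       * fy       * img[idx(yi1, xi1)]
  v[!inside] <- fill
  if (!is.null(out_dim)) dim(v) <- out_dim
  v
}

#' Serialise / deserialise a transform as JSON
#'
#' The matrix is stored as a row-major 9-element array together with the
#' `kind` tag.
#'
#' @param T `anchor_transform`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `write_transform_json`: the path (or JSON string), invisibly.
#' @export
write_transform_json <- function(T, path = NULL) {
  stopifnot(inherits(T, "anchor_transform"))
  obj <- list(kind = T$kind, m = as.vector(t(T$m)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_transform_json
#' @param x path to a JSON file, or a JSON string.
#' @return `read_transform_json`: the `anchor_transform`.
#' @export
read_transform_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  if (is.null(obj$m) || length(obj$m) != 9) stop("transform JSON must contain a 9-element 'm'")
  transform_matrix(matrix(obj$m, 3, 3, byrow = TRUE), obj$kind)
}
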