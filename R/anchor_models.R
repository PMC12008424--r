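#' Anchor-point models
#'
#' An anchor model holds the model-frame coordinates of the structural
#' features used as registration landmarks: the lattice sites of a periodic
#' structure, or the vertices of a device outline. Coordinates are stored in
#' unit-length-normalised model units; pixel scale enters only through the
#' affine placement.
#'
#' @param name model name.
#' @param points point matrix in model units.
#' @param unit_length the inter-structure distance L (> 0).
#' @param basis 2x2 matrix of lattice basis vectors (rows), or `NULL` for
#'   polygon models.
#' @return list of class `anchor_model` with fields `name`, `points`,
#'   `unit_length`, `basis`.
#' @export
anchor_model <- function(name, points, unit_length = 1, basis = NULL) {
  points <- as_points(points)
  if (unit_length <= 0) stop("unit_length must be positive")
  if (nrow(points) > 1 && min(stats::dist(points)) < 1e-9) {
    stop("anchor points must be pairwise distinct")
  }
  structure(list(name = as.character(name), points = points,
                 unit_length = unit_length, basis = basis),
            class = "anchor_model")
}

#' @export
print.anchor_model <- function(x, ...) {
  cat(sprintf("<anchor_model '%s': %d points, L = %g, %s>\n", x$name,
              nrow(x$points), x$unit_length,
              if (is.null(x$basis)) "polygon" else "lattice"))
  invisible(x)
}

#' Build a periodic lattice anchor model
#'
#' Generates `rows x cols` points at `L * (i * b1 + j * b2)` for
#' `i = 0..cols-1` (x direction), `j = 0..rows-1` (y direction), in row-major
#' order (j outer, i inner), emulating a periodic surface structure with
#' fixed inter-site spacing.
#'
#' @param rows,cols lattice extent (>= 1 each).
#' @param unit_length inter-site distance L.
#' @param basis 2x2 matrix whose rows are the two lattice basis vectors;
#'   default the unit square basis.
#' @return `anchor_model` with `basis` set.
#' @export
make_lattice_model <- function(rows, cols, unit_length = 1,
                               basis = rbind(c(1, 0), c(0, 1))) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  basis <- as.matrix(basis)
  if (!identical(dim(basis), c(2L, 2L))) stop("basis must be a 2x2 matrix")
  if (abs(det(basis)) < 1e-12) stop("degenerate (linearly dependent) basis")
  ij <- expand.grid(i = seq_len(cols) - 1, j = seq_len(rows) - 1)
  pts <- unit_length * (outer(ij$i, basis[1, ]) + outer(ij$j, basis[2, ]))
  anchor_model(sprintf("lattice_%dx%d", rows, cols), pts,
               unit_length = unit_length, basis = basis)
}

#' Build a polygonal anchor model from vertices
#'
#' Vertices are canonicalised to counterclockwise order (in the x-right,
#' y-down image convention) starting from the vertex with the smallest `y`,
#' ties broken by smallest `x`. `unit_length` is set to the shortest edge.
#'
#' @param vertices >= 3 non-collinear vertices.
#' @return `anchor_model` with `basis = NULL`.
#' @export
make_polygon_model <- function(vertices) {
  v <- as_points(vertices)
  if (nrow(v) < 3) stop("a polygon model needs at least 3 vertices")
  if (nrow(unique(round(v, 9))) != nrow(v)) stop("duplicate vertices")
  ctr <- colMeans(v)
  ang <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  v <- v[order(ang), , drop = FALSE]  # counterclockwise in image convention
  area <- abs(sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
                  v[c(2:nrow(v), 1), 1] * v[, 2])) / 2
  if (area < 1e-9) stop("vertices are collinear")
  # rotate so the first vertex has smallest (y, then x)
  start <- order(v[, 2], v[, 1])[1]
  if (start > 1) v <- v[c(start:nrow(v), 1:(start - 1)), , drop = FALSE]
  edges <- sqrt(rowSums((v - v[c(2:nrow(v), 1), , drop = FALSE])^2))
  if (min(edges) < 1e-12) stop("degenerate (zero-length) edge")
  anchor_model("polygon", v, unit_length = min(edges), basis = NULL)
}

#' Unit-cell template with sub-feature coordinates
#'
#' A template describes one repeating cell of a periodic model: the cell's
#' defining anchor offsets (e.g. corner holes) and an ordered list of
#' sub-feature offsets (e.g. adatoms) in model units relative to the cell
#' origin. The sub-feature order is fixed: it defines the element order of
#' cell feature vectors.
#'
#' @param cell_anchor_offsets anchor offsets defining the cell.
#' @param subfeature_offsets ordered sub-feature offsets.
#' @return list of class `unit_cell_template`.
#' @export
unit_cell_template <- function(cell_anchor_offsets, subfeature_offsets) {
  structure(list(cell_anchor_offsets = as_points(cell_anchor_offsets),
                 subfeature_offsets = as_points(subfeature_offsets),
                 n_subfeatures = nrow(as_points(subfeature_offsets))),
            class = "unit_cell_template")
}

#' Si(111)-(7x7) half-cell template
#'
#' Models one triangular half cell of the Si(111)-(7x7) reconstruction: three
#' corner holes at the vertices of an equilateral triangle with spacing
#' normalised to 1, and six adatoms as sub-features. Sub-feature numbering is
#' fixed and stable: corner adatoms 1-3 counterclockwise starting from the
#' lowest-left corner hole, then centre adatoms 4-6 in the same angular
#' order. Adatom positions use the standard dimer-adatom-stacking-fault
#' fractional placement along each corner-hole-to-centroid direction; only
#' the relative geometry matters for registration.
#'
#' @return `unit_cell_template` with 3 cell anchors and 6 sub-features.
#' @export
si7x7_template <- function() {
  ch <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  ctr <- colMeans(ch)
  # corner adatoms sit closer to their corner hole, centre adatoms closer to
  # the cell centroid, along the corner-to-centroid line
  corner_ad <- ch + 0.30 * (matrix(ctr, 3, 2, byrow = TRUE) - ch)
  center_ad <- ch + 0.62 * (matrix(ctr, 3, 2, byrow = TRUE) - ch)
  unit_cell_template(ch, rbind(corner_ad, center_ad))
}

#' Project template sub-features into image coordinates
#'
#' Maps the template's sub-feature offsets, translated to a cell origin in
#' the model frame, through the affine placement `A` and the estimated
#' homography `H`: `H (A (cell_origin + offsets))`. Output order follows the
#' template's sub-feature order.
#'
#' @param template `unit_cell_template`.
#' @param A,H `anchor_transform` objects (affine placement and homography).
#' @param cell_origin length-2 model-frame coordinate of the cell origin.
#' @return point matrix in image coordinates.
#' @export
project_subfeatures <- function(template, A, H, cell_origin = c(0, 0)) {
  stopifnot(inherits(template, "unit_cell_template"))
  pts <- sweep(template$subfeature_offsets, 2, as.numeric(cell_origin), "+")
  apply_transform(H, apply_transform(A, pts))
}

#' Serialise an anchor model to JSON (and back)
#'
#' @param model `anchor_model`.
#' @param path output path, or `NULL` to return the JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "anchor_model"))
  obj <- list(name = model$name, unit_length = model$unit_length,
              basis = if (is.null(model$basis)) NULL else unname(model$basis),
              points = unname(model$points))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_model_json
#' @param x path or JSON string.
#' @export
read_model_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  anchor_model(obj$name, obj$points, unit_length = obj$unit_length,
               basis = obj$basis)
}
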