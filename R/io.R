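#' Read and write grayscale images
#'
#' Supported formats: TIFF and PNG (decided by file extension). Images are
#' returned as numeric matrices in `[0, 1]`; multi-channel inputs are
#' converted to a single channel by the Rec. 601 luminance weights.
#' `write_image` stores 16-bit TIFF by default (or PNG by extension), so a
#' write/read round trip is exact to the 16-bit quantisation step.
#'
#' @param path file path.
#' @return `read_image`: numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop(sprintf("unsupported image format '%s' for %s", ext, path)))
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else arr[, , 1]
  }
  pmin(pmax(as.matrix(arr), 0), 1)
}

#' @rdname read_image
#' @param img numeric image matrix in `[0, 1]`.
#' @param bits TIFF bit depth (8 or 16).
#' @export
write_image <- function(img, path, bits = 16) {
  img <- pmin(pmax(as.matrix(img), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
         png = png::writePNG(img, path),
         stop(sprintf("unsupported image format '%s' for %s", ext, path)))
  invisible(path)
}

#' Read and write point sets
#'
#' CSV files use a mandatory `x,y` header (optional extra `score` column),
#' comma separation and `.` decimals; coordinates round-trip exactly at
#' full double precision. JSON files hold an array of `[x, y]` pairs.
#'
#' @param path file path (`.csv` or `.json`).
#' @return `read_points`: point matrix (possibly with 0 rows).
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop(sprintf("point file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.list(obj) && !is.null(obj$points)) obj <- obj$points
    if (length(obj) == 0) return(as_points(matrix(numeric(0), 0, 2)))
    return(as_points(obj))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(as_points(matrix(numeric(0), 0, 2)))
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!all(c("x", "y") %in% trimws(header))) {
    stop(sprintf("%s: line 1: header must contain columns x,y", path))
  }
  xi <- match("x", trimws(header)); yi <- match("y", trimws(header))
  n <- length(lines) - 1
  out <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    f <- strsplit(lines[k + 1], ",")[[1]]
    vals <- suppressWarnings(as.numeric(f[c(xi, yi)]))
    if (length(f) < max(xi, yi) || any(is.na(vals))) {
      stop(sprintf("%s: line %d: malformed point row '%s'", path, k + 1,
                   lines[k + 1]))
    }
    out[k, ] <- vals
  }
  as_points(out)
}

#' @rdname read_points
#' @param pts point matrix.
#' @param score optional numeric score column for CSV output.
#' @export
write_points <- function(pts, path, score = NULL) {
  pts <- as_points(pts)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    writeLines(as.character(jsonlite::toJSON(unname(pts), digits = NA)), path)
    return(invisible(path))
  }
  header <- if (is.null(score)) "x,y" else "x,y,score"
  rows <- vapply(seq_len(nrow(pts)), function(i) {
    base <- paste(format(pts[i, 1], digits = 17), format(pts[i, 2], digits = 17),
                  sep = ",")
    if (is.null(score)) base else paste(base, format(score[i], digits = 17), sep = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Accepts the nested sections `detection`, `vote`, `lmeds`, `metric`,
#' `affine`, `sweep` plus scalar entries `gate`, `grid_step`, `seed`;
#' unknown top-level keys are rejected. Each present section is validated
#' by its constructor.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of validated configuration objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path)
         else stop(sprintf("unsupported config format '%s'", ext))
  if (is.null(raw)) raw <- list()
  known <- c("detection", "vote", "lmeds", "metric", "affine", "sweep",
             "gate", "grid_step", "seed", "pixels_per_unit")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  out <- raw
  if (!is.null(raw$detection)) out$detection <- do.call(detection_config, raw$detection)
  if (!is.null(raw$vote)) out$vote <- do.call(vote_config, raw$vote)
  if (!is.null(raw$lmeds)) out$lmeds <- do.call(lmeds_config, raw$lmeds)
  if (!is.null(raw$metric)) out$metric <- do.call(metric_config, raw$metric)
  if (!is.null(raw$affine)) out$affine <- do.call(affine_params, raw$affine)
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    if (!is.null(sw$magnitude)) sw$magnitude <- do.call(homography_magnitude, sw$magnitude)
    out$sweep <- do.call(sweep_config, sw)
  }
  out
}
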