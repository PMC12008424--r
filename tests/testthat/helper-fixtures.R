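# Shared test helpers: reference transforms and synthetic scenes.

# Worked homography used in hand-checked examples throughout the suite:
# maps (100, 100) to (62.5, 81.25) since z_t = 1.6, x_t = 100, y_t = 130.
worked_H <- function() {
  transform_matrix(matrix(c(0.8, 0.2, 0,
                            0.1, 1.2, 0,
                            0.005, 0.001, 1), 3, 3, byrow = TRUE),
                   "homography")
}

# A moderate pixel-scale homography mapping model units to image pixels:
# affine placement (scale px_per_unit, offset) with small projective terms.
pixel_scale_H <- function(px_per_unit = 15, offset = c(12, 12),
                          g = 1e-4, h = -6e-5) {
  m <- matrix(c(px_per_unit, 0, offset[1],
                0, px_per_unit, offset[2],
                g, h, 1), 3, 3, byrow = TRUE)
  transform_matrix(m, "homography")
}

# Square unit-cell template: 4 corner anchors, 2 interior sub-features.
square_cell_template <- function() {
  unit_cell_template(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                     rbind(c(0.3, 0.4), c(0.7, 0.6)))
}

expect_points_close <- function(got, want, tol = 1e-9) {
  got <- as_points(got); want <- as_points(want)
  expect_equal(nrow(got), nrow(want))
  expect_lt(max(sqrt(rowSums((got - want)^2))), tol)
}
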