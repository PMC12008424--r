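test_that("dark keypoint detection recovers rendered holes to sub-pixel accuracy", {
  model <- make_lattice_model(3, 3)
  H <- pixel_scale_H(18, c(14, 14))
  fx <- render_fixture(model, H, size = c(90, 90))
  det <- detect_dark_keypoints(fx$image, detection_config(min_separation = 5))
  expect_equal(nrow(det), 9)
  # every truth anchor matched within 0.5 px
  dmin <- apply(fx$anchors_image, 1, function(p) {
    min(sqrt((det[, 1] - p[1])^2 + (det[, 2] - p[2])^2))
  })
  expect_lt(max(dmin), 0.5)
})

test_that("flat images yield no keypoints and below-mean filtering is sound", {
  expect_equal(nrow(detect_dark_keypoints(matrix(0.5, 40, 40))), 0)

  # mixed dark holes and bright spots: below_mean keeps only dark features
  model <- make_lattice_model(2, 2)
  H <- pixel_scale_H(25, c(18, 18))
  fx <- render_fixture(model, H, size = c(80, 80),
                       template = unit_cell_template(rbind(c(0, 0)),
                                                     rbind(c(0.5, 0.5))),
                       cell_origins = rbind(c(0, 0)))
  cfg <- detection_config(intensity_filter = "below_mean", min_separation = 4)
  det <- detect_dark_keypoints(fx$image, cfg)
  sm <- as.matrix(EBImage::gblur(fx$image, 1, boundary = "replicate"))
  vals <- sm[cbind(round(det[, 2]) + 1, round(det[, 1]) + 1)]
  expect_true(all(vals < mean(sm)))
})

test_that("detection is deterministic and respects min_separation", {
  model <- make_lattice_model(4, 4)
  fx <- render_fixture(model, pixel_scale_H(14, c(12, 12)), size = c(80, 80),
                       noise_sd = 0.03, seed = 5)
  cfg <- detection_config(min_separation = 6)
  d1 <- detect_dark_keypoints(fx$image, cfg)
  d2 <- detect_dark_keypoints(fx$image, cfg)
  expect_identical(d1, d2)
  if (nrow(d1) > 1) expect_gte(min(dist(d1)), 6)
})

test_that("detection recall and precision reach 0.99 on SNR >= 10 fixtures", {
  model <- make_lattice_model(4, 4)
  H <- pixel_scale_H(16, c(14, 14))
  # amplitude 0.4, noise sd 0.04 -> SNR 10
  fx <- render_fixture(model, H, size = c(92, 92), noise_sd = 0.04, seed = 9)
  det <- detect_dark_keypoints(fx$image, detection_config(min_separation = 5))
  d <- as.matrix(dist(rbind(fx$anchors_image, det)))
  d <- d[seq_len(16), 16 + seq_len(nrow(det)), drop = FALSE]
  hits <- sum(apply(d, 1, min) < 0.5)
  expect_gte(hits / 16, 0.99)                # recall
  expect_gte(sum(apply(d, 2, min) < 0.5) / nrow(det), 0.99)  # precision
})

test_that("square corner detection hits rendered corners within 1 px", {
  render_square <- function(theta = 0, side = 40, n = 100, centre = c(49.5, 49.5)) {
    xg <- matrix(rep(0:(n - 1), each = n), n, n)
    yg <- matrix(rep(0:(n - 1), times = n), n, n)
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    u <- R[1, 1] * (xg - centre[1]) + R[1, 2] * (yg - centre[2])
    v <- R[2, 1] * (xg - centre[1]) + R[2, 2] * (yg - centre[2])
    img <- 0.1 + 0.8 * (abs(u) <= side / 2 & abs(v) <= side / 2)
    # region is {p : |R (p - c)| <= side/2 componentwise}, so corners sit at
    # c + R^T s
    corners <- t(vapply(list(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
                        function(s) centre + c(R[1, 1] * s[1] * side / 2 + R[2, 1] * s[2] * side / 2,
                                               R[1, 2] * s[1] * side / 2 + R[2, 2] * s[2] * side / 2),
                        numeric(2)))
    list(img = img, corners = corners)
  }
  for (theta in c(0, pi / 6)) {
    sq <- render_square(theta)
    got <- detect_square_corners(sq$img, detection_config(blur_sigma = 1))
    dmin <- apply(sq$corners, 1, function(p) {
      min(sqrt((got[, 1] - p[1])^2 + (got[, 2] - p[2])^2))
    })
    expect_lt(max(dmin), 1)
    expect_equal(nrow(got), 4)
  }
  expect_error(detect_square_corners(matrix(0.5, 50, 50)), "detection failure")
})

test_that("square corners come back counterclockwise from the origin corner", {
  n <- 80
  img <- matrix(0.1, n, n)
  img[21:60, 21:60] <- 0.9
  got <- detect_square_corners(img, detection_config(blur_sigma = 1))
  expect_lt(sqrt(sum((got[1, ] - c(20, 20))^2)), 1.5)  # origin-nearest first
  # counterclockwise in x-right / y-down convention: signed area positive
  sa <- sum(got[, 1] * got[c(2:4, 1), 2] - got[c(2:4, 1), 1] * got[, 2]) / 2
  expect_gt(sa, 0)
  expect_equal(unname(attr(got, "centroid")), c(40, 40), tolerance = 0.1)
})

test_that("classify_sites separates bright spots from background", {
  model <- make_lattice_model(2, 2)
  tpl <- square_cell_template()
  H <- pixel_scale_H(30, c(20, 20))
  fx <- render_fixture(model, H, size = c(90, 90), template = tpl,
                       cell_origins = rbind(c(0, 0)))
  on_spot <- fx$subfeatures_image[, c("x", "y")]
  between <- apply_transform(H, rbind(c(0.1, 0.9)))  # background position
  lab <- classify_sites(fx$image, rbind(as.matrix(on_spot), between), window = 2)
  expect_equal(as.character(lab$label), c("present", "present", "absent"))

  # constant image: threshold side deterministic, all labels identical
  flat <- classify_sites(matrix(0.3, 20, 20), rbind(c(5, 5), c(10, 10)))
  expect_equal(as.character(unique(flat$label)), "present")

  expect_error(classify_sites(matrix(0.3, 20, 20), rbind(c(5, 5), c(30, 5))),
               "index 2")
})
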