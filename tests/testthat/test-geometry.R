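test_that("coplanar screens reduce to the flat-wall closed form", {
  lay <- screen_layout(inter_screen_angle_deg = 180)
  cov <- layout_coverage(lay)
  expect_equal(unname(cov["horizontal"]),
               2 * atan(1.5 * 3.05 / 3.75) * 180 / pi, tolerance = 1e-10)
  expect_equal(unname(cov["vertical"]),
               2 * atan(0.5 * 1.89 / 3.75) * 180 / pi, tolerance = 1e-10)
})

test_that("angled layout matches an independent rotation-matrix construction", {
  lay <- screen_layout()
  # independent oracle: rotate the center-screen plane about the shared
  # vertical edge by the exterior angle, in homogeneous 3-D
  th <- (180 - 151) * pi / 180
  rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                                -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  edge <- c(3.05 / 2, 0, 3.75)           # shared right edge at eye height
  # corner pixel (1919, 1199) of the right screen, via explicit rotation
  px_w <- 3.05 / 1920; px_h <- 1.89 / 1200
  local <- c(1919.5 * px_w, 0, 0)        # along the unrotated center plane
  p_oracle <- edge + drop(rot_y(th) %*% local) +
    c(0, 1.89 / 2 - 1199.5 * px_h, 0)
  p <- pixel_to_point(lay, 2L, 1919, 1199)
  expect_equal(drop(p), p_oracle, tolerance = 1e-12)

  # horizontal coverage equals the closed form from the same construction
  outer <- edge + drop(rot_y(th) %*% c(3.05, 0, 0))
  expect_equal(unname(layout_coverage(lay)["horizontal"]),
               2 * atan2(outer[1], outer[3]) * 180 / pi, tolerance = 1e-10)
})

test_that("center of the center screen is the zero-eccentricity reference", {
  lay <- screen_layout()
  cx <- (1920 - 1) / 2; cy <- (1200 - 1) / 2
  expect_equal(eccentricity_from_center(lay, 1L, cx, cy), 0, tolerance = 1e-9)
  d <- pixel_to_direction(lay, 1L, cx, cy)
  expect_equal(drop(d), c(0, 0, 1), tolerance = 1e-12)
})

test_that("mirror-symmetric pixels have equal eccentricity, opposite side", {
  lay <- screen_layout()
  cy <- (1200 - 1) / 2
  dl <- pixel_to_direction(lay, 0L, 100, cy)
  dr <- pixel_to_direction(lay, 2L, 1920 - 1 - 100, cy)
  expect_equal(unname(dl[1, 1]), unname(-dr[1, 1]), tolerance = 1e-12)
  expect_equal(unname(dl[1, 3]), unname(dr[1, 3]), tolerance = 1e-12)
  ecc_l <- eccentricity_from_center(lay, 0L, 100, cy)
  ecc_r <- eccentricity_from_center(lay, 2L, 1920 - 1 - 100, cy)
  expect_equal(ecc_l, ecc_r, tolerance = 1e-9)
})

test_that("pixel -> direction -> pixel round-trips on all screens", {
  lay <- screen_layout()
  set.seed(11)
  for (i in 1:60) {
    s <- sample(0:2, 1)
    x <- runif(1, 0, 1919); y <- runif(1, 0, 1199)
    d <- pixel_to_direction(lay, s, x, y)
    back <- direction_to_pixel(lay, drop(d))
    expect_identical(back$screen, s)
    expect_lt(abs(back$x - x), 1e-6)
    expect_lt(abs(back$y - y), 1e-6)
  }
})

test_that("angular_distance is a metric and matches the dot-product oracle", {
  lay <- screen_layout()
  set.seed(7)
  pts <- data.frame(s = sample(0:2, 30, TRUE),
                    x = runif(30, 0, 1919), y = runif(30, 0, 1199))
  for (i in 1:10) {
    a <- pts[3 * i - 2, ]; b <- pts[3 * i - 1, ]; cc <- pts[3 * i, ]
    ab <- angular_distance(lay, a$s, a$x, a$y, b$s, b$x, b$y)
    ba <- angular_distance(lay, b$s, b$x, b$y, a$s, a$x, a$y)
    expect_equal(ab, ba, tolerance = 1e-10)          # symmetry
    expect_gte(ab, 0)                                # non-negativity
    ac <- angular_distance(lay, a$s, a$x, a$y, cc$s, cc$x, cc$y)
    cb <- angular_distance(lay, cc$s, cc$x, cc$y, b$s, b$x, b$y)
    expect_lte(ab, ac + cb + 1e-9)                   # triangle inequality
    # dot-product oracle
    da <- pixel_to_direction(lay, a$s, a$x, a$y)
    db <- pixel_to_direction(lay, b$s, b$x, b$y)
    expect_equal(ab, acos(min(1, sum(da * db))) * 180 / pi, tolerance = 1e-9)
  }
  expect_equal(angular_distance(lay, 1L, 10, 10, 1L, 10, 10), 0)
})

test_that("pixel distances use the unrolled three-canvas convention", {
  expect_equal(px_distance(1L, 10, 10, 1L, 10, 10), 0)
  # horizontally adjacent grid features are 200 px apart
  g <- generate_grid(1, default_layout, occlusion = matrix(TRUE, 25, 6))
  a <- g[g$col == 3 & g$row == 2, ]; b <- g[g$col == 4 & g$row == 2, ]
  expect_equal(px_distance(a$screen_id, a$x, a$y, b$screen_id, b$x, b$y), 200)
  # last column of screen 0 to first column of screen 1, by hand:
  # global x are 0*1920+1900 and 1*1920+15 -> dx = 35
  expect_equal(px_distance(0L, 1900, 500, 1L, 15, 500), 35)
})

test_that("horizontal coverage grows as screens fold inwards", {
  covs <- vapply(c(180, 170, 160, 151, 140, 120),
                 function(a) layout_coverage(
                   screen_layout(inter_screen_angle_deg = a))["horizontal"],
                 numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("a layout can be solved for a target coverage", {
  lay <- layout_for_coverage(149)
  expect_equal(unname(layout_coverage(lay)["horizontal"]), 149,
               tolerance = 1e-6)
  expect_equal(max_measurable_eccentricity(lay), 74.5, tolerance = 1e-6)
})

test_that("invalid configurations and pixels are rejected", {
  expect_error(screen_layout(inter_screen_angle_deg = 80), "90")
  expect_error(screen_layout(width_m = -1), "positive")
  expect_error(pixel_to_direction(screen_layout(), 1L, 5000, 10), "bounds")
  expect_error(pixel_to_direction(screen_layout(), 5L, 10, 10), "screen_id")
})
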