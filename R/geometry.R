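#' Three-screen simulator geometry
#'
#' Builds the 3-D layout of a driving simulator with three planar projection
#' canvases: a center screen perpendicular to the viewing axis and two side
#' screens rotated towards the viewer about the shared vertical edges. The
#' layout maps (screen, pixel) coordinates to unit viewing directions from a
#' fixed eye point, from which visual angles and eccentricities are computed.
#'
#' Coordinate conventions: the eye sits at the origin; x grows to the
#' viewer's right, y up, z towards the center screen. Per screen, pixel
#' (0, 0) is the *center* of the top-left pixel; pixel x grows rightward and
#' pixel y downward. For pixel-space distances the three canvases are
#' unrolled into one 5760 x 1200 plane (global x = screen_id * width_px + x).
#'
#' @param width_m,height_m Physical screen size in metres (each screen).
#' @param px Integer vector `c(columns, rows)` of the projector resolution.
#' @param inter_screen_angle_deg Angle between adjacent screen planes in
#'   degrees; must lie in (90, 180]. 180 means the three screens are coplanar.
#' @param eye_distance_m Distance from the eye point to the center of the
#'   center screen, metres.
#' @param reported_coverage_deg Optional length-2 numeric (horizontal,
#'   vertical) documenting an externally reported coverage; stored verbatim,
#'   never used in computation.
#' @return An object of class `screen_layout`.
#' @export
#' @examples
#' lay <- screen_layout()
#' layout_coverage(lay)
screen_layout <- function(width_m = 3.05, height_m = 1.89,
                          px = c(1920L, 1200L),
                          inter_screen_angle_deg = 151,
                          eye_distance_m = 3.75,
                          reported_coverage_deg = NULL) {
  if (width_m <= 0 || height_m <= 0 || eye_distance_m <= 0) {
    stop("screen dimensions and eye distance must be positive", call. = FALSE)
  }
  if (any(px <= 0) || length(px) != 2L) {
    stop("px must be two positive pixel counts", call. = FALSE)
  }
  if (inter_screen_angle_deg <= 90 || inter_screen_angle_deg > 180) {
    stop("inter_screen_angle_deg must lie in (90, 180]", call. = FALSE)
  }
  W <- width_m; H <- height_m; d <- eye_distance_m
  theta <- deg2rad(180 - inter_screen_angle_deg)  # outward turn of side screens

  # Per screen: 3-D position of the top-left *corner*, and unit basis vectors
  # u (along growing pixel x) and v (along growing pixel y, i.e. downward).
  vdown <- c(0, -1, 0)
  u_c <- c(1, 0, 0)
  corner_c <- c(-W / 2, H / 2, d)
  u_r <- c(cos(theta), 0, -sin(theta))
  corner_r <- c(W / 2, H / 2, d)
  u_l <- c(cos(theta), 0, sin(theta))
  corner_l <- c(-W / 2 - W * cos(theta), H / 2, d - W * sin(theta))

  layout <- structure(list(
    screen_width_m = W, screen_height_m = H,
    screen_px = as.integer(px),
    inter_screen_angle_deg = inter_screen_angle_deg,
    eye_distance_m = d,
    eye_point = c(0, 0, 0),
    px_size_m = c(W / px[1], H / px[2]),
    corners = rbind(corner_l, corner_c, corner_r),   # screen 0, 1, 2
    u = rbind(u_l, u_c, u_r),
    v = rbind(vdown, vdown, vdown),
    reported_coverage_deg = reported_coverage_deg
  ), class = "screen_layout")
  layout
}

#' @export
print.screen_layout <- function(x, ...) {
  cov <- layout_coverage(x)
  cat("Three-screen simulator layout\n")
  cat(sprintf("  screens: 3 x %.2f m x %.2f m (%d x %d px each)\n",
              x$screen_width_m, x$screen_height_m,
              x$screen_px[1], x$screen_px[2]))
  cat(sprintf("  inter-screen angle: %.1f deg, eye distance: %.2f m\n",
              x$inter_screen_angle_deg, x$eye_distance_m))
  cat(sprintf("  geometric coverage: %.1f deg x %.1f deg\n",
              cov["horizontal"], cov["vertical"]))
  if (!is.null(x$reported_coverage_deg)) {
    cat(sprintf("  reported coverage (documentation): %.0f deg x %.0f deg\n",
                x$reported_coverage_deg[1], x$reported_coverage_deg[2]))
  }
  invisible(x)
}

check_pixels <- function(layout, screen, x, y) {
  npx <- layout$screen_px
  if (any(screen < 0L | screen > 2L)) {
    stop("screen_id must be 0 (left), 1 (center) or 2 (right)", call. = FALSE)
  }
  if (any(x < -0.5 | x > npx[1] - 0.5 | y < -0.5 | y > npx[2] - 0.5)) {
    stop("pixel coordinates outside screen bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Map screen pixels to 3-D positions and viewing directions
#'
#' @param layout A [screen_layout()].
#' @param screen Integer screen id(s): 0 left, 1 center, 2 right.
#' @param x,y Pixel coordinates (0-based pixel centers); vectors recycled
#'   against `screen`.
#' @return `pixel_to_point()` returns an n x 3 matrix of positions in metres;
#'   `pixel_to_direction()` the corresponding unit directions from the eye.
#' @export
pixel_to_point <- function(layout, screen, x, y) {
  n <- max(length(screen), length(x), length(y))
  screen <- rep_len(as.integer(screen), n)
  x <- rep_len(x, n); y <- rep_len(y, n)
  check_pixels(layout, screen, x, y)
  s <- screen + 1L
  a <- (x + 0.5) * layout$px_size_m[1]
  b <- (y + 0.5) * layout$px_size_m[2]
  layout$corners[s, , drop = FALSE] +
    layout$u[s, , drop = FALSE] * a +
    layout$v[s, , drop = FALSE] * b
}

#' @rdname pixel_to_point
#' @export
pixel_to_direction <- function(layout, screen, x, y) {
  p <- pixel_to_point(layout, screen, x, y)
  p <- sweep(p, 2, layout$eye_point)
  p / sqrt(rowSums(p^2))
}

#' Invert a viewing direction back to a screen pixel
#'
#' Intersects the ray from the eye point with each screen plane and returns
#' the screen on which the intersection lies within bounds.
#'
#' @param layout A [screen_layout()].
#' @param dir Length-3 direction vector (need not be unit norm).
#' @return A list with `screen`, `x`, `y`, or an error if the ray misses all
#'   three screens.
#' @export
direction_to_pixel <- function(layout, dir) {
  npx <- layout$screen_px
  for (s in 1:3) {
    n <- pracma_cross(layout$u[s, ], layout$v[s, ])
    denom <- sum(dir * n)
    if (abs(denom) < 1e-12) next
    t <- sum((layout$corners[s, ] - layout$eye_point) * n) / denom
    if (t <= 0) next
    p <- layout$eye_point + t * dir
    rel <- p - layout$corners[s, ]
    a <- sum(rel * layout$u[s, ])
    b <- sum(rel * layout$v[s, ])
    px <- a / layout$px_size_m[1] - 0.5
    py <- b / layout$px_size_m[2] - 0.5
    if (px >= -0.5 - 1e-9 && px <= npx[1] - 0.5 + 1e-9 &&
        py >= -0.5 - 1e-9 && py <= npx[2] - 0.5 + 1e-9) {
      return(list(screen = s - 1L, x = px, y = py))
    }
  }
  stop("direction does not intersect any screen", call. = FALSE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angular distance between two on-screen points
#'
#' The angle, in degrees, between the viewing directions through two
#' (screen, pixel) points. Symmetric, non-negative, bounded by 180.
#'
#' @param layout A [screen_layout()].
#' @param screen_a,xa,ya First point (vectors allowed).
#' @param screen_b,xb,yb Second point (vectors allowed, recycled).
#' @return Numeric vector of angles in degrees.
#' @export
angular_distance <- function(layout, screen_a, xa, ya, screen_b, xb, yb) {
  da <- pixel_to_direction(layout, screen_a, xa, ya)
  db <- pixel_to_direction(layout, screen_b, xb, yb)
  n <- max(nrow(da), nrow(db))
  if (nrow(da) < n) da <- da[rep_len(seq_len(nrow(da)), n), , drop = FALSE]
  if (nrow(db) < n) db <- db[rep_len(seq_len(nrow(db)), n), , drop = FALSE]
  dp <- rowSums(da * db)
  rad2deg(acos(pmin(1, pmax(-1, dp))))
}

#' Angular distance between unrolled-canvas pixel positions
#'
#' Convenience wrapper taking global (unrolled) pixel coordinates, as used by
#' the alignment and simulation code.
#'
#' @param layout A [screen_layout()].
#' @param gxa,gya,gxb,gyb Global pixel coordinates (global x = screen * 1920 + x).
#' @return Degrees.
#' @export
angular_distance_global <- function(layout, gxa, gya, gxb, gyb) {
  a <- global_to_screen(layout, gxa, gya)
  b <- global_to_screen(layout, gxb, gyb)
  angular_distance(layout, a$screen, a$x, a$y, b$screen, b$x, b$y)
}

#' Convert between per-screen and unrolled global pixel coordinates
#' @param layout A [screen_layout()].
#' @param gx,gy Global pixel coordinates.
#' @return A list with `screen`, `x`, `y`.
#' @export
global_to_screen <- function(layout, gx, gy) {
  w <- layout$screen_px[1]
  screen <- pmin(2L, pmax(0L, as.integer(floor((gx + 0.5) / w))))
  list(screen = screen, x = gx - screen * w, y = gy)
}

#' @rdname global_to_screen
#' @param screen,x,y Per-screen pixel coordinates.
#' @export
screen_to_global <- function(layout, screen, x, y) {
  list(gx = screen * layout$screen_px[1] + x, gy = y)
}

#' Euclidean pixel distance on the unrolled three-canvas plane
#'
#' The three screens are laid side by side on one logical 5760 x 1200 canvas;
#' distances are plain Euclidean distances there. This is the pixel scale
#' used by the alignment transition weights and pixel saccade amplitudes.
#'
#' @param screen_a,xa,ya,screen_b,xb,yb Points in per-screen coordinates.
#' @param width_px Screen width in pixels (default 1920).
#' @return Pixel distance(s).
#' @export
px_distance <- function(screen_a, xa, ya, screen_b, xb, yb, width_px = 1920) {
  gxa <- screen_a * width_px + xa
  gxb <- screen_b * width_px + xb
  sqrt((gxa - gxb)^2 + (ya - yb)^2)
}

#' Field-of-view coverage of a layout
#'
#' Horizontal coverage is the angle between the viewing directions to the two
#' outermost screen edges at eye height; vertical coverage the angle between
#' the top and bottom edges of the center screen.
#'
#' @param layout A [screen_layout()].
#' @return Named numeric vector `c(horizontal=, vertical=)`, degrees.
#' @export
layout_coverage <- function(layout) {
  # outer edge of right screen at eye height (y mid-screen)
  eR <- layout$corners[3, ] + layout$u[3, ] * layout$screen_width_m +
    layout$v[3, ] * (layout$screen_height_m / 2)
  eL <- layout$corners[1, ] + layout$v[1, ] * (layout$screen_height_m / 2)
  ang <- function(a, b) {
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    rad2deg(acos(pmin(1, pmax(-1, sum(a * b)))))
  }
  top <- c(0, layout$screen_height_m / 2, layout$eye_distance_m)
  bot <- c(0, -layout$screen_height_m / 2, layout$eye_distance_m)
  c(horizontal = ang(eL, eR), vertical = ang(top, bot))
}

#' Maximum measurable eccentricity of a layout
#'
#' The eccentricity of the outermost canvas point at eye height, i.e. half
#' the horizontal coverage: a stimulus change can never be farther from a
#' centrally resting gaze than this, so it bounds the measurable pUFOV.
#'
#' @param layout A [screen_layout()].
#' @return Degrees.
#' @export
max_measurable_eccentricity <- function(layout) {
  unname(layout_coverage(layout)["horizontal"] / 2)
}

#' Solve the eye distance for a target horizontal coverage
#'
#' Keeps the screen sizes and inter-screen angle fixed and finds the eye
#' distance at which the layout's horizontal coverage equals
#' `coverage_deg`. Used for coverage presets quoted for the same simulator.
#'
#' @param coverage_deg Target horizontal coverage, degrees.
#' @param ... Passed to [screen_layout()] (all but `eye_distance_m`).
#' @return A `screen_layout`.
#' @export
layout_for_coverage <- function(coverage_deg, ...) {
  f <- function(d) {
    layout_coverage(screen_layout(eye_distance_m = d, ...))["horizontal"] -
      coverage_deg
  }
  # lower bound: eye just in front of the side-screen plane depth
  d <- stats::uniroot(f, c(1.6, 100), tol = 1e-10)$root
  screen_layout(eye_distance_m = d, ...)
}

#' Local pixel-per-degree scale of a screen
#'
#' The pixel equivalent of one degree of visual angle at the center of the
#' given screen, used to convert tracker noise and calibration errors between
#' degrees and pixels.
#'
#' @param layout A [screen_layout()].
#' @param screen Screen id 0/1/2.
#' @return Named vector `c(x=, y=)`, pixels per degree.
#' @export
px_per_degree <- function(layout, screen) {
  cx <- (layout$screen_px[1] - 1) / 2
  cy <- (layout$screen_px[2] - 1) / 2
  dx <- angular_distance(layout, screen, cx - 0.5, cy, screen, cx + 0.5, cy)
  dy <- angular_distance(layout, screen, cx, cy - 0.5, screen, cx, cy + 0.5)
  c(x = 1 / dx, y = 1 / dy)
}

#' Eccentricity of on-screen points from the straight-ahead reference
#'
#' The reference direction is eye-to-center of the center screen (the
#' instructed resting gaze).
#'
#' @param layout A [screen_layout()].
#' @param screen,x,y Point(s) in per-screen pixel coordinates.
#' @return Degrees.
#' @export
eccentricity_from_center <- function(layout, screen, x, y) {
  cx <- (layout$screen_px[1] - 1) / 2
  cy <- (layout$screen_px[2] - 1) / 2
  angular_distance(layout, screen, x, y, 1L, cx, cy)
}
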