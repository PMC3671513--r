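# Ellipse geometry: five-point conic fit, conversion to geometric
# parameters, midpoint rasterization, and the signed ellipse function.
#
# The conic is written a*x^2 + 2h*x*y + b*y^2 + 2g*x + 2f*y + 1 = 0, which is
# linear in (a, h, b, g, f) once the constant is pinned at 1. An ellipse
# candidate is any five distinct edge pixels; the conic through them either
# is an ellipse (and can be scored) or is rejected as degenerate.

#' Ellipse parameters
#'
#' Geometric description of an ellipse: center `(x0, y0)` in pixel
#' coordinates, semi-axes `rmax >= rmin` in pixels, and orientation `theta`
#' (radians, angle of the major axis, normalized to (-pi/2, pi/2]).
#'
#' @param x0,y0 center.
#' @param rmax,rmin semi-major and semi-minor axes, `rmax >= rmin > 0`.
#' @param theta major-axis angle in radians.
#' @return an object of class `ellipse_params`.
#' @export
ellipse_params <- function(x0, y0, rmax, rmin, theta = 0) {
  if (!all(is.finite(c(x0, y0, rmax, rmin, theta)))) {
    abort_wbc("ellipse parameters must be finite", "wbc_validation_error")
  }
  if (rmin <= 0 || rmax < rmin) {
    abort_wbc("need rmax >= rmin > 0", "wbc_validation_error")
  }
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  if (theta == -pi / 2) theta <- pi / 2
  structure(list(x0 = x0, y0 = y0, rmax = rmax, rmin = rmin, theta = theta),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: center (%.2f, %.2f), axes %.2f x %.2f, theta %.1f deg\n",
              x$x0, x$y0, x$rmax, x$rmin, x$theta * 180 / pi))
  invisible(x)
}

#' Fit a conic through five points
#'
#' Solves the 5x5 linear system obtained by substituting each point into
#' `a x^2 + 2h x y + b y^2 + 2g x + 2f y + 1 = 0`. Columns are scaled by
#' their maximum absolute value before solving; a reciprocal condition
#' number below 1e-10 (collinear, coincident, or otherwise degenerate
#' configurations, including conics through the origin where the constant-1
#' normalization cannot hold) raises a `wbc_degenerate_candidate_error`.
#'
#' @param points 5x2 numeric matrix of (x, y) coordinates.
#' @return list with elements `a, h, b, g, f` (class `conic_coefficients`).
#' @export
fit_conic <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 5L || ncol(points) != 2L || any(!is.finite(points))) {
    abort_wbc("`points` must be a finite 5x2 matrix", "wbc_validation_error")
  }
  if (anyDuplicated(points)) {
    abort_wbc("duplicated points", "wbc_degenerate_candidate_error")
  }
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(x^2, 2 * x * y, y^2, 2 * x, 2 * y)
  scale <- vapply(1:5, function(j) max(abs(A[, j])), numeric(1))
  scale[scale == 0] <- 1
  As <- A / rep(scale, each = 5L)
  # one QR factorization: rank and the |R| diagonal ratio (a cheap condition
  # estimate) gate degeneracy, then the same factorization solves the system
  dec <- qr(As)
  rdiag <- abs(diag(dec$qr))
  if (dec$rank < 5L || min(rdiag) == 0 || max(rdiag) / min(rdiag) > 1e10) {
    abort_wbc("degenerate five-point configuration", "wbc_degenerate_candidate_error")
  }
  coef <- qr.coef(dec, rep(-1, 5)) / scale
  structure(list(a = coef[1], h = coef[2], b = coef[3], g = coef[4], f = coef[5]),
            class = "conic_coefficients")
}

#' Convert conic coefficients to ellipse parameters
#'
#' The coefficients (and the constant term) are first normalized so that
#' `a + b < 0`, the sign convention under which a circle of radius r is
#' `a = b = -1/r^2`. With `C = ab - h^2`, `R = sqrt((a-b)^2 + 4h^2)` and
#' `Delta = det(\[a h g; h b f; g f k\])` (k the normalized constant), the
#' center is `-M^{-1}(g, f)` and the semi-axes are
#' `rmax^2 = -2 Delta / (C (a + b + R))`,
#' `rmin^2 = -2 Delta / (C (a + b - R))`,
#' with `theta = atan2(2h, a - b) / 2` the major-axis angle. Anything that is
#' not a real ellipse (hyperbola, parabola, degenerate conic) raises a
#' `wbc_non_ellipse_error`.
#'
#' @param conic list with `a, h, b, g, f`, as from [fit_conic()].
#' @return an [ellipse_params()] object.
#' @export
conic_to_ellipse <- function(conic) {
  a <- conic$a; h <- conic$h; b <- conic$b; g <- conic$g; f <- conic$f
  if (any(!is.finite(c(a, h, b, g, f)))) {
    abort_wbc("non-finite conic coefficients", "wbc_validation_error")
  }
  k <- 1
  if (a + b > 0) {  # normalize so the quadratic part is negative definite
    a <- -a; h <- -h; b <- -b; g <- -g; f <- -f; k <- -1
  }
  C <- a * b - h * h
  if (!is.finite(C) || C < 1e-12) {
    abort_wbc("conic is not an ellipse (C = ab - h^2 <= 0)", "wbc_non_ellipse_error")
  }
  R <- sqrt((a - b)^2 + 4 * h * h)
  Delta <- a * (b * k - f * f) - h * (h * k - f * g) + g * (h * f - b * g)
  x0 <- (h * f - b * g) / C
  y0 <- (g * h - a * f) / C
  arg_max <- -2 * Delta / (C * (a + b + R))
  arg_min <- -2 * Delta / (C * (a + b - R))
  if (!is.finite(arg_max) || !is.finite(arg_min) || arg_max <= 0 || arg_min <= 0) {
    abort_wbc("conic is not a real ellipse", "wbc_non_ellipse_error")
  }
  theta <- 0.5 * atan2(2 * h, a - b)
  ellipse_params(x0, y0, sqrt(arg_max), sqrt(arg_min), theta)
}

#' Signed ellipse function
#'
#' Evaluates `rmin^2 u^2 + rmax^2 v^2 - rmax^2 rmin^2` in the ellipse-aligned
#' frame (u along the major axis) and returns its sign: -1 inside, 0 on the
#' boundary (|value| < 1e-9 after normalization by `rmax^2 rmin^2`), +1
#' outside. Vectorized over `x` and `y`.
#'
#' @param x,y point coordinates (recycled against each other).
#' @param e an [ellipse_params()] object.
#' @return integer vector of signs in \{-1, 0, 1\}.
#' @export
ellipse_sign <- function(x, y, e) {
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- ct * (x - e$x0) + st * (y - e$y0)
  v <- -st * (x - e$x0) + ct * (y - e$y0)
  val <- (e$rmin^2 * u^2 + e$rmax^2 * v^2 - e$rmax^2 * e$rmin^2) /
    (e$rmax^2 * e$rmin^2)
  out <- sign(val)
  out[abs(val) < 1e-9] <- 0
  as.integer(out)
}

# First-quadrant pixels of the axis-aligned ellipse x^2/rx^2 + y^2/ry^2 = 1
# centered at the origin, chosen by the midpoint criterion: in the region
# where |dy/dx| <= 1 (x <= rx^2 / sqrt(rx^2 + ry^2)) walk columns and pick
# the y whose inter-pixel midpoint test brackets the curve; in the region
# where |dx/dy| <= 1 walk rows and pick x likewise. ceiling(t - 0.5) rounds
# to the nearest integer with the half-way case (midpoint exactly on the
# boundary, f = 0 treated as outside) resolved downwards.
mea_quadrant <- function(rx, ry) {
  xc <- rx^2 / sqrt(rx^2 + ry^2)
  yc <- ry^2 / sqrt(rx^2 + ry^2)
  xs <- 0:floor(xc)
  ys <- 0:floor(yc)
  col_pts <- cbind(xs, ceiling(ry * sqrt(pmax(0, 1 - xs^2 / rx^2)) - 0.5))
  row_pts <- cbind(ceiling(rx * sqrt(pmax(0, 1 - ys^2 / ry^2)) - 0.5), ys)
  rbind(col_pts, row_pts)
}

#' Rasterize an ellipse with the midpoint ellipse algorithm
#'
#' Produces the virtual shape S: the integer perimeter pixels of the ellipse,
#' selected by testing the sign of the ellipse function at half-pixel
#' midpoints (subpixel criterion), using the two-region scheme split where
#' the boundary slope is -1 and mirrored by 4-fold symmetry. For a rotated
#' ellipse the axis-aligned raster is rotated about the center, rounded to
#' the grid and de-duplicated. Pixels outside the image bounds are discarded.
#'
#' @param e an [ellipse_params()] object; both semi-axes must be >= 1 pixel.
#' @param width,height image bounds; kept pixels satisfy
#'   `0 <= x <= width - 1`, `0 <= y <= height - 1`.
#' @return object of class `virtual_shape`: list with `pixels` (n x 2 integer
#'   matrix of (x, y)) and `count` (Ns).
#' @export
mea_rasterize <- function(e, width, height) {
  if (e$rmax < 1 || e$rmin < 1) {
    abort_wbc("semi-axes below one pixel cannot be rasterized", "wbc_too_small_error")
  }
  quad <- mea_quadrant(e$rmax, e$rmin)
  qx <- quad[, 1]; qy <- quad[, 2]
  ux <- c(qx, -qx, qx, -qx)
  uy <- c(qy, qy, -qy, -qy)
  if (e$theta != 0) {
    ct <- cos(e$theta); st <- sin(e$theta)
    rx_ <- ct * ux - st * uy
    uy <- st * ux + ct * uy
    ux <- rx_
  }
  px <- floor(ux + e$x0 + 0.5)
  py <- floor(uy + e$y0 + 0.5)
  keep <- px >= 0 & px <= width - 1 & py >= 0 & py <= height - 1
  px <- px[keep]; py <- py[keep]
  dup <- duplicated(px * height + py)  # the key is injective on the grid
  pixels <- cbind(x = as.integer(px[!dup]), y = as.integer(py[!dup]))
  structure(list(pixels = pixels, count = nrow(pixels)), class = "virtual_shape")
}
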