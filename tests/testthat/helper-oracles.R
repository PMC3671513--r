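# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Parametric boundary points of an ellipse at the given parameter angles.
pts_on_ellipse <- function(x0, y0, rmax, rmin, theta, angles) {
  u <- rmax * cos(angles)
  v <- rmin * sin(angles)
  cbind(x0 + u * cos(theta) - v * sin(theta),
        y0 + u * sin(theta) + v * cos(theta))
}

# Exhaustive midpoint-test oracle for an axis-aligned ellipse at an integer
# center: every grid pixel is tested directly with the sign of the ellipse
# function at the half-pixel midpoints. A pixel is selected per column (in
# the region where the boundary slope is <= 1 in magnitude) when its
# vertical midpoints bracket the curve, and per row likewise; no closed-form
# y(x) or incremental decision variables are used.
mea_exhaustive_oracle <- function(rx, ry, x0, y0, width, height) {
  f <- function(x, y) ry^2 * x^2 + rx^2 * y^2 - rx^2 * ry^2
  xc <- rx^2 / sqrt(rx^2 + ry^2)
  yc <- ry^2 / sqrt(rx^2 + ry^2)
  # smallest y >= 0 whose upper midpoint lies outside-or-on the curve
  col_pick <- function(x) {
    y <- 0
    while (f(x, y + 0.5) < 0) y <- y + 1
    y
  }
  row_pick <- function(y) {
    x <- 0
    while (f(x + 0.5, y) < 0) x <- x + 1
    x
  }
  quad <- NULL
  for (x in 0:floor(xc)) quad <- rbind(quad, c(x, col_pick(x)))
  for (y in 0:floor(yc)) quad <- rbind(quad, c(row_pick(y), y))
  pts <- rbind(quad,
               cbind(-quad[, 1], quad[, 2]),
               cbind(quad[, 1], -quad[, 2]),
               cbind(-quad[, 1], -quad[, 2]))
  pts <- cbind(pts[, 1] + x0, pts[, 2] + y0)
  pts <- pts[pts[, 1] >= 0 & pts[, 1] <= width - 1 &
             pts[, 2] >= 0 & pts[, 2] <= height - 1, , drop = FALSE]
  unique(pts)
}

pixel_key <- function(m) sort(paste(m[, 1], m[, 2]))

# Distance from a point to the (axis-aligned, origin-centered) ellipse
# boundary, by dense parametric sampling.
boundary_distance <- function(px, py, rx, ry, n = 3600) {
  a <- seq(0, 2 * pi, length.out = n)
  min(sqrt((rx * cos(a) - px)^2 + (ry * sin(a) - py)^2))
}

# Brute-force boundary oracle for a binary mask: mask pixels with at least
# one false 8-neighbor, or lying on the image frame.
boundary_scan_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    if (r == 1 || r == nr || c == 1 || c == nc) { out[r, c] <- TRUE; next }
    nb <- mask[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (any(!nb)) out[r, c] <- TRUE
  }
  out
}

# Banded 64x64 test image with three flat intensity regions plus noise.
make_banded_image <- function(seed, sd = 10, sp = 0) {
  set.seed(seed)
  img <- matrix(rep(c(50, 128, 210), times = c(22, 21, 21)), 64, 64)
  img <- pmin(pmax(round(img + matrix(stats::rnorm(64 * 64, 0, sd), 64, 64)), 0), 255)
  if (sp > 0) img <- add_salt_pepper(img, sp, seed = seed + 1000)
  list(image = img, truth = matrix(rep(1:3, times = c(22, 21, 21)), 64, 64))
}

# Edge map + edge list for a rasterized ellipse (no segmentation involved).
raster_fixture <- function(e, width = 96, height = 96) {
  s <- mea_rasterize(e, width, height)
  em <- matrix(FALSE, height, width)
  em[cbind(s$pixels[, 2] + 1L, s$pixels[, 1] + 1L)] <- TRUE
  list(shape = s, edge_map = em, edges = edges_to_list(em))
}

# Gene vector addressing the given (x, y) rows of an edge list.
genes_for_points <- function(points, edges) {
  apply(points, 1, function(p) {
    which(edges$points[, 1] == p[1] & edges$points[, 2] == p[2])[1] - 1
  })
}
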