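test_that("fit_conic reproduces the circle closed form and satisfies the conic at its inputs", {
  pts <- rbind(c(2, 0), c(-2, 0), c(0, 2), c(0, -2), c(sqrt(2), sqrt(2)))
  cf <- fit_conic(pts)
  expect_equal(cf$a, -0.25, tolerance = 1e-12)
  expect_equal(cf$b, -0.25, tolerance = 1e-12)
  expect_equal(cf$h, 0, tolerance = 1e-12)
  expect_equal(cf$g, 0, tolerance = 1e-12)
  expect_equal(cf$f, 0, tolerance = 1e-12)

  p <- pts_on_ellipse(10, 20, 5, 3, pi / 6, c(0, 50, 120, 200, 290) * pi / 180)
  cf <- fit_conic(p)
  resid <- cf$a * p[, 1]^2 + 2 * cf$h * p[, 1] * p[, 2] + cf$b * p[, 2]^2 +
    2 * cf$g * p[, 1] + 2 * cf$f * p[, 2] + 1
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("fit_conic rejects degenerate point configurations", {
  collinear <- cbind(0:4, c(0, 1, 2, 3, 5))
  expect_error(fit_conic(collinear), class = "wbc_degenerate_candidate_error")
  dup <- rbind(c(1, 1), c(1, 1), c(2, 5), c(7, 3), c(4, 8))
  expect_error(fit_conic(dup), class = "wbc_degenerate_candidate_error")
})

test_that("conic_to_ellipse handles the circle, rejects non-ellipses", {
  e <- conic_to_ellipse(list(a = -0.25, h = 0, b = -0.25, g = 0, f = 0))
  expect_equal(e$x0, 0)
  expect_equal(e$y0, 0)
  expect_equal(e$rmax, 2, tolerance = 1e-12)
  expect_equal(e$rmin, 2, tolerance = 1e-12)
  expect_equal(e$theta, 0)
  expect_error(conic_to_ellipse(list(a = 1, h = 0, b = -1, g = 0, f = 0)),
               class = "wbc_non_ellipse_error")
  # an imaginary conic (no real points) is not an ellipse either
  expect_error(conic_to_ellipse(list(a = 0.25, h = 0, b = 0.25, g = 0, f = 0)),
               class = "wbc_non_ellipse_error")
})

test_that("five-point fit + conversion round-trips 100 random ellipses to 1e-6", {
  set.seed(42)
  done <- 0
  while (done < 100) {
    x0 <- runif(1, 10, 90); y0 <- runif(1, 10, 90)
    rmax <- runif(1, 3, 30); rmin <- runif(1, 3, rmax)
    theta <- runif(1, -pi / 2, pi / 2)
    p <- pts_on_ellipse(x0, y0, rmax, rmin, theta, sort(runif(5, 0, 2 * pi)))
    e <- tryCatch(conic_to_ellipse(fit_conic(p)), wbc_error = function(err) NULL)
    if (is.null(e)) next  # degenerate draw, excluded by contract
    done <- done + 1
    expect_equal(e$x0, x0, tolerance = 1e-6)
    expect_equal(e$y0, y0, tolerance = 1e-6)
    expect_equal(e$rmax, rmax, tolerance = 1e-6)
    expect_equal(e$rmin, rmin, tolerance = 1e-6)
    if (rmax - rmin > 1e-4) {
      dth <- abs(((e$theta - theta + pi / 2) %% pi) - pi / 2)
      expect_lt(dth, 1e-6)
    }
  }
})

test_that("mea_rasterize matches the exhaustive midpoint oracle (spot checks)", {
  for (ax in list(c(6, 4), c(5, 5), c(12, 3), c(8, 1), c(9, 9))) {
    e <- ellipse_params(20, 20, ax[1], ax[2])
    got <- mea_rasterize(e, 41, 41)
    want <- mea_exhaustive_oracle(ax[1], ax[2], 20, 20, 41, 41)
    expect_identical(pixel_key(got$pixels), pixel_key(want),
                     label = paste("axes", ax[1], ax[2]))
    expect_identical(got$count, nrow(want))
  }
})

test_that("axis-aligned rasters are closed under 4-fold reflection", {
  for (ax in list(c(7, 4), c(10, 6))) {
    e <- ellipse_params(30, 30, ax[1], ax[2])
    px <- mea_rasterize(e, 61, 61)$pixels
    k <- pixel_key(px)
    expect_identical(pixel_key(cbind(60 - px[, 1], px[, 2])), k)
    expect_identical(pixel_key(cbind(px[, 1], 60 - px[, 2])), k)
  }
})

test_that("raster pixels outside the image bounds are discarded", {
  e <- ellipse_params(0, 0, 5, 5)
  s <- mea_rasterize(e, 10, 10)
  expect_true(all(s$pixels[, 1] >= 0 & s$pixels[, 1] <= 9))
  expect_true(all(s$pixels[, 2] >= 0 & s$pixels[, 2] <= 9))
  # only the first quadrant of the circle survives
  full <- mea_rasterize(ellipse_params(20, 20, 5, 5), 41, 41)
  expect_lt(s$count, full$count)
  expect_error(mea_rasterize(ellipse_params(5, 5, 0.5, 0.5), 10, 10),
               class = "wbc_too_small_error")
})

test_that("rotated rasters stay within one pixel of the continuous boundary", {
  e <- ellipse_params(40.3, 39.6, 14, 9, 0.7)
  s <- mea_rasterize(e, 81, 81)
  ct <- cos(e$theta); st <- sin(e$theta)
  for (i in seq_len(s$count)) {
    u <- ct * (s$pixels[i, 1] - e$x0) + st * (s$pixels[i, 2] - e$y0)
    v <- -st * (s$pixels[i, 1] - e$x0) + ct * (s$pixels[i, 2] - e$y0)
    expect_lt(boundary_distance(u, v, e$rmax, e$rmin), 0.5 * sqrt(2) + 1)
  }
})

test_that("ellipse_sign classifies interior, boundary and exterior", {
  e <- ellipse_params(10, 20, 5, 3, pi / 6)
  expect_identical(ellipse_sign(e$x0, e$y0, e), -1L)
  b <- pts_on_ellipse(10, 20, 5, 3, pi / 6, 37 * pi / 180)
  expect_identical(ellipse_sign(b[1], b[2], e), 0L)
  expect_identical(ellipse_sign(e$x0 + 2 * e$rmax, e$y0, e), 1L)
})

test_that("ellipse_sign is monotone -..0..+ along scan lines through the center", {
  e <- ellipse_params(15, 12, 8, 5, 0.4)
  for (dir in list(c(1, 0), c(0, 1), c(cos(1.1), sin(1.1)))) {
    t <- seq(0, 20, by = 0.05)
    s <- ellipse_sign(e$x0 + t * dir[1], e$y0 + t * dir[2], e)
    expect_true(all(diff(s) >= 0))  # never returns inward
    expect_identical(s[1], -1L)
    expect_identical(s[length(s)], 1L)
  }
})
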