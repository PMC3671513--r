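# Seeded synthetic smear images with known ellipse ground truth: dark
# elliptical "cells" on a bright background, optional small round
# distractors standing in for red blood cells (mid intensity, so the
# segmenter assigns them to the middle class, as real RBCs are), plus the
# two corruption models used for robustness benchmarks: salt-and-pepper
# replacement and additive Gaussian intensity noise.

#' Render cells onto a synthetic smear image
#'
#' Cells are filled ellipses (pixels where the signed ellipse function is
#' <= 0), so rasterizing the returned ground truth reproduces the pre-noise
#' cell masks exactly. A mild per-pixel intensity jitter keeps the regions
#' from being perfectly flat.
#'
#' @param cells data frame with columns `x0, y0, rmax, rmin, theta` (0-based
#'   pixel coordinates, radians); may have zero rows.
#' @param width,height image size in pixels.
#' @param cell_intensity,background_intensity mean gray levels of cells and
#'   background (cells darker, as stained nuclei are).
#' @param intensity_jitter standard deviation of the per-pixel Gaussian
#'   jitter added before clipping.
#' @param n_distractors number of small round distractor blobs (red-cell
#'   stand-ins) drawn under the cells.
#' @param distractor_intensity gray level of the distractors.
#' @param seed integer seed for jitter and distractor placement.
#' @return list with `image` (numeric matrix in \[0, 255\]) and `truth`
#'   (the `cells` data frame, returned verbatim).
#' @export
render_cells <- function(cells, width = 128L, height = 128L,
                         cell_intensity = 60, background_intensity = 200,
                         intensity_jitter = 2, n_distractors = 0L,
                         distractor_intensity = 150, seed = NULL) {
  cells <- as.data.frame(cells)
  if (nrow(cells) > 0L) {
    need <- c("x0", "y0", "rmax", "rmin", "theta")
    if (!all(need %in% names(cells))) {
      abort_wbc("`cells` needs columns x0, y0, rmax, rmin, theta", "wbc_validation_error")
    }
    if (any(cells$rmin < 3) || any(cells$rmax < cells$rmin)) {
      abort_wbc("cells must satisfy rmax >= rmin >= 3", "wbc_validation_error")
    }
    outside <- cells$x0 + cells$rmax < 0 | cells$x0 - cells$rmax > width - 1 |
      cells$y0 + cells$rmax < 0 | cells$y0 - cells$rmax > height - 1
    if (any(outside)) {
      abort_wbc("a cell lies entirely outside the frame", "wbc_validation_error")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(background_intensity, height, width)
  xs <- matrix(rep(0:(width - 1L), each = height), height, width)
  ys <- matrix(rep(0:(height - 1L), width), height, width)
  if (n_distractors > 0L) {
    for (d in seq_len(n_distractors)) {
      r <- stats::runif(1, 3, 5)
      cx <- stats::runif(1, r, width - 1 - r)
      cy <- stats::runif(1, r, height - 1 - r)
      inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      img[inside] <- distractor_intensity
    }
  }
  for (i in seq_len(nrow(cells))) {
    e <- ellipse_params(cells$x0[i], cells$y0[i], cells$rmax[i], cells$rmin[i],
                        cells$theta[i])
    inside <- ellipse_sign(xs, ys, e) <= 0
    img[matrix(inside, height, width)] <- cell_intensity
  }
  if (intensity_jitter > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, intensity_jitter),
                        height, width)
  }
  img <- pmin(pmax(round(img), 0), 255)
  list(image = img, truth = cells)
}

#' Draw random non-degenerate cell layouts
#'
#' Centers are rejection-sampled until the pairwise separation demanded by
#' the overlap regime holds: `"none"` keeps full clearance between cells,
#' `"touching"` allows perimeters to meet, `"occluded"` forces partial
#' overlap (centers about 1.2 rmax apart).
#'
#' @param n_cells number of cells.
#' @param width,height frame size.
#' @param rmax_range,ratio_range ranges for the semi-major axis and the
#'   rmin/rmax aspect ratio.
#' @param overlap one of `"none"`, `"touching"`, `"occluded"`.
#' @param seed integer seed.
#' @return data frame with columns `x0, y0, rmax, rmin, theta`.
#' @export
random_cells <- function(n_cells = 3L, width = 128L, height = 128L,
                         rmax_range = c(12, 18), ratio_range = c(0.6, 0.95),
                         overlap = c("none", "touching", "occluded"),
                         seed = NULL) {
  overlap <- match.arg(overlap)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:200) {
    rmax <- stats::runif(n_cells, rmax_range[1], rmax_range[2])
    rmin <- pmax(rmax * stats::runif(n_cells, ratio_range[1], ratio_range[2]), 3)
    theta <- stats::runif(n_cells, -pi / 2, pi / 2)
    x0 <- stats::runif(n_cells, rmax + 2, width - 1 - rmax - 2)
    y0 <- stats::runif(n_cells, rmax + 2, height - 1 - rmax - 2)
    ok <- TRUE
    if (n_cells > 1L) {
      for (i in seq_len(n_cells - 1L)) for (j in (i + 1L):n_cells) {
        d <- sqrt((x0[i] - x0[j])^2 + (y0[i] - y0[j])^2)
        lim <- switch(overlap,
                      none = rmax[i] + rmax[j] + 6,
                      touching = rmax[i] + rmax[j],
                      occluded = 1.2 * max(rmax[i], rmax[j]))
        upper <- switch(overlap,
                        none = Inf,
                        touching = rmax[i] + rmax[j] + 4,
                        occluded = 1.35 * max(rmax[i], rmax[j]))
        if (d < lim || d > upper) { ok <- FALSE; break }
      }
    }
    if (ok) {
      return(data.frame(x0 = x0, y0 = y0, rmax = rmax, rmin = rmin, theta = theta))
    }
  }
  abort_wbc("could not place cells under the requested overlap regime",
            "wbc_validation_error")
}

#' Corrupt an image with salt-and-pepper noise
#'
#' Each pixel is independently replaced, with probability `p`, by pure black
#' or pure white (equal odds). `p` is the total corruption probability.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param p corruption probability in \[0, 1\].
#' @param seed integer seed.
#' @return corrupted image matrix.
#' @export
add_salt_pepper <- function(image, p, seed = NULL) {
  if (p < 0 || p > 1) abort_wbc("p must be in [0, 1]", "wbc_validation_error")
  if (!is.null(seed)) set.seed(seed)
  n <- length(image)
  hit <- stats::runif(n) < p
  salt <- stats::runif(n) < 0.5
  out <- image
  out[hit & salt] <- 255
  out[hit & !salt] <- 0
  out
}

#' Corrupt an image with additive Gaussian noise
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma`
#' (on the 0-255 intensity scale), clips to \[0, 255\] and rounds back to
#' the integer grid.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return corrupted image matrix.
#' @export
add_gaussian <- function(image, sigma, seed = NULL) {
  if (sigma < 0) abort_wbc("sigma must be >= 0", "wbc_validation_error")
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(image)
  out <- image + matrix(stats::rnorm(length(image), 0, sigma),
                        nrow(image), ncol(image))
  pmin(pmax(round(out), 0), 255)
}

#' Generate a complete synthetic smear fixture
#'
#' Convenience wrapper: draws a random layout, renders it with distractors,
#' and optionally applies one of the noise models.
#'
#' @inheritParams random_cells
#' @param n_distractors small round distractor blobs.
#' @param noise `NULL`, or a list `list(kind = "salt_pepper", level = p)` /
#'   `list(kind = "gaussian", level = sigma)`.
#' @param seed master seed (layout, rendering and noise are derived from it).
#' @return list with `image` (possibly noisy), `clean` (pre-noise image) and
#'   `truth` (ground-truth cell table).
#' @export
synth_smear <- function(n_cells = 3L, width = 128L, height = 128L,
                        overlap = "none", n_distractors = 3L, noise = NULL,
                        seed = 1L) {
  cells <- random_cells(n_cells, width, height, overlap = overlap, seed = seed)
  rend <- render_cells(cells, width, height, n_distractors = n_distractors,
                       seed = seed + 1L)
  img <- rend$image
  if (!is.null(noise)) {
    img <- switch(noise$kind,
                  salt_pepper = add_salt_pepper(img, noise$level, seed = seed + 2L),
                  gaussian = add_gaussian(img, noise$level, seed = seed + 2L),
                  abort_wbc("unknown noise kind", "wbc_validation_error"))
  }
  list(image = img, clean = rend$image, truth = rend$truth)
}
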