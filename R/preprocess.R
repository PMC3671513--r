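# Segmentation and edge extraction. The segmenter models pixel intensities
# as a K-component Gaussian mixture whose per-class posterior maps are
# smoothed by one explicit anisotropic-diffusion step per EM iteration
# (diffused expectation-maximization). The edge-stopping function
# g(s) = s^(-9/5) damps diffusion across sharp posterior boundaries; flat
# regions diffuse at the explicit-scheme stability cap.

#' Diffused-EM segmentation configuration
#'
#' Defaults are the calibrated setting for stained-smear segmentation:
#' K = 3 classes (cells / other structures / background), diffusion step
#' 0.1, 10 iterations, edge-stopping exponent -9/5.
#'
#' @param n_classes number of intensity classes K (>= 2).
#' @param diffusion_step diffusion step size lambda (> 0).
#' @param n_iterations number of EM iterations, each with a diffusion
#'   update of every posterior map.
#' @param edge_stopping_exponent exponent of the gradient magnitude in the
#'   edge-stopping function `g(s) = s^exponent` (negative: strong gradients
#'   diffuse less).
#' @param n_diffusion_steps explicit diffusion sub-steps applied to each
#'   posterior map per EM iteration (default 1, one update per iteration).
#'   More sub-steps smooth harder but let the posterior mass of small
#'   classes bleed into dominant neighbors, which can starve a minority
#'   intensity mode of its class; impulse noise is better removed from the
#'   class mask afterwards (see [clean_mask()]).
#' @param outlier_fraction fixed weight of the outlier component mixed into
#'   the model: point masses at the 8-bit rails 0 and 255 (45% each — on
#'   integer-quantized images impulse noise lives exactly there, and
#'   without the point masses a Gaussian class happily camps on the salt
#'   spike) plus a uniform floor over \[0, 255\] (10%). Outlier pixels are
#'   absorbed here instead of being forced into the nearest Gaussian class
#'   (which would inflate that class's variance until the classes merge);
#'   the spatial diffusion then labels them from their neighborhood. 0
#'   disables the guard.
#' @return list of class `dem_config`.
#' @export
dem_config <- function(n_classes = 3L, diffusion_step = 0.1,
                       n_iterations = 10L, edge_stopping_exponent = -9 / 5,
                       n_diffusion_steps = 1L, outlier_fraction = 0.02) {
  if (n_classes < 2L) abort_wbc("n_classes must be >= 2", "wbc_validation_error")
  if (diffusion_step <= 0) abort_wbc("diffusion_step must be > 0", "wbc_validation_error")
  if (n_iterations < 1L) abort_wbc("n_iterations must be >= 1", "wbc_validation_error")
  structure(list(n_classes = as.integer(n_classes),
                 diffusion_step = diffusion_step,
                 n_iterations = as.integer(n_iterations),
                 edge_stopping_exponent = edge_stopping_exponent,
                 n_diffusion_steps = as.integer(n_diffusion_steps),
                 outlier_fraction = outlier_fraction),
            class = "dem_config")
}

# One explicit 4-neighbor anisotropic diffusion step on a posterior map.
# The per-neighbor conductance lambda * g(|grad|) is capped at 0.25, the
# stability limit of the explicit scheme (the raw g(s) = s^(-9/5) diverges
# as s -> 0; the gradient magnitude is floored at 1e-3 and the cap keeps
# the update a convex combination of neighbors).
diffuse_step <- function(h, lambda, exponent) {
  nr <- nrow(h); nc <- ncol(h)
  # replicate-padded neighbor shifts (frame gradient = 0 -> no frame flux)
  up    <- h[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- h[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- h[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- h[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  acc <- h
  for (nb in list(up, down, left, right)) {
    grad <- nb - h
    cond <- pmin(lambda * pmax(abs(grad), 1e-3)^exponent, 0.25)
    acc <- acc + cond * grad
  }
  acc
}

#' Segment an image with diffused expectation-maximization
#'
#' Fits a K-component Gaussian mixture (plus a fixed-weight uniform outlier
#' component) to the pixel intensities by EM with spatial regularization:
#' after every E-step each class-posterior map is smoothed by
#' `n_diffusion_steps` explicit anisotropic-diffusion updates (4-neighbor,
#' conductance `lambda * g(|grad h|)` with `g(s) = s^(-9/5)`, gradient
#' floored at 1e-3 and the per-neighbor conductance capped at the
#' explicit-scheme stability limit 0.25) and renormalized to the pixel's
#' Gaussian share. Class weights and the final labels come from the
#' diffused posteriors; the Gaussian means and variances are estimated
#' from the intensity-only responsibilities, which keeps them robust to
#' posterior mass relocated by diffusion. Runs exactly `n_iterations`
#' iterations. Classes are relabeled in ascending order of their mean
#' intensity.
#'
#' @param image numeric intensity matrix on the \[0, 255\] scale; must
#'   contain at least two distinct values.
#' @param config a [dem_config()].
#' @param seed unused by the deterministic quantile initializer; accepted so
#'   callers can treat all segmenters uniformly.
#' @return object of class `wbc_labels`: list with `labels` (integer matrix,
#'   values 1..K, 1 = lowest-mean class), `class_means` (ascending) and
#'   `posteriors` (pixels x K matrix of final diffused posteriors).
#' @export
dem_segment <- function(image, config = dem_config(), seed = NULL) {
  check_gray_image(image, require_nonconstant = TRUE)
  K <- config$n_classes
  x <- as.vector(image)
  n <- length(x)
  # deterministic initialization: class means spread over the intensity
  # range (quantile-based init collapses classes when one class dominates
  # the histogram, as background does in smear images)
  rng <- range(x)
  mu <- rng[1] + (seq_len(K) - 0.5) / K * (rng[2] - rng[1])
  # start the class widths at a fraction of the inter-mean spacing: a broad
  # shared variance lets the dominant intensity mode (the background) be
  # split across two classes, starving any minority mode of its own class
  sigma2 <- rep(max(((rng[2] - rng[1]) / (4 * K))^2, 1), K)
  w <- rep(1 / K, K)
  h <- matrix(0, n, K)
  eps <- config$outlier_fraction
  outlier_dens <- eps * (0.45 * (x <= 0) + 0.45 * (x >= 255) + 0.10 / 256)
  for (it in seq_len(config$n_iterations)) {
    # E-step: Gaussian class posteriors plus the fixed-weight outlier
    # component that soaks up impulse pixels no Gaussian class explains
    for (k in seq_len(K)) {
      h[, k] <- (1 - eps) * w[k] * stats::dnorm(x, mu[k], sqrt(sigma2[k]))
    }
    h <- h + 1e-300
    total <- rowSums(h) + outlier_dens
    h <- h / total
    u <- outlier_dens / total  # per-pixel outlier share, held fixed below
    e_post <- h  # intensity-only responsibilities, kept for the M-step moments
    # diffusion of each posterior map, then per-pixel renormalization
    for (k in seq_len(K)) {
      hk <- matrix(h[, k], nrow(image), ncol(image))
      for (s in seq_len(config$n_diffusion_steps)) {
        hk <- diffuse_step(hk, config$diffusion_step,
                           config$edge_stopping_exponent)
      }
      h[, k] <- as.vector(hk)
    }
    # renormalize the class maps to their pre-diffusion share 1 - u: an
    # outlier pixel keeps a near-zero class total (so it cannot distort the
    # M-step moments) while the diffused-in neighbor mass still decides its
    # label by argmax
    h[h < 0] <- 0
    h <- h * (1 - u) / pmax(rowSums(h), 1e-12)
    # M-step: class weights from the diffused posteriors (the spatial
    # regularization feeding back into the mixture), but means/variances
    # from the intensity-only responsibilities — diffusion relocates
    # posterior mass onto pixels whose intensity the class does not
    # explain (outliers, border bands), and counting that mass in the
    # moments inflates the variances until the classes merge. Classes with
    # (almost) no support keep their parameters instead of degenerating.
    nk <- colSums(e_post)
    live <- nk > n * 1e-8
    w <- colSums(h) / sum(colSums(h))
    mu[live] <- (colSums(e_post * x) / nk)[live]
    sigma2[live] <- pmax(colSums(e_post * (outer(x, mu, "-"))^2) / nk, 0.25)[live]
  }
  ord <- order(mu)
  labels_flat <- max.col(h[, ord, drop = FALSE], ties.method = "first")
  structure(list(labels = matrix(as.integer(labels_flat), nrow(image), ncol(image)),
                 class_means = mu[ord],
                 posteriors = h[, ord, drop = FALSE]),
            class = "wbc_labels")
}

#' Multilevel Otsu segmentation (fast fallback)
#'
#' Exhaustively maximizes the between-class variance over all (K-1)-tuples
#' of thresholds on the 256-level histogram (K = 2 or 3). A histogram
#' segmenter is a legitimate stand-in for the diffused-EM default when
#' speed matters.
#'
#' @inheritParams dem_segment
#' @param n_classes 2 or 3.
#' @return `wbc_labels` (without posteriors).
#' @export
otsu_segment <- function(image, n_classes = 3L, seed = NULL) {
  check_gray_image(image, require_nonconstant = TRUE)
  v <- pmin(pmax(round(as.vector(image)), 0), 255)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  cw <- cumsum(p)
  cm <- cumsum(p * lev)
  total_mean <- cm[256L]
  class_stat <- function(i, j) {  # mass/mean of levels (i..j], 0-based thresholds
    wgt <- cw[j + 1L] - if (i >= 0L) cw[i + 1L] else 0
    mn <- cm[j + 1L] - if (i >= 0L) cm[i + 1L] else 0
    if (wgt <= 0) 0 else mn^2 / wgt
  }
  if (n_classes == 2L) {
    best <- -Inf; t1b <- 127L
    for (t1 in 0:254) {
      s <- class_stat(-1L, t1) + class_stat(t1, 255L)
      if (s > best) { best <- s; t1b <- t1 }
    }
    thr <- t1b
  } else if (n_classes == 3L) {
    best <- -Inf; thr <- c(84L, 170L)
    for (t1 in 0:253) {
      s1 <- class_stat(-1L, t1)
      for (t2 in (t1 + 1L):254L) {
        s <- s1 + class_stat(t1, t2) + class_stat(t2, 255L)
        if (s > best) { best <- s; thr <- c(t1, t2) }
      }
    }
  } else {
    abort_wbc("otsu_segment supports 2 or 3 classes", "wbc_validation_error")
  }
  labels_flat <- findInterval(v, c(thr + 0.5)) + 1L
  labels <- matrix(as.integer(labels_flat), nrow(image), ncol(image))
  means <- vapply(seq_len(n_classes), function(k) {
    if (any(labels == k)) mean(image[labels == k]) else NA_real_
  }, numeric(1))
  structure(list(labels = labels, class_means = means, posteriors = NULL),
            class = "wbc_labels")
}

#' Select the white-blood-cell class as a binary mask
#'
#' By convention the WBC class is the one with the lowest mean intensity
#' (stained nuclei are darkest); pass `class_index` to override.
#'
#' @param labels a `wbc_labels` object.
#' @param class_index class to extract (default: lowest-mean class, which is
#'   class 1 after relabeling).
#' @return logical matrix, `TRUE` at WBC pixels. Empty selections warn.
#' @export
select_wbc_mask <- function(labels, class_index = NULL) {
  if (length(labels$class_means) < 2L) {
    abort_wbc("need at least two classes", "wbc_validation_error")
  }
  if (is.null(class_index)) class_index <- which.min(labels$class_means)
  mask <- labels$labels == class_index
  if (!any(mask)) {
    warn_wbc("selected WBC class contains no pixels", "wbc_empty_class_warning")
  }
  mask
}

#' Majority-filter a binary mask
#'
#' 3x3 majority vote: a pixel belongs to the cleaned mask when at least
#' `min_votes` of the 9 pixels in its neighborhood (frame-padded with
#' background) belong to the input mask. With the default 5 this removes
#' isolated foreground speckle (salt-and-pepper survivors of segmentation)
#' and fills isolated holes, while leaving straight blob boundaries in
#' place.
#'
#' @param mask logical matrix.
#' @param min_votes votes (out of 9) required to keep a pixel.
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, min_votes = 5L) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  votes <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    votes <- votes + padded[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
  }
  votes >= min_votes
}

#' Morphological edge detection
#'
#' Erodes the binary mask by the all-ones 3x3 structuring element (pixels on
#' the image frame are treated as background for the erosion) and returns
#' `mask AND NOT eroded`: the pixels of the mask whose 3x3 neighborhood is
#' not entirely inside it.
#'
#' @param mask logical matrix.
#' @return logical edge map of the same shape.
#' @export
morph_edge <- function(mask) {
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      abort_wbc("`mask` must be binary", "wbc_validation_error")
    }
    mask <- mask == 1
  }
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  eroded <- padded[2:(nr + 1L), 2:(nc + 1L)]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    eroded <- eroded & padded[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
  }
  mask & !eroded
}

#' Flatten an edge map into the edge-pixel vector P
#'
#' @param edge_map logical matrix of edge pixels.
#' @return object of class `edge_list`: list with `points` (Np x 2 integer
#'   matrix of 0-based (x, y), in row-major scan order: by y, then x),
#'   `count` (Np) and `dim` (height, width). Fewer than five edge pixels —
#'   too few to define an ellipse candidate — raise
#'   `wbc_too_few_edges_error`.
#' @export
edges_to_list <- function(edge_map) {
  idx <- which(edge_map, arr.ind = TRUE)
  pts <- cbind(x = as.integer(idx[, 2] - 1L), y = as.integer(idx[, 1] - 1L))
  pts <- pts[order(pts[, 2], pts[, 1]), , drop = FALSE]
  if (nrow(pts) < 5L) {
    abort_wbc(sprintf("only %d edge pixels; an ellipse candidate needs 5", nrow(pts)),
              "wbc_too_few_edges_error")
  }
  structure(list(points = pts, count = nrow(pts),
                 dim = c(height = nrow(edge_map), width = ncol(edge_map))),
            class = "edge_list")
}

#' Rebuild the edge map from an edge list
#'
#' Inverse of [edges_to_list()]; mostly useful for round-trip checks.
#'
#' @param edges an `edge_list`.
#' @return logical matrix.
#' @export
list_to_edges <- function(edges) {
  m <- matrix(FALSE, edges$dim[["height"]], edges$dim[["width"]])
  m[cbind(edges$points[, 2] + 1L, edges$points[, 1] + 1L)] <- TRUE
  m
}
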