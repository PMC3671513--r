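# End-to-end detector: segment -> edge map -> repeated DE searches with
# detect-and-mask. Each accepted ellipse removes its perimeter pixels (plus
# a small neighborhood) from the live edge list before the next search
# stage, so the same cell cannot be found twice. A stage consists of up to
# `n_restarts` independent DE runs (the search is multimodal and a single
# run converges to an acceptable ellipse only part of the time); the loop
# stops at the first stage in which every restart is rejected, when too few
# edge pixels remain to carry an acceptable ellipse, or at the detection
# cap.

#' Detector configuration
#'
#' @param de a [de_config()] for each search restart (bounds and seed are
#'   managed by the detector).
#' @param accept_threshold largest matching error J accepted as a cell;
#'   0.35 sits just above the score of a clearly valid partially occluded
#'   ellipse.
#' @param max_detections safety cap on accepted ellipses per image.
#' @param mask_dilation Chebyshev radius (pixels) around an accepted
#'   perimeter within which edge pixels are removed before the next run.
#' @param limits [size_limits()] on admissible ellipse axes.
#' @param segmenter `"dem"` (diffused EM, default) or `"otsu3"` (fast
#'   three-class histogram thresholding).
#' @param dem a [dem_config()] used when `segmenter = "dem"`.
#' @param mask_clean apply the 3x3 majority filter ([clean_mask()]) to the
#'   WBC mask before edge extraction, suppressing impulse-noise speckle.
#' @param n_restarts independent DE runs attempted per detection stage
#'   before the stage — and the whole loop — is declared failed.
#' @param seed master seed; the DE run with global index r uses `seed + r`.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(de = de_config(), accept_threshold = 0.35,
                            max_detections = 20L, mask_dilation = 2L,
                            limits = size_limits(),
                            segmenter = c("dem", "otsu3"),
                            dem = dem_config(), mask_clean = TRUE,
                            n_restarts = 10L, seed = 1L) {
  if (accept_threshold <= 0 || accept_threshold >= 1) {
    abort_wbc("accept_threshold must be in (0, 1)", "wbc_validation_error")
  }
  if (max_detections < 1L) abort_wbc("max_detections must be >= 1", "wbc_validation_error")
  if (n_restarts < 1L) abort_wbc("n_restarts must be >= 1", "wbc_validation_error")
  structure(list(de = de, accept_threshold = accept_threshold,
                 max_detections = as.integer(max_detections),
                 mask_dilation = as.integer(mask_dilation), limits = limits,
                 segmenter = match.arg(segmenter), dem = dem,
                 mask_clean = isTRUE(mask_clean),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "detector_config")
}

# Smallest number of edge pixels that could still support an acceptable
# detection: an accepted ellipse needs (1 - threshold) * Ns matching edge
# pixels and the smallest admissible ellipse is the circle of radius
# `min_axis`, so fewer live edge pixels than that bound makes acceptance
# impossible.
min_viable_edges <- function(config) {
  r <- max(config$limits$min_axis, 1)
  c0 <- 2 * r + 2
  ns_min <- mea_rasterize(ellipse_params(c0, c0, r, r), 4 * r + 8, 4 * r + 8)$count
  max(5L, ceiling((1 - config$accept_threshold) * ns_min))
}

# Remove all edge pixels within Chebyshev distance `radius` of the shape's
# perimeter pixels.
mask_out_shape <- function(edge_map, shape, radius) {
  nr <- nrow(edge_map); nc <- ncol(edge_map)
  for (dy in -radius:radius) for (dx in -radius:radius) {
    yy <- shape$pixels[, 2] + dy + 1L
    xx <- shape$pixels[, 1] + dx + 1L
    ok <- yy >= 1L & yy <= nr & xx >= 1L & xx <= nc
    edge_map[cbind(yy[ok], xx[ok])] <- FALSE
  }
  edge_map
}

#' Detect white blood cells in a smear image
#'
#' Pipeline: luminance conversion (RGB input), segmentation, WBC-class mask,
#' morphological edge map, then repeated DE ellipse searches with
#' detect-and-mask (see [detector_config()]). Deterministic for a fixed
#' configuration seed.
#'
#' @param image numeric intensity matrix (or RGB array) on the \[0, 255\]
#'   scale; may be `NULL` when `edge_map` is supplied directly.
#' @param config a [detector_config()].
#' @param edge_map optional precomputed logical edge map, bypassing
#'   segmentation.
#' @return object of class `wbc_detections`: data frame with one row per
#'   accepted ellipse (`x0, y0, rmax, rmin, theta, score, run_index`),
#'   sorted by ascending score. The per-run best-J histories are attached
#'   as attribute `"histories"`, the final edge map as `"edge_map"`.
#' @export
detect_wbc <- function(image, config = detector_config(), edge_map = NULL) {
  if (is.null(edge_map)) {
    image <- to_gray(image)
    check_gray_image(image)
    labels <- switch(config$segmenter,
                     dem = dem_segment(image, config$dem),
                     otsu3 = otsu_segment(image, 3L))
    mask <- suppressWarnings(select_wbc_mask(labels))
    if (config$mask_clean) mask <- clean_mask(mask)
    edge_map <- morph_edge(mask)
  }
  empty <- data.frame(x0 = numeric(0), y0 = numeric(0), rmax = numeric(0),
                      rmin = numeric(0), theta = numeric(0), score = numeric(0),
                      run_index = integer(0))
  rows <- list()
  histories <- list()
  run <- 0L
  min_np <- min_viable_edges(config)
  repeat {
    edges <- tryCatch(edges_to_list(edge_map),
                      wbc_too_few_edges_error = function(e) NULL)
    if (is.null(edges) || edges$count < min_np ||
        length(rows) >= config$max_detections) break
    objective <- make_ellipse_objective(edges, edge_map, config$limits)
    accepted <- NULL
    for (attempt in seq_len(config$n_restarts)) {
      run <- run + 1L
      de_cfg <- config$de
      de_cfg$bounds <- matrix(c(0, edges$count - 1), 1L, 2L)[rep(1L, 5L), ]
      de_cfg$seed <- config$seed + run
      # a run may quit as soon as it reaches an acceptable score (the
      # detect-and-mask loop only needs one acceptable ellipse per stage)
      # or once it has clearly stalled; restarting beats waiting out a
      # stagnated population
      de_cfg$stop_value <- config$accept_threshold
      de_cfg$stall_generations <- 60L
      res <- run_de(objective, de_cfg)
      histories[[run]] <- res$history
      fit <- evaluate_candidate(res$best, edges, edge_map, config$limits)
      e <- attr(fit, "ellipse")
      if (!is.null(e) && fit$value <= config$accept_threshold) {
        accepted <- list(ellipse = e, value = fit$value, run = run)
        break
      }
    }
    if (is.null(accepted)) break
    e <- accepted$ellipse
    rows[[length(rows) + 1L]] <- data.frame(
      x0 = e$x0, y0 = e$y0, rmax = e$rmax, rmin = e$rmin, theta = e$theta,
      score = accepted$value, run_index = accepted$run)
    shape <- mea_rasterize(e, ncol(edge_map), nrow(edge_map))
    edge_map <- mask_out_shape(edge_map, shape, config$mask_dilation)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("wbc_detections", "data.frame"),
            histories = histories, edge_map = edge_map)
}

#' Write a detection report
#'
#' One row per detection with columns `x0, y0, rmax, rmin, theta_deg, J`.
#' The dialect is chosen by the file extension: `.csv` or `.json`.
#'
#' @param detections a `wbc_detections` (or compatible data frame).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_report <- function(detections, path) {
  df <- as.data.frame(detections)
  report <- data.frame(x0 = df$x0, y0 = df$y0, rmax = df$rmax, rmin = df$rmin,
                       theta_deg = if (nrow(df)) df$theta * 180 / pi else numeric(0),
                       J = df$score)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext == "json") {
      jsonlite::write_json(report, path, digits = NA, dataframe = "rows")
    } else if (ext == "csv") {
      utils::write.csv(format(report, digits = 15, trim = TRUE), path,
                       row.names = FALSE, quote = FALSE)
    } else {
      abort_wbc(paste("unsupported report format:", ext), "wbc_io_error")
    }
    TRUE
  }, error = function(e) {
    if (inherits(e, "wbc_error")) stop(e)
    abort_wbc(paste("cannot write report:", conditionMessage(e)), "wbc_io_error")
  })
  invisible(path)
}

#' Read a detection report back
#'
#' @param path a `.csv` or `.json` report written by [write_report()].
#' @return data frame with columns `x0, y0, rmax, rmin, theta_deg, J`.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    if (nrow(df) == 0L) {
      df <- data.frame(x0 = numeric(0), y0 = numeric(0), rmax = numeric(0),
                       rmin = numeric(0), theta_deg = numeric(0), J = numeric(0))
    }
    return(df)
  }
  if (ext == "csv") {
    return(utils::read.csv(path))
  }
  abort_wbc(paste("unsupported report format:", ext), "wbc_io_error")
}

#' Render a detection overlay
#'
#' Paints the accepted perimeters (value 255) over a dimmed copy of the
#' image; a quick visual check, not an analysis artifact.
#'
#' @param image grayscale matrix.
#' @param detections `wbc_detections`.
#' @return image matrix with perimeters burned in.
#' @export
overlay_detections <- function(image, detections) {
  out <- image * 0.7
  df <- as.data.frame(detections)
  for (i in seq_len(nrow(df))) {
    e <- ellipse_params(df$x0[i], df$y0[i], df$rmax[i], df$rmin[i], df$theta[i])
    s <- mea_rasterize(e, ncol(image), nrow(image))
    out[cbind(s$pixels[, 2] + 1L, s$pixels[, 1] + 1L)] <- 255
  }
  out
}
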