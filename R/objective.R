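# Candidate scoring: a candidate is five continuous gene values, each an
# index position (0-based) into the edge list. Scoring decodes the genes to
# edge pixels, fits the conic, converts to an ellipse, rasterizes it, and
# measures the fraction of perimeter pixels missing from the edge map:
# J(E) = 1 - sum(G) / Ns, with G the per-pixel edge-existence indicator.
# Every degeneracy maps to the worst score 1 so the optimizer's greedy
# selection stays total.

worst_fitness <- function() {
  structure(list(value = 1, matches = 0L, ns = 0L), class = "wbc_fitness")
}

#' Size limits for plausible cell ellipses
#'
#' Candidate ellipses outside these limits score the worst value 1. The
#' limits are detector plumbing, not biology from any particular corpus:
#' they stop the optimizer from exploiting tiny ellipses that trivially
#' match a few pixels.
#'
#' @param min_axis smallest admissible semi-minor axis in pixels.
#' @param max_axis_frac largest admissible semi-major axis, as a fraction of
#'   the shorter image side.
#' @return list of class `size_limits`.
#' @export
size_limits <- function(min_axis = 3, max_axis_frac = 0.5) {
  structure(list(min_axis = min_axis, max_axis_frac = max_axis_frac),
            class = "size_limits")
}

#' Decode candidate genes to edge pixels
#'
#' Genes are rounded to the nearest integer (half-way up) and clamped to
#' `[0, Np - 1]` — repair, not rejection, so mutants may roam outside the
#' index range without breaking the search.
#'
#' @param genes numeric vector of five index positions.
#' @param edges an `edge_list` from [edges_to_list()].
#' @return 5x2 matrix of (x, y) edge-pixel coordinates.
#' @export
decode_candidate <- function(genes, edges) {
  np <- edges$count
  idx <- pmin(pmax(floor(genes + 0.5), 0), np - 1)
  edges$points[idx + 1L, , drop = FALSE]
}

#' Matching error between a virtual shape and the edge map
#'
#' @param shape a `virtual_shape` from [mea_rasterize()].
#' @param edge_map logical matrix of edge pixels.
#' @return `wbc_fitness`: list with `value` (J in \[0, 1\]), `matches`
#'   (number of shape pixels present in the edge map) and `ns` (shape size).
#' @export
match_score <- function(shape, edge_map) {
  if (shape$count == 0L) return(worst_fitness())
  hits <- edge_map[cbind(shape$pixels[, 2] + 1L, shape$pixels[, 1] + 1L)]
  m <- sum(hits)
  structure(list(value = 1 - m / shape$count, matches = as.integer(m),
                 ns = shape$count), class = "wbc_fitness")
}

#' Score one candidate against the edge map
#'
#' Runs decode -> conic fit -> ellipse conversion -> rasterization ->
#' matching. Degenerate fits, non-ellipse conics, out-of-limit axes and
#' empty rasters all return the worst fitness (value 1) instead of raising.
#'
#' @param genes five gene values (edge-list index positions).
#' @param edges `edge_list` the genes index into.
#' @param edge_map logical matrix the virtual shape is matched against.
#' @param limits [size_limits()] on the admissible ellipse axes.
#' @return `wbc_fitness`; the fitted `ellipse_params` is attached as
#'   attribute `"ellipse"` when the candidate is non-degenerate.
#' @export
evaluate_candidate <- function(genes, edges, edge_map, limits = size_limits()) {
  pts <- decode_candidate(genes, edges)
  if (anyDuplicated(pts)) return(worst_fitness())
  e <- tryCatch(conic_to_ellipse(fit_conic(pts)), wbc_error = function(err) NULL)
  if (is.null(e)) return(worst_fitness())
  max_axis <- limits$max_axis_frac * min(dim(edge_map))
  if (e$rmin < limits$min_axis || e$rmax > max_axis) return(worst_fitness())
  shape <- tryCatch(mea_rasterize(e, ncol(edge_map), nrow(edge_map)),
                    wbc_error = function(err) NULL)
  if (is.null(shape) || shape$count == 0L) return(worst_fitness())
  fit <- match_score(shape, edge_map)
  attr(fit, "ellipse") <- e
  fit
}

#' Build the detection objective for the optimizer
#'
#' @inheritParams evaluate_candidate
#' @return function mapping a gene vector to its J value in \[0, 1\].
#' @export
make_ellipse_objective <- function(edges, edge_map, limits = size_limits()) {
  force(edges); force(edge_map); force(limits)
  function(genes) evaluate_candidate(genes, edges, edge_map, limits)$value
}
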