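# Corpus-level scoring: detections are matched one-to-one to ground-truth
# cells, and the match counts yield the detection rate (DR) and the
# false-alarm rate (FAR), both expressed as percentages of the
# expert-determined (here: generator-determined) leukocyte count.

#' Match detections to ground-truth ellipses
#'
#' Greedy one-to-one matching by ascending center distance. A pairing
#' counts as correct when the center distance is within `center_tol` pixels
#' and both semi-axes agree within `axis_tol` relative error. Unmatched
#' ground-truth cells are missing; unmatched detections are false alarms.
#'
#' @param detections data frame with columns `x0, y0, rmax, rmin` (e.g. the
#'   output of [detect_wbc()]); may have zero rows.
#' @param truth data frame of ground-truth cells with the same columns.
#' @param center_tol center tolerance in pixels (> 0).
#' @param axis_tol relative semi-axis tolerance (> 0).
#' @return object of class `match_result`: list with `detected_correct`,
#'   `missing`, `false_alarms`, `expert_total`.
#' @export
match_detections <- function(detections, truth, center_tol = 5, axis_tol = 0.25) {
  if (center_tol <= 0 || axis_tol <= 0) {
    abort_wbc("tolerances must be positive", "wbc_validation_error")
  }
  detections <- as.data.frame(detections)
  truth <- as.data.frame(truth)
  nd <- nrow(detections); nt <- nrow(truth)
  correct <- 0L
  if (nd > 0L && nt > 0L) {
    dist <- outer(detections$x0, truth$x0, "-")^2 +
      outer(detections$y0, truth$y0, "-")^2
    ok_axis <- abs(outer(detections$rmax, truth$rmax, "-")) <=
      axis_tol * outer(rep(1, nd), truth$rmax) &
      abs(outer(detections$rmin, truth$rmin, "-")) <=
      axis_tol * outer(rep(1, nd), truth$rmin)
    eligible <- dist <= center_tol^2 & ok_axis
    dist[!eligible] <- Inf
    used_d <- logical(nd); used_t <- logical(nt)
    repeat {
      m <- which.min(dist)
      if (length(m) == 0L || !is.finite(dist[m])) break
      di <- (m - 1L) %% nd + 1L
      ti <- (m - 1L) %/% nd + 1L
      correct <- correct + 1L
      used_d[di] <- TRUE; used_t[ti] <- TRUE
      dist[di, ] <- Inf; dist[, ti] <- Inf
    }
    false_alarms <- sum(!used_d)
    missing <- sum(!used_t)
  } else {
    false_alarms <- nd
    missing <- nt
  }
  structure(list(detected_correct = as.integer(correct),
                 missing = as.integer(missing),
                 false_alarms = as.integer(false_alarms),
                 expert_total = as.integer(nt)),
            class = "match_result")
}

#' Aggregate match results
#'
#' Sums the counts of several per-image `match_result`s, as corpus-level
#' rates are computed from pooled counts rather than averaged per image.
#'
#' @param results list of `match_result` objects.
#' @return a pooled `match_result`.
#' @export
pool_matches <- function(results) {
  structure(list(
    detected_correct = sum(vapply(results, `[[`, integer(1), "detected_correct")),
    missing = sum(vapply(results, `[[`, integer(1), "missing")),
    false_alarms = sum(vapply(results, `[[`, integer(1), "false_alarms")),
    expert_total = sum(vapply(results, `[[`, integer(1), "expert_total"))),
    class = "match_result")
}

#' Detection rate and false-alarm rate
#'
#' DR is the percentage of expert-counted leukocytes correctly detected;
#' FAR is the number of non-leukocyte objects wrongly identified as
#' leukocytes, as a percentage of the same expert count. Both are reported
#' to two decimals.
#'
#' @param result a `match_result` (from [match_detections()] or
#'   [pool_matches()]); `expert_total` must be positive.
#' @return named numeric vector `c(DR = ..., FAR = ...)` in percent.
#' @export
compute_dr_far <- function(result) {
  if (result$expert_total <= 0L) {
    abort_wbc("expert_total must be positive to define DR/FAR",
              "wbc_undefined_metric_error")
  }
  c(DR = round(100 * result$detected_correct / result$expert_total, 2),
    FAR = round(100 * result$false_alarms / result$expert_total, 2))
}
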