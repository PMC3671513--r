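# Differential evolution, best/1/bin: the printed update equations are
#   init:      x_{j,i,0} = low_j + U(0,1) (high_j - low_j)
#   mutation:  v_i = x_best + F (x_r1 - x_r2),   r1 != r2 != i
#   crossover: u_{j,i} = v_{j,i} if U(0,1) <= CR or j = j_rand, else x_{j,i}
#   selection: trial replaces parent iff f(trial) <= f(parent)
# The population is updated in place within a generation (classic
# Storn-Price bookkeeping), so an improved best is available immediately.
# Genes are not clipped here; domain repair lives in decode_candidate().

#' Differential evolution configuration
#'
#' Defaults follow the calibrated detector settings: population 20,
#' F = 0.25, CR = 0.80, 200 generations.
#'
#' @param pop_size number of candidate vectors (>= 4; best/1 mutation needs
#'   the best member plus two distinct others different from the target).
#' @param scale_factor mutation scale F (> 0).
#' @param crossover_rate binomial crossover probability CR in \[0, 1\].
#' @param n_generations number of generations to run (sole stopping rule
#'   unless `stop_value` is set).
#' @param bounds 2-column matrix (or list `low`/`high`) of per-dimension
#'   initialization bounds.
#' @param seed optional integer seed set at the start of [run_de()].
#' @param stop_value optional objective threshold: stop early once the best
#'   value is <= this. Off (`NULL`) by default.
#' @param stall_generations optional stagnation window: stop early when the
#'   best value has not improved for this many consecutive generations. Off
#'   (`NULL`) by default.
#' @return list of class `de_config`.
#' @export
de_config <- function(pop_size = 20L, scale_factor = 0.25, crossover_rate = 0.80,
                      n_generations = 200L, bounds = NULL, seed = NULL,
                      stop_value = NULL, stall_generations = NULL) {
  if (pop_size < 4L) abort_wbc("pop_size must be >= 4", "wbc_validation_error")
  if (scale_factor <= 0) abort_wbc("scale_factor must be > 0", "wbc_validation_error")
  if (crossover_rate < 0 || crossover_rate > 1) {
    abort_wbc("crossover_rate must be in [0, 1]", "wbc_validation_error")
  }
  if (n_generations < 1L) abort_wbc("n_generations must be >= 1", "wbc_validation_error")
  structure(list(pop_size = as.integer(pop_size), scale_factor = scale_factor,
                 crossover_rate = crossover_rate,
                 n_generations = as.integer(n_generations),
                 bounds = bounds, seed = seed, stop_value = stop_value,
                 stall_generations = stall_generations),
            class = "de_config")
}

as_bounds_matrix <- function(bounds, d = NULL) {
  if (is.list(bounds) && !is.null(bounds$low)) {
    bounds <- cbind(bounds$low, bounds$high)
  }
  bounds <- as.matrix(bounds)
  if (!is.null(d) && nrow(bounds) == 1L) {
    bounds <- bounds[rep(1L, d), , drop = FALSE]
  }
  if (any(bounds[, 1] > bounds[, 2])) {
    abort_wbc("lower bound exceeds upper bound", "wbc_validation_error")
  }
  bounds
}

#' Initialize a DE population uniformly within bounds
#'
#' @param config [de_config()] with `bounds` set.
#' @param d problem dimension (inferred from `bounds` when omitted).
#' @return `pop_size` x `d` matrix of gene values.
#' @export
init_population <- function(config, d = NULL) {
  bounds <- as_bounds_matrix(config$bounds, d)
  d <- nrow(bounds)
  u <- matrix(stats::runif(config$pop_size * d), config$pop_size, d)
  sweep(sweep(u, 2L, bounds[, 2] - bounds[, 1], "*"), 2L, bounds[, 1], "+")
}

# r1, r2 distinct from each other and from the target index i.
draw_donors <- function(pop_size, i) {
  pool <- setdiff(seq_len(pop_size), i)
  pool[sample.int(length(pool), 2L)]
}

#' best/1 mutation
#'
#' `v = x_best + F (x_r1 - x_r2)` with `r1 != r2 != i`. The donor indices
#' can be supplied for deterministic tests; otherwise they are drawn.
#'
#' @param members population matrix (rows are candidates).
#' @param best_index row index of the current best member.
#' @param i target member index (excluded from the donor draw).
#' @param scale_factor mutation scale F.
#' @param donors optional length-2 integer vector (r1, r2).
#' @return list with `mutant` (gene vector) and `donors`.
#' @export
de_mutate <- function(members, best_index, i, scale_factor, donors = NULL) {
  if (nrow(members) < 4L) {
    abort_wbc("best/1 mutation needs a population of at least 4", "wbc_validation_error")
  }
  if (is.null(donors)) donors <- draw_donors(nrow(members), i)
  mutant <- members[best_index, ] +
    scale_factor * (members[donors[1L], ] - members[donors[2L], ])
  list(mutant = mutant, donors = donors)
}

#' Binomial crossover
#'
#' Per dimension the trial takes the mutant gene when `U(0,1) <= CR` or at
#' the forced coordinate `j_rand`, else the parent gene, so the trial always
#' differs from the parent in at least the forced coordinate (whenever the
#' mutant does).
#'
#' @param mutant,parent gene vectors of equal length.
#' @param crossover_rate CR in \[0, 1\].
#' @param j_rand optional forced coordinate (drawn uniformly when `NULL`).
#' @return trial gene vector.
#' @export
de_crossover <- function(mutant, parent, crossover_rate, j_rand = NULL) {
  d <- length(mutant)
  if (is.null(j_rand)) j_rand <- sample.int(d, 1L)
  take <- stats::runif(d) <= crossover_rate
  take[j_rand] <- TRUE
  ifelse(take, mutant, parent)
}

#' Greedy one-to-one selection
#'
#' @param parent_value,trial_value objective values of parent and trial.
#' @return `TRUE` when the trial survives (`trial_value <= parent_value`).
#' @export
de_select <- function(parent_value, trial_value) trial_value <= parent_value

#' Run the differential evolution optimizer
#'
#' Runs exactly `n_generations` generations of best/1/bin (or fewer if the
#' optional `stop_value` threshold is reached). Elitism is structural: the
#' greedy selection never discards the best member, so the best-value
#' history is non-increasing. Fully deterministic for a fixed `seed`.
#'
#' @param objective function mapping a gene vector to a finite scalar; it
#'   must never raise on the bounded domain (degeneracies should map to a
#'   worst-case value).
#' @param config a [de_config()].
#' @return list with `best` (gene vector), `best_value`, `history`
#'   (best value after each generation), `population`, `values`, and
#'   `n_generations_run`.
#' @export
run_de <- function(objective, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  members <- init_population(config)
  np <- nrow(members)
  values <- apply(members, 1L, objective)
  best_i <- which.min(values)
  history <- numeric(config$n_generations)
  gens_run <- 0L
  for (t in seq_len(config$n_generations)) {
    for (i in seq_len(np)) {
      mutant <- de_mutate(members, best_i, i, config$scale_factor)$mutant
      trial <- de_crossover(mutant, members[i, ], config$crossover_rate)
      trial_value <- objective(trial)
      if (de_select(values[i], trial_value)) {
        members[i, ] <- trial
        values[i] <- trial_value
        if (trial_value <= values[best_i]) best_i <- i
      }
    }
    gens_run <- t
    history[t] <- values[best_i]
    if (!is.null(config$stop_value) && values[best_i] <= config$stop_value) break
    if (!is.null(config$stall_generations) && t > config$stall_generations &&
        history[t] >= history[t - config$stall_generations]) break
  }
  list(best = members[best_i, ], best_value = values[best_i],
       history = history[seq_len(gens_run)], population = members,
       values = values, n_generations_run = gens_run)
}
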