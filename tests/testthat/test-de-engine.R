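sphere <- function(g) sum(g^2)
unit_bounds <- function(lo, hi) matrix(c(lo, hi), 1, 2)[rep(1, 5), ]

test_that("init_population respects bounds, seeds, and uniformity", {
  cfg <- de_config(bounds = unit_bounds(0, 0))
  set.seed(1)
  expect_true(all(init_population(cfg) == 0))

  cfg2 <- de_config(bounds = unit_bounds(0, 99), pop_size = 2000L)
  set.seed(7); a <- init_population(cfg2)
  set.seed(7); b <- init_population(cfg2)
  expect_identical(a, b)
  expect_gte(min(a), 0)
  expect_lte(max(a), 99)
  expect_equal(mean(a), 99 / 2, tolerance = 0.02)

  expect_error(de_config(bounds = unit_bounds(1, 0)) |> init_population(),
               class = "wbc_validation_error")
})

test_that("de_mutate implements best/1 and never reuses indices", {
  members <- rbind(rep(10, 5), rep(8, 5), rep(4, 5), rep(0, 5))
  m <- de_mutate(members, best_index = 1, i = 4, scale_factor = 0.25,
                 donors = c(2, 3))
  expect_equal(m$mutant, rep(11, 5))
  m0 <- de_mutate(members, best_index = 1, i = 4, scale_factor = 0,
                  donors = c(2, 3))
  expect_equal(m0$mutant, rep(10, 5))

  set.seed(3)
  for (rep in 1:10000) {
    i <- sample.int(8, 1)
    d <- wbcde:::draw_donors(8, i)
    expect_true(d[1] != d[2] && d[1] != i && d[2] != i)
  }
})

test_that("de_crossover honours CR extremes and the forced coordinate", {
  mutant <- rep(1, 5); parent <- rep(0, 5)
  set.seed(2)
  expect_equal(de_crossover(mutant, parent, 1), mutant)
  tr0 <- de_crossover(mutant, parent, 0, j_rand = 3)
  expect_equal(tr0, c(0, 0, 1, 0, 0))
  # expected mutant-gene fraction CR + (1 - CR)/D
  set.seed(9)
  frac <- mean(replicate(10000, mean(de_crossover(mutant, parent, 0.8))))
  expect_equal(frac, 0.8 + 0.2 / 5, tolerance = 0.01)
})

test_that("greedy selection keeps the trial on ties and better scores only", {
  expect_true(de_select(0.3, 0.3))
  expect_true(de_select(0.3, 0.1))
  expect_false(de_select(0.3, 0.9))
})

test_that("run_de is elitist, deterministic, and optimizes the sphere", {
  cfg <- de_config(bounds = unit_bounds(-5, 5), seed = 3)
  res <- run_de(sphere, cfg)
  expect_true(all(diff(res$history) <= 0))
  expect_identical(res$n_generations_run, 200L)
  # the paper's parameters converge on most but not all seeds (premature
  # convergence of best/1 at F = 0.25 is real; see the acceptance suite)
  vals <- vapply(1:8, function(s) {
    run_de(sphere, de_config(bounds = unit_bounds(-5, 5), seed = s))$best_value
  }, numeric(1))
  expect_gte(sum(vals <= 1e-3), 4)
  expect_lt(median(vals), 0.05)

  res2 <- run_de(sphere, cfg)
  expect_identical(res$best, res2$best)
  expect_identical(res$history, res2$history)
})

test_that("stop_value and stall_generations terminate runs early", {
  cfg <- de_config(bounds = unit_bounds(-5, 5), seed = 1, stop_value = 1)
  res <- run_de(sphere, cfg)
  expect_lt(res$n_generations_run, 200L)
  expect_lte(res$best_value, 1)
  cfg2 <- de_config(bounds = unit_bounds(-5, 5), seed = 2,
                    stall_generations = 10L)
  res2 <- run_de(function(g) 1, cfg2)  # flat objective stalls immediately
  expect_identical(res2$n_generations_run, 11L)
})

test_that("run_de recovers a single rendered ellipse in most runs", {
  fx <- raster_fixture(ellipse_params(45, 50, 15, 11, 0.4))
  obj <- make_ellipse_objective(fx$edges, fx$edge_map)
  ok <- 0
  for (s in 1:8) {
    cfg <- de_config(bounds = matrix(c(0, fx$edges$count - 1), 1, 2)[rep(1, 5), ],
                     seed = s, stop_value = 0.35)
    ok <- ok + (run_de(obj, cfg)$best_value <= 0.35)
  }
  # a single run reaches an acceptable score only most of the time (the
  # landscape is multimodal); the detector compensates with restarts
  expect_gte(ok, 5)
})
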