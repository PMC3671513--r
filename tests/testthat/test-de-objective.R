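test_that("decode_candidate rounds half-up and clamps to the index range", {
  fx <- raster_fixture(ellipse_params(40, 40, 12, 8, 0.3))
  np <- fx$edges$count
  expect_identical(decode_candidate(0:4, fx$edges), fx$edges$points[1:5, ])
  got <- decode_candidate(c(-0.4, np - 0.6, 2.49, 2.51, 2.5), fx$edges)
  want <- fx$edges$points[c(1, np, 3, 4, 4) , ]
  # -0.4 -> 0, Np-0.6 -> Np-1, 2.49 -> 2, 2.51 -> 3, 2.5 -> 3 (half up)
  expect_identical(got[1, ], fx$edges$points[1, ])
  expect_identical(got[2, ], fx$edges$points[np, ])
  expect_identical(got[3, ], fx$edges$points[3, ])
  expect_identical(got[4, ], fx$edges$points[4, ])
  expect_identical(got[5, ], fx$edges$points[4, ])
})

test_that("match_score reproduces the worked 35-of-52 example and the extremes", {
  # an ellipse whose in-bounds perimeter has exactly 52 pixels
  e <- ellipse_params(32, 32, 9, 9)
  s <- mea_rasterize(e, 64, 64)
  expect_identical(s$count, 52L)
  em <- matrix(FALSE, 64, 64)
  set.seed(7)
  keep <- sample(s$count, 35)
  em[cbind(s$pixels[keep, 2] + 1L, s$pixels[keep, 1] + 1L)] <- TRUE
  f <- match_score(s, em)
  expect_identical(f$matches, 35L)
  expect_identical(f$ns, 52L)
  expect_equal(round(f$value, 3), 0.327)

  full <- matrix(TRUE, 64, 64)
  expect_equal(match_score(s, full)$value, 0)
  expect_equal(match_score(s, matrix(FALSE, 64, 64))$value, 1)
})

test_that("evaluate_candidate scores on-perimeter candidates and degenerates", {
  fx <- raster_fixture(ellipse_params(40, 40, 14, 10, 0.5))
  sel <- fx$shape$pixels[round(seq(1, fx$shape$count, length.out = 5)), ]
  genes <- genes_for_points(sel, fx$edges)
  f <- evaluate_candidate(genes, fx$edges, fx$edge_map)
  # integer rounding of the five points perturbs the fit, so the refit
  # raster does not coincide exactly with the source raster; a valid cell
  # still scores well below the acceptance threshold
  expect_lt(f$value, 0.35)
  expect_s3_class(attr(f, "ellipse"), "ellipse_params")

  # duplicated decoded points are repaired to the worst score, not an error
  f_dup <- evaluate_candidate(rep(genes[1], 5), fx$edges, fx$edge_map)
  expect_identical(f_dup$value, 1)
  expect_null(attr(f_dup, "ellipse"))
})

test_that("erasing edge pixels can only worsen J (monotonicity in matches)", {
  fx <- raster_fixture(ellipse_params(40, 40, 14, 10, 0.5))
  sel <- fx$shape$pixels[round(seq(1, fx$shape$count, length.out = 5)), ]
  genes <- genes_for_points(sel, fx$edges)
  f_full <- evaluate_candidate(genes, fx$edges, fx$edge_map)
  # erase half of the perimeter, keeping the candidate's own five pixels
  set.seed(11)
  keep_idx <- genes + 1
  droppable <- setdiff(seq_len(fx$shape$count), keep_idx)
  drop <- sample(droppable, floor(fx$shape$count / 2))
  em2 <- fx$edge_map
  em2[cbind(fx$shape$pixels[drop, 2] + 1L, fx$shape$pixels[drop, 1] + 1L)] <- FALSE
  f_half <- evaluate_candidate(genes, fx$edges, em2)
  expect_gt(f_half$value, f_full$value)

  # for a fixed shape the match count drops by exactly the erased matches
  s_fit <- mea_rasterize(attr(f_full, "ellipse"), 96, 96)
  m_full <- match_score(s_fit, fx$edge_map)
  m_half <- match_score(s_fit, em2)
  erased <- sum(fx$edge_map & !em2)
  expect_lte(m_full$matches - m_half$matches, erased)
  expect_gte(m_full$matches, m_half$matches)
})

test_that("size limits and empty shapes map to the worst fitness", {
  fx <- raster_fixture(ellipse_params(40, 40, 14, 10, 0.5))
  sel <- fx$shape$pixels[round(seq(1, fx$shape$count, length.out = 5)), ]
  genes <- genes_for_points(sel, fx$edges)
  strict <- size_limits(min_axis = 12)  # rmin ~10 now inadmissible
  expect_identical(evaluate_candidate(genes, fx$edges, fx$edge_map, strict)$value, 1)
  expect_identical(match_score(structure(list(pixels = matrix(0L, 0, 2), count = 0L),
                                         class = "virtual_shape"),
                               fx$edge_map)$value, 1)
})

test_that("match_score equals brute-force set intersection", {
  set.seed(5)
  for (i in 1:10) {
    e <- ellipse_params(runif(1, 20, 70), runif(1, 20, 70),
                        runif(1, 5, 15), runif(1, 3, 5), runif(1, -1, 1))
    s <- mea_rasterize(e, 96, 96)
    em <- matrix(runif(96 * 96) < 0.3, 96, 96)
    f <- match_score(s, em)
    edge_set <- paste(which(em, arr.ind = TRUE)[, 2] - 1,
                      which(em, arr.ind = TRUE)[, 1] - 1)
    shape_set <- paste(s$pixels[, 1], s$pixels[, 2])
    expect_identical(f$matches, length(intersect(shape_set, edge_set)))
    expect_equal(f$value, 1 - f$matches / s$count)
    expect_gte(f$value, 0); expect_lte(f$value, 1)
  }
})
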