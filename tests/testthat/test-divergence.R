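test_that("buffer backgrounds match a brute-force distance test", {
  h <- grid_header(5, 5, 0, 40, 1)
  occ <- make_occ(2.5, 42.5)
  # radius 0: only the cell containing the occurrence
  b0 <- buffer_background(occ, 0, h)
  expect_equal(sum(b0$mask), 1)
  rc <- cell_of(2.5, 42.5, h)
  expect_true(b0$mask[rc$row, rc$col])
  # radius beyond half the Earth: everything
  ball <- buffer_background(occ, 25000, h)
  expect_true(all(ball$mask))
  # brute force on the 5x5 grid
  b <- buffer_background(occ, 200, h)
  for (r in 1:5) for (c in 1:5) {
    ctr <- cell_center(r, c, h)
    inside <- haversine_km(ctr$lon, ctr$lat, 2.5, 42.5) <= 200 ||
      (r == rc$row && c == rc$col)
    expect_identical(b$mask[r, c], inside)
  }
})

test_that("background point sampling is uniform without replacement", {
  h <- grid_header(4, 4, 0, 0, 1)
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  spec <- mask_background(m, h)
  # n equal to the number of true cells returns exactly that set
  pts <- sample_background_points(spec, 4, seed = 1)
  rc <- cell_of(pts$lon, pts$lat, h)
  expect_equal(sort(paste(rc$row, rc$col)), c("1 1", "1 2", "2 1", "2 2"))
  expect_error(sample_background_points(spec, 5, seed = 1), "sampling")
  # every sampled point satisfies the mask; frequencies uniform within 3 sigma
  counts <- setNames(numeric(4), c("1 1", "1 2", "2 1", "2 2"))
  for (i in 1:2000) {
    p <- sample_background_points(spec, 2, seed = i)
    rc <- cell_of(p$lon, p$lat, h)
    keys <- paste(rc$row, rc$col)
    expect_true(all(keys %in% names(counts)))
    counts[keys] <- counts[keys] + 1
  }
  # each cell appears in 2 of 4 slots per draw: expectation 1000
  sigma <- sqrt(2000 * 0.5 * 0.5)
  expect_true(all(abs(counts - 1000) < 3 * sigma))
})

test_that("background verdicts implement the confidence-interval rule", {
  null <- rnorm(100, 0.5, 0.01)
  expect_equal(decide_background_verdict(min(null) - 0.1, null), "divergence")
  expect_equal(decide_background_verdict(max(null) + 0.1, null),
               "conservatism")
  expect_equal(decide_background_verdict(median(null), null), "not_rejected")
  # normal-approximation CI option
  ci <- background_ci(null, method = "normal")
  expect_equal(ci[1], mean(null) - qnorm(0.975) * sd(null))
})

test_that("verdict fixtures reproduce reported comparisons", {
  # strong case: actual overlap far below a null at 0.171 +/- 0.006
  set.seed(1)
  null_high <- rnorm(100, 0.171, 0.006)
  expect_equal(decide_background_verdict(0.067, null_high), "divergence")
  # weak case: null at 0.062 +/- 0.005 straddles the observed 0.067
  set.seed(2)
  null_near <- rnorm(100, 0.062, 0.005)
  expect_equal(decide_background_verdict(0.067, null_near), "not_rejected")
  # multivariate fixtures: mean-difference vs replicate background range
  expect_equal(decide_mv_verdict(0.44, c(0.91, 1.12)), "conservatism")
  expect_equal(decide_mv_verdict(0.66, c(0.49, 0.72)), "inconclusive")
  expect_equal(decide_mv_verdict(0.50, c(0.09, 0.37)), "divergence")
  expect_error(decide_mv_verdict(1, numeric(0)), "non-empty")
})

test_that("the background-similarity result is internally consistent", {
  sc <- gen_scenario(scenario_config(
    seed = 8, header = grid_header(45, 40, -100, 42, 0.25),
    n_occ_A = 60, n_occ_B = 60,
    background_A = region_circles(-96, 45, 250),
    background_B = region_circles(-93.5, 45, 250)))
  mA <- fit_maxent(sc$env, sc$occ_A, seed = 18, background_n = 500)
  mB <- fit_maxent(sc$env, sc$occ_B, seed = 19, background_n = 500)
  pA <- standardize_surface(mA$raw_surface)
  act <- niche_overlap(pA, standardize_surface(mB$raw_surface))
  bt <- background_similarity_test(pA, 60,
                                   mask_background(sc$background_B,
                                                   sc$env$header),
                                   sc$env, act, n_reps = 8, seed = 20,
                                   background_n = 500)
  expect_length(bt$null_D, 8)
  expect_true(all(bt$null_D >= 0 & bt$null_D <= 1))
  expect_true(all(bt$null_I >= bt$null_D - 1e-12))
  expect_equal(bt$verdict_D,
               decide_background_verdict(bt$actual_D, bt$null_D))
  expect_equal(bt$ci_D,
               background_ci(bt$null_D, 0.05, "percentile"))
  expect_gte(bt$p_D, 0); expect_lte(bt$p_D, 1)
  # determinism
  bt2 <- background_similarity_test(pA, 60,
                                    mask_background(sc$background_B,
                                                    sc$env$header),
                                    sc$env, act, n_reps = 8, seed = 20,
                                    background_n = 500)
  expect_identical(bt$null_D, bt2$null_D)
})

test_that("multivariate test: identical inputs give zero actual differences", {
  sc <- gen_scenario(scenario_config(
    seed = 12, header = grid_header(45, 40, -100, 42, 0.25),
    n_occ_A = 60, n_occ_B = 60,
    background_A = region_circles(-96, 45, 250),
    background_B = region_circles(-93.5, 45, 250)))
  bg <- mask_background(sc$background_A, sc$env$header)
  mv <- multivariate_divergence_test(sc$env, sc$occ_A, sc$occ_A, bg, bg,
                                     n_bg = 150, n_reps = 10, seed = 13)
  ret <- mv$table$retained
  expect_true(all(mv$table$d_actual[ret] < 1e-12))
  expect_false(any(mv$table$verdict[ret] == "divergence"))
  # variance fractions sum to one; retention follows the threshold
  expect_equal(sum(mv$table$var_frac), 1, tolerance = 1e-9)
  expect_identical(mv$table$retained, mv$table$var_frac >= 0.06)
})

test_that("correlation-matrix PCA is invariant to affine layer rescaling", {
  sc <- gen_scenario(scenario_config(
    seed = 14, header = grid_header(45, 40, -100, 42, 0.25),
    n_occ_A = 60, n_occ_B = 60,
    background_A = region_circles(-96, 45, 250),
    background_B = region_circles(-93.5, 45, 250)))
  bgA <- mask_background(sc$background_A, sc$env$header)
  bgB <- mask_background(sc$background_B, sc$env$header)
  mv1 <- multivariate_divergence_test(sc$env, sc$occ_A, sc$occ_B, bgA, bgB,
                                      n_bg = 150, n_reps = 10, seed = 15)
  scaled <- sc$env
  scaled$layers$env_2 <- new_grid(sc$env$header,
                                  100 * sc$env$layers$env_2$values + 7)
  mv2 <- multivariate_divergence_test(scaled, sc$occ_A, sc$occ_B, bgA, bgB,
                                      n_bg = 150, n_reps = 10, seed = 15)
  expect_equal(mv2$table$var_frac, mv1$table$var_frac, tolerance = 1e-9)
  expect_equal(mv2$table$d_actual, mv1$table$d_actual, tolerance = 1e-9)
  expect_identical(mv2$table$verdict, mv1$table$verdict)
})

test_that("a constant layer is a named PCA degeneracy error", {
  h <- grid_header(20, 20, 0, 40, 0.5)
  set.seed(1)
  st <- layer_stack(list(ok = new_grid(h, matrix(rnorm(400), 20, 20)),
                         flat = new_grid(h, matrix(3, 20, 20))))
  suit <- true_suitability(st, niche_params(c(0, 3), weights = c(1, 0)))
  occ <- sample_occurrences(suit, 30, seed = 2)
  bg <- mask_background(matrix(TRUE, 20, 20), h)
  expect_error(multivariate_divergence_test(st, occ, occ, bg, bg,
                                            n_bg = 50, n_reps = 5, seed = 3),
               "flat")
})

test_that("minimum-training-presence backgrounds derive from the model threshold", {
  st <- layer_stack(list(x = new_grid(grid_header(8, 8, 0, 0, 1),
                                      matrix(seq(-2, 2, length.out = 64),
                                             8, 8))))
  ctr <- cell_center(rep(1:4, 2), rep(7:8, each = 4), st$header)
  occ <- occurrence_set("sp", ctr$lon, ctr$lat)
  m <- fit_maxent(st, occ, seed = 2, background_n = 64)
  bg <- mtp_background(m, occ)
  mtp <- min_training_presence(m, occ)
  expect_identical(bg$mask, mtp$mask$values == 1 & mtp$mask$mask)
  expect_equal(bg$threshold, mtp$threshold)
})
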