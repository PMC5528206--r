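# toy fitting problems ------------------------------------------------------

toy_1layer <- function(nrows = 4, ncols = 5, seed = 21) {
  h <- grid_header(ncols, nrows, 0, 0, 1)
  set.seed(seed)
  layer_stack(list(x = new_grid(h, matrix(rnorm(nrows * ncols), nrows,
                                          ncols))))
}

occ_at_cells <- function(stack, rows, cols, species = "toy") {
  ctr <- cell_center(rows, cols, stack$header)
  occurrence_set(species, ctr$lon, ctr$lat)
}

test_that("infinite regularization collapses to the uniform surface", {
  st <- toy_1layer()
  occ <- occ_at_cells(st, c(1, 1, 2, 3, 4), c(1, 3, 2, 4, 5))
  m <- fit_maxent(st, occ, reg_lambda = 1e6, seed = 1, background_n = 20)
  N <- sum(st$mask)
  expect_equal(max(abs(m$raw_surface$values[st$mask] - 1 / N)), 0,
               tolerance = 1e-9)
})

test_that("presences at high layer values yield a positive linear weight", {
  h <- grid_header(10, 10, 0, 0, 1)
  st <- layer_stack(list(x = new_grid(h, matrix(seq(-2, 2, length.out = 100),
                                                10, 10))))
  occ <- occ_at_cells(st, rep(1:5, 2), rep(9:10, each = 5))  # high-x cells
  m <- fit_maxent(st, occ, seed = 2, background_n = 100)
  expect_gt(m$weights["x"], 0)
})

test_that("the penalized likelihood trace is non-decreasing", {
  st <- toy_1layer(6, 6, seed = 9)
  occ <- occ_at_cells(st, c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  m <- fit_maxent(st, occ, seed = 3, background_n = 36)
  expect_true(all(diff(m$objective_trace) >= -1e-12))
  expect_true(m$converged)
})

test_that("fitted weights match a dense grid-search maximizer of the same objective", {
  st <- toy_1layer(4, 5, seed = 21)            # 20 cells
  occ <- occ_at_cells(st, c(1, 1, 2, 2, 3, 3, 4, 4), c(1, 3, 2, 4, 1, 5, 3, 5))
  lambda <- 0.05
  m <- fit_maxent(st, occ, reg_lambda = lambda, seed = 4, background_n = 20,
                  tol = 1e-9)
  # identical features, by construction of the model's stored constants
  fx <- m$features$layers[[1]]
  z_of <- function(cells) (st$layers$x$values[cells] - fx$mean) / fx$sd
  ref <- sort(unique(c(m$background_cells, m$presence_cells)))
  Fr <- cbind(z_of(ref), z_of(ref)^2)
  Fp <- cbind(z_of(m$presence_cells), z_of(m$presence_cells)^2)
  np <- length(m$presence_cells)
  pen_ll <- function(w1, w2) {
    # vectorized over a grid of weight pairs
    eta <- Fr %*% rbind(w1, w2)
    M <- apply(eta, 2, max)
    lse <- M + log(colSums(exp(sweep(eta, 2, M))))
    colSums(Fp %*% rbind(w1, w2)) - np * lse -
      lambda * (abs(w1) + abs(w2))
  }
  centre <- c(0, 0); half <- 4
  for (level in 1:3) {
    g1 <- seq(centre[1] - half, centre[1] + half, length.out = 81)
    g2 <- seq(centre[2] - half, centre[2] + half, length.out = 81)
    gr <- expand.grid(w1 = g1, w2 = g2)
    best <- which.max(pen_ll(gr$w1, gr$w2))
    centre <- c(gr$w1[best], gr$w2[best])
    half <- half / 20
  }
  expect_lt(max(abs(unname(m$weights) - centre)), 1e-3)
})

test_that("degenerate presence data is rejected", {
  h <- grid_header(5, 4, 0, 0, 1)
  st <- layer_stack(list(flat = new_grid(h, matrix(7, 4, 5))))
  occ <- occ_at_cells(st, c(1, 2, 3, 4, 1), c(1, 2, 3, 4, 5))
  expect_error(fit_maxent(st, occ, seed = 1), "degenerate")
  expect_error(fit_maxent(st, occ_at_cells(st, 1:2, 1:2), seed = 1),
               ">= 5 distinct")
})

test_that("the raw surface is invariant to affine rescaling of an input layer", {
  st <- toy_1layer(8, 8, seed = 33)
  occ <- occ_at_cells(st, c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 8))
  m1 <- fit_maxent(st, occ, seed = 7, background_n = 64)
  st2 <- layer_stack(list(x = new_grid(st$header,
                                       3.5 * st$layers$x$values - 11)))
  m2 <- fit_maxent(st2, occ, seed = 7, background_n = 64)
  expect_equal(m1$raw_surface$values[st$mask],
               m2$raw_surface$values[st$mask], tolerance = 1e-6)
})

test_that("AUC follows the Mann-Whitney formulation", {
  expect_equal(auc_mw(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_mw(c(1, 1), c(1, 1)), 0.5)
  # hand enumeration: pairs 3>2, 3>0, 1>0 of 4
  expect_equal(auc_mw(c(3, 1), c(2, 0)), 0.75)
  expect_error(auc_mw(numeric(0), 1), "non-empty")
})

test_that("replicated fits are deterministic and the mean surface sums to one", {
  sc <- gen_scenario(scenario_config(
    seed = 3, header = grid_header(45, 40, -100, 42, 0.25),
    n_occ_A = 60, n_occ_B = 60,
    background_A = region_circles(-96, 45, 250),
    background_B = region_circles(-93.5, 45, 250)))
  r1 <- replicate_maxent(sc$env, sc$occ_A, n_replicates = 3, seed = 11,
                         background_n = 500)
  r2 <- replicate_maxent(sc$env, sc$occ_A, n_replicates = 3, seed = 11,
                         background_n = 500)
  expect_identical(r1$evaluation$auc_test_reps, r2$evaluation$auc_test_reps)
  expect_equal(sum(r1$mean_surface$values[sc$env$mask]), 1,
               tolerance = 1e-9)
  expect_equal(length(r1$evaluation$auc_test_reps), 3)
  # train_fraction = 1, one replicate: mean surface equals the single fit
  rf <- replicate_maxent(sc$env, sc$occ_A, n_replicates = 1,
                         train_fraction = 1, seed = 11, background_n = 500)
  single <- fit_maxent(sc$env, sc$occ_A, seed = 12, background_n = 500)
  expect_equal(rf$mean_surface$values, single$raw_surface$values,
               tolerance = 1e-9)
  expect_true(is.na(rf$evaluation$auc_test))
  # tiny sets cannot be split
  tiny <- occ_at_cells(sc$env, 1:2, 1:2)
  expect_error(replicate_maxent(sc$env, tiny, n_replicates = 2, seed = 1),
               "split error")
})

test_that("jackknife contributions sum to 100 and redundant layers drop nothing", {
  h <- grid_header(20, 20, 0, 0, 1)
  set.seed(17)
  x <- matrix(rnorm(400), 20, 20)
  st <- layer_stack(list(a = new_grid(h, x), a_copy = new_grid(h, x),
                         b = new_grid(h, matrix(rnorm(400), 20, 20))))
  suit <- true_suitability(st[c("a", "b")],
                           niche_params(c(1.2, 0), weights = c(1, 0)))
  occ <- sample_occurrences(suit, 40, seed = 5)
  jk <- jackknife_contributions(st, occ, seed = 6, background_n = 400)
  expect_equal(sum(jk$percent_contribution), 100, tolerance = 1e-6)
  expect_true(all(jk$percent_contribution >= 0))
  # removing either duplicate is compensated by the other
  expect_lt(max(abs(jk$auc_drop[jk$layer %in% c("a", "a_copy")])), 0.03)
})

test_that("minimum training presence contains every training presence", {
  st <- toy_1layer(8, 8, seed = 41)
  occ <- occ_at_cells(st, c(1, 3, 5, 7, 2, 4), c(2, 4, 6, 8, 7, 1))
  m <- fit_maxent(st, occ, seed = 8, background_n = 64)
  mtp <- min_training_presence(m, occ)
  rc <- cell_of(occ$records$lon, occ$records$lat, st$header)
  idx <- rc$row + (rc$col - 1) * st$header$nrows
  expect_true(all(mtp$mask$values[idx] == 1))
  # the threshold is the brute-force minimum over presence cells
  expect_equal(mtp$threshold, min(m$logistic_surface$values[idx]))
  # a single presence at the global maximum isolates the argmax cells
  top <- which(m$logistic_surface$values ==
                 max(m$logistic_surface$values[st$mask]))[1]
  r <- ((top - 1) %% st$header$nrows) + 1
  c <- ((top - 1) %/% st$header$nrows) + 1
  mtp1 <- min_training_presence(m, occ_at_cells(st, r, c))
  expect_equal(which(mtp1$mask$values == 1),
               which(m$logistic_surface$values ==
                       max(m$logistic_surface$values[st$mask])))
})

test_that("thresholding matches a brute-force count", {
  g <- random_masked_grid(seed = 10)
  expect_equal(sum(threshold_surface(g, min(g$values[g$mask]))$values[g$mask]),
               sum(g$mask))
  expect_equal(sum(threshold_surface(g, max(g$values[g$mask]) +
                                       1)$values[g$mask]), 0)
  t <- stats::median(g$values[g$mask])
  expect_equal(sum(threshold_surface(g, t)$values[g$mask]),
               sum(g$values[g$mask] >= t))
})

test_that("model-set comparison reproduces a hand-computed ANOVA", {
  cmp <- compare_model_sets(list(low = c(1, 2, 3), high = c(4, 5, 6)))
  expect_equal(cmp$anova$F, 13.5)
  expect_equal(cmp$anova$df_between, 1)
  expect_equal(cmp$anova$df_within, 4)
  # shifting every value leaves F unchanged
  cmp2 <- compare_model_sets(list(low = c(1, 2, 3) + 10,
                                  high = c(4, 5, 6) + 10))
  expect_equal(cmp2$anova$F, cmp$anova$F)
  # identical groups: F = 0, no significant pair
  same <- compare_model_sets(list(a = c(0.8, 0.9, 0.85),
                                  b = c(0.8, 0.9, 0.85)))
  expect_equal(same$anova$F, 0)
  expect_true(all(same$tukey$`p adj` > 0.99))
  expect_error(compare_model_sets(list(a = c(1, 1), b = c(2, 2))),
               "degenerate")
  expect_error(compare_model_sets(list(a = c(1, 2))), ">= 2 model sets")
})
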