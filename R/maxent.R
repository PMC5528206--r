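# Presence-only maximum-entropy suitability model.
#
# The model is the Gibbs distribution p(cell) = exp(w . f(cell)) / Z over a
# reference set of background + presence cells, fitted by maximizing the
# L1-penalized presence log-likelihood
#     sum_presences log p(cell) - lambda * sum_j |w_j| .
# Features are linear + quadratic terms of each continuous layer
# (standardized on the training background cells) and a single indicator
# for each binary (0/1) layer. The optimizer is a monotone accelerated
# proximal-gradient scheme with backtracking, so the penalized likelihood
# is non-decreasing across iterations by construction.

# ---- feature expansion -----------------------------------------------------

# Decide per-layer feature classes and standardization constants from the
# training background cells only (so the fitted surface is invariant to
# affine rescaling of any continuous input layer).
feature_spec <- function(stack, bg_cells) {
  spec <- lapply(stack$names, function(nm) {
    v <- stack$layers[[nm]]$values
    vv <- v[stack$mask]
    if (all(vv %in% c(0, 1))) {
      list(layer = nm, type = "binary", mean = 0, sd = 1,
           features = nm)
    } else {
      m <- mean(v[bg_cells]); s <- stats::sd(v[bg_cells])
      if (!is.finite(s) || s == 0) s <- 1  # constant layer: inert feature
      list(layer = nm, type = "continuous", mean = m, sd = s,
           features = paste0(nm, c("", "^2")))
    }
  })
  names(spec) <- stack$names
  structure(list(layers = spec,
                 feature_names = unlist(lapply(spec, `[[`, "features"),
                                        use.names = FALSE)),
            class = "feature_spec")
}

feature_matrix <- function(fx, stack, cells) {
  cols <- vector("list", 0)
  for (sp in fx$layers) {
    x <- stack$layers[[sp$layer]]$values[cells]
    if (sp$type == "binary") {
      cols[[length(cols) + 1]] <- x
    } else {
      z <- (x - sp$mean) / sp$sd
      cols[[length(cols) + 1]] <- z
      cols[[length(cols) + 1]] <- z^2
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- fx$feature_names
  F
}

# ---- optimizer -------------------------------------------------------------

# Minimize g(w) + lambda_s * ||w||_1 with
#   g(w) = logsumexp(F_ref w) - mean_f . w
# (the negative presence log-likelihood divided by the number of presence
# cells). Monotone FISTA: an accelerated step is accepted only if it does
# not increase the penalized objective, otherwise a plain backtracked
# proximal step from the current iterate is taken.
fit_weights_l1 <- function(F_ref, mean_f, lambda_s, max_iter = 1000,
                           tol = 1e-6) {
  p <- ncol(F_ref)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  gval <- function(w) {
    eta <- drop(F_ref %*% w); M <- max(eta)
    M + log(sum(exp(eta - M))) - sum(mean_f * w)
  }
  ggrad <- function(w) {
    eta <- drop(F_ref %*% w); M <- max(eta)
    q <- exp(eta - M); q <- q / sum(q)
    drop(crossprod(F_ref, q)) - mean_f
  }
  pen <- function(w) gval(w) + lambda_s * sum(abs(w))
  # backtracked proximal step from y; returns list(w, t)
  prox_step <- function(y, gy, grad_y, t) {
    repeat {
      w_new <- soft(y - t * grad_y, t * lambda_s)
      d <- w_new - y
      if (gval(w_new) <= gy + sum(grad_y * d) + sum(d * d) / (2 * t) + 1e-15)
        return(list(w = w_new, t = t))
      t <- t / 2
      if (t < 1e-14) return(list(w = y, t = t))
    }
  }
  w <- rep(0, p); w_prev <- w
  t_step <- 1
  obj <- pen(w)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    beta <- (it - 1) / (it + 2)
    y <- w + beta * (w - w_prev)
    st <- prox_step(y, gval(y), ggrad(y), t_step)
    obj_new <- pen(st$w)
    if (obj_new > obj) {     # momentum overshoot: fall back to plain step
      st <- prox_step(w, gval(w), ggrad(w), t_step)
      obj_new <- pen(st$w)
    }
    t_step <- st$t * 1.25
    w_prev <- w
    if (obj_new <= obj) { w <- st$w; obj <- obj_new }
    trace <- c(trace, obj)
    if (it %% 5 == 0 || it == max_iter) {
      gr <- ggrad(w)
      kkt <- ifelse(w != 0, abs(gr + lambda_s * sign(w)),
                    pmax(abs(gr) - lambda_s, 0))
      if (max(kkt) < tol) { converged <- TRUE; break }
    }
  }
  list(weights = w, objective_trace = trace, converged = converged,
       n_iter = length(trace) - 1)
}

# ---- model fitting ---------------------------------------------------------

#' Fit a maximum-entropy suitability model
#'
#' Fits the Gibbs model described in the package vignette to presence-only
#' occurrences over a uniformly sampled background, producing a raw
#' (sum-to-one over valid cells) suitability surface and a logistic-scaled
#' surface `raw * N / (1 + raw * N)` with `N` the number of valid cells
#' (cell-count calibration: a cell at the uniform baseline `1/N` scores 0.5).
#'
#' @param stack Predictor [layer_stack()].
#' @param occ An [occurrence_set()]; at least 5 distinct valid presence
#'   cells are required.
#' @param reg_lambda Non-negative L1 penalty on the summed presence
#'   log-likelihood; default `0.1 * sqrt(n_features / n_presence_cells)`.
#' @param seed Integer seed for the background sample.
#' @param background_n Background cells drawn uniformly from valid cells
#'   (capped at the number of valid cells).
#' @param max_iter,tol Optimizer iteration cap and KKT tolerance (infinity
#'   norm of the per-presence-scaled subgradient).
#' @return Object of class `maxent_model` with elements `weights`,
#'   `features`, `reg_lambda`, `raw_surface`, `logistic_surface`,
#'   `presence_cells`, `background_cells`, `objective_trace` (penalized
#'   likelihood per accepted iterate, non-decreasing), `converged`, `seed`.
#' @export
fit_maxent <- function(stack, occ, reg_lambda = NULL, seed = 1,
                       background_n = 10000, max_iter = 1000, tol = 1e-6) {
  stopifnot(inherits(stack, "layer_stack"), inherits(occ, "occurrence_set"))
  valid <- which(stack$mask)
  rc <- cell_of(occ$records$lon, occ$records$lat, stack$header)
  inb <- !is.na(rc$row)
  idx <- cell_linear(rc$row[inb], rc$col[inb], stack$header)
  pres <- unique(idx[stack$mask[idx]])
  if (length(pres) < 5)
    stop("need >= 5 distinct valid presence cells, got ", length(pres))
  set.seed(seed)
  bg <- sample(valid, min(background_n, length(valid)))
  fx <- feature_spec(stack, bg)
  ref <- unique(c(bg, pres))
  F_ref <- feature_matrix(fx, stack, ref)
  F_pres <- feature_matrix(fx, stack, pres)
  if (nrow(unique(F_pres)) == 1)
    stop("degenerate data: all presence cells have identical features")
  n_feat <- ncol(F_ref)
  if (is.null(reg_lambda))
    reg_lambda <- 0.1 * sqrt(n_feat / length(pres))
  if (reg_lambda < 0) stop("reg_lambda must be non-negative")
  fit <- fit_weights_l1(F_ref, colMeans(F_pres),
                        lambda_s = reg_lambda / length(pres),
                        max_iter = max_iter, tol = tol)
  if (!fit$converged)
    stop(sprintf(paste0("fitting error: no convergence after %d iterations ",
                        "(final objective %.6g)"),
                 fit$n_iter, fit$objective_trace[length(fit$objective_trace)]))
  # surfaces over all valid cells
  F_all <- feature_matrix(fx, stack, valid)
  eta <- drop(F_all %*% fit$weights)
  eta <- eta - max(eta)
  p <- exp(eta); p <- p / sum(p)
  h <- stack$header
  raw <- matrix(h$nodata_value, h$nrows, h$ncols)
  raw[valid] <- p
  N <- length(valid)
  lgs <- matrix(h$nodata_value, h$nrows, h$ncols)
  lgs[valid] <- p * N / (1 + p * N)
  structure(list(weights = stats::setNames(fit$weights, fx$feature_names),
                 features = fx, reg_lambda = reg_lambda,
                 raw_surface = new_grid(h, raw, stack$mask),
                 logistic_surface = new_grid(h, lgs, stack$mask),
                 presence_cells = pres, background_cells = bg,
                 objective_trace = -fit$objective_trace,
                 converged = fit$converged, n_iter = fit$n_iter,
                 seed = seed),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d features, lambda = %.4g, ",
                     "%d presence cells, converged in %d iterations\n"),
              length(x$weights), x$reg_lambda, length(x$presence_cells),
              x$n_iter))
  invisible(x)
}

#' Presence-background AUC (Mann-Whitney form)
#'
#' The probability that a random presence value exceeds a random background
#' value, ties counted half: `(#(p > b) + 0.5 #(p = b)) / (n_p n_b)`.
#'
#' @param presence,background Non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(presence, background) {
  np <- length(presence); nb <- length(background)
  if (np < 1 || nb < 1) stop("both score vectors must be non-empty")
  r <- rank(c(presence, background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

# internal: AUC of a fitted model on a set of presence cells
model_auc <- function(model, cells) {
  v <- model$raw_surface$values
  auc_mw(v[cells], v[model$background_cells])
}

occ_cells <- function(occ, stack) {
  rc <- cell_of(occ$records$lon, occ$records$lat, stack$header)
  inb <- !is.na(rc$row)
  idx <- cell_linear(rc$row[inb], rc$col[inb], stack$header)
  idx[stack$mask[idx]]
}

#' Replicated model fitting and evaluation
#'
#' Per replicate, the occurrence records are split into a seeded
#' train/test partition (75/25 by default), the model is fitted on the
#' training part, and test AUC is computed against the model's background
#' sample. The mean surface is the arithmetic mean of the per-replicate raw
#' surfaces, renormalized to sum to 1.
#'
#' @inheritParams fit_maxent
#' @param n_replicates Number of replicates (>= 1; 25 is the conventional
#'   minimum for reporting).
#' @param train_fraction Fraction of records used for calibration; with
#'   `train_fraction = 1` no test AUC is computed.
#' @return List with `mean_surface` (sum-to-one `enm_grid`) and
#'   `evaluation` (class `model_evaluation`: mean and per-replicate train
#'   and test AUC, replicate count, train fraction, seed).
#' @export
replicate_maxent <- function(stack, occ, n_replicates = 25,
                             train_fraction = 0.75, seed = 1,
                             reg_lambda = NULL, background_n = 10000) {
  stopifnot(n_replicates >= 1, train_fraction > 0, train_fraction <= 1)
  n <- n_occurrences(occ)
  n_train <- max(1L, round(train_fraction * n))
  if (train_fraction < 1 && n_train >= n)
    stop("split error: empty test partition (too few records)")
  auc_tr <- auc_te <- numeric(n_replicates)
  acc <- NULL
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r
    set.seed(rep_seed)
    tr <- sample.int(n, n_train)
    m <- fit_maxent(stack, subset_occurrences(occ, tr),
                    reg_lambda = reg_lambda, seed = rep_seed,
                    background_n = background_n)
    auc_tr[r] <- model_auc(m, occ_cells(subset_occurrences(occ, tr), stack))
    auc_te[r] <- if (n_train < n)
      model_auc(m, occ_cells(subset_occurrences(occ, -tr), stack))
    else NA_real_
    v <- m$raw_surface$values
    v[!stack$mask] <- 0
    acc <- if (is.null(acc)) v else acc + v
  }
  acc <- acc / sum(acc[stack$mask])
  acc[!stack$mask] <- stack$header$nodata_value
  ev <- structure(list(auc_train = mean(auc_tr), auc_test = mean(auc_te),
                       auc_train_reps = auc_tr, auc_test_reps = auc_te,
                       n_replicates = n_replicates,
                       train_fraction = train_fraction, seed = seed),
                  class = "model_evaluation")
  list(mean_surface = new_grid(stack$header, acc, stack$mask),
       evaluation = ev)
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<model_evaluation> %d replicates (train fraction ",
                     "%.2f): AUC_train = %.3f, AUC_test = %.3f\n"),
              x$n_replicates, x$train_fraction, x$auc_train, x$auc_test))
  invisible(x)
}

#' Jackknife variable contributions
#'
#' For each layer, the model is refitted without that layer on the same
#' seeded train/test split and the drop in test AUC relative to the full
#' model is recorded. Percent contributions are the drops clipped at zero
#' and normalized to sum to 100; if every drop is zero (fully redundant
#' predictors) contributions are uniform and the result is flagged.
#'
#' @inheritParams fit_maxent
#' @param train_fraction Train fraction for the single evaluation split.
#' @return Data frame (`layer`, `auc_drop`, `percent_contribution`) with
#'   attributes `auc_full` and `all_zero`.
#' @export
jackknife_contributions <- function(stack, occ, seed = 1,
                                    train_fraction = 0.75,
                                    reg_lambda = NULL, background_n = 10000) {
  if (length(stack$layers) < 2) stop("need >= 2 layers for a jackknife")
  n <- n_occurrences(occ)
  n_train <- max(1L, round(train_fraction * n))
  if (n_train >= n) stop("split error: empty test partition")
  set.seed(seed)
  tr <- sample.int(n, n_train)
  occ_tr <- subset_occurrences(occ, tr)
  test_cells <- function(st) occ_cells(subset_occurrences(occ, -tr), st)
  full <- fit_maxent(stack, occ_tr, reg_lambda = reg_lambda, seed = seed,
                     background_n = background_n)
  auc_full <- model_auc(full, test_cells(stack))
  drops <- vapply(seq_along(stack$layers), function(i) {
    st <- stack[-i]
    m <- fit_maxent(st, occ_tr, reg_lambda = reg_lambda, seed = seed,
                    background_n = background_n)
    auc_full - model_auc(m, test_cells(st))
  }, numeric(1))
  pos <- pmax(drops, 0)
  all_zero <- all(pos == 0)
  pct <- if (all_zero) rep(100 / length(pos), length(pos)) else
    100 * pos / sum(pos)
  out <- data.frame(layer = stack$names, auc_drop = drops,
                    percent_contribution = pct)
  attr(out, "auc_full") <- auc_full
  attr(out, "all_zero") <- all_zero
  out
}

#' Minimum training presence threshold
#'
#' The lowest logistic suitability at any training presence cell; cells at
#' or above it form the smallest thresholded surface containing all
#' training presences, a standard delineation of a species' accessible
#' area.
#'
#' @param model A fitted `maxent_model`.
#' @param training_occ The training [occurrence_set()] (all records must be
#'   on valid cells of the model surface).
#' @return List with `threshold` and `mask` (binary `enm_grid`).
#' @export
min_training_presence <- function(model, training_occ) {
  stopifnot(inherits(model, "maxent_model"))
  g <- model$logistic_surface
  rc <- cell_of(training_occ$records$lon, training_occ$records$lat, g$header)
  if (anyNA(rc$row)) stop("training occurrences outside the grid extent")
  idx <- cell_linear(rc$row, rc$col, g$header)
  if (!all(g$mask[idx])) stop("training occurrences on masked cells")
  thr <- min(g$values[idx])
  list(threshold = thr, mask = threshold_surface(g, thr))
}

#' Threshold a surface to a binary grid
#'
#' @param grid An `enm_grid`.
#' @param t Threshold; cells with `value >= t` become 1, others 0 (the 0.2
#'   logistic threshold is a common presentation choice for range maps).
#' @return Binary `enm_grid` (same mask).
#' @export
threshold_surface <- function(grid, t = 0.2) {
  stopifnot(inherits(grid, "enm_grid"))
  v <- ifelse(grid$values >= t, 1, 0)
  v[!grid$mask] <- grid$header$nodata_value
  new_grid(grid$header, v, grid$mask)
}

#' Compare model variable sets by test AUC
#'
#' One-way fixed-effects ANOVA on per-replicate test AUC across model sets,
#' followed by Tukey's HSD post-hoc pairwise comparisons.
#'
#' @param evaluations Named list: one numeric vector of per-replicate test
#'   AUC per model set (each length >= 2), or a list of `model_evaluation`
#'   objects.
#' @return Object of class `model_set_comparison`: list with `anova`
#'   (data frame: F, df, p), `tukey` (pairwise table), `group_means`.
#' @export
compare_model_sets <- function(evaluations) {
  vals <- lapply(evaluations, function(e)
    if (inherits(e, "model_evaluation")) e$auc_test_reps else as.numeric(e))
  if (length(vals) < 2) stop("need >= 2 model sets")
  if (any(vapply(vals, length, 1L) < 2)) stop("each set needs >= 2 replicates")
  if (all(vapply(vals, stats::var, 1) == 0))
    stop("degenerate error: zero within-group variance in all groups")
  df <- data.frame(auc = unlist(vals),
                   set = factor(rep(names(vals), lengths(vals))))
  fit <- stats::aov(auc ~ set, data = df)
  s <- summary(fit)[[1]]
  anova_tab <- data.frame(F = s[1, "F value"], df_between = s[1, "Df"],
                          df_within = s[2, "Df"], p = s[1, "Pr(>F)"])
  tukey <- as.data.frame(stats::TukeyHSD(fit)$set)
  tukey$pair <- rownames(tukey); rownames(tukey) <- NULL
  structure(list(anova = anova_tab, tukey = tukey,
                 group_means = vapply(vals, mean, 1)),
            class = "model_set_comparison")
}

#' @export
print.model_set_comparison <- function(x, ...) {
  cat(sprintf("<model_set_comparison> F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  means <- sprintf("%s = %.3f", names(x$group_means), x$group_means)
  cat("  group means:", paste(means, collapse = ", "), "\n")
  invisible(x)
}
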