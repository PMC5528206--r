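# Inferential tests for niche divergence vs conservatism:
#  (1) the background-similarity test — observed overlap between two
#      species' actual niche models compared against a resampling null of
#      overlaps between one species' actual model and models fitted to
#      random points from the other species' background; and
#  (2) the multivariate test — per-PC differences of actual niche means
#      compared against replicate differences of background niche means.

#' Distance-buffer background
#'
#' The accessible area delineated as all cells whose center lies within
#' `radius_km` (great circle) of at least one occurrence; cells containing
#' occurrences are always included (so radius 0 gives exactly the occupied
#' cells).
#'
#' @param occ A non-empty [occurrence_set()].
#' @param radius_km Buffer radius in km (dispersal-scale choices such as
#'   200 and 700 km are typical).
#' @param header Grid geometry.
#' @param base_mask Optional logical matrix intersected with the buffer
#'   (e.g. a stack's joint validity mask).
#' @return Object of class `background_spec` (kind `"buffer"`).
#' @export
buffer_background <- function(occ, radius_km, header, base_mask = NULL) {
  stopifnot(inherits(occ, "occurrence_set"), n_occurrences(occ) > 0)
  rc <- expand.grid(row = seq_len(header$nrows), col = seq_len(header$ncols))
  ctr <- cell_center(rc$row, rc$col, header)
  lon <- occ$records$lon; lat <- occ$records$lat
  mind <- rep(Inf, nrow(rc))
  for (i in seq_along(lon))
    mind <- pmin(mind, haversine_km(ctr$lon, ctr$lat, lon[i], lat[i]))
  mask <- matrix(mind <= radius_km, header$nrows, header$ncols)
  occ_rc <- cell_of(lon, lat, header)
  inb <- !is.na(occ_rc$row)
  mask[cell_linear(occ_rc$row[inb], occ_rc$col[inb], header)] <- TRUE
  if (!is.null(base_mask)) mask <- mask & base_mask
  structure(list(kind = "buffer", radius_km = radius_km, mask = mask,
                 header = header),
            class = "background_spec")
}

#' Minimum-training-presence background
#'
#' The accessible area delineated by thresholding a fitted model's logistic
#' surface at its minimum training presence (see
#' [min_training_presence()]).
#'
#' @param model A fitted `maxent_model`.
#' @param training_occ The model's training occurrences.
#' @return Object of class `background_spec` (kind `"mtp"`).
#' @export
mtp_background <- function(model, training_occ) {
  mtp <- min_training_presence(model, training_occ)
  mask <- mtp$mask$values == 1 & mtp$mask$mask
  structure(list(kind = "mtp", threshold = mtp$threshold, mask = mask,
                 header = model$logistic_surface$header),
            class = "background_spec")
}

#' Background from an explicit mask
#'
#' @param mask Logical matrix (`TRUE` = accessible).
#' @param header Grid geometry.
#' @return Object of class `background_spec` (kind `"mask"`).
#' @export
mask_background <- function(mask, header) {
  stopifnot(is.logical(mask), nrow(mask) == header$nrows,
            ncol(mask) == header$ncols)
  structure(list(kind = "mask", mask = mask, header = header),
            class = "background_spec")
}

#' @export
print.background_spec <- function(x, ...) {
  extra <- switch(x$kind, buffer = sprintf(" (radius %g km)", x$radius_km),
                  mtp = sprintf(" (threshold %.4f)", x$threshold), "")
  cat(sprintf("<background_spec> kind = %s%s, %d cells\n", x$kind, extra,
              sum(x$mask)))
  invisible(x)
}

#' Sample points from a background
#'
#' `n` distinct cells drawn uniformly without replacement from the
#' background's true cells; points are placed at cell centers.
#'
#' @param spec A `background_spec`.
#' @param n Number of points; must not exceed the number of true cells.
#' @param seed Integer seed.
#' @return Data frame with columns `lon`, `lat`.
#' @export
sample_background_points <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "background_spec"))
  cells <- which(spec$mask)
  if (length(cells) < n)
    stop(sprintf("sampling error: background has %d cells, need %d",
                 length(cells), n))
  set.seed(seed)
  idx <- if (length(cells) == 1) cells else sample(cells, n)
  h <- spec$header
  row <- ((idx - 1L) %% h$nrows) + 1L
  col <- ((idx - 1L) %/% h$nrows) + 1L
  cell_center(row, col, h)
}

#' Percentile or normal confidence interval of a null distribution
#'
#' @param null_values Numeric vector of null statistics.
#' @param alpha Two-sided level (default 0.05).
#' @param method `"percentile"` (linear-interpolation quantiles, the
#'   default decision rule) or `"normal"` (mean +/- z * sd, matching
#'   mean-plus-minus-sd reporting conventions).
#' @return Numeric length-2 vector (lower, upper).
#' @export
background_ci <- function(null_values, alpha = 0.05,
                          method = c("percentile", "normal")) {
  method <- match.arg(method)
  if (!length(null_values)) stop("null_values must be non-empty")
  if (method == "percentile") {
    unname(stats::quantile(null_values, c(alpha / 2, 1 - alpha / 2),
                           type = 7))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    mean(null_values) + c(-1, 1) * z * stats::sd(null_values)
  }
}

#' Verdict of a background-similarity comparison
#'
#' Divergence if the actual overlap falls below the null confidence
#' interval (actual niches less similar than background availability alone
#' predicts), conservatism if above it, otherwise the null of
#' background-driven differences is not rejected.
#'
#' @param actual Observed overlap statistic.
#' @param null_values Null overlap values (non-empty).
#' @param alpha Two-sided level.
#' @param method CI method, see [background_ci()].
#' @return One of `"divergence"`, `"conservatism"`, `"not_rejected"`.
#' @export
decide_background_verdict <- function(actual, null_values, alpha = 0.05,
                                      method = c("percentile", "normal")) {
  ci <- background_ci(null_values, alpha, method)
  if (actual < ci[1]) "divergence"
  else if (actual > ci[2]) "conservatism"
  else "not_rejected"
}

empirical_p <- function(actual, null_values) {
  lo <- mean(null_values <= actual)
  hi <- mean(null_values >= actual)
  min(1, 2 * min(lo, hi))
}

#' Background-similarity test
#'
#' Per replicate, `occ_count` points are drawn from the background of the
#' other species, a maximum-entropy model is fitted to a seeded 75%
#' calibration subset of them, and the D and I overlaps between that null
#' model's standardized surface and the focal species' actual surface are
#' recorded. After `n_reps` replicates the observed actual-vs-actual
#' overlaps are compared to the null distributions via
#' [decide_background_verdict()]. Replicate fit failures are retried with a
#' fresh draw (up to 3 attempts) and counted.
#'
#' @param actual_surface The focal species' actual model surface
#'   (sum-to-one, see [standardize_surface()]).
#' @param occ_count Number of points per null replicate (the occurrence
#'   count of the species whose background is resampled).
#' @param background A `background_spec` (the other species' accessible
#'   area).
#' @param stack Predictor [layer_stack()] used for the null models.
#' @param actual_overlap List with elements `D` and `I`: the observed
#'   overlap between the two species' actual surfaces (see
#'   [niche_overlap()]).
#' @param n_reps Number of null replicates (default 100).
#' @param seed Integer seed.
#' @param alpha Two-sided level for the verdict CI.
#' @param train_fraction Calibration fraction per replicate.
#' @param reg_lambda,background_n Passed to [fit_maxent()].
#' @param direction Optional label, e.g. `"A_actual vs B_background"`.
#' @param ci_method CI method for the verdict, see [background_ci()].
#' @return Object of class `background_similarity`: actual and null D / I,
#'   percentile and normal CIs, empirical two-sided p values, verdicts,
#'   failure count.
#' @export
background_similarity_test <- function(actual_surface, occ_count, background,
                                       stack, actual_overlap, n_reps = 100,
                                       seed = 1, alpha = 0.05,
                                       train_fraction = 0.75,
                                       reg_lambda = NULL, background_n = 1000,
                                       direction = NULL,
                                       ci_method = "percentile") {
  stopifnot(inherits(background, "background_spec"),
            inherits(stack, "layer_stack"),
            is.list(actual_overlap), !is.null(actual_overlap$D))
  null_D <- null_I <- numeric(n_reps)
  failures <- 0L
  for (r in seq_len(n_reps)) {
    done <- FALSE
    for (attempt in 1:3) {
      rep_seed <- seed + 1000L * r + attempt
      res <- tryCatch({
        pts <- sample_background_points(background, occ_count, rep_seed)
        bocc <- occurrence_set("background_replicate", pts$lon, pts$lat)
        set.seed(rep_seed + 7L)
        ntr <- max(5L, round(train_fraction * occ_count))
        tr <- sample.int(occ_count, min(ntr, occ_count))
        m <- fit_maxent(stack, subset_occurrences(bocc, tr),
                        reg_lambda = reg_lambda, seed = rep_seed,
                        background_n = background_n)
        p <- standardize_surface(m$raw_surface)
        list(D = schoener_D(actual_surface, p),
             I = hellinger_I(actual_surface, p))
      }, error = function(e) NULL)
      if (!is.null(res)) { done <- TRUE; break }
      failures <- failures + 1L
    }
    if (!done) stop("replicate ", r, " failed after 3 attempts")
    null_D[r] <- res$D; null_I[r] <- res$I
  }
  structure(list(
    direction = direction,
    actual_D = actual_overlap$D, actual_I = actual_overlap$I,
    null_D = null_D, null_I = null_I,
    ci_D = background_ci(null_D, alpha, ci_method),
    ci_I = background_ci(null_I, alpha, ci_method),
    ci_D_normal = background_ci(null_D, alpha, "normal"),
    ci_I_normal = background_ci(null_I, alpha, "normal"),
    p_D = empirical_p(actual_overlap$D, null_D),
    p_I = empirical_p(actual_overlap$I, null_I),
    verdict_D = decide_background_verdict(actual_overlap$D, null_D, alpha,
                                          ci_method),
    verdict_I = decide_background_verdict(actual_overlap$I, null_I, alpha,
                                          ci_method),
    n_reps = n_reps, failures = failures, alpha = alpha, seed = seed),
    class = "background_similarity")
}

#' @export
print.background_similarity <- function(x, ...) {
  cat(sprintf("<background_similarity>%s %d replicates\n",
              if (is.null(x$direction)) "" else paste0(" ", x$direction),
              x$n_reps))
  cat(sprintf("  D: actual %.3f vs null %.3f +/- %.3f -> %s (p = %.3g)\n",
              x$actual_D, mean(x$null_D), stats::sd(x$null_D), x$verdict_D,
              x$p_D))
  cat(sprintf("  I: actual %.3f vs null %.3f +/- %.3f -> %s (p = %.3g)\n",
              x$actual_I, mean(x$null_I), stats::sd(x$null_I), x$verdict_I,
              x$p_I))
  invisible(x)
}

#' Verdict of a multivariate (per-PC) comparison
#'
#' Divergence if the actual mean difference exceeds every replicate
#' background difference, conservatism if it is below every one, otherwise
#' inconclusive.
#'
#' @param d_actual Absolute difference of the species' actual niche means
#'   on a PC axis.
#' @param d_background Replicate background differences (non-empty vector,
#'   or a length-2 range `c(min, max)`).
#' @return One of `"divergence"`, `"conservatism"`, `"inconclusive"`.
#' @export
decide_mv_verdict <- function(d_actual, d_background) {
  if (!length(d_background)) stop("d_background must be non-empty")
  if (d_actual > max(d_background)) "divergence"
  else if (d_actual < min(d_background)) "conservatism"
  else "inconclusive"
}

#' Multivariate niche divergence test
#'
#' Environmental values are extracted at both species' occurrences and at
#' `n_bg` background points per species (sampled once, seeded). A single
#' correlation-matrix PCA is run on all four pooled row groups so actual
#' and background means live in one coordinate system. For each PC
#' explaining at least `min_var_frac` of the variance, the actual mean
#' difference `d_actual` is compared to the range of `d_background` over
#' `n_reps` replicates in which a `subsample` fraction of each background
#' sample is drawn.
#'
#' @param stack Environmental [layer_stack()].
#' @param occ_A,occ_B Occurrence sets.
#' @param bg_A,bg_B `background_spec`s for the two species.
#' @param n_bg Background points per species (default 1000).
#' @param min_var_frac Minimum explained-variance fraction for a PC to be
#'   analyzed (default 0.06).
#' @param n_reps Number of subsampling replicates (default 25).
#' @param subsample Fraction subsampled per replicate (default 0.75).
#' @param seed Integer seed.
#' @return Object of class `mv_divergence`: per-PC table (`pc`,
#'   `var_frac`, `retained`, `d_actual`, `d_bg_min`, `d_bg_max`,
#'   `verdict`), full loadings, group means on each PC.
#' @export
multivariate_divergence_test <- function(stack, occ_A, occ_B, bg_A, bg_B,
                                         n_bg = 1000, min_var_frac = 0.06,
                                         n_reps = 25, subsample = 0.75,
                                         seed = 1) {
  stopifnot(inherits(stack, "layer_stack"))
  pts_A <- sample_background_points(bg_A, n_bg, seed)
  pts_B <- sample_background_points(bg_B, n_bg, seed + 1L)
  grab <- function(lon, lat, what) {
    ex <- extract_values(stack, lon, lat)
    if (!all(ex$valid))
      stop("points with invalid layer values in ", what)
    as.matrix(ex[stack$names])
  }
  X <- rbind(grab(occ_A$records$lon, occ_A$records$lat, "occ_A"),
             grab(occ_B$records$lon, occ_B$records$lat, "occ_B"),
             grab(pts_A$lon, pts_A$lat, "background_A"),
             grab(pts_B$lon, pts_B$lat, "background_B"))
  grp <- rep(c("occ_A", "occ_B", "bg_A", "bg_B"),
             c(n_occurrences(occ_A), n_occurrences(occ_B), n_bg, n_bg))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("PCA degeneracy: constant layer(s) across all rows: ",
         paste(stack$names[sds == 0], collapse = ", "))
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  var_frac <- pca$sdev^2 / sum(pca$sdev^2)
  retained <- var_frac >= min_var_frac
  scores <- pca$x
  gmean <- function(g, pc) mean(scores[grp == g, pc])
  npc <- ncol(scores)
  d_actual <- d_bg_min <- d_bg_max <- rep(NA_real_, npc)
  verdict <- rep(NA_character_, npc)
  iA <- which(grp == "bg_A"); iB <- which(grp == "bg_B")
  n_sub <- max(2L, round(subsample * n_bg))
  for (pc in which(retained)) {
    d_actual[pc] <- abs(gmean("occ_A", pc) - gmean("occ_B", pc))
    d_bg <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(seed + 31L * pc + r)
      sA <- sample(iA, n_sub); sB <- sample(iB, n_sub)
      d_bg[r] <- abs(mean(scores[sA, pc]) - mean(scores[sB, pc]))
    }
    d_bg_min[pc] <- min(d_bg); d_bg_max[pc] <- max(d_bg)
    verdict[pc] <- decide_mv_verdict(d_actual[pc], d_bg)
  }
  tab <- data.frame(pc = paste0("PC", seq_len(npc)), var_frac = var_frac,
                    retained = retained, d_actual = d_actual,
                    d_bg_min = d_bg_min, d_bg_max = d_bg_max,
                    verdict = verdict)
  means <- sapply(c("occ_A", "occ_B", "bg_A", "bg_B"), function(g)
    colMeans(scores[grp == g, , drop = FALSE]))
  structure(list(table = tab, loadings = pca$rotation, var_frac = var_frac,
                 group_means = means, n_bg = n_bg,
                 min_var_frac = min_var_frac, n_reps = n_reps,
                 subsample = subsample, seed = seed),
            class = "mv_divergence")
}

#' @export
print.mv_divergence <- function(x, ...) {
  cat(sprintf("<mv_divergence> %d PCs, %d retained (>= %.0f%% variance)\n",
              nrow(x$table), sum(x$table$retained), 100 * x$min_var_frac))
  t <- x$table[x$table$retained, ]
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %s (%.1f%%): d_actual = %.3f, background %.3f-%.3f -> %s\n",
                t$pc[i], 100 * t$var_frac[i], t$d_actual[i], t$d_bg_min[i],
                t$d_bg_max[i], t$verdict[i]))
  invisible(x)
}
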