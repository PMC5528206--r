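# Synthetic landscapes: seeded spatially autocorrelated environmental
# layers, Gaussian (bell-curve) virtual-species niches, occurrence sampling
# and biotic (tree) suitability layers under planted conservatism or
# divergence. The simulator stands in for real bioclimatic rasters and
# compiled occurrence databases, with the advantage that the true niche of
# every species is known exactly.

#' Gaussian niche response parameters
#'
#' The virtual species' true suitability at a cell with (standardized)
#' environment `x` is `exp(-sum_k w_k (x_k - o_k)^2 / (2 b_k^2))`, rescaled
#' so its maximum over valid cells is 1. A shift of one optimum is then a
#' single-parameter notion of niche divergence.
#'
#' @param optima Numeric vector, one optimum per environmental layer
#'   (layer units; layers are standardized so these are roughly z-scores).
#' @param breadths Positive numeric vector, niche breadth per layer
#'   (same units).
#' @param weights Non-negative weights per layer; at least one positive.
#' @return Object of class `niche_params`.
#' @export
niche_params <- function(optima, breadths = rep(1, length(optima)),
                         weights = rep(1, length(optima))) {
  optima <- as.numeric(optima)
  breadths <- as.numeric(breadths); weights <- as.numeric(weights)
  if (length(breadths) != length(optima) || length(weights) != length(optima))
    stop("optima, breadths and weights must have equal length")
  if (any(breadths <= 0)) stop("breadths must be > 0")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative with at least one positive")
  structure(list(optima = optima, breadths = breadths, weights = weights),
            class = "niche_params")
}

identical_niche <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' Background region as a union of circles
#'
#' Accessible-area specification mirroring distance-buffer delineations:
#' a cell belongs to the region if its center lies within `radius_km`
#' (great circle) of any circle center.
#'
#' @param lon,lat Circle center coordinates (degrees), recycled together.
#' @param radius_km Circle radii in km.
#' @return Object of class `region_circles`.
#' @export
region_circles <- function(lon, lat, radius_km) {
  structure(data.frame(lon = lon, lat = lat, radius_km = radius_km),
            class = c("region_circles", "data.frame"))
}

#' Rasterize a region spec to a logical mask
#'
#' @param region A [region_circles()] object or a logical matrix already on
#'   the grid.
#' @param header Target [grid_header()].
#' @return Logical `nrows x ncols` matrix.
#' @export
region_mask <- function(region, header) {
  if (is.matrix(region) && is.logical(region)) {
    if (nrow(region) != header$nrows || ncol(region) != header$ncols)
      stop("mask dimensions do not match header")
    return(region)
  }
  stopifnot(inherits(region, "region_circles"))
  rc <- expand.grid(row = seq_len(header$nrows), col = seq_len(header$ncols))
  ctr <- cell_center(rc$row, rc$col, header)
  inside <- rep(FALSE, nrow(rc))
  for (i in seq_len(nrow(region))) {
    d <- haversine_km(ctr$lon, ctr$lat, region$lon[i], region$lat[i])
    inside <- inside | d <= region$radius_km[i]
  }
  matrix(inside, nrow = header$nrows, ncol = header$ncols)
}

#' Default simulated study extent
#'
#' A 50 x 70 grid of 0.25-degree cells (roughly 20-28 km at the grid's
#' latitudes) spanning 100-82.5 W, 42-54.5 N: a mid-latitude window large
#' enough to hold two partially overlapping accessible areas, at a
#' resolution scaled up from the ~5 km cells of continental analyses so the
#' whole pipeline runs at desk scale.
#'
#' @return A [grid_header()].
#' @export
default_grid_header <- function() {
  grid_header(ncols = 70, nrows = 50, xllcorner = -100, yllcorner = 42,
              cellsize = 0.25, nodata_value = -9999)
}

# Truncated-Gaussian smoothing of a matrix (separable, kernel sd = L,
# radius 3L), with edge renormalization so the field has no border fade.
smooth_field <- function(mat, L) {
  if (L <= 0) return(mat)
  radius <- ceiling(3 * L)
  k <- stats::dnorm(seq(-radius, radius), sd = L)
  conv_rows <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m)); wt <- matrix(0, n, ncol(m))
    for (s in -radius:radius) {
      lo <- max(1L, 1L - s); hi <- min(n, n - s)
      if (lo > hi) next
      w <- k[s + radius + 1L]
      out[lo:hi, ] <- out[lo:hi, ] + w * m[(lo:hi) + s, ]
      wt[lo:hi, ] <- wt[lo:hi, ] + w
    }
    out / wt
  }
  t(conv_rows(t(conv_rows(mat))))
}

standardize_matrix <- function(m, mask) {
  v <- m[mask]
  s <- stats::sd(v)
  if (s == 0) stop("cannot standardize a constant field")
  m[mask] <- (v - mean(v)) / s
  m
}

#' Scenario configuration
#'
#' Bundles everything needed to generate a reproducible synthetic study:
#' grid geometry, environmental layer settings, the two species' true
#' niches, their accessible areas, occurrence sample sizes and the biotic
#' (tree) niche specs. `kind = "conservatism"` forces identical niches;
#' `"divergence"` shifts the layer-1 optima to +1 / -1 (two breadths apart);
#' `"partial"` uses +0.5 / -0.5. Explicitly supplied niche params override
#' the kind-based defaults but are validated against `kind`.
#'
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param kind One of `"divergence"`, `"conservatism"`, `"partial"`.
#' @param header Grid geometry, default [default_grid_header()].
#' @param n_layers Number of environmental layers (>= 2).
#' @param autocorrelation_length Noise autocorrelation length in cells;
#'   must be below `min(nrows, ncols)`.
#' @param species_A,species_B Optional [niche_params()] overrides.
#' @param background_A,background_B Accessible-area specs
#'   ([region_circles()] or logical masks). Defaults: two 450-km circles
#'   offset so they overlap about 70% by area.
#' @param n_occ_A,n_occ_B Occurrence sample sizes (defaults 274 and 534,
#'   typical cleaned presence-only dataset sizes for a restricted-range and
#'   a widespread congener).
#' @param tree_specs Named list of [niche_params()] for the biotic layers.
#' @param divergent_axes Layer names declared divergent (recorded in the
#'   truth record); derived from `kind` when omitted.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            kind = c("divergence", "conservatism", "partial"),
                            header = default_grid_header(),
                            n_layers = 5,
                            autocorrelation_length = 4,
                            species_A = NULL, species_B = NULL,
                            background_A = NULL, background_B = NULL,
                            n_occ_A = 274, n_occ_B = 534,
                            tree_specs = NULL,
                            divergent_axes = NULL) {
  kind <- match.arg(kind)
  if (n_layers < 2) stop("n_layers must be >= 2")
  if (autocorrelation_length >= min(header$nrows, header$ncols))
    stop("config error: autocorrelation_length must be < min(nrows, ncols)")
  shift <- switch(kind, divergence = 1, partial = 0.5, conservatism = 0)
  # The planted optima align with the species' accessible areas (A's lower
  # layer-1 baseline in the western circle, B's higher one in the eastern):
  # divergence expresses as species occupying environmentally distinct
  # regions rather than cancelling against background availability.
  base_opt <- rep(0, n_layers)
  if (is.null(species_A)) {
    oA <- base_opt; oA[1] <- -shift
    species_A <- niche_params(oA)
  }
  if (is.null(species_B)) {
    oB <- base_opt; oB[1] <- shift
    species_B <- niche_params(oB)
  }
  if (kind == "conservatism" && !identical_niche(species_A, species_B))
    stop("conservatism scenarios require identical species niches")
  if (kind != "conservatism" && identical_niche(species_A, species_B))
    stop("divergence scenarios require niches differing on >= 1 axis")
  if (is.null(divergent_axes)) {
    divergent_axes <- if (kind == "conservatism") character(0) else
      paste0("env_", which(species_A$optima != species_B$optima |
                             species_A$breadths != species_B$breadths |
                             species_A$weights != species_B$weights))
  }
  if (kind == "conservatism" && length(divergent_axes))
    stop("conservatism scenarios must declare no divergent axes")
  if (is.null(background_A)) background_A <- region_circles(-93, 48, 450)
  if (is.null(background_B)) background_B <- region_circles(-88.5, 48, 450)
  if (is.null(tree_specs)) {
    pad <- function(x) c(x, rep(0, n_layers))[seq_len(n_layers)]
    tree_specs <- list(
      fir    = niche_params(pad(c(-0.8, -0.3)), rep(1.2, n_layers),
                            pad(c(1, 1))),
      spruce = niche_params(pad(c(0.8, 0.3)), rep(1.2, n_layers),
                            pad(c(1, 1))),
      birch  = niche_params(pad(c(0, 0, 0.6)), rep(1.2, n_layers),
                            pad(c(0, 0, 1))))
  }
  structure(list(seed = as.integer(seed), kind = kind, header = header,
                 n_layers = as.integer(n_layers),
                 autocorrelation_length = autocorrelation_length,
                 species_A = species_A, species_B = species_B,
                 background_A = background_A, background_B = background_B,
                 n_occ_A = as.integer(n_occ_A), n_occ_B = as.integer(n_occ_B),
                 tree_specs = tree_specs, divergent_axes = divergent_axes),
            class = "scenario_config")
}

#' Generate environmental layers
#'
#' Each layer is a deterministic large-scale linear gradient (azimuth varied
#' across layers) plus a seeded Gaussian-smoothed white-noise field with the
#' requested autocorrelation length, mixed 1:1 and standardized to mean 0,
#' sd 1 over valid cells. Fully reproducible from the config seed.
#'
#' @param config A [scenario_config()].
#' @return A [layer_stack()] with layers `env_1 ... env_k`.
#' @export
gen_env_layers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  h <- config$header
  if (config$autocorrelation_length >= min(h$nrows, h$ncols))
    stop("config error: autocorrelation_length must be < min(nrows, ncols)")
  set.seed(config$seed)
  mask <- matrix(TRUE, h$nrows, h$ncols)
  east <- ((seq_len(h$ncols)) - 0.5) / h$ncols - 0.5
  north <- ((h$nrows - seq_len(h$nrows)) + 0.5) / h$nrows - 0.5
  U <- outer(rep(1, h$nrows), east)
  V <- outer(north, rep(1, h$ncols))
  # deterministic large-scale patterns drawn from a family of mutually
  # orthogonal spatial modes, so the layers are uncorrelated over the grid
  # (rotated copies of one linear gradient would be collinear)
  modes <- list(
    function(u, v) u,
    function(u, v) v,
    function(u, v) u * v,
    function(u, v) cos(2 * pi * u),
    function(u, v) cos(2 * pi * v),
    function(u, v) u * cos(2 * pi * v),
    function(u, v) v * cos(2 * pi * u),
    function(u, v) cos(2 * pi * u) * cos(2 * pi * v))
  layers <- vector("list", config$n_layers)
  for (k in seq_len(config$n_layers)) {
    f_mode <- modes[[((k - 1) %% length(modes)) + 1]]
    cycle <- (k - 1) %/% length(modes)  # reuse with higher frequency
    grad <- f_mode(U * (cycle + 1), V * (cycle + 1))
    noise <- smooth_field(matrix(stats::rnorm(h$nrows * h$ncols),
                                 h$nrows, h$ncols),
                          config$autocorrelation_length)
    # gradient and autocorrelated noise contribute equal variance: the
    # gradient gives the accessible areas distinct environmental baselines,
    # the noise gives each species room to select habitat within its area
    f <- (standardize_matrix(grad, mask) + standardize_matrix(noise, mask)) /
      sqrt(2)
    layers[[k]] <- new_grid(h, standardize_matrix(f, mask), mask)
  }
  layer_stack(layers, names = paste0("env_", seq_len(config$n_layers)))
}

#' Generate environmental layers with collinear blocks
#'
#' Real bioclimatic variable sets are strongly collinear, falling into a few
#' correlated clusters (temperature-like, precipitation-like, ...) that
#' anchor distinct principal components. This generator emulates that
#' structure: each block shares a common field (orthogonal large-scale
#' anchor gradient plus seeded autocorrelated noise) and each member layer
#' mixes the common field with idiosyncratic noise to reach the requested
#' within-block correlation. Layers are standardized to mean 0, sd 1 over
#' valid cells and named `env_1 ... env_k` in block order.
#'
#' @param seed Integer seed.
#' @param header Grid geometry.
#' @param block_sizes Integer vector, one entry per block (e.g. `c(3, 2)`).
#' @param within_r Target within-block correlation (0-1).
#' @param autocorrelation_length Noise autocorrelation length in cells.
#' @return A [layer_stack()] with attribute `blocks` (block index per
#'   layer).
#' @export
gen_correlated_env_layers <- function(seed, header = default_grid_header(),
                                      block_sizes = c(3, 2), within_r = 0.8,
                                      autocorrelation_length = 4) {
  if (within_r < 0 || within_r > 1) stop("within_r must be in [0, 1]")
  if (autocorrelation_length >= min(header$nrows, header$ncols))
    stop("config error: autocorrelation_length must be < min(nrows, ncols)")
  set.seed(seed)
  h <- header
  mask <- matrix(TRUE, h$nrows, h$ncols)
  east <- ((seq_len(h$ncols)) - 0.5) / h$ncols - 0.5
  north <- ((h$nrows - seq_len(h$nrows)) + 0.5) / h$nrows - 0.5
  U <- outer(rep(1, h$nrows), east)
  V <- outer(north, rep(1, h$ncols))
  anchors <- list(U, V, U * V, cos(2 * pi * U), cos(2 * pi * V))
  std <- function(x) standardize_matrix(x, mask)
  noise <- function() std(smooth_field(
    matrix(stats::rnorm(h$nrows * h$ncols), h$nrows, h$ncols),
    autocorrelation_length))
  layers <- list()
  block_id <- integer(0)
  for (b in seq_along(block_sizes)) {
    common <- std(std(anchors[[((b - 1) %% length(anchors)) + 1]]) + noise())
    for (j in seq_len(block_sizes[b])) {
      v <- if (j == 1) common else
        std(sqrt(within_r) * common + sqrt(1 - within_r) * noise())
      layers[[length(layers) + 1]] <- new_grid(h, v, mask)
      block_id <- c(block_id, b)
    }
  }
  st <- layer_stack(layers, names = paste0("env_", seq_along(layers)))
  attr(st, "blocks") <- block_id
  st
}

#' True suitability surface of a Gaussian niche
#'
#' `s = exp(-sum_k w_k (x_k - o_k)^2 / (2 b_k^2))`, rescaled to a maximum of
#' 1 over valid cells.
#'
#' @param stack Environmental [layer_stack()].
#' @param niche A [niche_params()] with one entry per layer.
#' @return An `enm_grid` of suitabilities in (0, 1\].
#' @export
true_suitability <- function(stack, niche) {
  stopifnot(inherits(stack, "layer_stack"), inherits(niche, "niche_params"))
  if (length(niche$optima) != length(stack$layers))
    stop("niche parameter length must equal the number of layers")
  h <- stack$header
  d2 <- matrix(0, h$nrows, h$ncols)
  for (k in seq_along(stack$layers)) {
    if (niche$weights[k] == 0) next
    d2 <- d2 + niche$weights[k] *
      (stack$layers[[k]]$values - niche$optima[k])^2 /
      (2 * niche$breadths[k]^2)
  }
  s <- exp(-d2)
  s[!stack$mask] <- 0
  s <- s / max(s[stack$mask])
  new_grid(h, s, stack$mask)
}

#' Sample occurrences from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability (times an
#' optional restriction mask). With `dedup = TRUE` (default) draws are made
#' with replacement but duplicates are redrawn, which is equivalent to
#' successive weighted sampling without replacement, yielding at most one
#' record per cell. Each point is then placed uniformly within its cell.
#' Records carry synthetic breeding-season dates (June 15 - July 25) and
#' sub-5-km coordinate uncertainties so the cleaning filters are exercised.
#'
#' @param suitability Non-negative `enm_grid`.
#' @param n Number of records to draw.
#' @param seed Integer seed.
#' @param restrict Optional logical matrix; sampling is confined to it.
#' @param dedup At most one record per cell (default `TRUE`).
#' @param species Species name for the returned set.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(suitability, n, seed = 1, restrict = NULL,
                               dedup = TRUE, species = "virtual") {
  stopifnot(inherits(suitability, "enm_grid"))
  h <- suitability$header
  s <- suitability$values
  if (any(s[suitability$mask] < 0)) stop("suitability must be non-negative")
  ok <- suitability$mask & s > 0
  if (!is.null(restrict)) {
    restrict <- region_mask(restrict, h)
    ok <- ok & restrict
  }
  cells <- which(ok)
  if (dedup && length(cells) < n)
    stop(sprintf("sampling error: %d positive-suitability cells for n = %d",
                 length(cells), n))
  if (!dedup && length(cells) < 1) stop("sampling error: no positive cells")
  set.seed(seed)
  idx <- if (length(cells) == 1) rep(cells, n) else
    sample(cells, n, replace = !dedup, prob = s[cells])
  row <- ((idx - 1L) %% h$nrows) + 1L
  col <- ((idx - 1L) %/% h$nrows) + 1L
  lon <- h$xllcorner + (col - 1 + stats::runif(n)) * h$cellsize
  lat <- h$yllcorner + (h$nrows - row + stats::runif(n)) * h$cellsize
  dates <- as.Date("2015-06-15") + sample.int(41, n, replace = TRUE) - 1L
  unc <- stats::runif(n, 0, 4.9)
  occurrence_set(species, lon, lat, date = dates, uncertainty_km = unc,
                 source_tag = "synthetic")
}

#' Generate a full synthetic scenario
#'
#' Produces the environmental stack, tree suitability layers (the biotic
#' covariates), binary "range-map" layers (tree suitability thresholded at
#' 0.2, emulating rasterized published range polygons), the two species'
#' occurrence sets sampled inside their accessible areas, and a truth record
#' carrying the true suitability surfaces and the declared divergent axes.
#'
#' @param config A [scenario_config()].
#' @return Object of class `niche_scenario`: list with elements `env`,
#'   `trees`, `shapefiles` (all `layer_stack`s), `occ_A`, `occ_B`,
#'   `background_A`, `background_B` (logical masks), and `truth`.
#' @export
gen_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  env <- gen_env_layers(config)
  trees <- layer_stack(lapply(config$tree_specs, function(sp)
    true_suitability(env, sp)), names = names(config$tree_specs))
  shapefiles <- layer_stack(lapply(trees$layers, function(g)
    threshold_surface(g, 0.2)), names = paste0(names(config$tree_specs),
                                               "_range"))
  mask_A <- region_mask(config$background_A, config$header)
  mask_B <- region_mask(config$background_B, config$header)
  suit_A <- true_suitability(env, config$species_A)
  suit_B <- true_suitability(env, config$species_B)
  occ_A <- sample_occurrences(suit_A, config$n_occ_A,
                              seed = config$seed + 101L, restrict = mask_A,
                              species = "species_A")
  occ_B <- sample_occurrences(suit_B, config$n_occ_B,
                              seed = config$seed + 202L, restrict = mask_B,
                              species = "species_B")
  truth <- list(true_A = suit_A, true_B = suit_B, trees_true = trees,
                divergent_axes = config$divergent_axes, kind = config$kind,
                config = config)
  structure(list(env = env, trees = trees, shapefiles = shapefiles,
                 occ_A = occ_A, occ_B = occ_B,
                 background_A = mask_A, background_B = mask_B,
                 truth = truth),
            class = "niche_scenario")
}

#' @export
print.niche_scenario <- function(x, ...) {
  cat(sprintf(paste0("<niche_scenario> kind = %s, %d env + %d tree layers, ",
                     "%d + %d occurrences, divergent axes: %s\n"),
              x$truth$kind, length(x$env$layers), length(x$trees$layers),
              n_occurrences(x$occ_A), n_occurrences(x$occ_B),
              if (length(x$truth$divergent_axes))
                paste(x$truth$divergent_axes, collapse = ", ") else "none"))
  invisible(x)
}
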