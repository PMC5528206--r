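# Niche overlap statistics between two suitability surfaces standardized to
# sum to one: Schoener's D and the Hellinger-distance-based I statistic.
# Both use the conventional 1/2 factor so that 0 means disjoint support and
# 1 means identical surfaces.

#' Standardize a surface to sum to one
#'
#' Divides every valid cell by the total over valid cells, turning a
#' suitability surface into a probability surface suitable for overlap
#' statistics.
#'
#' @param grid A non-negative `enm_grid` with positive total.
#' @return An `enm_grid` with subclass `prob_surface`.
#' @export
standardize_surface <- function(grid) {
  stopifnot(inherits(grid, "enm_grid"))
  v <- grid$values[grid$mask]
  if (any(v < 0)) stop("domain error: negative values in surface")
  tot <- sum(v)
  if (tot <= 0) stop("domain error: zero total over valid cells")
  out <- grid$values
  out[grid$mask] <- v / tot
  out[!grid$mask] <- grid$header$nodata_value
  g <- new_grid(grid$header, out, grid$mask)
  class(g) <- c("prob_surface", class(g))
  g
}

check_overlap_args <- function(pX, pY) {
  stopifnot(inherits(pX, "enm_grid"), inherits(pY, "enm_grid"))
  if (!headers_compatible(pX$header, pY$header))
    stop("surfaces have incompatible grid geometry")
  if (!identical(pX$mask, pY$mask))
    stop("surfaces have different validity masks; re-mask explicitly first")
  for (g in list(pX, pY)) {
    tot <- sum(g$values[g$mask])
    if (abs(tot - 1) > 1e-6)
      stop("surface is not standardized to sum 1 (total = ", tot,
           "); call standardize_surface() first")
  }
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum_i |p_X,i - p_Y,i|` over the shared valid cells of two
#' sum-to-one surfaces. 0 = no overlap, 1 = identical.
#'
#' @param pX,pY Sum-to-one surfaces (see [standardize_surface()]) sharing
#'   geometry and mask.
#' @return Numeric in \[0, 1\].
#' @export
schoener_D <- function(pX, pY) {
  check_overlap_args(pX, pY)
  m <- pX$mask
  d <- 1 - 0.5 * sum(abs(pX$values[m] - pY$values[m]))
  min(max(d, 0), 1)
}

#' Hellinger-based I niche overlap
#'
#' `I = 1 - 0.5 * sum_i (sqrt(p_X,i) - sqrt(p_Y,i))^2`, treating the two
#' surfaces as probability distributions. Satisfies `I >= D` for any pair.
#'
#' @inheritParams schoener_D
#' @return Numeric in \[0, 1\].
#' @export
hellinger_I <- function(pX, pY) {
  check_overlap_args(pX, pY)
  m <- pX$mask
  i <- 1 - 0.5 * sum((sqrt(pX$values[m]) - sqrt(pY$values[m]))^2)
  min(max(i, 0), 1)
}

#' Both overlap statistics at once
#'
#' @inheritParams schoener_D
#' @return List with elements `D` and `I`.
#' @export
niche_overlap <- function(pX, pY) {
  list(D = schoener_D(pX, pY), I = hellinger_I(pX, pY))
}
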