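# Small builders shared across the test files. Everything is generated in
# code; no stored fixtures.

tiny_header <- function(ncols = 5, nrows = 4, cellsize = 1,
                        xll = 10, yll = 40) {
  grid_header(ncols, nrows, xll, yll, cellsize)
}

# grid with deterministic values v[r, c] = 10 r + c and full mask
counting_grid <- function(header = tiny_header()) {
  v <- outer(seq_len(header$nrows) * 10, seq_len(header$ncols), `+`)
  new_grid(header, v)
}

random_masked_grid <- function(header = tiny_header(), seed = 1,
                               mask_frac = 0.2) {
  set.seed(seed)
  v <- matrix(rnorm(header$nrows * header$ncols) * 100,
              header$nrows, header$ncols)
  m <- matrix(runif(length(v)) > mask_frac, header$nrows, header$ncols)
  new_grid(header, v, m)
}

# stack of k seeded white-noise layers on one header
noise_stack <- function(k = 2, header = tiny_header(100, 100), seed = 1) {
  set.seed(seed)
  layer_stack(lapply(seq_len(k), function(i)
    new_grid(header, matrix(rnorm(header$nrows * header$ncols),
                            header$nrows, header$ncols))))
}

# sum-to-one surface from non-negative weights (full mask)
prob_grid <- function(w, header) {
  v <- matrix(w, header$nrows, header$ncols)
  standardize_surface(new_grid(header, v))
}

# a pair of random sum-to-one surfaces sharing geometry
random_prob_pair <- function(seed, nrows = 5, ncols = 6) {
  h <- grid_header(ncols, nrows, 0, 0, 1)
  set.seed(seed)
  a <- matrix(rexp(nrows * ncols), nrows, ncols)
  b <- matrix(rexp(nrows * ncols), nrows, ncols)
  list(standardize_surface(new_grid(h, a)),
       standardize_surface(new_grid(h, b)))
}

make_occ <- function(lon, lat, species = "sp", ...) {
  occurrence_set(species, lon, lat, ...)
}

# per-cell loop oracles for the overlap statistics
loop_D <- function(pX, pY) {
  s <- 0
  for (i in seq_along(pX$values))
    if (pX$mask[i]) s <- s + abs(pX$values[i] - pY$values[i])
  1 - 0.5 * s
}
loop_I <- function(pX, pY) {
  s <- 0
  for (i in seq_along(pX$values))
    if (pX$mask[i]) s <- s + (sqrt(pX$values[i]) - sqrt(pY$values[i]))^2
  1 - 0.5 * s
}
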