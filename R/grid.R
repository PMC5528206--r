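# Raster data model: ESRI ASCII grids, layer stacks, point-to-cell mapping,
# value extraction and collinearity screening.

#' Construct a grid header
#'
#' Describes the geometry of an ESRI ASCII grid: cell counts, the lower-left
#' corner of the extent, the (square) cell size in decimal degrees and the
#' nodata sentinel. Row 1 of a grid is the northernmost row, matching the
#' ESRI ASCII row order.
#'
#' @param ncols,nrows Positive integers, number of columns / rows.
#' @param xllcorner,yllcorner Longitude / latitude of the lower-left corner
#'   of the extent (degrees, unprojected WGS84 implied).
#' @param cellsize Cell edge length in degrees; cells are square.
#' @param nodata_value Sentinel written at invalid cells.
#' @return An object of class `grid_header`.
#' @seealso [new_grid()], [read_ascii_grid()]
#' @export
grid_header <- function(ncols, nrows, xllcorner, yllcorner, cellsize,
                        nodata_value = -9999) {
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (is.na(ncols) || ncols < 1L) stop("ncols must be a positive integer")
  if (is.na(nrows) || nrows < 1L) stop("nrows must be a positive integer")
  cellsize <- as.numeric(cellsize)
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  structure(list(ncols = ncols, nrows = nrows,
                 xllcorner = as.numeric(xllcorner),
                 yllcorner = as.numeric(yllcorner),
                 cellsize = cellsize,
                 nodata_value = as.numeric(nodata_value)),
            class = "grid_header")
}

#' Test whether two grid headers describe the same geometry
#'
#' @param a,b `grid_header` objects.
#' @param tol Numeric tolerance applied to every field.
#' @return Logical scalar.
#' @export
headers_compatible <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_header"), inherits(b, "grid_header"))
  all(abs(unlist(a) - unlist(b)) <= tol)
}

#' Construct a grid
#'
#' A grid couples a header with an `nrows x ncols` value matrix and a logical
#' validity mask. Values at masked-out cells are forced to the header's
#' nodata sentinel so that write/read round-trips are exact.
#'
#' @param header A [grid_header()].
#' @param values Numeric matrix, `nrows x ncols`, row 1 = northernmost row.
#' @param mask Optional logical matrix of the same shape (`TRUE` = valid).
#'   Defaults to `values != nodata_value`.
#' @return An object of class `enm_grid`.
#' @export
new_grid <- function(header, values, mask = NULL) {
  stopifnot(inherits(header, "grid_header"))
  values <- as.matrix(values)
  if (nrow(values) != header$nrows || ncol(values) != header$ncols)
    stop(sprintf("values must be %d x %d, got %d x %d",
                 header$nrows, header$ncols, nrow(values), ncol(values)))
  if (is.null(mask)) {
    mask <- values != header$nodata_value
    mask[is.na(values)] <- FALSE
  } else {
    mask <- as.matrix(mask)
    if (!is.logical(mask) || any(dim(mask) != dim(values)))
      stop("mask must be a logical matrix matching the value matrix")
  }
  values[!mask] <- header$nodata_value
  structure(list(header = header, values = values, mask = mask),
            class = "enm_grid")
}

#' @export
print.enm_grid <- function(x, ...) {
  h <- x$header
  cat(sprintf("<enm_grid> %d rows x %d cols, cellsize %g deg, %d/%d valid cells\n",
              h$nrows, h$ncols, h$cellsize, sum(x$mask), length(x$mask)))
  invisible(x)
}

.header_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                  "nodata_value")

#' Read an ESRI ASCII grid
#'
#' Expects six header lines (NCOLS, NROWS, XLLCORNER, YLLCORNER, CELLSIZE,
#' NODATA_VALUE; keys case-insensitive, any order) followed by `nrows` lines
#' of `ncols` whitespace-separated values. Cells equal to the nodata value
#' are masked out.
#'
#' @param path Path to a `.asc` file.
#' @return An `enm_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("malformed ASCII grid: fewer than 7 lines")
  hdr <- list()
  for (i in 1:6) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) != 2)
      stop(sprintf("malformed header line %d: '%s'", i, lines[[i]]))
    key <- tolower(toks[[1]])
    val <- suppressWarnings(as.numeric(toks[[2]]))
    if (!key %in% .header_keys || is.na(val))
      stop(sprintf("malformed header line %d: '%s'", i, lines[[i]]))
    hdr[[key]] <- val
  }
  missing <- setdiff(.header_keys, names(hdr))
  if (length(missing))
    stop("malformed header: missing key(s) ", paste(missing, collapse = ", "))
  header <- grid_header(hdr$ncols, hdr$nrows, hdr$xllcorner, hdr$yllcorner,
                        hdr$cellsize, hdr$nodata_value)
  body <- trimws(lines[-(1:6)])
  body <- body[nzchar(body)]
  toks <- unlist(strsplit(body, "\\s+"))
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop("format error: non-numeric token '", toks[which(is.na(vals))[1]],
         "' in value section")
  if (length(vals) != header$nrows * header$ncols)
    stop(sprintf("dimension error: expected %d values, found %d",
                 header$nrows * header$ncols, length(vals)))
  values <- matrix(vals, nrow = header$nrows, ncol = header$ncols, byrow = TRUE)
  new_grid(header, values)
}

#' Write an ESRI ASCII grid
#'
#' Header keys are emitted in the canonical order NCOLS..NODATA_VALUE; values
#' are serialized with 17 significant digits so a read-back reproduces the
#' grid exactly. Masked cells are written as the literal nodata value.
#'
#' @param grid An `enm_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "enm_grid"))
  h <- grid$header
  num <- function(x) {
    out <- sprintf("%.17g", x)
    ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))), out)
  }
  hdr <- c(sprintf("NCOLS %d", h$ncols),
           sprintf("NROWS %d", h$nrows),
           sprintf("XLLCORNER %s", num(h$xllcorner)),
           sprintf("YLLCORNER %s", num(h$yllcorner)),
           sprintf("CELLSIZE %s", num(h$cellsize)),
           sprintf("NODATA_VALUE %s", num(h$nodata_value)))
  rows <- apply(grid$values, 1, function(r) paste(num(r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to ", path)
  invisible(path)
}

#' Map coordinates to grid cells
#'
#' Half-open cell intervals with the floor convention: a point exactly on an
#' interior boundary belongs to the cell with the larger index. Points
#' outside the extent get `NA` row/col.
#'
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @param header A `grid_header`.
#' @return A data frame with 1-based integer columns `row` (row 1 = north)
#'   and `col`, `NA` where out of bounds.
#' @export
cell_of <- function(lon, lat, header) {
  stopifnot(inherits(header, "grid_header"))
  cs <- header$cellsize
  col0 <- floor((lon - header$xllcorner) / cs)
  row0 <- header$nrows - 1 - floor((lat - header$yllcorner) / cs)
  oob <- col0 < 0 | col0 >= header$ncols | row0 < 0 | row0 >= header$nrows |
    !is.finite(col0) | !is.finite(row0)
  row <- as.integer(row0) + 1L; col <- as.integer(col0) + 1L
  row[oob] <- NA_integer_; col[oob] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Coordinates of cell centers
#'
#' @param row,col 1-based cell indices (row 1 = northernmost row).
#' @param header A `grid_header`.
#' @return Data frame with columns `lon`, `lat`.
#' @export
cell_center <- function(row, col, header) {
  data.frame(lon = header$xllcorner + (col - 0.5) * header$cellsize,
             lat = header$yllcorner + (header$nrows - row + 0.5) * header$cellsize)
}

# linear (column-major) index into a value matrix from 1-based row/col
cell_linear <- function(row, col, header) {
  as.integer(row + (col - 1L) * header$nrows)
}

#' Stack layers sharing one geometry
#'
#' All layers must have compatible headers. The stack's joint mask is the
#' intersection of the per-layer masks; extraction and modelling honour it.
#'
#' @param layers A list of `enm_grid` objects (possibly named).
#' @param names Optional character vector of unique layer names; defaults to
#'   the list names or `layer_1`, `layer_2`, ...
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, names = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names)) names <- base::names(layers)
  if (is.null(names)) names <- paste0("layer_", seq_along(layers))
  if (length(names) != length(layers) || anyDuplicated(names))
    stop("layer names must be unique and match the number of layers")
  for (g in layers) {
    if (!inherits(g, "enm_grid")) stop("all layers must be enm_grid objects")
    if (!headers_compatible(g$header, layers[[1]]$header))
      stop("layer headers are not compatible")
  }
  mask <- Reduce(`&`, lapply(layers, `[[`, "mask"))
  structure(list(names = as.character(names), layers = stats::setNames(layers, names),
                 header = layers[[1]]$header, mask = mask),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers [%s], %d x %d cells, %d jointly valid\n",
              length(x$layers), paste(x$names, collapse = ", "),
              x$header$nrows, x$header$ncols, sum(x$mask)))
  invisible(x)
}

#' @export
`[.layer_stack` <- function(x, i) {
  layer_stack(x$layers[i], names = x$names[match(names(x$layers[i]), x$names)])
}

#' Extract layer values at points
#'
#' Points falling out of bounds or on jointly masked cells are flagged
#' invalid (`valid = FALSE`) with `NA` values, never dropped silently.
#'
#' @param stack A `layer_stack`.
#' @param lon,lat Coordinate vectors (degrees).
#' @return Data frame: `point_id`, `lon`, `lat`, one column per layer, `valid`.
#' @export
extract_values <- function(stack, lon, lat) {
  stopifnot(inherits(stack, "layer_stack"), length(lon) == length(lat))
  rc <- cell_of(lon, lat, stack$header)
  n <- length(lon)
  valid <- !is.na(rc$row)
  idx <- rep(NA_integer_, n)
  idx[valid] <- cell_linear(rc$row[valid], rc$col[valid], stack$header)
  valid[valid] <- stack$mask[idx[valid]]
  out <- data.frame(point_id = seq_len(n), lon = lon, lat = lat)
  for (nm in stack$names) {
    v <- rep(NA_real_, n)
    v[valid] <- stack$layers[[nm]]$values[idx[valid]]
    out[[nm]] <- v
  }
  out$valid <- valid
  out
}

#' Pairwise collinearity screen
#'
#' Pearson correlations over jointly valid cells. Pairs with `|r|` above the
#' threshold are flagged but never dropped: collinear predictors are reported
#' to the analyst, who decides (removing variables can reduce model accuracy).
#' Constant layers have undefined correlations and are listed separately.
#'
#' @param stack A `layer_stack` with at least two layers.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @return List with `correlations` (symmetric matrix, unit diagonal, `NA`
#'   rows/cols for constant layers), `flagged` (data frame of offending
#'   pairs) and `constant_layers`.
#' @export
correlation_screen <- function(stack, threshold = 0.7) {
  stopifnot(inherits(stack, "layer_stack"))
  if (length(stack$layers) < 2) stop("need at least 2 layers")
  X <- vapply(stack$layers, function(g) g$values[stack$mask],
              numeric(sum(stack$mask)))
  sds <- apply(X, 2, stats::sd)
  constant <- stack$names[sds == 0 | !is.finite(sds)]
  R <- suppressWarnings(stats::cor(X))
  diag(R) <- ifelse(stack$names %in% constant, NA_real_, 1)
  pairs <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
  flagged <- data.frame(layer_a = stack$names[pairs[, 1]],
                        layer_b = stack$names[pairs[, 2]],
                        r = R[pairs])
  list(correlations = R, flagged = flagged, constant_layers = constant,
       threshold = threshold)
}
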