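# Occurrence records and the cleaning rules applied before modelling:
# breeding-window filter, coordinate-uncertainty filter, per-cell
# deduplication and seeded uniform-density thinning.

#' Great-circle distance
#'
#' Haversine distance with Earth mean radius 6371.0088 km. Vectorized and
#' recycled over its arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  k <- pi / 180
  dlat <- (lat2 - lat1) * k / 2
  dlon <- (lon2 - lon1) * k / 2
  a <- sin(dlat)^2 + cos(lat1 * k) * cos(lat2 * k) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Construct an occurrence set
#'
#' Point records for a single species, with an attached provenance log that
#' every filter appends to, so record counts reconcile across a cleaning
#' pipeline.
#'
#' @param species Species name (single string).
#' @param lon,lat Coordinates in degrees; `lat` in \[-90, 90\], `lon` in
#'   \[-180, 180\].
#' @param date Optional vector coercible with [as.Date()].
#' @param uncertainty_km Optional non-negative coordinate uncertainty.
#' @param source_tag Optional free-text provenance per record.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat, date = NULL,
                           uncertainty_km = NULL, source_tag = NULL) {
  n <- length(lon)
  stopifnot(length(lat) == n, is.character(species), length(species) == 1)
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) stop("lat out of [-90, 90]")
  if (any(!is.na(lon) & (lon < -180 | lon > 180))) stop("lon out of [-180, 180]")
  if (!is.null(uncertainty_km) && any(uncertainty_km < 0, na.rm = TRUE))
    stop("uncertainty_km must be non-negative")
  rec <- data.frame(
    lon = as.numeric(lon), lat = as.numeric(lat),
    date = if (is.null(date)) as.Date(rep(NA, n)) else as.Date(date),
    uncertainty_km = if (is.null(uncertainty_km)) rep(NA_real_, n)
                     else as.numeric(uncertainty_km),
    source_tag = if (is.null(source_tag)) rep(NA_character_, n)
                 else as.character(source_tag))
  structure(list(species = species, records = rec, log = list()),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d records, %d filter(s) applied\n",
              x$species, nrow(x$records), length(x$log)))
  invisible(x)
}

#' Number of records in an occurrence set
#' @param set An `occurrence_set`.
#' @return Integer count.
#' @export
n_occurrences <- function(set) nrow(set$records)

log_step <- function(set, filter, n_in, n_out, ...) {
  set$log[[length(set$log) + 1]] <-
    c(list(filter = filter, n_in = n_in, n_removed = n_in - n_out,
           n_out = n_out), list(...))
  set
}

keep_records <- function(set, keep, filter, ...) {
  n_in <- nrow(set$records)
  set$records <- set$records[keep, , drop = FALSE]
  rownames(set$records) <- NULL
  log_step(set, filter, n_in, nrow(set$records), ...)
}

parse_month_day <- function(x) {
  m <- regmatches(x, regexec("^([0-1]?[0-9])-([0-3]?[0-9])$", x))[[1]]
  if (length(m) != 3) stop("month-day must be 'MM-DD', got '", x, "'")
  as.integer(m[2]) * 100L + as.integer(m[3])
}

#' Breeding-window date filter
#'
#' Keeps records dated within \[start, end\] inclusive in any year (e.g. a
#' June 7 to July 31 breeding window excludes migrants in passage). Records
#' without dates cannot be verified and are dropped, counted separately in
#' the provenance log.
#'
#' @param set An `occurrence_set`.
#' @param start,end Month-day strings, `"MM-DD"`.
#' @return Filtered `occurrence_set`.
#' @export
filter_window <- function(set, start, end) {
  stopifnot(inherits(set, "occurrence_set"))
  s <- parse_month_day(start); e <- parse_month_day(end)
  if (s > e) stop("config error: window start is after end")
  d <- set$records$date
  md <- ifelse(is.na(d), NA_integer_,
               as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d")))
  missing <- is.na(md)
  keep <- !missing & md >= s & md <= e
  keep_records(set, keep, "window", start = start, end = end,
               n_missing_date = sum(missing))
}

#' Coordinate-uncertainty filter
#'
#' Keeps records whose stated uncertainty is strictly below `max_km`.
#' Records with missing uncertainty fail the filter (strict policy: cleaned
#' sets never contain unverifiable records).
#'
#' @param set An `occurrence_set`.
#' @param max_km Uncertainty bound in km (default 5, strict `<`).
#' @return Filtered `occurrence_set`.
#' @export
filter_uncertainty <- function(set, max_km = 5) {
  stopifnot(inherits(set, "occurrence_set"))
  u <- set$records$uncertainty_km
  missing <- is.na(u)
  keep <- !missing & u < max_km
  keep_records(set, keep, "uncertainty", max_km = max_km,
               n_missing_uncertainty = sum(missing))
}

#' Per-cell deduplication
#'
#' At most one record per grid cell; the first record in input order is
#' retained. Records falling outside the grid extent cannot be assigned a
#' cell and are dropped (counted in the log).
#'
#' @param set An `occurrence_set`.
#' @param header A [grid_header()] defining the deduplication grid.
#' @return Filtered `occurrence_set`.
#' @export
dedup_to_grid <- function(set, header) {
  stopifnot(inherits(set, "occurrence_set"))
  rc <- cell_of(set$records$lon, set$records$lat, header)
  oob <- is.na(rc$row)
  key <- paste(rc$row, rc$col)
  keep <- !oob & !duplicated(key)
  keep_records(set, keep, "dedup_grid", n_out_of_bounds = sum(oob))
}

#' Seeded uniform-density thinning
#'
#' Deterministic stand-in for manual thinning: records are visited in a
#' seeded random order and kept only if at least `min_spacing_km` (great
#' circle) from every record already kept, giving a roughly uniform density
#' and removing sampling-intensity bias. The output's pairwise distances are
#' all `>= min_spacing_km`; re-applying the filter is the identity.
#'
#' @param set An `occurrence_set`.
#' @param min_spacing_km Minimum spacing in km; 0 disables thinning.
#' @param seed Integer seed for the visiting order.
#' @return Filtered `occurrence_set`.
#' @export
thin_uniform <- function(set, min_spacing_km, seed = 1) {
  stopifnot(inherits(set, "occurrence_set"), min_spacing_km >= 0)
  n <- nrow(set$records)
  if (min_spacing_km == 0 || n <= 1)
    return(log_step(set, "thin", n, n, min_spacing_km = min_spacing_km,
                    seed = seed))
  set.seed(seed)
  ord <- sample.int(n)
  lon <- set$records$lon; lat <- set$records$lat
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        all(haversine_km(lon[i], lat[i], lon[kept], lat[kept]) >= min_spacing_km))
      kept <- c(kept, i)
  }
  keep_records(set, sort(kept), "thin", min_spacing_km = min_spacing_km,
               seed = seed)
}

#' Read / write occurrence CSV
#'
#' Columns: `species, lon, lat, date, uncertainty_km, source_tag` (ISO-8601
#' dates). `read_occurrences` expects a single species per file.
#'
#' @param path CSV path.
#' @return `read_occurrences`: an `occurrence_set`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, lon, lat")
  sp <- unique(df$species)
  if (length(sp) != 1) stop("expected a single species per file, got ",
                            length(sp))
  occurrence_set(sp, df$lon, df$lat,
                 date = if ("date" %in% names(df)) df$date,
                 uncertainty_km = if ("uncertainty_km" %in% names(df))
                   df$uncertainty_km,
                 source_tag = if ("source_tag" %in% names(df)) df$source_tag)
}

#' @rdname read_occurrences
#' @param set An `occurrence_set` to write.
#' @export
write_occurrences <- function(set, path) {
  df <- cbind(species = set$species, set$records)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# internal: subset an occurrence set by record index, without logging
subset_occurrences <- function(set, idx) {
  set$records <- set$records[idx, , drop = FALSE]
  rownames(set$records) <- NULL
  set
}
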