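# Curtis-McIntosh importance values for vegetation-survey tables and the
# strict >20% rule used to select biotic covariates.

#' Importance values from habitat study tables
#'
#' For each (study, species) row: relative frequency = sites with the
#' species / total sites; relative abundance = individuals / total
#' individuals; relative dominance = basal area / total basal area; the
#' importance value is the unweighted mean of the three. Cross-study
#' averages are unweighted means over studies.
#'
#' @param table Data frame with columns `study`, `species`, `sites_with`,
#'   `total_sites`, `individuals`, `total_individuals`, `basal`,
#'   `total_basal`. Basal areas may be in any (consistent-per-study) unit.
#' @return Object of class `importance_report`: list with `per_study`
#'   (per-row relative measures and importance value) and `averages`
#'   (cross-study means of the importance value and relative abundance per
#'   species).
#' @export
importance_values <- function(table) {
  need <- c("study", "species", "sites_with", "total_sites", "individuals",
            "total_individuals", "basal", "total_basal")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  tot <- table[c("total_sites", "total_individuals", "total_basal")]
  if (any(unlist(tot) <= 0)) stop("domain error: zero or negative totals")
  if (any(table$sites_with > table$total_sites) ||
      any(table$individuals > table$total_individuals) ||
      any(table$basal > table$total_basal))
    stop("per-species counts exceed study totals")
  if (any(table$sites_with < 0) || any(table$individuals < 0) ||
      any(table$basal < 0))
    stop("counts must be non-negative")
  per <- data.frame(
    study = table$study, species = table$species,
    rel_frequency = table$sites_with / table$total_sites,
    rel_abundance = table$individuals / table$total_individuals,
    rel_dominance = table$basal / table$total_basal)
  per$importance <- (per$rel_frequency + per$rel_abundance +
                       per$rel_dominance) / 3
  avg <- do.call(rbind, lapply(split(per, per$species), function(d)
    data.frame(species = d$species[1], n_studies = nrow(d),
               mean_importance = mean(d$importance),
               mean_rel_abundance = mean(d$rel_abundance))))
  rownames(avg) <- NULL
  structure(list(per_study = per, averages = avg),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report>\n")
  print(x$averages)
  invisible(x)
}

#' Select commonly associated species
#'
#' Species whose cross-study average importance value (or relative
#' abundance) strictly exceeds the threshold; a species averaging exactly
#' the threshold is excluded.
#'
#' @param report An `importance_report` (or its `averages` data frame).
#' @param threshold Fraction, default 0.20.
#' @param mode Average to compare: `"importance"` or `"abundance"`.
#' @return Character vector of selected species names.
#' @export
select_species <- function(report, threshold = 0.20,
                           mode = c("importance", "abundance")) {
  mode <- match.arg(mode)
  avg <- if (inherits(report, "importance_report")) report$averages else report
  if (is.null(avg) || nrow(avg) == 0) return(character(0))
  col <- if (mode == "importance") "mean_importance" else "mean_rel_abundance"
  sort(avg$species[avg[[col]] > threshold])
}
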