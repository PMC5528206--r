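# Configuration-driven orchestration of the full analysis: simulate ->
# clean occurrences -> fit the four variable-set models -> compare them ->
# actual overlap -> background-similarity tests (2 directions x 3
# backgrounds, D and I) -> multivariate tests (3 backgrounds) -> report.

#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the conventional protocol: 25 model replicates with a 75/25 split,
#' 100-replicate background-similarity nulls at alpha = 0.05, 200 and
#' 700 km buffers plus a minimum-training-presence background, 1000
#' background points and 25 x 75% subsampling replicates with a 6%
#' variance-fraction retention rule for the multivariate test.
#'
#' @param scenario A [scenario_config()] describing the synthetic study.
#' @param window_A,window_B Breeding windows (`c(start, end)` month-day
#'   strings) for the two species.
#' @param max_uncertainty_km Coordinate-uncertainty bound (strict `<`).
#' @param thin_spacing_km Thinning spacing; `NULL` = one cell diagonal.
#' @param n_replicates Model replicates per variable set.
#' @param reg_lambda,background_n Passed to [fit_maxent()].
#' @param buffer_radii_km Buffer radii for background delineation.
#' @param use_mtp Also use the minimum-training-presence background.
#' @param bg_test_reps Null replicates per background-similarity test.
#' @param bg_test_background_n Background cells per null model fit.
#' @param n_bg_points Background points per species in the multivariate
#'   test.
#' @param mv_reps,mv_subsample Multivariate subsampling replicates and
#'   fraction.
#' @param alpha Two-sided level for verdicts.
#' @param min_var_frac PC retention rule.
#' @param final_set Variable set used for the divergence tests (default
#'   `"climate_trees"`).
#' @param seed Master seed; defaults to the scenario seed.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(scenario = scenario_config(),
                            window_A = c("06-07", "07-31"),
                            window_B = c("06-14", "07-31"),
                            max_uncertainty_km = 5,
                            thin_spacing_km = NULL,
                            n_replicates = 25,
                            reg_lambda = NULL,
                            background_n = 10000,
                            buffer_radii_km = c(200, 700),
                            use_mtp = TRUE,
                            bg_test_reps = 100,
                            bg_test_background_n = 1000,
                            n_bg_points = 1000,
                            mv_reps = 25,
                            mv_subsample = 0.75,
                            alpha = 0.05,
                            min_var_frac = 0.06,
                            final_set = "climate_trees",
                            seed = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(seed)) seed <- scenario$seed
  if (is.null(thin_spacing_km)) {
    h <- scenario$header
    mid <- h$yllcorner + h$nrows * h$cellsize / 2
    thin_spacing_km <- haversine_km(0, mid, h$cellsize, mid + h$cellsize)
  }
  structure(list(scenario = scenario, window_A = window_A,
                 window_B = window_B,
                 max_uncertainty_km = max_uncertainty_km,
                 thin_spacing_km = thin_spacing_km,
                 n_replicates = n_replicates, reg_lambda = reg_lambda,
                 background_n = background_n,
                 buffer_radii_km = buffer_radii_km, use_mtp = use_mtp,
                 bg_test_reps = bg_test_reps,
                 bg_test_background_n = bg_test_background_n,
                 n_bg_points = n_bg_points, mv_reps = mv_reps,
                 mv_subsample = mv_subsample, alpha = alpha,
                 min_var_frac = min_var_frac, final_set = final_set,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

prep_occurrences <- function(occ, window, config) {
  occ <- filter_window(occ, window[1], window[2])
  occ <- filter_uncertainty(occ, config$max_uncertainty_km)
  occ <- dedup_to_grid(occ, config$scenario$header)
  thin_uniform(occ, config$thin_spacing_km, seed = config$seed + 11L)
}

#' Run the full niche-divergence analysis
#'
#' Deterministic given the configuration: every stochastic stage is seeded
#' from the config seed. Any stage error aborts with the stage name.
#'
#' @param config An [analysis_config()].
#' @param verbose Print stage progress.
#' @return Object of class `niche_analysis_report`: scenario, cleaned
#'   occurrence sets, per-variable-set model evaluations and ANOVA/Tukey
#'   comparisons per species, the actual overlap (D, I), the
#'   background-similarity results (2 directions x backgrounds), the
#'   multivariate results (one per background type), verdict tallies,
#'   per-stage timings and the resolved config.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  timings <- c()
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  scen <- stage("simulate", gen_scenario(config$scenario))
  occ_A <- stage("prep_A", prep_occurrences(scen$occ_A, config$window_A,
                                            config))
  occ_B <- stage("prep_B", prep_occurrences(scen$occ_B, config$window_B,
                                            config))
  full <- stage("stack", layer_stack(c(scen$env$layers, scen$trees$layers,
                                       scen$shapefiles$layers)))
  sets <- list(climate = scen$env$names,
               climate_trees = c(scen$env$names, scen$trees$names),
               climate_shapefiles = c(scen$env$names, scen$shapefiles$names),
               trees = scen$trees$names)
  screen <- stage("correlation_screen", correlation_screen(full))

  fits <- stage("models", {
    out <- list()
    for (sp in c("A", "B")) {
      occ <- if (sp == "A") occ_A else occ_B
      out[[sp]] <- lapply(seq_along(sets), function(i) {
        replicate_maxent(full[sets[[i]]], occ,
                         n_replicates = config$n_replicates,
                         seed = config$seed + 1000L * i +
                           500L * (sp == "B"),
                         reg_lambda = config$reg_lambda,
                         background_n = config$background_n)
      })
      names(out[[sp]]) <- names(sets)
    }
    out
  })
  comparisons <- stage("compare_models", lapply(fits, function(f)
    compare_model_sets(lapply(f, `[[`, "evaluation"))))

  fstack <- full[sets[[config$final_set]]]
  surf_A <- standardize_surface(fits$A[[config$final_set]]$mean_surface)
  surf_B <- standardize_surface(fits$B[[config$final_set]]$mean_surface)
  actual <- stage("overlap", niche_overlap(surf_A, surf_B))

  backgrounds <- stage("backgrounds", {
    mk <- function(occ, full_fit_seed) {
      bgs <- lapply(config$buffer_radii_km, function(r)
        buffer_background(occ, r, fstack$header, base_mask = fstack$mask))
      names(bgs) <- paste0("buffer_", config$buffer_radii_km, "km")
      if (config$use_mtp) {
        m <- fit_maxent(fstack, occ, reg_lambda = config$reg_lambda,
                        seed = full_fit_seed,
                        background_n = config$background_n)
        bgs$mtp <- mtp_background(m, occ)
        bgs$mtp$mask <- bgs$mtp$mask & fstack$mask
      }
      bgs
    }
    list(A = mk(occ_A, config$seed + 71L), B = mk(occ_B, config$seed + 72L))
  })

  bg_tests <- stage("background_similarity", {
    out <- list()
    i <- 0L
    for (bg_name in names(backgrounds$A)) {
      for (dir in c("A_actual_vs_B_background", "B_actual_vs_A_background")) {
        i <- i + 1L
        focal <- if (dir == "A_actual_vs_B_background") surf_A else surf_B
        other_bg <- if (dir == "A_actual_vs_B_background")
          backgrounds$B[[bg_name]] else backgrounds$A[[bg_name]]
        n_pts <- if (dir == "A_actual_vs_B_background")
          n_occurrences(occ_B) else n_occurrences(occ_A)
        out[[paste(bg_name, dir, sep = ".")]] <-
          background_similarity_test(
            focal, n_pts, other_bg, fstack, actual,
            n_reps = config$bg_test_reps,
            seed = config$seed + 10000L * i, alpha = config$alpha,
            reg_lambda = config$reg_lambda,
            background_n = config$bg_test_background_n,
            direction = paste(bg_name, dir))
      }
    }
    out
  })

  mv_stack <- full[c(scen$env$names, scen$trees$names)]
  mv_tests <- stage("multivariate", {
    out <- list()
    j <- 0L
    for (bg_name in names(backgrounds$A)) {
      j <- j + 1L
      out[[bg_name]] <- multivariate_divergence_test(
        mv_stack, occ_A, occ_B,
        backgrounds$A[[bg_name]], backgrounds$B[[bg_name]],
        n_bg = config$n_bg_points, min_var_frac = config$min_var_frac,
        n_reps = config$mv_reps, subsample = config$mv_subsample,
        seed = config$seed + 20000L * j)
    }
    out
  })

  bg_verdicts <- unlist(lapply(bg_tests, function(t)
    c(t$verdict_D, t$verdict_I)))
  mv_verdicts <- unlist(lapply(mv_tests, function(t)
    t$table$verdict[t$table$retained]))
  tally <- function(v, levels) {
    out <- table(factor(v, levels = levels))
    stats::setNames(as.integer(out), names(out))
  }
  summary <- list(
    n_background_tests = length(bg_verdicts),
    background = tally(bg_verdicts,
                       c("divergence", "conservatism", "not_rejected")),
    n_mv_axes = length(mv_verdicts),
    multivariate = tally(mv_verdicts,
                         c("divergence", "conservatism", "inconclusive")))

  structure(list(scenario = scen, occ_A = occ_A, occ_B = occ_B,
                 correlation_screen = screen,
                 variable_sets = sets, models = fits,
                 comparisons = comparisons, actual_overlap = actual,
                 backgrounds = backgrounds,
                 background_tests = bg_tests, mv_tests = mv_tests,
                 verdict_summary = summary, timings = timings,
                 config = config),
            class = "niche_analysis_report")
}

#' @export
print.niche_analysis_report <- function(x, ...) {
  s <- x$verdict_summary
  cat("<niche_analysis_report>\n")
  cat(sprintf("  scenario: %s (seed %d)\n", x$config$scenario$kind,
              x$config$seed))
  cat(sprintf("  occurrences after cleaning: A = %d, B = %d\n",
              n_occurrences(x$occ_A), n_occurrences(x$occ_B)))
  for (sp in names(x$models)) {
    auc <- vapply(x$models[[sp]], function(f) f$evaluation$auc_test, 1)
    cat(sprintf("  species %s AUC_test: %s\n", sp,
                paste(sprintf("%s = %.3f", names(auc), auc),
                      collapse = ", ")))
  }
  cat(sprintf("  actual overlap: D = %.3f, I = %.3f\n",
              x$actual_overlap$D, x$actual_overlap$I))
  cat(sprintf("  background tests (%d): %s\n", s$n_background_tests,
              paste(sprintf("%s %d", names(s$background), s$background),
                    collapse = ", ")))
  cat(sprintf("  multivariate axes (%d): %s\n", s$n_mv_axes,
              paste(sprintf("%s %d", names(s$multivariate),
                            s$multivariate), collapse = ", ")))
  invisible(x)
}

#' Serialize a report's headline numbers to JSON
#'
#' Writes the cleaned occurrence counts, per-set test AUCs, actual overlap,
#' per-test verdicts and the verdict tallies (not the full surfaces) as a
#' JSON file, together with the resolved seeds, so a published run can be
#' re-executed and checked.
#'
#' @param report A `niche_analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "niche_analysis_report"))
  x <- list(
    kind = report$config$scenario$kind,
    seed = report$config$seed,
    n_occ_A = n_occurrences(report$occ_A),
    n_occ_B = n_occurrences(report$occ_B),
    auc_test = lapply(report$models, function(f)
      lapply(f, function(m) m$evaluation$auc_test)),
    actual_overlap = report$actual_overlap,
    background_tests = lapply(report$background_tests, function(t)
      list(direction = t$direction, actual_D = t$actual_D,
           null_D_mean = mean(t$null_D), null_D_sd = stats::sd(t$null_D),
           verdict_D = t$verdict_D, actual_I = t$actual_I,
           null_I_mean = mean(t$null_I), null_I_sd = stats::sd(t$null_I),
           verdict_I = t$verdict_I, p_D = t$p_D, p_I = t$p_I)),
    mv_tests = lapply(report$mv_tests, function(t)
      t$table[t$table$retained, ]),
    verdict_summary = report$verdict_summary,
    timings = as.list(report$timings))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
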