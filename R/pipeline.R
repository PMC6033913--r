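#' Pool occurrence sets into a combined set
#'
#' Concatenates records of several species into one `"combined"` set
#' (pooling happens before thinning, so the combined analysis is thinned as
#' a unit).
#'
#' @param occ_list List of [occurrence_set]s.
#' @return An [occurrence_set] labelled `"combined"`.
#' @export
combine_occurrences <- function(occ_list) {
  stopifnot(length(occ_list) >= 1L)
  recs <- do.call(rbind, lapply(occ_list, function(o) o$records))
  logs <- lapply(occ_list, function(o) o$cleaning_log)
  nms <- unique(unlist(lapply(logs, names)))
  log <- stats::setNames(vapply(nms, function(nm)
    sum(vapply(logs, function(l)
      if (nm %in% names(l)) as.integer(l[[nm]]) else 0L, integer(1))),
    integer(1)), nms)
  occurrence_set(recs, species = "combined", cleaning_log = log)
}

#' Pipeline run configuration
#'
#' Bundles every input and constant of a full two-scheme run. Defaults are
#' the workflow's standard settings: 50 km thinning, correlation screen at
#' 0.70, 10-fold cross-validation, acceptability at AUC > 0.7 and
#' TSS > 0.4.
#'
#' @param stack Candidate-predictor [grid_stack][align_stack].
#' @param occurrences An [occurrence_set] (pool with
#'   [combine_occurrences()] for a combined run).
#' @param elevation Elevation [env_grid] for the study mask.
#' @param target_group An [occurrence_set] of target-group records (may be
#'   empty for a random-only run).
#' @param out_dir Artifact directory (created if absent).
#' @param priority Screening priority order (defaults to stack order).
#' @param screen_threshold Correlation cutoff.
#' @param max_elev_m,lat_floor Study-mask rules.
#' @param max_error_km Positional-error cutoff.
#' @param thin_min_km,thin_reps Thinning distance and repetitions.
#' @param n_background Random background size.
#' @param algorithms Algorithms to run.
#' @param hyperparams Named list (per algorithm) of hyperparameter lists.
#' @param k Cross-validation folds.
#' @param n_perm Permutations per fold for variable importance.
#' @param auc_min,tss_min Acceptability cut-offs.
#' @param schemes Background schemes to run.
#' @param projections Named list of projection-region stacks (optional).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stack, occurrences, elevation, target_group = NULL,
                       out_dir = tempfile("sdm_run_"),
                       priority = NULL, screen_threshold = 0.70,
                       max_elev_m = 2500, lat_floor = -Inf,
                       max_error_km = 50,
                       thin_min_km = 50, thin_reps = 100,
                       n_background = 10000,
                       algorithms = sdm_algorithms,
                       hyperparams = list(),
                       k = 10, n_perm = 10,
                       auc_min = 0.7, tss_min = 0.4,
                       schemes = c("random", "targeted"),
                       projections = list(),
                       seed = 1) {
  stopifnot(is_grid_stack(stack), inherits(occurrences, "occurrence_set"),
            is_env_grid(elevation))
  schemes <- match.arg(schemes, several.ok = TRUE)
  if ("targeted" %in% schemes && is.null(target_group))
    stop("targeted scheme requested but no target_group records supplied")
  if (is.null(priority)) priority <- stack_names(stack)
  structure(list(
    stack = stack, occurrences = occurrences, elevation = elevation,
    target_group = target_group, out_dir = out_dir, priority = priority,
    screen_threshold = screen_threshold, max_elev_m = max_elev_m,
    lat_floor = lat_floor, max_error_km = max_error_km,
    thin_min_km = thin_min_km, thin_reps = thin_reps,
    n_background = n_background, algorithms = algorithms,
    hyperparams = hyperparams, k = k, n_perm = n_perm,
    auc_min = auc_min, tss_min = tss_min, schemes = schemes,
    projections = projections, seed = as.integer(seed)),
    class = "run_config")
}

subset_stack <- function(stack, keep) {
  align_stack(stack$layers[keep])
}

#' Run the full modelling pipeline
#'
#' Executes, for each background scheme, the complete workflow: study-area
#' masking and occurrence cleaning; correlation screening of the candidate
#' layers over the study-area cells; spatial thinning (the `"random"` scheme
#' pairs thinned presences with a uniform random background; the
#' `"targeted"` scheme pairs un-thinned presences with a target-group
#' background); fitting and cross-validating each algorithm; evaluation
#' metrics and permutation importance; the ensemble mean map; and MESS
#' novelty surfaces for the training region and any projection regions.
#' All artifacts are written under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `metrics`, `importance`, `retained`
#'   (screened layer names), per-scheme ensembles and MESS maps, and the
#'   per-scheme `sdm_cv`/`sdm_fit` objects.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("sdmensemble %s | R %s", as.character(utils::packageVersion("sdmensemble")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("schemes: %s", paste(config$schemes, collapse = ", ")))

  say("stage: study mask + cleaning")
  mask <- build_study_mask(config$elevation, config$max_elev_m, config$lat_floor)
  cleaned <- clean_occurrences(config$occurrences, mask, config$max_error_km)
  write_occurrences(cleaned, file.path(config$out_dir, "occurrences_cleaned.csv"),
                    file.path(config$out_dir, "cleaning_log.csv"))

  say("stage: predictor screening")
  cell_vals <- extract_values(config$stack, cell_centers(config$stack$layers[[1]]))
  cell_vals <- cell_vals[cell_vals$valid & as.vector(mask_matrix(mask)),
                         stack_names(config$stack), drop = FALSE]
  # Kendall's tau is O(n^2) per pair; a few thousand cells estimate the
  # coefficients to well under the 0.70 decision margin
  if (nrow(cell_vals) > 2000L)
    cell_vals <- cell_vals[withr::with_seed(child_seed(config$seed, 5),
                                            sample(nrow(cell_vals), 2000L)), ,
                           drop = FALSE]
  cmat <- pairwise_max_correlation(cell_vals)
  retained <- screen_predictors(cmat, config$priority, config$screen_threshold)
  utils::write.csv(as.data.frame(cmat),
                   file.path(config$out_dir, "correlation_matrix.csv"))
  writeLines(retained, file.path(config$out_dir, "retained_layers.txt"))
  stack <- subset_stack(config$stack, retained)
  log_lines <- c(log_lines, sprintf("retained layers: %s",
                                    paste(retained, collapse = ", ")))

  presences <- list()
  backgrounds <- list()
  if ("random" %in% config$schemes) {
    say("stage: spatial thinning + random background")
    thinned <- thin_occurrences(cleaned, config$thin_min_km, config$thin_reps,
                                seed = child_seed(config$seed, 1))
    write_occurrences(thinned, file.path(config$out_dir, "occurrences_thinned.csv"))
    presences$random <- thinned
    backgrounds$random <- sample_random_background(
      mask, n = config$n_background, seed = child_seed(config$seed, 2))
    write_background(backgrounds$random,
                     file.path(config$out_dir, "background_random.csv"))
    log_lines <- c(log_lines,
                   sprintf("thinned records: %d (from %d)", n_records(thinned),
                           n_records(cleaned)))
  }
  if ("targeted" %in% config$schemes) {
    say("stage: target-group background")
    tg <- clean_occurrences(config$target_group, mask, config$max_error_km)
    presences$targeted <- cleaned
    backgrounds$targeted <- build_target_background(tg, list(cleaned), mask)
    write_background(backgrounds$targeted,
                     file.path(config$out_dir, "background_targeted.csv"))
    log_lines <- c(log_lines, sprintf("targeted background points: %d",
                                      backgrounds$targeted$n))
  }

  metrics <- list(); importance <- list(); result <- list(retained = retained)
  for (scheme in config$schemes) {
    say("stage: model fitting (", scheme, " scheme)")
    table <- make_training_table(stack, presences[[scheme]], backgrounds[[scheme]])
    cv_list <- list(); full_models <- list(); maps <- list()
    for (i in seq_along(config$algorithms)) {
      alg <- config$algorithms[i]
      s <- child_seed(config$seed, 100 * i + match(scheme, c("random", "targeted")))
      cv_list[[alg]] <- crossvalidate(table, alg, k = config$k,
                                      hyperparams = config$hyperparams[[alg]] %||% list(),
                                      seed = s)
      full_models[[alg]] <- fit_sdm(table, alg,
                                    hyperparams = config$hyperparams[[alg]] %||% list(),
                                    seed = child_seed(s, 7))
      maps[[alg]] <- predict_map(full_models[[alg]], stack)
    }
    metrics[[scheme]] <- evaluation_report(
      cv_list, full_models, background_method = scheme,
      auc_min = config$auc_min, tss_min = config$tss_min)
    say("stage: permutation importance (", scheme, " scheme)")
    imp <- importance_table(cv_list, n_perm = config$n_perm,
                            seed = child_seed(config$seed, 31))
    imp$background_method <- scheme
    importance[[scheme]] <- imp

    ens <- ensemble_mean(maps, name = paste0("ensemble_", scheme))
    write_grid(ens, file.path(config$out_dir, paste0("ensemble_", scheme, ".asc")))
    mess_train <- mess_map(table[, retained, drop = FALSE], stack)
    write_grid(mess_train$similarity,
               file.path(config$out_dir, paste0("mess_train_", scheme, ".asc")))
    result[[scheme]] <- list(table = table, cv = cv_list, models = full_models,
                             maps = maps, ensemble = ens, mess = mess_train)
    for (rg in names(config$projections)) {
      proj_stack <- subset_stack(config$projections[[rg]], retained)
      proj_maps <- lapply(full_models, predict_map, stack = proj_stack)
      proj_ens <- ensemble_mean(proj_maps, name = paste0("ensemble_", scheme, "_", rg))
      mm <- mess_map(table[, retained, drop = FALSE], proj_stack)
      write_grid(proj_ens, file.path(config$out_dir,
                                     sprintf("ensemble_%s_%s.asc", scheme, rg)))
      write_grid(mm$similarity, file.path(config$out_dir,
                                          sprintf("mess_%s_%s.asc", scheme, rg)))
      write_grid(mm$novelty, file.path(config$out_dir,
                                       sprintf("novelty_%s_%s.asc", scheme, rg)))
      result[[scheme]]$projection[[rg]] <- list(ensemble = proj_ens, mess = mm)
    }
  }

  metrics <- do.call(rbind, metrics); rownames(metrics) <- NULL
  importance <- do.call(rbind, importance); rownames(importance) <- NULL
  num <- vapply(metrics, is.numeric, logical(1)) & names(metrics) != "pcc"
  metrics[num] <- lapply(metrics[num], round, digits = 6)
  metrics$pcc <- round(metrics$pcc, 4)
  importance$delta_auc <- round(importance$delta_auc, 6)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  imp_out <- importance
  imp_out$delta_auc <- ifelse(is.na(imp_out$delta_auc), "na",
                              format(imp_out$delta_auc, trim = TRUE))
  utils::write.csv(imp_out, file.path(config$out_dir, "importance.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(log_lines, log_path)
  result$metrics <- metrics
  result$importance <- importance
  invisible(result)
}
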