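#' Run the full region-wise brain-age pipeline on a synthetic cohort
#'
#' End-to-end driver: generates the cohort, builds per-region maps for each
#' modality (injecting configured pathology into patient maps), selects key
#' voxels per region on the training controls, trains one GP brain-age model
#' per region with k-fold cross-validation and bias correction, applies every
#' model to the test cohort, and runs the region-wise group ANCOVA with FDR
#' correction plus (optionally) the clinical and dose regressions on regions
#' with significant group differences. All randomness derives from
#' `config$seed`, so two runs with the same configuration are identical.
#'
#' By default FC maps are generated directly at region level in Fisher-z
#' units (same data model as maps built from BOLD series); set
#' `fc_from_bold = TRUE` to synthesise BOLD series and build FC maps through
#' [build_fc_map()] — intended for reduced atlas sizes, since whole-volume
#' voxel-pair correlation scales quadratically in voxel count.
#'
#' @param config a [synthetic_config()].
#' @param selection a [selection_params()].
#' @param k_folds cross-validation folds (default 5).
#' @param alpha significance level on adjusted p values (default 0.05).
#' @param fdr_family "modality" or "joint" (see [group_compare_regions()]).
#' @param run_regressions run [clinical_regression()] / [cpz_regression()]
#'   on significant regions (default TRUE when patients are present).
#' @param fc_from_bold build FC maps from synthetic BOLD series.
#' @param verbose print one progress line per modality.
#' @return object of class `result_bundle`: list with `subjects`, `models`
#'   (per-region summary data frame), `model_objects`, `masks`, `estimates`
#'   (test-cohort long table), `group_tests`, `duration_tests` (clinical
#'   regressions), `cpz_tests`, `truth`, `config`, `provenance`.
#' @export
run_full <- function(config = synthetic_config(),
                     selection = selection_params(),
                     k_folds = 5L, alpha = 0.05,
                     fdr_family = c("modality", "joint"),
                     run_regressions = TRUE,
                     fc_from_bold = FALSE,
                     verbose = TRUE) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(config, "synthetic_config"),
            inherits(selection, "selection_params"))
  t0 <- Sys.time()
  subjects <- generate_subjects(config)
  train_rows <- which(subjects$cohort == "train")
  test_rows <- which(subjects$cohort == "test")

  model_rows <- list()
  model_objects <- list()
  masks <- list()
  estimates <- list()
  truth <- list()

  for (m in names(config$n_regions)) {
    atlas <- make_grid_atlas(m, n_regions = config$n_regions[[m]],
                             voxels_per_region = config$voxels_per_region)
    if (m == "FC" && fc_from_bold) {
      bold <- generate_bold(subjects, atlas, config)
      maps <- fc_maps_from_bold(bold, atlas)
    } else {
      maps <- generate_region_maps(subjects, atlas, config)
    }
    maps <- inject_pathology(maps, subjects, config$effect_spec,
                             config$duration_scaled)
    truth[[m]] <- maps$truth
    ages_train <- subjects$chronological_age[train_rows]
    for (key in names(maps$values)) {
      rid <- as.integer(key)
      vals_train <- maps$values[[key]][train_rows, , drop = FALSE]
      mask <- select_features(vals_train, ages_train, selection,
                              seed = substream_seed(config$seed, "select", m, rid))
      model <- train_region_model(
        vals_train[, mask$selected_voxels, drop = FALSE], ages_train,
        k_folds = k_folds,
        seed = substream_seed(config$seed, "train", m, rid),
        modality = m, region_id = rid, mask = mask)
      masks[[m]][[key]] <- mask
      model_objects[[m]][[key]] <- model
      model_rows[[length(model_rows) + 1L]] <- data.frame(
        modality = m, region_id = rid,
        n_features = length(mask$selected_voxels),
        alpha = model$alpha, beta = model$beta,
        cv_mae = model$cv_mae, cv_r = model$cv_r,
        stringsAsFactors = FALSE)
      if (length(test_rows) > 0L) {
        est <- apply_model(
          model,
          maps$values[[key]][test_rows, mask$selected_voxels, drop = FALSE],
          subjects[test_rows, , drop = FALSE])
        estimates[[length(estimates) + 1L]] <- est
      }
    }
    if (verbose) {
      done <- do.call(rbind, model_rows)
      done <- done[done$modality == m, , drop = FALSE]
      message(sprintf("[%s] %d models trained (mean cv MAE %.2f y, mean cv r %.3f)",
                      m, nrow(done), mean(done$cv_mae), mean(done$cv_r)))
    }
  }

  models <- do.call(rbind, model_rows)
  estimates <- if (length(estimates)) do.call(rbind, estimates) else NULL
  test_subjects <- subjects[test_rows, , drop = FALSE]

  group_tests <- NULL
  duration_tests <- NULL
  cpz_tests <- NULL
  if (!is.null(estimates) && length(unique(test_subjects$group)) == 2L) {
    group_tests <- group_compare_regions(estimates, test_subjects,
                                         fdr_family = fdr_family)
    if (isTRUE(run_regressions)) {
      sig <- group_tests[group_tests$p_adjusted < alpha, , drop = FALSE]
      scz <- test_subjects[test_subjects$group == "SCZ", , drop = FALSE]
      reg_rows <- list(); cpz_rows <- list()
      for (i in seq_len(nrow(sig))) {
        sel <- estimates$modality == sig$modality[i] &
          estimates$region_id == sig$region_id[i] &
          estimates$subject_id %in% scz$subject_id
        g <- estimates$brain_age_gap[sel][match(scz$subject_id,
                                                estimates$subject_id[sel])]
        reg <- tryCatch(
          suppressMessages(clinical_regression(g, scz)),
          error = function(e) NULL)
        if (!is.null(reg)) {
          reg_rows[[length(reg_rows) + 1L]] <-
            cbind(sig[i, c("modality", "region_id")], reg, row.names = NULL)
        }
        cpz <- tryCatch(
          suppressMessages(cpz_regression(g, scz)),
          error = function(e) NULL)
        if (!is.null(cpz)) {
          cpz_rows[[length(cpz_rows) + 1L]] <-
            cbind(sig[i, c("modality", "region_id")], cpz, row.names = NULL)
        }
      }
      adjust_by_predictor <- function(tab) {
        if (is.null(tab)) return(NULL)
        tab$p_adjusted <- NA_real_
        for (pr in unique(tab$predictor)) {
          sel <- tab$predictor == pr
          tab$p_adjusted[sel] <- fdr_adjust(tab$p_value[sel])
        }
        tab
      }
      duration_tests <- adjust_by_predictor(
        if (length(reg_rows)) do.call(rbind, reg_rows) else NULL)
      cpz_tests <- adjust_by_predictor(
        if (length(cpz_rows)) do.call(rbind, cpz_rows) else NULL)
    }
  }

  structure(
    list(subjects = subjects, models = models, model_objects = model_objects,
         masks = masks, estimates = estimates, group_tests = group_tests,
         duration_tests = duration_tests, cpz_tests = cpz_tests,
         truth = truth, config = config,
         provenance = list(seed = config$seed,
                           n_models = nrow(models),
                           alpha = alpha, fdr_family = fdr_family,
                           elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs")),
                           r_version = as.character(getRversion()))),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %d region models over %d subjects\n",
              nrow(x$models), nrow(x$subjects)))
  for (m in unique(x$models$modality)) {
    sel <- x$models$modality == m
    cat(sprintf("  %s: %d models, mean cv MAE %.2f y, mean cv r %.3f\n",
                m, sum(sel), mean(x$models$cv_mae[sel]),
                mean(x$models$cv_r[sel])))
  }
  if (!is.null(x$group_tests)) {
    cat(sprintf("  group ANCOVA: %d/%d regions FDR-significant\n",
                sum(x$group_tests$p_adjusted < x$provenance$alpha),
                nrow(x$group_tests)))
  }
  invisible(x)
}

#' Write the pipeline report tables
#'
#' Emits the per-region performance table, the significant-region table
#' (adjusted p below the bundle's alpha, sorted by descending partial
#' eta-squared, ties by region id), the regression tables, the test-cohort
#' estimates, and a JSON summary. All tables are TSV with 6-decimal floats,
#' so regenerating the report from the same bundle is byte-identical.
#'
#' @param bundle a `result_bundle` from [run_full()].
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  missing <- c("models", "subjects")[c(is.null(bundle$models),
                                       is.null(bundle$subjects))]
  if (length(missing)) {
    stop("incomplete bundle; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  path <- function(f) file.path(dir, f)

  write_tsv6(bundle$models, path("model_performance.tsv"))
  files <- c(files, path("model_performance.tsv"))

  if (!is.null(bundle$group_tests)) {
    gt <- bundle$group_tests
    write_tsv6(gt[order(gt$modality, gt$region_id), ], path("group_tests.tsv"))
    sig <- gt[gt$p_adjusted < bundle$provenance$alpha, , drop = FALSE]
    sig <- sig[order(-sig$partial_eta_sq, sig$region_id), , drop = FALSE]
    write_tsv6(sig, path("significant_regions.tsv"))
    files <- c(files, path("group_tests.tsv"), path("significant_regions.tsv"))
  }
  if (!is.null(bundle$duration_tests)) {
    write_tsv6(bundle$duration_tests, path("clinical_regressions.tsv"))
    files <- c(files, path("clinical_regressions.tsv"))
  }
  if (!is.null(bundle$cpz_tests)) {
    write_tsv6(bundle$cpz_tests, path("cpz_regressions.tsv"))
    files <- c(files, path("cpz_regressions.tsv"))
  }
  if (!is.null(bundle$estimates)) {
    write_tsv6(bundle$estimates, path("estimates.tsv"))
    files <- c(files, path("estimates.tsv"))
  }
  summary <- list(
    seed = bundle$provenance$seed,
    n_models = bundle$provenance$n_models,
    n_models_by_modality = as.list(table(bundle$models$modality)),
    mean_cv_mae = as.list(tapply(bundle$models$cv_mae,
                                 bundle$models$modality, mean)),
    mean_cv_r = as.list(tapply(bundle$models$cv_r,
                               bundle$models$modality, mean)),
    alpha = bundle$provenance$alpha,
    fdr_family = bundle$provenance$fdr_family,
    r_version = bundle$provenance$r_version
  )
  if (!is.null(bundle$group_tests)) {
    summary$n_significant_by_modality <- as.list(
      tapply(bundle$group_tests$p_adjusted < bundle$provenance$alpha,
             bundle$group_tests$modality, sum))
  }
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, path("summary.json"))
  invisible(files)
}
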