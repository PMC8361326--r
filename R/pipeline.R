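#' Run configuration for the end-to-end pipeline
#'
#' @param manifest Path to a subject manifest CSV.
#' @param out_dir Output directory for artifacts.
#' @param mode `"multi"`, `"fused"`, `"fn"`, `"fa"` or `"md"` (mapped to
#'   the [loocv()] modes).
#' @param selection `"fscore"` or `"lasso"`.
#' @param kernel `"linear"`, `"poly"` or `"rbf"`.
#' @param c_grid,fraction_grid Hyperparameter grids; length-1 grids skip
#'   the search and run a single LOOCV.
#' @param positive_group Manifest group coded +1 (patients).
#' @param seed Integer seed recorded in all outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, out_dir, mode = "multi",
                       selection = "fscore", kernel = "linear",
                       c_grid = 1, fraction_grid = 0.0014,
                       positive_group = NULL, seed = 1L) {
  mode <- match.arg(mode, c("multi", "fused", "fn", "fa", "md"))
  kernel <- match.arg(kernel, c("linear", "poly", "rbf"))
  if (length(c_grid) == 0 || length(fraction_grid) == 0)
    stop("grids must be non-empty")
  structure(list(manifest = manifest, out_dir = out_dir, mode = mode,
                 selection = match.arg(selection, c("fscore", "lasso")),
                 kernel = kernel, c_grid = c_grid,
                 fraction_grid = fraction_grid,
                 positive_group = positive_group, seed = as.integer(seed)),
            class = "run_config")
}

.loocv_mode <- function(mode) switch(mode,
  multi = "multi_kernel", fused = "single_kernel_fused",
  fn = "single_network:FN", fa = "single_network:FA",
  md = "single_network:MD")

.kernel_of <- function(kernel) switch(kernel,
  linear = kernel_spec("linear"),
  poly = kernel_spec("polynomial"),
  rbf = kernel_spec("rbf"))

#' Export an evaluation report to JSON and CSV artifacts
#'
#' Writes `<prefix>.json` (counts, metrics, config, seed, per-fold
#' records), `<prefix>_folds.csv` and `<prefix>_roc.csv`.
#'
#' @param report An `evaluation_report`.
#' @param prefix Output path prefix.
#' @param extra Named list merged into the JSON root (e.g. resolved
#'   config).
#' @return Invisibly, the JSON path.
#' @export
write_evaluation_report <- function(report, prefix, extra = list()) {
  folds_df <- data.frame(
    test_subject_id = vapply(report$folds, `[[`, character(1), "test_subject_id"),
    true_label = vapply(report$folds, `[[`, numeric(1), "true_label"),
    predicted_label = vapply(report$folds, `[[`, numeric(1), "predicted_label"),
    decision_value = vapply(report$folds, `[[`, numeric(1), "decision_value"),
    n_selected = vapply(report$folds, function(f)
      length(f$selected_features), numeric(1)))
  utils::write.csv(folds_df, paste0(prefix, "_folds.csv"), row.names = FALSE)
  utils::write.csv(report$roc_points, paste0(prefix, "_roc.csv"),
                   row.names = FALSE)
  obj <- c(list(counts = as.list(report$counts),
                accuracy = report$accuracy,
                sensitivity = report$sensitivity,
                specificity = report$specificity, auc = report$auc,
                config = list(C = report$config$C,
                              count_or_fraction = report$config$count_or_fraction,
                              kernel = report$config$kernel[c("kind", "degree", "gamma", "coef0")],
                              selection = report$config$selection,
                              mode = report$config$mode,
                              seed = report$config$seed),
                folds = lapply(report$folds, function(f)
                  list(test_subject_id = f$test_subject_id,
                       true_label = f$true_label,
                       predicted_label = f$predicted_label,
                       decision_value = f$decision_value,
                       beta = f$beta,
                       n_selected = length(f$selected_features)))),
           extra)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full classification pipeline on a manifest
#'
#' Reads the cohort, vectorizes it, runs LOOCV (or a grid search when any
#' grid has more than one point), writes the evaluation artifacts, the
#' accuracy surface and — for linear-kernel runs — the discriminative
#' consensus-feature report, plus a run log embedding the resolved
#' configuration, seed and package version.
#'
#' @param config A [run_config()].
#' @return The evaluation report of the (best) configuration, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- read_manifest(config$manifest, config$positive_group)
  tab <- vectorize_cohort(man$cohort, man$subject_ids)
  spec <- .kernel_of(config$kernel)
  mode <- .loocv_mode(config$mode)
  if (length(config$c_grid) > 1 || length(config$fraction_grid) > 1) {
    gs <- grid_search(tab, config$c_grid, config$fraction_grid, spec,
                      config$selection, mode, seed = config$seed)
    report <- gs$best$report
    utils::write.csv(gs$surface,
                     file.path(config$out_dir, "accuracy_surface.csv"),
                     row.names = FALSE)
  } else {
    report <- loocv(tab, config$c_grid, config$fraction_grid, spec,
                    config$selection, mode, seed = config$seed)
  }
  resolved <- list(resolved_config = c(
    config[c("manifest", "out_dir", "mode", "selection", "kernel",
             "c_grid", "fraction_grid", "seed")],
    list(package_version = as.character(utils::packageVersion("mklconn")))))
  write_evaluation_report(report, file.path(config$out_dir, "evaluation"),
                          extra = resolved)
  if (config$kernel == "linear") {
    rep2 <- discriminative_report(tab, report$folds)
    write_discriminative_report(rep2, tab,
                                file.path(config$out_dir, "discriminative"))
  }
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(sprintf("mklconn %s", utils::packageVersion("mklconn")),
               sprintf("seed: %d", config$seed),
               sprintf("mode: %s  selection: %s  kernel: %s",
                       config$mode, config$selection, config$kernel),
               sprintf("C grid: %s", paste(config$c_grid, collapse = " ")),
               sprintf("fraction grid: %s",
                       paste(config$fraction_grid, collapse = " ")),
               sprintf("subjects: %d  features: %d",
                       nrow(tab$features), ncol(tab$features)),
               sprintf("accuracy: %.4f  sensitivity: %.4f  specificity: %.4f  auc: %.4f",
                       report$accuracy, report$sensitivity,
                       report$specificity, report$auc)),
             log_path)
  invisible(report)
}
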