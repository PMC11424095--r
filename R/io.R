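#' Write experiment results to a directory
#'
#' Serializes an experiment to plain-text files: `snapshots.csv` (tidy
#' per-run, per-test-epoch unit activities), `metrics.csv` (per-run,
#' per-epoch metrics), `aggregate.csv` (condition-level means and 95%
#' confidence intervals), `classification.csv` (per-run labels),
#' `config.json` (the fully resolved configuration plus per-run seeds, for
#' provenance), and `run.log`.  Re-reading the CSVs reproduces the
#' in-memory tables.
#'
#' @param result An `nmph_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "nmph_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- experiment_metrics(result)
  paths <- c(
    snapshots = file.path(dir, "snapshots.csv"),
    metrics = file.path(dir, "metrics.csv"),
    aggregate = file.path(dir, "aggregate.csv"),
    classification = file.path(dir, "classification.csv"),
    config = file.path(dir, "config.json"),
    log = file.path(dir, "run.log")
  )
  utils::write.csv(result$snapshots, paths["snapshots"], row.names = FALSE)
  utils::write.csv(metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(aggregate_runs(metrics), paths["aggregate"],
                   row.names = FALSE)
  utils::write.csv(classify_runs(result), paths["classification"],
                   row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$resolved <- list(study = result$study,
                       condition = as.character(result$condition),
                       osc_variant = result$osc_variant,
                       lrate = result$lrate,
                       n_runs = result$n_runs, n_epochs = result$n_epochs,
                       seed = result$seed, run_seeds = result$run_seeds)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(
    sprintf("study: %s", result$study),
    sprintf("condition: %s", as.character(result$condition)),
    sprintf("runs: %d  epochs: %d  lrate: %g", result$n_runs,
            result$n_epochs, result$lrate),
    sprintf("master seed: %d", result$seed),
    sprintf("run seeds: %s", paste(result$run_seeds, collapse = " "))
  ), paths["log"])
  invisible(paths)
}

#' Read back a snapshots table
#'
#' @param dir Directory previously written by [write_results()].
#' @return The snapshots tibble.
#' @export
read_snapshots <- function(dir) {
  tibble::as_tibble(utils::read.csv(file.path(dir, "snapshots.csv"),
                                    stringsAsFactors = FALSE))
}
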