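#' Tidy an experiment into per-run, per-epoch metrics
#'
#' @param x An `nmph_experiment`.
#' @param ... Unused.
#' @return The tibble from [experiment_metrics()].
#' @export
tidy.nmph_experiment <- function(x, ...) {
  experiment_metrics(x)
}

#' One-row summary of an experiment
#'
#' @param x An `nmph_experiment`.
#' @param delta Band half-width for run classification.
#' @param ... Unused.
#' @return A one-row tibble: condition, run counts by classification,
#'   baseline and final mean within-pair correlation.
#' @export
glance.nmph_experiment <- function(x, delta = 0.1, ...) {
  cls <- classify_runs(x, delta = delta)
  tibble::tibble(
    study = x$study,
    condition = as.character(x$condition),
    lrate = x$lrate,
    n_runs = x$n_runs,
    n_epochs = x$n_epochs,
    mean_baseline_correlation = mean(cls$baseline, na.rm = TRUE),
    mean_final_correlation = mean(cls$final, na.rm = TRUE),
    n_differentiated = sum(cls$label == "differentiated"),
    n_integrated = sum(cls$label == "integrated"),
    n_unchanged = sum(cls$label == "unchanged")
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
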