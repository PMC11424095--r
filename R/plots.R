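#' Plot within-pair correlation trajectories
#'
#' One line per model run (test epochs on the x-axis), with the across-run
#' mean overlaid; the horizontal band marks the baseline correlation.
#' This is the per-run view in which abrupt differentiation and the
#' bimodal split between anticorrelated and integrated runs are visible.
#'
#' @param object An `nmph_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmph_experiment <- function(object, ...) {
  metrics <- experiment_metrics(object)
  baseline <- mean(metrics$within_pair_correlation[metrics$epoch == 0],
                   na.rm = TRUE)
  means <- metrics |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(m = mean(.data$within_pair_correlation, na.rm = TRUE))
  ggplot2::ggplot(metrics,
                  ggplot2::aes(.data$epoch, .data$within_pair_correlation)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = baseline - 0.02, ymax = baseline + 0.02,
                      fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(group = .data$run),
                       colour = "#7b5ea7", alpha = 0.35) +
    ggplot2::geom_line(data = means, ggplot2::aes(.data$epoch, .data$m),
                       linewidth = 1, colour = "black") +
    ggplot2::labs(
      x = "test epoch", y = "within-pair correlation (hidden layer)",
      title = sprintf("%s / %s (lrate %g)", object$study,
                      object$condition, object$lrate)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Compare conditions on a summary metric
#'
#' Condition-level means with 95% confidence intervals at baseline and
#' after learning, in the style of the aggregate result panels: one
#' point-range per condition and epoch extreme.
#'
#' @param results A list of `nmph_experiment` objects.
#' @param metric Metric column from [experiment_metrics()].
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(results,
                                   metric = "within_pair_correlation") {
  agg <- dplyr::bind_rows(lapply(results, function(r) {
    aggregate_runs(experiment_metrics(r), vars = metric)
  }))
  agg <- agg |>
    dplyr::filter(.data$epoch %in% c(0, max(.data$epoch))) |>
    dplyr::mutate(when = ifelse(.data$epoch == 0, "before", "after"),
                  when = factor(.data$when, c("before", "after")))
  ggplot2::ggplot(agg, ggplot2::aes(.data$condition, .data$mean,
                                    colour = .data$when)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "condition", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Aligned MDS plot of representational change
#'
#' Draws, for every run, the aligned 2-D embedding of the four per-run
#' hidden patterns (pairmate 1/2 before/after learning), with optional
#' plotting-only jitter to separate coincident points.
#'
#' @param result An `nmph_experiment`.
#' @param jitter Standard deviation of the optional visual jitter, in
#'   embedded units (0 disables it).
#' @return A ggplot object.
#' @export
plot_mds <- function(result, jitter = 0.05) {
  hid <- snapshot_patterns(result, "hidden") |>
    dplyr::left_join(result$pairmate1, by = "run") |>
    dplyr::mutate(
      pairmate = ifelse(.data$stimulus == .data$pairmate1, 1L, 2L)) |>
    dplyr::filter(.data$epoch %in% c(0L, max(.data$epoch)))
  final_epoch <- max(hid$epoch)
  coords <- hid |>
    dplyr::mutate(when = ifelse(.data$epoch == 0, "before", "after")) |>
    dplyr::select("run", "pairmate", "when", "pattern") |>
    tidyr::pivot_wider(names_from = c("pairmate", "when"),
                       values_from = "pattern") |>
    dplyr::group_by(.data$run) |>
    dplyr::reframe(mds_embed_align(.data$`1_before`[[1]],
                                   .data$`2_before`[[1]],
                                   .data$`1_after`[[1]],
                                   .data$`2_after`[[1]]))
  if (jitter > 0) {
    coords$x <- coords$x + stats::rnorm(nrow(coords), 0, jitter)
    coords$y <- coords$y + stats::rnorm(nrow(coords), 0, jitter)
  }
  ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y,
                                       colour = .data$point)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s / %s: hidden-layer MDS (epoch 0 vs %d)",
                                  result$study, result$condition,
                                  final_epoch),
                  x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
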