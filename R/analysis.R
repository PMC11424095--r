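#' Within-pair Pearson correlation of two activity patterns
#'
#' @param pattern_a,pattern_b Equal-length activity vectors (e.g. the
#'   hidden-layer patterns evoked by the two pairmates at test).
#' @return The product-moment correlation, or `NA` if either pattern has
#'   zero variance (flagged undefined; excluded from aggregates).
#' @export
within_pair_correlation <- function(pattern_a, pattern_b) {
  stopifnot(length(pattern_a) == length(pattern_b))
  if (stats::sd(pattern_a) == 0 || stats::sd(pattern_b) == 0) {
    return(NA_real_)
  }
  stats::cor(pattern_a, pattern_b)
}

#' Center of mass of a topographic activity pattern
#'
#' The activity-weighted mean unit position, used as the model's color
#' "report" in the topographic output layer.
#'
#' @param pattern Non-negative activity vector.
#' @return Position in unit coordinates, or `NA` for an all-zero pattern.
#' @export
center_of_mass <- function(pattern) {
  total <- sum(pattern)
  if (total <= 0) return(NA_real_)
  sum(seq_along(pattern) * pattern) / total
}

#' Repulsion and attraction metrics from baseline and final snapshots
#'
#' Computes the change in distance between the two pairmates' output
#' centers-of-mass (positive = repulsion, negative = attraction) and a
#' signed per-pairmate color error: each pairmate's center-of-mass
#' displacement, signed so that movement away from the competitor is
#' negative and movement toward it positive.
#'
#' @param baseline_1,baseline_2 Output patterns for pairmates 1 and 2
#'   before learning.
#' @param final_1,final_2 Output patterns after learning.
#' @return A list with `com_distance_change`, `color_error_1`,
#'   `color_error_2`, and the four centers-of-mass.
#' @export
repulsion_metrics <- function(baseline_1, baseline_2, final_1, final_2) {
  com_b1 <- center_of_mass(baseline_1)
  com_b2 <- center_of_mass(baseline_2)
  com_f1 <- center_of_mass(final_1)
  com_f2 <- center_of_mass(final_2)
  toward_1 <- sign(com_b2 - com_b1)  # direction from pairmate 1 toward 2
  list(
    com_distance_change = abs(com_f1 - com_f2) - abs(com_b1 - com_b2),
    color_error_1 = (com_f1 - com_b1) * toward_1,
    color_error_2 = (com_f2 - com_b2) * -toward_1,
    com_baseline_1 = com_b1, com_baseline_2 = com_b2,
    com_final_1 = com_f1, com_final_2 = com_f2
  )
}

#' Classify one run's correlation time series
#'
#' A run is `differentiated` if its final within-pair correlation falls
#' more than `delta` below baseline, `integrated` if more than `delta`
#' above, otherwise `unchanged`.  The onset epoch is the first test epoch
#' at which the series leaves the `delta` band in the final direction.
#'
#' @param correlations Within-pair correlations by test epoch, the first
#'   entry being the baseline (epoch 0).
#' @param delta Half-width of the "unchanged" band (correlation units).
#' @return A list with `label`, `onset_epoch` (`NA` when unchanged) and
#'   the baseline/final correlations.
#' @export
classify_run <- function(correlations, delta = 0.1) {
  baseline <- correlations[1]
  final <- correlations[length(correlations)]
  label <- if (is.na(final) || is.na(baseline)) {
    "unchanged"
  } else if (final < baseline - delta) {
    "differentiated"
  } else if (final > baseline + delta) {
    "integrated"
  } else {
    "unchanged"
  }
  onset <- NA_integer_
  if (label != "unchanged") {
    dir_ok <- if (label == "differentiated") {
      correlations < baseline - delta
    } else {
      correlations > baseline + delta
    }
    idx <- which(dir_ok)
    idx <- idx[idx > 1]
    if (length(idx)) onset <- idx[1] - 1L  # epochs are 0-based
  }
  list(label = label, onset_epoch = onset,
       baseline = baseline, final = final)
}

#' Asymmetry of representational change
#'
#' Attributes movement to pairmates from the Euclidean displacement of
#' each pairmate's hidden pattern relative to its own baseline.  If
#' neither moves appreciably the answer is `"neither"`; if one pairmate
#' moves at least twice as far as the other it is named; otherwise
#' `"both"`.
#'
#' @param displacement_1,displacement_2 Euclidean displacements of
#'   pairmates 1 and 2 from their own baselines.
#' @param min_move Displacement below which a pairmate counts as anchored.
#' @return One of `"neither"`, `"pairmate1"`, `"pairmate2"`, `"both"`.
#' @export
asymmetry_label <- function(displacement_1, displacement_2,
                            min_move = 0.25) {
  if (max(displacement_1, displacement_2) < min_move) return("neither")
  if (displacement_1 >= 2 * displacement_2) return("pairmate1")
  if (displacement_2 >= 2 * displacement_1) return("pairmate2")
  "both"
}

#' Aligned 2-D multidimensional scaling of four patterns
#'
#' Classical metric MDS of the pairwise Euclidean distances between the
#' four per-run patterns (pairmate 1/2 before/after learning), followed
#' by a rigid transform and uniform scaling that places pairmate
#' 1-before at the origin and pairmate 2-before on the positive x-axis at
#' its baseline distance; the reflection is fixed so pairmate 2-after has
#' non-negative y.
#'
#' @param p1_before,p2_before,p1_after,p2_after Equal-length activity
#'   vectors.
#' @return A tibble with columns `point`, `x`, `y`, plus attribute
#'   `degenerate` when all four patterns coincide.
#' @export
mds_embed_align <- function(p1_before, p2_before, p1_after, p2_after) {
  pts <- rbind(p1_before, p2_before, p1_after, p2_after)
  d <- stats::dist(pts)
  labels <- c("pairmate1_before", "pairmate2_before",
              "pairmate1_after", "pairmate2_after")
  if (max(d) == 0) {
    out <- tibble::tibble(point = labels, x = 0, y = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xy <- stats::cmdscale(d, k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  # translate pairmate1_before to origin
  xy <- sweep(xy, 2, xy[1, ])
  # rotate pairmate2_before onto the positive x-axis
  ang <- atan2(xy[2, 2], xy[2, 1])
  rot <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  xy <- xy %*% t(rot)
  # fix the reflection
  if (xy[4, 2] < 0) xy[, 2] <- -xy[, 2]
  # uniform scale so the embedded baseline distance equals the true one
  emb <- sqrt(sum(xy[2, ]^2))
  true <- sqrt(sum((p1_before - p2_before)^2))
  if (emb > 0) xy <- xy * (true / emb)
  out <- tibble::tibble(point = labels, x = as.numeric(xy[, 1]),
                        y = as.numeric(xy[, 2]))
  attr(out, "degenerate") <- FALSE
  out
}

snapshot_patterns <- function(result, layer_name) {
  result$snapshots |>
    dplyr::filter(.data$layer == layer_name) |>
    dplyr::arrange(.data$run, .data$epoch, .data$stimulus,
                   .data$unit_index) |>
    dplyr::group_by(.data$run, .data$epoch, .data$stimulus) |>
    dplyr::summarise(pattern = list(.data$activity), .groups = "drop")
}

#' Per-run, per-epoch representational-change metrics
#'
#' Computes, for every run and test epoch, the within-pair correlation of
#' the hidden-layer patterns and (for topographic output layers) the
#' output centers-of-mass, their distance, and the signed per-pairmate
#' color errors relative to baseline.  Pairmate 1/2 are assigned by each
#' run's first training trial.
#'
#' @param result An `nmph_experiment`.
#' @return A tibble with one row per run and test epoch.
#' @export
experiment_metrics <- function(result) {
  stopifnot(inherits(result, "nmph_experiment"))
  hid <- snapshot_patterns(result, "hidden") |>
    dplyr::left_join(result$pairmate1, by = "run") |>
    dplyr::mutate(
      pairmate = ifelse(.data$stimulus == .data$pairmate1, 1L, 2L))
  wide <- hid |>
    dplyr::select("run", "epoch", "pairmate", "pattern") |>
    tidyr::pivot_wider(names_from = "pairmate", values_from = "pattern",
                       names_prefix = "p")
  out <- wide |>
    dplyr::mutate(
      within_pair_correlation = purrr::map2_dbl(
        .data$p1, .data$p2, within_pair_correlation))

  if (isTRUE(result$topographic_output)) {
    outp <- snapshot_patterns(result, "output") |>
      dplyr::left_join(result$pairmate1, by = "run") |>
      dplyr::mutate(
        pairmate = ifelse(.data$stimulus == .data$pairmate1, 1L, 2L)) |>
      dplyr::select("run", "epoch", "pairmate", "pattern") |>
      tidyr::pivot_wider(names_from = "pairmate", values_from = "pattern",
                         names_prefix = "o")
    out <- out |>
      dplyr::left_join(outp, by = c("run", "epoch")) |>
      dplyr::mutate(
        com_1 = purrr::map_dbl(.data$o1, center_of_mass),
        com_2 = purrr::map_dbl(.data$o2, center_of_mass),
        com_distance = abs(.data$com_1 - .data$com_2)) |>
      dplyr::group_by(.data$run) |>
      dplyr::mutate(
        com_distance_change = .data$com_distance -
          .data$com_distance[.data$epoch == 0],
        color_error_1 = (.data$com_1 - .data$com_1[.data$epoch == 0]) *
          sign(.data$com_2[.data$epoch == 0] - .data$com_1[.data$epoch == 0]),
        color_error_2 = (.data$com_2 - .data$com_2[.data$epoch == 0]) *
          -sign(.data$com_2[.data$epoch == 0] - .data$com_1[.data$epoch == 0])
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-"o1", -"o2")
  }
  out |>
    dplyr::select(-"p1", -"p2") |>
    dplyr::mutate(study = result$study,
                  condition = as.character(result$condition),
                  lrate = result$lrate, .before = 1)
}

#' Per-run classification of representational change
#'
#' Applies [classify_run()] to each run's correlation time series and
#' attributes asymmetry with [asymmetry_label()] from the final hidden
#' patterns.
#'
#' @param result An `nmph_experiment`.
#' @param delta Band half-width passed to [classify_run()].
#' @return A tibble with one row per run: `label`, `onset_epoch`,
#'   `baseline`, `final`, displacements and `asymmetry`.
#' @export
classify_runs <- function(result, delta = 0.1) {
  metrics <- experiment_metrics(result)
  cls <- metrics |>
    dplyr::arrange(.data$run, .data$epoch) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      res = list(classify_run(.data$within_pair_correlation, delta = delta)),
      .groups = "drop") |>
    dplyr::mutate(
      label = purrr::map_chr(.data$res, "label"),
      onset_epoch = purrr::map_int(.data$res, "onset_epoch"),
      baseline = purrr::map_dbl(.data$res, "baseline"),
      final = purrr::map_dbl(.data$res, "final")) |>
    dplyr::select(-"res")

  hid <- snapshot_patterns(result, "hidden") |>
    dplyr::left_join(result$pairmate1, by = "run") |>
    dplyr::mutate(
      pairmate = ifelse(.data$stimulus == .data$pairmate1, 1L, 2L)) |>
    dplyr::filter(.data$epoch %in% c(0L, max(.data$epoch)))
  disp <- hid |>
    dplyr::group_by(.data$run, .data$pairmate) |>
    dplyr::summarise(
      displacement = sqrt(sum((.data$pattern[[which(.data$epoch != 0)]] -
                               .data$pattern[[which(.data$epoch == 0)]])^2)),
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pairmate", values_from = "displacement",
                       names_prefix = "displacement_")
  cls |>
    dplyr::left_join(disp, by = "run") |>
    dplyr::mutate(asymmetry = purrr::map2_chr(
      .data$displacement_1, .data$displacement_2, asymmetry_label))
}

#' Condition-level aggregates with confidence intervals
#'
#' Means and Student-t 95% confidence intervals across runs, per epoch,
#' for each numeric metric column.
#'
#' @param metrics A tibble from [experiment_metrics()].
#' @param vars Metric columns to aggregate.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per epoch and metric: `mean`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
aggregate_runs <- function(metrics,
                           vars = c("within_pair_correlation",
                                    "com_distance_change",
                                    "color_error_1", "color_error_2"),
                           conf_level = 0.95) {
  vars <- intersect(vars, names(metrics))
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("study", "condition", "lrate", "epoch", "metric")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop") |>
    dplyr::mutate(
      # a single run has no dispersion estimate, so its interval is NA
      half = ifelse(.data$n > 1,
                    stats::qt(1 - (1 - conf_level) / 2,
                              pmax(.data$n - 1, 1)) * .data$se,
                    NA_real_),
      ci_lo = .data$mean - .data$half,
      ci_hi = .data$mean + .data$half) |>
    dplyr::select(-"half") |>
    dplyr::select(-"se")
}

#' @importFrom rlang .data
NULL
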