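#' Default configuration for a simulated study
#'
#' Returns the full parameter tree for one of the three simulated
#' paradigms: per-layer inhibitory/activity parameters, per-projection
#' weight ranges, scales and U-shaped learning parameters, and the
#' simulation schedule constants.  These defaults are the study conditions;
#' condition-specific structure (overlap, pre-wired associates, curricula)
#' is added by the corresponding network builder.
#'
#' @param study `"chanales"` (stimulus-similarity / color repulsion),
#'   `"favila"` (shared vs. different associates) or `"schlichting"`
#'   (blocked vs. interleaved curricula).
#' @return A nested list of class `nmph_config`.
#' @export
study_config <- function(study = c("chanales", "favila", "schlichting")) {
  study <- match.arg(study)
  thr <- 0.25  # default activation threshold; see the methods vignette
  base <- list(
    study = study,
    act_threshold = thr,
    net_gain = 1,  # global synaptic drive gain; see the methods vignette
    sim = list(n_runs = 50L, n_epochs = 20L, n_cycles = 200L, dt = 0.3,
               lrate = 1),
    layers = list(
      category = list(n_units = 3L, k = 1L, k_max = Inf, kwta_point = 0.75,
                      target_diff = 0, osc = 0, xx1_gain = 100,
                      clamp_gain = 2),
      item = list(n_units = 2L, k = 1L, k_max = Inf, kwta_point = 0.95,
                  target_diff = 0.2, osc = NA_real_, xx1_gain = 100,
                  clamp_gain = 0.3),
      hidden = list(n_units = 50L, k = 6L, k_max = 10L, kwta_point = NA_real_,
                    target_diff = NA_real_, osc = NA_real_, xx1_gain = 100,
                    clamp_gain = 0),
      output = list(n_units = NA_integer_, k = NA_integer_, k_max = Inf,
                    kwta_point = NA_real_, target_diff = NA_real_,
                    osc = NA_real_, xx1_gain = NA_real_, clamp_gain = 0)
    ),
    projections = list()
  )
  if (study == "chanales") {
    # Calibrated operating point (see the methods vignette, "Calibration"):
    # net_gain = 2 compensates the sender-averaged net-input convention;
    # per-layer activation thresholds position retrieval, competitor pop-up
    # and bystander recruitment relative to the layer drive scales.
    base$net_gain <- 2
    base$layers$hidden$act_threshold <- 0.15
    base$layers$output$act_threshold <- 0.09
    base$layers$item$act_threshold <- -0.16
    base$layers$category$act_threshold <- 0.05
    base$layers$item$osc <- 0.22
    base$layers$hidden[c("kwta_point", "target_diff", "osc")] <-
      list(0.75, 0.03, 0.11)
    base$layers$output[c("n_units", "k", "k_max", "kwta_point",
                         "target_diff", "osc", "xx1_gain")] <-
      list(50L, 6L, 15L, 0.95, 0.05, 0.115, 30)
    base$projections <- list(
      hidden_hidden = proj_cfg(c(0.45, 0.55), 1.8, 1.8,
                               c(0.15, 0.24, -4.5, 0.4, 0.1)),
      hidden_output = proj_cfg(c(0.01, 0.03), 3.0, 2.0,
                               c(0.1, 0.44, -10, 0.6, 1.5)),
      category_hidden = proj_cfg(c(0.01, 0.03), 0.2, 0.2,
                                 c(0.2, 0.3, -0.1, 0.46, 0.06)),
      item_hidden = proj_cfg(c(0.45, 0.55), 0.2, 0.2,
                             c(0.2, 0.3, -2.5, 0.46, 0.3)),
      output_output = proj_cfg(c(0.01, 0.03), 1.0, 1.0,
                               c(0.53, 0.6, -0.3, 0.68, 0.3),
                               learnable = FALSE)
    )
  } else if (study == "favila") {
    # Calibrated operating point (see the methods vignette, "Calibration"):
    # same rationale as the color model; the deep item threshold places the
    # competitor item's inhibition-trough pop-up so that its coactivity
    # with the shared units falls in the weakening dip.
    base$net_gain <- 2.5
    base$layers$item$act_threshold <- -0.23
    base$layers$category$act_threshold <- 0.05
    base$layers$item$osc <- 0.2
    base$layers$hidden[c("kwta_point", "target_diff", "osc")] <-
      list(0.8, 0.02, 0.067)
    base$layers$output[c("n_units", "k", "kwta_point", "target_diff",
                         "osc", "xx1_gain")] <-
      list(10L, 1L, 0.75, 0.03, 0.07, 100)
    base$projections <- list(
      hidden_hidden = proj_cfg(c(0.45, 0.55), 1.8, 1.8,
                               c(0.11, 0.23, -1.5, 0.4, 0.1)),
      hidden_output = proj_cfg(c(0.01, 0.03), 1.2, 1.7,
                               c(0.11, 0.23, -0.01, 0.4, 0.5)),
      category_hidden = proj_cfg(c(0.01, 0.03), 0.1, 0.1,
                                 c(0.2, 0.3, -0.1, 0.46, 0.06)),
      item_hidden = proj_cfg(c(0.45, 0.55), 0.3, 0.2,
                             c(0.215, 0.4, -2.5, 0.6, 0.3))
    )
  } else {
    # Calibrated operating point (see the methods vignette, "Calibration"):
    # same rationale as the other studies; chosen so the competitor pop-up
    # crosses the weakening dip as the oscillation amplitude grows.
    base$net_gain <- 2.4
    base$layers$item$act_threshold <- -0.23
    base$layers$category$act_threshold <- 0.05
    base$layers$item$osc <- 0.156
    base$layers$hidden[c("kwta_point", "target_diff", "osc")] <-
      list(0.8, 0.02, 0.0623)
    base$layers$output[c("n_units", "k", "kwta_point", "target_diff",
                         "osc", "xx1_gain")] <-
      list(10L, 1L, 0.75, 0.03, 0.03, 100)
    base$projections <- list(
      hidden_hidden = proj_cfg(c(0.45, 0.55), 1.9, 1.9,
                               c(0.11, 0.23, -1.5, 0.4, 1)),
      hidden_output = proj_cfg(c(0.01, 0.03), 1.2, 1.7,
                               c(0.11, 0.23, -0.01, 0.4, 0.5)),
      category_hidden = proj_cfg(c(0.01, 0.03), 0.2, 0.1,
                                 c(0.2, 0.3, -0.1, 0.46, 0.06)),
      item_hidden = proj_cfg(c(0.45, 0.55), 0.3, 0.2,
                             c(0.11, 0.23, -1.5, 0.4, 1))
    )
  }
  structure(base, class = "nmph_config")
}

proj_cfg <- function(wt_range, fwd, bwd, u, learnable = TRUE) {
  list(wt_range = wt_range, wt_scale_fwd = fwd, wt_scale_bwd = bwd,
       ushape = list(dthr = u[1], drev = u[2], drev_mag = u[3],
                     thrp = u[4], dmax_mag = u[5]),
       learnable = learnable)
}

#' Load and validate a configuration
#'
#' Starts from [study_config()] defaults, optionally merges a YAML or JSON
#' file, then applies programmatic overrides.  Unknown keys at any level
#' are rejected with an error naming the offending key, so typos never pass
#' silently.
#'
#' @param study Study name, as in [study_config()].
#' @param path Optional path to a YAML (`.yml`/`.yaml`) or JSON file whose
#'   structure mirrors the default tree.
#' @param overrides Optional named list merged on top (same structure).
#' @return The resolved `nmph_config`.
#' @export
load_config <- function(study = c("chanales", "favila", "schlichting"),
                        path = NULL, overrides = list()) {
  cfg <- study_config(study)
  if (!is.null(path)) {
    from_file <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- merge_config(cfg, from_file, "")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "")
  structure(cfg, class = "nmph_config")
}

merge_config <- function(base, upd, prefix) {
  if (!length(upd)) return(base)
  if (is.null(names(upd)) || any(names(upd) == "")) {
    stop("configuration overrides must be fully named (at '",
         prefix, "')", call. = FALSE)
  }
  for (key in names(upd)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(upd[[key]])) {
      base[[key]] <- merge_config(base[[key]], upd[[key]], full)
    } else {
      base[[key]] <- upd[[key]]
    }
  }
  base
}

config_layer <- function(cfg, name, act_threshold = NULL) {
  p <- cfg$layers[[name]]
  if (is.null(act_threshold)) {
    act_threshold <-
      if (!is.null(p$act_threshold)) p$act_threshold else cfg$act_threshold
  }
  layer_spec(name, n_units = p$n_units, k = p$k, k_max = p$k_max,
             kwta_point = p$kwta_point, target_diff = p$target_diff,
             osc = p$osc, xx1_gain = p$xx1_gain, clamp_gain = p$clamp_gain,
             act_threshold = act_threshold)
}

config_ushape <- function(cfg, name) {
  u <- cfg$projections[[name]]$ushape
  ushape_params(u$dthr, u$drev, u$drev_mag, u$thrp, u$dmax_mag)
}
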