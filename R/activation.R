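#' S-shaped rate-coded activation function
#'
#' Maps a unit's above-threshold drive to a firing rate in `[0, 1)` via
#' `g(x) = gain * x / (gain * x + 1)` with `x = max(0, net - threshold -
#' inhibition)`.  The function is monotone in the drive, bounded below 1,
#' and steeper for larger gains; low gains give a graded response that
#' permits moderate competitor pop-up.
#'
#' @param net_input Net excitatory input (vectorized).
#' @param inhibition Layer inhibition (scalar or vector).
#' @param gain Gain of the S-shaped nonlinearity (positive).
#' @param threshold Activation threshold.
#' @return Firing rates in `[0, 1)`.
#' @export
activation_function <- function(net_input, inhibition, gain, threshold) {
  x <- pmax(net_input - threshold - inhibition, 0)
  gain * x / (gain * x + 1)
}

#' Net excitatory input to one layer
#'
#' Sums the contribution of every projection touching the layer: each
#' contributes its directional weight scale times the mean, over sender
#' units, of weight times sender activity (division by the sending
#' layer's unit count), so the configured weight scales stay comparable
#' across layer sizes.
#' Recurrent projections contribute in a single pass.  Clamped external
#' input enters additively, multiplied by the layer's clamp gain.
#'
#' @param net An `nmph_network`.
#' @param layer_name Name of the receiving layer.
#' @param acts Named list of current activity vectors, one per layer.
#' @param ext Named list of external input patterns (or `NULL` entries).
#' @return Numeric vector of net inputs for the layer.
#' @export
compute_net_input <- function(net, layer_name, acts, ext = NULL) {
  layer <- net$layers[[layer_name]]
  gain <- if (is.null(net$net_gain)) 1 else net$net_gain
  out <- numeric(layer$n_units)
  for (p in net$projections) {
    if (p$receiver == layer_name) {
      ns <- net$layers[[p$sender]]$n_units
      out <- out + gain * p$wt_scale_fwd *
        drop(crossprod(p$weights, acts[[p$sender]])) / ns
    } else if (p$sender == layer_name && p$receiver != p$sender) {
      nr <- net$layers[[p$receiver]]$n_units
      out <- out + gain * p$wt_scale_bwd *
        drop(p$weights %*% acts[[p$receiver]]) / nr
    }
  }
  e <- ext[[layer_name]]
  if (!is.null(e) && layer$clamp_gain > 0) {
    out <- out + gain * layer$clamp_gain * e
  }
  out
}

#' One synchronous settling cycle (reference implementation)
#'
#' Updates every layer once, in the fixed per-cycle order: net inputs (from
#' the previous cycle's activities), kWTA inhibition, oscillation,
#' activation, running-average traces.  Activities move toward their
#' instantaneous target by a step `dt` (exponential approach).
#'
#' This pure-R path mirrors the compiled settling loop and is used for
#' small networks and testing; [run_trial()] with `compiled = TRUE` is the
#' fast path.
#'
#' @param net An `nmph_network`.
#' @param state Settling state as returned by [init_trial_state()].
#' @param ext Named list of external input patterns.
#' @param oscillate Logical: apply the inhibitory oscillation schedule
#'   (training trials only; test trials settle at baseline inhibition).
#' @param dt Integration step per cycle.
#' @return The updated state, with `cycle` incremented.
#' @export
settle_cycle <- function(net, state, ext, oscillate = TRUE, dt = 0.3) {
  cycle <- state$cycle + 1L
  tp <- trace_params()
  nets <- lapply(names(net$layers), function(nm) {
    compute_net_input(net, nm, state$act, ext)
  })
  names(nets) <- names(net$layers)
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    g_ranked <- inhibition_thresholds(nets[[nm]], l$act_threshold)
    kw <- kwta_inhibition(g_ranked, l$k, l$k_max, l$kwta_point, l$target_diff)
    gi <- if (oscillate) {
      oscillate_inhibition(kw$gi_base, l$osc, cycle)
    } else {
      kw$gi_base
    }
    target <- activation_function(nets[[nm]], gi, l$xx1_gain, l$act_threshold)
    a <- state$act[[nm]] + dt * (target - state$act[[nm]])
    state$act[[nm]] <- a
    state$net[[nm]] <- nets[[nm]]
    state$gi_base[[nm]] <- kw$gi_base
    state$gi_eff[[nm]] <- gi
    state$traces[[nm]] <- update_running_averages(state$traces[[nm]], a, tp)
  }
  state$cycle <- cycle
  state
}

#' Fresh per-trial settling state
#'
#' Activities and running-average traces start every trial at zero, so the
#' end-of-trial coactivities reflect that trial only.
#'
#' @param net An `nmph_network`.
#' @return A list with zeroed `act`, `net`, traces and `cycle = 0`.
#' @export
init_trial_state <- function(net) {
  zeros <- lapply(net$layers, function(l) numeric(l$n_units))
  traces <- lapply(net$layers, function(l) {
    list(mu_super_short = numeric(l$n_units),
         mu_short = numeric(l$n_units),
         mu_raw_medium = numeric(l$n_units),
         mu_medium = numeric(l$n_units))
  })
  list(act = zeros, net = zeros,
       gi_base = as.list(stats::setNames(numeric(length(net$layers)),
                                         names(net$layers))),
       gi_eff = as.list(stats::setNames(numeric(length(net$layers)),
                                        names(net$layers))),
       traces = traces, cycle = 0L)
}

#' Run one 200-cycle trial
#'
#' Presents a stimulus (external input patterns clamped to the input
#' layers) and settles the network for `n_cycles` synchronous cycles.  In
#' training mode the inhibitory oscillation runs from cycle 125 and the
#' U-shaped weight update is applied once at the end of the trial; in test
#' mode oscillations are off and no weights change, so test trials are
#' side-effect free.
#'
#' @param net An `nmph_network`.
#' @param stimulus Named list of external input vectors, one per clamped
#'   layer; each input layer must have exactly one active unit.
#' @param mode `"train"` or `"test"`.
#' @param n_cycles Number of settling cycles (default 200).
#' @param dt Integration step per cycle.
#' @param compiled Use the compiled settling loop (default) or the pure-R
#'   reference path.
#' @param record_gi Also return per-cycle baseline and effective inhibition
#'   for each layer.
#' @param record_act Also return the full per-cycle activity matrices.
#' @return A list with `network` (weights updated in train mode), `act`
#'   (final activities per layer), `mu_medium` (end-of-trial medium-term
#'   traces per layer), and optionally `gi` / `act_history`.
#' @export
run_trial <- function(net, stimulus, mode = c("train", "test"),
                      n_cycles = 200L, dt = 0.3, compiled = TRUE,
                      record_gi = FALSE, record_act = FALSE) {
  mode <- match.arg(mode)
  validate_stimulus(net, stimulus)
  train <- mode == "train"
  ext <- stimulus_ext(net, stimulus)
  if (compiled) {
    res <- run_trial_compiled(net, ext, train, n_cycles, dt,
                              record_gi, record_act)
  } else {
    res <- run_trial_reference(net, ext, train, n_cycles, dt,
                               record_gi, record_act)
  }
  res
}

run_trial_reference <- function(net, ext, train, n_cycles, dt,
                                record_gi, record_act) {
  state <- init_trial_state(net)
  gi_log <- if (record_gi) vector("list", n_cycles) else NULL
  act_log <- if (record_act) vector("list", n_cycles) else NULL
  for (cycle in seq_len(n_cycles)) {
    state <- settle_cycle(net, state, ext, oscillate = train, dt = dt)
    if (record_gi) {
      gi_log[[cycle]] <- list(gi_base = unlist(state$gi_base),
                              gi_eff = unlist(state$gi_eff))
    }
    if (record_act) act_log[[cycle]] <- state$act
  }
  if (train && net$lrate > 0) {
    mu <- lapply(state$traces, `[[`, "mu_medium")
    for (i in seq_along(net$projections)) {
      p <- net$projections[[i]]
      if (!p$learnable) next
      net$projections[[i]]$weights <- trial_weight_update(
        p$weights, mu[[p$sender]], mu[[p$receiver]], p$ushape,
        lrate = net$lrate, recurrent = identical(p$sender, p$receiver))
    }
  }
  out <- list(network = net, act = state$act,
              mu_medium = lapply(state$traces, `[[`, "mu_medium"))
  if (record_gi) out$gi <- gi_log
  if (record_act) out$act_history <- act_log
  out
}

run_trial_compiled <- function(net, ext, train, n_cycles, dt,
                               record_gi, record_act) {
  lnames <- names(net$layers)
  gain0 <- if (is.null(net$net_gain)) 1 else net$net_gain
  layers_c <- lapply(net$layers, function(l) {
    list(n = l$n_units, k = l$k, k_max = l$k_max, kwta_point = l$kwta_point,
         target_diff = l$target_diff, osc = l$osc, gain = l$xx1_gain,
         clamp_gain = gain0 * l$clamp_gain, threshold = l$act_threshold)
  })
  gain <- if (is.null(net$net_gain)) 1 else net$net_gain
  proj_c <- lapply(net$projections, function(p) {
    u <- if (is.null(p$ushape)) rep(0, 5) else unlist(p$ushape)
    list(s = match(p$sender, lnames), r = match(p$receiver, lnames),
         W = p$weights, fs = gain * p$wt_scale_fwd,
         fb = gain * p$wt_scale_bwd,
         learnable = p$learnable, u = as.numeric(u))
  })
  ext_c <- lapply(lnames, function(nm) {
    if (is.null(ext[[nm]])) numeric(0) else as.numeric(ext[[nm]])
  })
  res <- settle_trial_cpp(layers_c, proj_c, ext_c, train, n_cycles, dt,
                          net$lrate, record_gi, record_act)
  names(res$act) <- lnames
  names(res$mu_medium) <- lnames
  if (train && net$lrate > 0) {
    for (i in seq_along(net$projections)) {
      if (net$projections[[i]]$learnable) {
        net$projections[[i]]$weights <- res$weights[[i]]
      }
    }
  }
  out <- list(network = net, act = res$act, mu_medium = res$mu_medium)
  if (record_gi) {
    out$gi <- list(gi_base = res$gi_base, gi_eff = res$gi_eff)
    colnames(out$gi$gi_base) <- lnames
    colnames(out$gi$gi_eff) <- lnames
  }
  if (record_act) {
    out$act_history <- res$act_history
    names(out$act_history) <- lnames
  }
  out
}

stimulus_ext <- function(net, stimulus) {
  ext <- stats::setNames(vector("list", length(net$layers)),
                         names(net$layers))
  for (nm in names(stimulus)) ext[[nm]] <- stimulus[[nm]]
  ext
}

validate_stimulus <- function(net, stimulus) {
  if (is.null(names(stimulus)) || any(!names(stimulus) %in% names(net$layers))) {
    stop("stimulus must be a named list of layer input patterns",
         call. = FALSE)
  }
  for (nm in names(stimulus)) {
    v <- stimulus[[nm]]
    if (length(v) != net$layers[[nm]]$n_units ||
        any(v < 0) || any(v > 1)) {
      stop("invalid external pattern for layer '", nm, "'", call. = FALSE)
    }
    if (net$layers[[nm]]$clamp_gain > 0 && sum(v > 0) != 1L) {
      stop("input layer '", nm,
           "' must have exactly one active unit", call. = FALSE)
    }
  }
  invisible(TRUE)
}
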