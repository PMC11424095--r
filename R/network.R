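#' Layer specification
#'
#' Describes one layer of the rate-coded network: its size, the inhibitory
#' competition parameters of the tie-tolerant k-winners-take-all rule, the
#' amplitude of the sinusoidal inhibitory oscillation, and the gain of the
#' S-shaped activation function.
#'
#' @param name Layer identifier (character scalar).
#' @param n_units Number of rate-coded units.
#' @param k Target number of winners for the kWTA computation.
#' @param k_max Hard cap on the number of winners once ties are admitted.
#'   Use `Inf` for no cap (it is clamped to `n_units`).
#' @param kwta_point Fraction in `[0, 1]` placing the inhibition between the
#'   k'-th and (k'+1)-th ranked unit; higher values put inhibition closer to
#'   the (k'+1)-th unit, i.e. lower inhibition.
#' @param target_diff Tolerance for counting units beyond the k-th as "tied"
#'   with it (in threshold-inhibition units).
#' @param osc Amplitude of the sinusoidal inhibitory oscillation that
#'   multiplies the layer's inhibition late in a training trial.
#' @param xx1_gain Gain of the S-shaped activation function; larger values
#'   give a steeper, more binary response.
#' @param clamp_gain Multiplier on external (clamped) input; use 0 for
#'   layers that receive no external input.
#' @param act_threshold Activation threshold: drive at or below this value
#'   produces zero activity.
#'
#' @return An object of class `nmph_layer`.
#' @export
layer_spec <- function(name, n_units, k, k_max = Inf, kwta_point = 0.75,
                       target_diff = 0, osc = 0, xx1_gain = 100,
                       clamp_gain = 0, act_threshold = 0.05) {
  stopifnot(is.character(name), length(name) == 1L,
            n_units >= 1, k >= 1, k_max >= k,
            kwta_point >= 0, kwta_point <= 1,
            target_diff >= 0, osc >= 0, xx1_gain > 0, clamp_gain >= 0)
  k_max <- min(k_max, n_units)
  if (k >= n_units) {
    stop("layer '", name, "': k must be smaller than n_units", call. = FALSE)
  }
  structure(
    list(name = name, n_units = as.integer(n_units), k = as.integer(k),
         k_max = as.integer(k_max), kwta_point = kwta_point,
         target_diff = target_diff, osc = osc, xx1_gain = xx1_gain,
         clamp_gain = clamp_gain, act_threshold = act_threshold),
    class = "nmph_layer"
  )
}

#' U-shaped learning function parameters
#'
#' The five parameters of the nonmonotonic plasticity function mapping a
#' unit pair's coactivity to a raw weight change: zero change below `dthr`,
#' peak weakening `drev_mag` at `drev`, zero again at `thrp`, and peak
#' strengthening `dmax_mag` at coactivity 1.
#'
#' @param dthr Coactivity below which no change occurs.
#' @param drev Coactivity of peak weakening.
#' @param drev_mag Peak weakening (must be `<= 0`).
#' @param thrp Coactivity at which the function crosses zero again.
#' @param dmax_mag Peak strengthening, attained at coactivity 1
#'   (must be `>= 0`).
#'
#' @return An object of class `nmph_ushape`.
#' @export
ushape_params <- function(dthr, drev, drev_mag, thrp, dmax_mag) {
  if (!(0 <= dthr && dthr < drev && drev < thrp && thrp <= 1)) {
    stop("u-shape abscissae must satisfy 0 <= dthr < drev < thrp <= 1",
         call. = FALSE)
  }
  if (drev_mag > 0 || dmax_mag < 0) {
    stop("require drev_mag <= 0 and dmax_mag >= 0", call. = FALSE)
  }
  structure(list(dthr = dthr, drev = drev, drev_mag = drev_mag,
                 thrp = thrp, dmax_mag = dmax_mag),
            class = "nmph_ushape")
}

#' Bidirectional projection between two layers
#'
#' A projection holds a single weight matrix shared by both directions of
#' flow (weights are symmetric in strength), with separate forward and
#' backward scaling factors.  Recurrent projections (`sender == receiver`)
#' hold a symmetric square matrix with a zero diagonal and send activity in
#' one pass only.
#'
#' @param sender,receiver Layer names.
#' @param weights Weight matrix, `n_sender x n_receiver`, entries in
#'   `[0, 1]`.
#' @param wt_scale_fwd,wt_scale_bwd Multipliers applied to the
#'   sender-to-receiver and receiver-to-sender direction respectively.
#' @param wt_range Length-2 numeric, the uniform range used for the random
#'   part of the initialization (kept for provenance).
#' @param learnable Logical; fixed projections are never updated.
#' @param ushape [ushape_params()] attached to this projection.
#'
#' @return An object of class `nmph_projection`.
#' @export
projection <- function(sender, receiver, weights, wt_scale_fwd, wt_scale_bwd,
                       wt_range = c(NA_real_, NA_real_), learnable = TRUE,
                       ushape = NULL) {
  stopifnot(is.matrix(weights), all(weights >= 0), all(weights <= 1),
            wt_scale_fwd > 0, wt_scale_bwd > 0)
  if (identical(sender, receiver)) {
    stopifnot(nrow(weights) == ncol(weights))
    if (any(diag(weights) != 0)) {
      stop("recurrent projections must have a zero diagonal", call. = FALSE)
    }
  }
  if (learnable && is.null(ushape)) {
    stop("learnable projections need u-shape parameters", call. = FALSE)
  }
  structure(
    list(sender = sender, receiver = receiver, weights = weights,
         wt_scale_fwd = wt_scale_fwd, wt_scale_bwd = wt_scale_bwd,
         wt_range = wt_range, learnable = isTRUE(learnable),
         ushape = ushape),
    class = "nmph_projection"
  )
}

#' Assemble a network
#'
#' @param layers List of [layer_spec()] objects.
#' @param projections List of [projection()] objects; every sender and
#'   receiver must name an existing layer and the weight matrix dimensions
#'   must match the layer sizes.
#' @param lrate Global learning-rate multiplier applied to every learnable
#'   projection's weight change.
#' @param net_gain Global gain applied to the entire net input (synaptic
#'   projections and clamped external input alike).  This is the single
#'   directional calibration constant of the default configuration: it sets
#'   the overall scale of drive relative to the fixed gain of the S-shaped
#'   activation function, and thereby how graded competitor pop-up is
#'   during the low-inhibition phase of the oscillation.
#'
#' @return An object of class `nmph_network`.
#' @export
network <- function(layers, projections, lrate = 1, net_gain = 1) {
  names(layers) <- vapply(layers, function(l) l$name, character(1))
  for (p in projections) {
    if (!p$sender %in% names(layers) || !p$receiver %in% names(layers)) {
      stop("projection ", p$sender, " -> ", p$receiver,
           " references an unknown layer", call. = FALSE)
    }
    if (nrow(p$weights) != layers[[p$sender]]$n_units ||
        ncol(p$weights) != layers[[p$receiver]]$n_units) {
      stop("projection ", p$sender, " -> ", p$receiver,
           ": weight matrix dimensions do not match the layer sizes",
           call. = FALSE)
    }
  }
  stopifnot(lrate >= 0, net_gain > 0)
  structure(list(layers = layers, projections = projections, lrate = lrate,
                 net_gain = net_gain),
            class = "nmph_network")
}

#' @export
print.nmph_network <- function(x, ...) {
  cat("<nmph_network>\n")
  for (l in x$layers) {
    cat(sprintf("  layer %-9s n=%3d  k=%d  k_max=%s  osc=%g\n",
                l$name, l$n_units, l$k,
                ifelse(is.finite(l$k_max), l$k_max, "Inf"), l$osc))
  }
  for (p in x$projections) {
    cat(sprintf("  %s <-> %s  scale %g/%g%s\n", p$sender, p$receiver,
                p$wt_scale_fwd, p$wt_scale_bwd,
                if (p$learnable) "" else "  (fixed)"))
  }
  invisible(x)
}

#' Random symmetric weight matrix
#'
#' Draws a square matrix with entries uniform on `range`, symmetrized and
#' with a zero diagonal, for recurrent projections.
#'
#' @param n Matrix dimension.
#' @param range Length-2 numeric range.
#' @return An `n x n` symmetric matrix with zero diagonal.
#' @keywords internal
random_symmetric_weights <- function(n, range) {
  w <- matrix(stats::runif(n * n, range[1], range[2]), n, n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  w
}

#' Random weight matrix
#' @param n_sender,n_receiver Matrix dimensions.
#' @param range Length-2 numeric range.
#' @return An `n_sender x n_receiver` matrix.
#' @keywords internal
random_weights <- function(n_sender, n_receiver, range) {
  matrix(stats::runif(n_sender * n_receiver, range[1], range[2]),
         n_sender, n_receiver)
}
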