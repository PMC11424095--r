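#' Running-average time-scale constants
#'
#' The cascade of exponential averages that turns per-cycle activity into
#' the medium-term trace entering the coactivity: super-short and short
#' averages with rate 0.5, a raw medium average with rate 0.1, and a final
#' medium trace mixing the raw medium and short averages 0.9/0.1.
#'
#' @return A list of the five constants.
#' @export
trace_params <- function() {
  list(alpha_super_short = 0.5, alpha_short = 0.5, alpha_raw_medium = 0.1,
       alpha_mix = 0.9, beta_mix = 0.1)
}

#' Update the running-average activity traces by one cycle
#'
#' Applies the hierarchical recurrences
#' \deqn{\mu^{ss} \leftarrow \mu^{ss} + 0.5 (x - \mu^{ss})}
#' \deqn{\mu^{s} \leftarrow \mu^{s} + 0.5 (\mu^{ss} - \mu^{s})}
#' \deqn{\mu^{raw} \leftarrow \mu^{raw} + 0.1 (\mu^{s} - \mu^{raw})}
#' \deqn{\mu^{med} = 0.9\, \mu^{raw} + 0.1\, \mu^{s}}
#'
#' @param averages List with `mu_super_short`, `mu_short`, `mu_raw_medium`,
#'   `mu_medium` (vectors of equal length).
#' @param x Current activity (same length), values in `[0, 1]`.
#' @param params Constants from [trace_params()].
#' @return The updated list of traces.
#' @export
update_running_averages <- function(averages, x, params = trace_params()) {
  ss <- averages$mu_super_short +
    params$alpha_super_short * (x - averages$mu_super_short)
  s <- averages$mu_short + params$alpha_short * (ss - averages$mu_short)
  raw <- averages$mu_raw_medium +
    params$alpha_raw_medium * (s - averages$mu_raw_medium)
  list(mu_super_short = ss, mu_short = s, mu_raw_medium = raw,
       mu_medium = params$alpha_mix * raw + params$beta_mix * s)
}

#' Coactivity of a connected unit pair
#'
#' The product of the two units' end-of-trial medium-term running-average
#' activities; symmetric in its arguments and bounded in `[0, 1]`.
#'
#' @param mu_receiver,mu_sender Medium-term traces (scalars or vectors).
#' @return The elementwise product.
#' @export
coactivity <- function(mu_receiver, mu_sender) {
  mu_receiver * mu_sender
}

#' U-shaped (nonmonotonic) learning function
#'
#' Piecewise-linear through the control points (0, 0), (`dthr`, 0),
#' (`drev`, `drev_mag`), (`thrp`, 0) and (1, `dmax_mag`): no change at low
#' coactivity, weakening at moderate coactivity with its peak at `drev`,
#' and strengthening at high coactivity growing to `dmax_mag` at 1.
#'
#' @param kappa Coactivity values in `[0, 1]` (vectorized).
#' @param params [ushape_params()].
#' @return Raw weight changes (before the learning-rate multiplier).
#' @export
u_shape <- function(kappa, params) {
  stopifnot(inherits(params, "nmph_ushape"))
  out <- numeric(length(kappa))
  seg2 <- kappa > params$dthr & kappa <= params$drev
  seg3 <- kappa > params$drev & kappa <= params$thrp
  seg4 <- kappa > params$thrp
  out[seg2] <- params$drev_mag * (kappa[seg2] - params$dthr) /
    (params$drev - params$dthr)
  out[seg3] <- params$drev_mag * (params$thrp - kappa[seg3]) /
    (params$thrp - params$drev)
  out[seg4] <- params$dmax_mag * (kappa[seg4] - params$thrp) /
    (1 - params$thrp)
  out
}

#' End-of-trial weight update for one projection
#'
#' For every connected pair, adds `lrate * u_shape(coactivity)` to the
#' shared weight and clips the result to `[0, 1]`.  Recurrent projections
#' skip the diagonal; since the coactivity is symmetric, symmetric weight
#' matrices remain symmetric.
#'
#' @param weights `n_sender x n_receiver` weight matrix.
#' @param mu_sender,mu_receiver End-of-trial medium-term traces.
#' @param ushape [ushape_params()] for this projection.
#' @param lrate Learning-rate multiplier (0 disables learning).
#' @param recurrent Logical: is this a within-layer projection?
#' @return The updated, clipped weight matrix.
#' @export
trial_weight_update <- function(weights, mu_sender, mu_receiver, ushape,
                                lrate = 1, recurrent = FALSE) {
  if (lrate == 0) return(weights)
  kappa <- outer(mu_sender, mu_receiver)
  dw <- lrate * matrix(u_shape(as.numeric(kappa), ushape),
                       nrow(weights), ncol(weights))
  if (recurrent) diag(dw) <- 0
  w <- weights + dw
  w[w < 0] <- 0
  w[w > 1] <- 1
  w
}
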