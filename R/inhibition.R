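#' Per-unit threshold inhibition, ranked
#'
#' For each unit, the amount of layer inhibition that would place it exactly
#' at the threshold of activating given its current excitatory input.  With
#' the activation function used here a unit is active when
#' `net - act_threshold - gi > 0`, so the threshold inhibition is simply
#' `net - act_threshold`, which is monotone in net input.
#'
#' @param net_input Numeric vector of net inputs.
#' @param act_threshold Activation threshold of the layer.
#' @return The threshold-inhibition values sorted in descending order.
#' @export
inhibition_thresholds <- function(net_input, act_threshold) {
  sort(net_input - act_threshold, decreasing = TRUE)
}

#' Tie-tolerant k-winners-take-all inhibition
#'
#' Sets the layer inhibition from the descending ranking of threshold
#' inhibitions.  Units ranked beyond the k-th whose threshold inhibition is
#' within `target_diff` of the k-th unit's are treated as tied with it and
#' admitted as winners, up to `k_max` in total.  The inhibition is then
#' placed between the last winner (rank k') and the first loser: a
#' `kwta_point` of 0 puts it at the k'-th unit's value (highest inhibition,
#' last winner barely active) and 1 at the (k'+1)-th unit's value (lowest
#' inhibition), so inhibition decreases as `kwta_point` grows.  When every
#' unit in the layer is admitted (k' = n, possible only when `k_max` is at
#' least the layer size), the "(k'+1)-th" value is taken to be 0 -- the
#' threshold inhibition of a hypothetical unit with no excitation.
#'
#' @param g_thr_ranked Threshold inhibitions sorted in descending order.
#' @param k Target number of winners.
#' @param k_max Cap on winners once ties are admitted.
#' @param kwta_point Interpolation fraction in `[0, 1]`.
#' @param target_diff Tie tolerance.
#' @return A list with `gi_base` (non-negative inhibition) and `n_winners`
#'   (the effective winner count k').
#' @export
kwta_inhibition <- function(g_thr_ranked, k, k_max, kwta_point, target_diff) {
  n <- length(g_thr_ranked)
  if (k >= n) stop("k must be smaller than the number of units", call. = FALSE)
  k_max <- min(k_max, n)
  k_eff <- k
  while (k_eff < k_max &&
         g_thr_ranked[k] - g_thr_ranked[k_eff + 1L] <= target_diff) {
    k_eff <- k_eff + 1L
  }
  g_next <- if (k_eff < n) g_thr_ranked[k_eff + 1L] else 0
  gi <- g_thr_ranked[k_eff] - kwta_point * (g_thr_ranked[k_eff] - g_next)
  list(gi_base = max(gi, 0), n_winners = as.integer(k_eff))
}

#' Sinusoidal inhibitory oscillation
#'
#' Inhibition is constant over the first part of the trial, then from cycle
#' 125 follows one full sine period until the trial ends at cycle 200:
#' raised above baseline over cycles 125-162.5 and lowered below baseline
#' afterwards, returning to baseline at cycle 200.  The below-baseline phase
#' is what lets competitor units pop up.
#'
#' @param gi_base Baseline (kWTA-derived) inhibition.
#' @param osc Oscillation amplitude; the multiplier is `1 + osc * sin(...)`.
#' @param cycle Cycle index within the trial (1-based).
#' @param osc_start First cycle at which the oscillation applies.
#' @param period Length, in cycles, of the single sine period.
#' @return The effective inhibition at this cycle.
#' @export
oscillate_inhibition <- function(gi_base, osc, cycle, osc_start = 125,
                                 period = 75) {
  if (cycle < osc_start || osc == 0) return(gi_base)
  gi_base * (1 + osc * sin(2 * pi * (cycle - osc_start) / period))
}
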