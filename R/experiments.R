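#' @importFrom stats runif setNames
NULL

PREWIRE_STRENGTH <- 0.99

#' Stimulus patterns shared by all studies
#'
#' Each stimulus activates a single unit in each input layer: the middle
#' category unit (shared between pairmates) plus a pairmate-specific item
#' unit (A = top row, B = bottom row).
#'
#' @param net An `nmph_network` built by one of the builders.
#' @param which `"A"` or `"B"`.
#' @return A named list of external input vectors.
#' @export
pairmate_stimulus <- function(net, which = c("A", "B")) {
  which <- match.arg(which)
  cat_pat <- numeric(net$layers$category$n_units)
  cat_pat[ceiling(length(cat_pat) / 2)] <- 1
  item_pat <- numeric(net$layers$item$n_units)
  item_pat[if (which == "A") 1L else 2L] <- 1
  list(category = cat_pat, item = item_pat)
}

prewire <- function(weights, sender_idx, receiver_idx,
                    strength = PREWIRE_STRENGTH, symmetric = FALSE) {
  weights[sender_idx, receiver_idx] <- strength
  if (symmetric) {
    weights[receiver_idx, sender_idx] <- strength
    diag(weights) <- 0
  }
  weights
}

#' Hidden-layer unit assignment for a pairmate pair
#'
#' Places two blocks of six units with a given overlap centrally in the
#' layer (0 overlap means the blocks are side by side), leaving padding at
#' both ends so topographic repulsion never reaches a boundary.
#'
#' @param n_units Layer size.
#' @param overlap Number of shared units, 0 to 5.
#' @return List with integer vectors `a`, `b`, `shared`, `union`.
#' @export
pairmate_blocks <- function(n_units, overlap) {
  if (!(overlap %in% 0:5)) {
    stop("overlap must be an integer between 0 and 5", call. = FALSE)
  }
  width <- 12L - overlap
  start <- (n_units - width) %/% 2L + 1L
  a <- start:(start + 5L)
  b <- (start + 6L - overlap):(start + 11L - overlap)
  list(a = a, b = b, shared = intersect(a, b), union = union(a, b))
}

base_projections <- function(cfg, blocks, seed_weights) {
  n_h <- cfg$layers$hidden$n_units
  n_i <- cfg$layers$item$n_units
  n_c <- cfg$layers$category$n_units

  w_ih <- random_weights(n_i, n_h, cfg$projections$item_hidden$wt_range)
  w_ih <- prewire(w_ih, 1L, blocks$a)
  w_ih <- prewire(w_ih, 2L, blocks$b)

  w_ch <- random_weights(n_c, n_h, cfg$projections$category_hidden$wt_range)
  w_ch <- prewire(w_ch, ceiling(n_c / 2), blocks$union)

  w_hh <- random_symmetric_weights(n_h, cfg$projections$hidden_hidden$wt_range)
  w_hh <- prewire(w_hh, blocks$a, blocks$a, symmetric = TRUE)
  w_hh <- prewire(w_hh, blocks$b, blocks$b, symmetric = TRUE)

  list(
    item_hidden = projection(
      "item", "hidden", w_ih,
      cfg$projections$item_hidden$wt_scale_fwd,
      cfg$projections$item_hidden$wt_scale_bwd,
      cfg$projections$item_hidden$wt_range,
      ushape = config_ushape(cfg, "item_hidden")),
    category_hidden = projection(
      "category", "hidden", w_ch,
      cfg$projections$category_hidden$wt_scale_fwd,
      cfg$projections$category_hidden$wt_scale_bwd,
      cfg$projections$category_hidden$wt_range,
      ushape = config_ushape(cfg, "category_hidden")),
    hidden_hidden = projection(
      "hidden", "hidden", w_hh,
      cfg$projections$hidden_hidden$wt_scale_fwd,
      cfg$projections$hidden_hidden$wt_scale_bwd,
      cfg$projections$hidden_hidden$wt_range,
      ushape = config_ushape(cfg, "hidden_hidden"))
  )
}

#' Build the stimulus-similarity (color repulsion) network
#'
#' Two pairmates are pre-wired into the hidden layer as six-unit blocks
#' sharing `overlap` units, mirrored topographically in a color output
#' layer: pairmate hidden blocks connect all-to-all to their output
#' blocks, every non-pairmate hidden unit connects one-to-one to the
#' output unit directly above it, and the output layer carries a fixed
#' (non-learnable) recurrent projection wiring each unit to its seven
#' neighbors on either side, giving color space its continuity.
#'
#' @param overlap Number of hidden/output units shared by the pairmates
#'   (0 to 5); 0 places the blocks side by side.
#' @param seed Optional integer seed for the random background weights.
#' @param config Optional resolved configuration (defaults to
#'   `study_config("chanales")`).
#' @return An `nmph_network` with attributes `blocks` (unit assignments)
#'   and `study`.
#' @export
build_chanales <- function(overlap, seed = NULL, config = NULL) {
  cfg <- config %||% study_config("chanales")
  if (!is.null(seed)) set.seed(seed)
  n_h <- cfg$layers$hidden$n_units
  n_o <- cfg$layers$output$n_units
  blocks <- pairmate_blocks(n_h, overlap)

  projs <- base_projections(cfg, blocks)

  w_ho <- random_weights(n_h, n_o, cfg$projections$hidden_output$wt_range)
  w_ho <- prewire(w_ho, blocks$a, blocks$a)
  w_ho <- prewire(w_ho, blocks$b, blocks$b)
  nonpair <- setdiff(seq_len(n_h), blocks$union)
  w_ho[cbind(nonpair, nonpair)] <- PREWIRE_STRENGTH
  projs$hidden_output <- projection(
    "hidden", "output", w_ho,
    cfg$projections$hidden_output$wt_scale_fwd,
    cfg$projections$hidden_output$wt_scale_bwd,
    cfg$projections$hidden_output$wt_range,
    ushape = config_ushape(cfg, "hidden_output"))

  w_oo <- random_symmetric_weights(n_o, cfg$projections$output_output$wt_range)
  for (i in seq_len(n_o)) {
    nb <- setdiff(max(1L, i - 7L):min(n_o, i + 7L), i)
    w_oo[i, nb] <- PREWIRE_STRENGTH
    w_oo[nb, i] <- PREWIRE_STRENGTH
  }
  projs$output_output <- projection(
    "output", "output", w_oo,
    cfg$projections$output_output$wt_scale_fwd,
    cfg$projections$output_output$wt_scale_bwd,
    cfg$projections$output_output$wt_range,
    learnable = FALSE)

  net <- network(
    layers = list(config_layer(cfg, "category"), config_layer(cfg, "item"),
                  config_layer(cfg, "hidden"), config_layer(cfg, "output")),
    projections = unname(projs),
    lrate = cfg$sim$lrate, net_gain = cfg$net_gain %||% 1)
  attr(net, "blocks") <- blocks
  attr(net, "study") <- "chanales"
  attr(net, "topographic_output") <- TRUE
  net
}

#' Build the shared- vs. different-associate network
#'
#' Pairmate hidden representations are pre-wired with two of six units
#' shared (as in the moderate-similarity condition of the color model).
#' The output layer holds one unit per face associate, with no recurrence
#' and no topography: in the same-face condition all twelve pairmate
#' hidden units connect strongly to a single face unit, in the
#' different-face condition each pairmate's six hidden units connect to a
#' different face unit.
#'
#' @param condition `"same-face"` or `"different-face"`.
#' @param seed Optional integer seed for the random background weights.
#' @param config Optional resolved configuration (defaults to
#'   `study_config("favila")`).
#' @return An `nmph_network`.
#' @export
build_favila <- function(condition = c("same-face", "different-face"),
                         seed = NULL, config = NULL) {
  condition <- match.arg(condition)
  cfg <- config %||% study_config("favila")
  if (!is.null(seed)) set.seed(seed)
  blocks <- pairmate_blocks(cfg$layers$hidden$n_units, overlap = 2L)
  projs <- base_projections(cfg, blocks)

  n_h <- cfg$layers$hidden$n_units
  n_o <- cfg$layers$output$n_units
  face_a <- 3L
  face_b <- if (condition == "same-face") face_a else 8L
  w_ho <- random_weights(n_h, n_o, cfg$projections$hidden_output$wt_range)
  w_ho <- prewire(w_ho, blocks$a, face_a)
  w_ho <- prewire(w_ho, blocks$b, face_b)
  projs$hidden_output <- projection(
    "hidden", "output", w_ho,
    cfg$projections$hidden_output$wt_scale_fwd,
    cfg$projections$hidden_output$wt_scale_bwd,
    cfg$projections$hidden_output$wt_range,
    ushape = config_ushape(cfg, "hidden_output"))

  net <- network(
    layers = list(config_layer(cfg, "category"), config_layer(cfg, "item"),
                  config_layer(cfg, "hidden"), config_layer(cfg, "output")),
    projections = unname(projs),
    lrate = cfg$sim$lrate, net_gain = cfg$net_gain %||% 1)
  attr(net, "blocks") <- blocks
  attr(net, "study") <- "favila"
  attr(net, "condition") <- condition
  attr(net, "faces") <- c(a = face_a, b = face_b)
  net
}

#' Build the blocked- vs. interleaved-curriculum network
#'
#' Structure follows the same-face associate network (a single shared
#' output unit X), but the pre-wired strengths to X encode the learning
#' history: hidden B units connect to X at 0.7 in both conditions, while
#' hidden A units connect at 0.999 in the blocked condition (A-X fully
#' learned before any B-X trial) or 0.8 in the interleaved condition
#' (limited initial A-X learning).  Units shared by the two hidden blocks
#' take the A-side strength.
#'
#' @param condition `"blocked"` or `"interleaved"`.
#' @param osc_variant Hidden-layer oscillation amplitude; one of 0.0623
#'   (default), 0.0525 or 0.09.
#' @param seed Optional integer seed for the random background weights.
#' @param config Optional resolved configuration (defaults to
#'   `study_config("schlichting")`).
#' @return An `nmph_network`.
#' @export
build_schlichting <- function(condition = c("blocked", "interleaved"),
                              osc_variant = 0.0623, seed = NULL,
                              config = NULL) {
  condition <- match.arg(condition)
  if (!any(vapply(c(0.0623, 0.0525, 0.09, 0.0535),
                  function(v) isTRUE(all.equal(v, osc_variant)),
                  logical(1)))) {
    stop("osc_variant must be one of 0.0623, 0.0525, 0.09 (or the 0.0535 ",
         "alternate)", call. = FALSE)
  }
  cfg <- config %||% study_config("schlichting")
  cfg$layers$hidden$osc <- osc_variant
  if (!is.null(seed)) set.seed(seed)
  blocks <- pairmate_blocks(cfg$layers$hidden$n_units, overlap = 2L)
  projs <- base_projections(cfg, blocks)

  n_h <- cfg$layers$hidden$n_units
  n_o <- cfg$layers$output$n_units
  x_unit <- 3L
  a_strength <- if (condition == "blocked") 0.999 else 0.8
  w_ho <- random_weights(n_h, n_o, cfg$projections$hidden_output$wt_range)
  w_ho <- prewire(w_ho, blocks$b, x_unit, strength = 0.7)
  w_ho <- prewire(w_ho, blocks$a, x_unit, strength = a_strength)
  projs$hidden_output <- projection(
    "hidden", "output", w_ho,
    cfg$projections$hidden_output$wt_scale_fwd,
    cfg$projections$hidden_output$wt_scale_bwd,
    cfg$projections$hidden_output$wt_range,
    ushape = config_ushape(cfg, "hidden_output"))

  net <- network(
    layers = list(config_layer(cfg, "category"), config_layer(cfg, "item"),
                  config_layer(cfg, "hidden"), config_layer(cfg, "output")),
    projections = unname(projs),
    lrate = cfg$sim$lrate, net_gain = cfg$net_gain %||% 1)
  attr(net, "blocks") <- blocks
  attr(net, "study") <- "schlichting"
  attr(net, "condition") <- condition
  attr(net, "x_unit") <- x_unit
  net
}

build_study_network <- function(study, condition, osc_variant, seed, config) {
  switch(study,
    chanales = build_chanales(overlap = condition, seed = seed,
                              config = config),
    favila = build_favila(condition = condition, seed = seed, config = config),
    schlichting = build_schlichting(condition = condition,
                                    osc_variant = osc_variant, seed = seed,
                                    config = config))
}

training_order <- function(study, condition) {
  if (study == "schlichting") {
    if (condition == "blocked") "B" else c("B", "A")
  } else {
    sample(c("A", "B"))
  }
}

#' Run a full multi-run experiment
#'
#' For each of `n_runs` model runs: build the study network with
#' run-specific random weights, record a baseline test epoch (pairmates A
#' and B presented with oscillations and learning off), then alternate
#' training epochs (each scheduled stimulus once; order randomized except
#' in the blocked/interleaved curricula, where B always comes first) with
#' test epochs.  Fully reproducible from `seed`.
#'
#' @param study `"chanales"`, `"favila"` or `"schlichting"`.
#' @param condition Overlap 0-5 (chanales), `"same-face"`/
#'   `"different-face"` (favila), or `"blocked"`/`"interleaved"`
#'   (schlichting).
#' @param n_runs Number of independent model runs.
#' @param n_epochs Number of train/test epoch pairs after baseline.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param lrate Global learning rate multiplier (the fixed output
#'   recurrence never learns regardless).
#' @param osc_variant Hidden-layer oscillation amplitude (schlichting
#'   only).
#' @param config Optional resolved configuration override.
#' @param keep_layers Layers whose test-epoch activity snapshots are kept.
#' @return An object of class `nmph_experiment`: a list with `snapshots`
#'   (a tibble of per-run, per-test-epoch unit activities), `pairmate1`
#'   (per run, which stimulus was trained first), and the resolved
#'   settings.
#' @export
run_experiment <- function(study = c("chanales", "favila", "schlichting"),
                           condition, n_runs = NULL, n_epochs = NULL,
                           seed = 1L, lrate = NULL, osc_variant = 0.0623,
                           config = NULL,
                           keep_layers = c("hidden", "output")) {
  study <- match.arg(study)
  cfg <- config %||% study_config(study)
  n_runs <- n_runs %||% cfg$sim$n_runs
  n_epochs <- n_epochs %||% cfg$sim$n_epochs
  if (!is.null(lrate)) cfg$sim$lrate <- lrate
  stopifnot(n_runs >= 1)

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  snap_list <- vector("list", n_runs)
  pairmate1 <- character(n_runs)
  for (run in seq_len(n_runs)) {
    set.seed(run_seeds[run])
    net <- build_study_network(study, condition, osc_variant, seed = NULL,
                               config = cfg)
    stim <- list(A = pairmate_stimulus(net, "A"),
                 B = pairmate_stimulus(net, "B"))
    recs <- list()
    # with no training epochs, fall back to the first-trained convention
    first <- if (study == "schlichting") "B" else "A"
    test_epoch <- function(net, epoch) {
      for (s in c("A", "B")) {
        tr <- run_trial(net, stim[[s]], mode = "test",
                        n_cycles = cfg$sim$n_cycles, dt = cfg$sim$dt)
        for (ly in keep_layers) {
          recs[[length(recs) + 1L]] <<- list(
            epoch = epoch, stimulus = s, layer = ly, act = tr$act[[ly]])
        }
      }
    }
    test_epoch(net, 0L)
    for (ep in seq_len(n_epochs)) {
      order <- training_order(study, condition)
      if (ep == 1L) first <- order[1]
      for (s in order) {
        tr <- run_trial(net, stim[[s]], mode = "train",
                        n_cycles = cfg$sim$n_cycles, dt = cfg$sim$dt)
        net <- tr$network
      }
      test_epoch(net, ep)
    }
    pairmate1[run] <- first
    snap_list[[run]] <- tibble::tibble(
      run = run,
      epoch = vapply(recs, `[[`, integer(1), "epoch"),
      phase = "test",
      stimulus = vapply(recs, `[[`, character(1), "stimulus"),
      layer = vapply(recs, `[[`, character(1), "layer"),
      act = lapply(recs, `[[`, "act")
    )
  }

  snapshots <- dplyr::bind_rows(snap_list) |>
    tidyr::unnest_longer(act, values_to = "activity",
                         indices_to = "unit_index")

  structure(
    list(snapshots = snapshots,
         pairmate1 = tibble::tibble(run = seq_len(n_runs),
                                    pairmate1 = pairmate1),
         study = study, condition = condition,
         osc_variant = if (study == "schlichting") osc_variant else NA_real_,
         lrate = cfg$sim$lrate, n_runs = n_runs, n_epochs = n_epochs,
         seed = seed, run_seeds = run_seeds,
         topographic_output = study == "chanales",
         config = cfg),
    class = "nmph_experiment")
}

#' @export
print.nmph_experiment <- function(x, ...) {
  cat("<nmph_experiment> ", x$study, " / condition ", x$condition,
      ": ", x$n_runs, " runs x ", x$n_epochs, " epochs (lrate ",
      x$lrate, ")\n", sep = "")
  invisible(x)
}

#' Learning-rate sweep
#'
#' Re-runs an experiment configuration at each requested global learning
#' rate (the fixed, topographic output recurrence stays non-learnable
#' throughout).
#'
#' @param study,condition,n_runs,n_epochs,seed,osc_variant,config As in
#'   [run_experiment()].
#' @param lrates Non-empty vector of non-negative learning rates.
#' @return A named list of `nmph_experiment` objects, one per rate.
#' @export
lrate_sweep <- function(study, condition, lrates = c(0.1, 0.25, 0.5, 1.0),
                        n_runs = NULL, n_epochs = NULL, seed = 1L,
                        osc_variant = 0.0623, config = NULL) {
  stopifnot(length(lrates) > 0, all(lrates >= 0))
  res <- lapply(lrates, function(lr) {
    run_experiment(study, condition, n_runs = n_runs, n_epochs = n_epochs,
                   seed = seed, lrate = lr, osc_variant = osc_variant,
                   config = config)
  })
  setNames(res, paste0("lrate_", lrates))
}

#' Oscillation-amplitude sweep (blocked/interleaved model)
#'
#' Re-runs the curriculum experiment at each hidden-layer oscillation
#' amplitude, leaving every other parameter untouched.
#'
#' @param condition `"blocked"` or `"interleaved"`.
#' @param variants Oscillation amplitudes to test.
#' @param n_runs,n_epochs,seed,config As in [run_experiment()].
#' @return A named list of `nmph_experiment` objects, one per variant.
#' @export
osc_sweep <- function(condition, variants = c(0.0525, 0.0623, 0.09),
                      n_runs = NULL, n_epochs = NULL, seed = 1L,
                      config = NULL) {
  res <- lapply(variants, function(v) {
    run_experiment("schlichting", condition, n_runs = n_runs,
                   n_epochs = n_epochs, seed = seed, osc_variant = v,
                   config = config)
  })
  setNames(res, paste0("osc_", variants))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
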