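test_that("activation function is gated, monotone and bounded", {
  expect_equal(activation_function(0.2, 0, 100, 0.25), 0)   # below threshold
  expect_equal(activation_function(0.5, 0.5, 100, 0), 0)    # inhibited away
  a <- activation_function(seq(0.3, 2, by = 0.1), 0, 100, 0.25)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a < 1))
  # closed form g(x) = gain x / (gain x + 1)
  expect_equal(activation_function(0.35, 0, 100, 0.25), 10 / 11)
})

toy_net <- function(w = matrix(c(1, 0.5, 0, 1), 2, 2), scale = 2) {
  network(
    layers = list(
      layer_spec("in", n_units = 2, k = 1, clamp_gain = 1,
                 act_threshold = 0, osc = 0, xx1_gain = 100,
                 kwta_point = 0.5, target_diff = 0),
      layer_spec("out", n_units = 2, k = 1, clamp_gain = 0,
                 act_threshold = 0, osc = 0, xx1_gain = 100,
                 kwta_point = 0.5, target_diff = 0)),
    projections = list(projection("in", "out", w, scale, scale, c(0, 1),
                                  learnable = FALSE)))
}

test_that("net input averages weighted sender activity and scales linearly", {
  net <- toy_net()
  acts <- list("in" = c(0.5, 1), "out" = c(0, 0))
  got <- compute_net_input(net, "out", acts)
  w <- net$projections[[1]]$weights
  expect_equal(got, 2 * drop(crossprod(w, acts$`in`)) / 2)
  # linear in sender activities
  acts2 <- acts
  acts2$`in` <- 3 * acts$`in`
  expect_equal(compute_net_input(net, "out", acts2), 3 * got)
  # additive in superposed inputs
  e1 <- list("in" = c(1, 0), "out" = c(0, 0))
  e2 <- list("in" = c(0, 1), "out" = c(0, 0))
  expect_equal(compute_net_input(net, "out", e1) +
               compute_net_input(net, "out", e2),
               compute_net_input(net, "out",
                                 list("in" = c(1, 1), "out" = c(0, 0))))
  # linear in the weight scale
  net2 <- toy_net(scale = 4)
  expect_equal(compute_net_input(net2, "out", acts), 2 * got)
})

test_that("zero activity and zero clamp give zero net input", {
  net <- toy_net()
  acts <- list("in" = c(0, 0), "out" = c(0, 0))
  expect_equal(compute_net_input(net, "out", acts), c(0, 0))
})

test_that("clamped input enters through the clamp gain", {
  net <- toy_net()
  acts <- list("in" = c(0, 0), "out" = c(0, 0))
  got <- compute_net_input(net, "in", acts, ext = list("in" = c(1, 0)))
  expect_equal(got, c(1, 0))  # clamp_gain 1, net_gain 1
})

test_that("activities stay in [0, 1] at every cycle of a real trial", {
  net <- build_chanales(3L, seed = 2)
  tr <- run_trial(net, pairmate_stimulus(net, "A"), "train",
                  record_act = TRUE)
  for (m in tr$act_history) {
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("settling converges before the oscillation starts", {
  net <- build_chanales(2L, seed = 4)
  tr <- run_trial(net, pairmate_stimulus(net, "A"), "test",
                  record_act = TRUE)
  for (m in tr$act_history) {
    expect_lt(max(abs(m[124, ] - m[123, ])), 1e-4)
  }
})

test_that("compiled and reference settling paths agree", {
  net <- build_chanales(2L, seed = 11)
  stim <- pairmate_stimulus(net, "B")
  a <- run_trial(net, stim, "test", compiled = TRUE)
  b <- run_trial(net, stim, "test", compiled = FALSE)
  expect_equal(a$act, b$act, tolerance = 1e-12)
  at <- run_trial(net, stim, "train", compiled = TRUE)
  bt <- run_trial(net, stim, "train", compiled = FALSE)
  expect_equal(at$mu_medium, bt$mu_medium, tolerance = 1e-10)
  for (i in seq_along(at$network$projections)) {
    expect_equal(at$network$projections[[i]]$weights,
                 bt$network$projections[[i]]$weights, tolerance = 1e-10)
  }
})

test_that("test trials are side-effect free", {
  net <- build_chanales(2L, seed = 6)
  w_before <- lapply(net$projections, `[[`, "weights")
  tr <- run_trial(net, pairmate_stimulus(net, "A"), "test")
  w_after <- lapply(tr$network$projections, `[[`, "weights")
  expect_identical(w_after, w_before)
})

test_that("stimuli are validated", {
  net <- build_chanales(0L, seed = 1)
  expect_error(run_trial(net, list(bogus = 1), "test"), "named list")
  bad <- pairmate_stimulus(net, "A")
  bad$item <- c(1, 1)
  expect_error(run_trial(net, bad, "test"), "exactly one active unit")
})
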