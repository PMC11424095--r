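test_that("running averages follow the hierarchical recurrences", {
  tr <- list(mu_super_short = 0, mu_short = 0, mu_raw_medium = 0,
             mu_medium = 0)
  tr1 <- update_running_averages(tr, 1)
  expect_equal(tr1$mu_super_short, 0.5)
  expect_equal(tr1$mu_short, 0.25)
  expect_equal(tr1$mu_raw_medium, 0.025)
  expect_equal(tr1$mu_medium, 0.9 * 0.025 + 0.1 * 0.25)
  tr2 <- update_running_averages(tr1, 1)
  expect_equal(tr2$mu_super_short, 0.75)
  expect_equal(tr2$mu_short, 0.5)
  expect_equal(tr2$mu_raw_medium, 0.025 + 0.1 * (0.5 - 0.025))
  expect_equal(tr2$mu_medium, 0.9 * tr2$mu_raw_medium + 0.1 * tr2$mu_short)
})

test_that("constant activity drives the medium trace to a fixed point", {
  x <- 0.73
  tr <- list(mu_super_short = 0, mu_short = 0, mu_raw_medium = 0,
             mu_medium = 0)
  for (i in 1:200) tr <- update_running_averages(tr, x)
  expect_lt(abs(tr$mu_medium - x), 1e-6)
})

test_that("u_shape matches a piecewise-linear interpolation oracle", {
  set.seed(42)
  for (i in 1:25) {
    cuts <- sort(runif(3, 0.05, 0.95))
    p <- ushape_params(dthr = cuts[1], drev = cuts[2], drev_mag = -runif(1, 0.1, 10),
                       thrp = cuts[3], dmax_mag = runif(1, 0.1, 2))
    kappa <- runif(40)
    oracle <- approx(x = c(0, p$dthr, p$drev, p$thrp, 1),
                     y = c(0, 0, p$drev_mag, 0, p$dmax_mag),
                     xout = kappa)$y
    expect_equal(u_shape(kappa, p), oracle, tolerance = 1e-12)
  }
})

test_that("u_shape hits its control points", {
  p <- ushape_params(0.2, 0.4, -3, 0.6, 1.5)
  expect_equal(u_shape(c(0, 0.1, 0.2), p), c(0, 0, 0))
  expect_equal(u_shape(0.4, p), -3)
  expect_equal(u_shape(0.6, p), 0)
  expect_equal(u_shape(1, p), 1.5)
  expect_equal(u_shape(0.3, p), -1.5)   # midpoint of the falling flank
})

test_that("coactivity is the symmetric product of the traces", {
  expect_equal(coactivity(0.3, 0.8), 0.24)
  expect_equal(coactivity(0.8, 0.3), coactivity(0.3, 0.8))
  expect_true(all(coactivity(runif(10), runif(10)) >= 0))
})

test_that("weight updates are clipped to [0, 1]", {
  p <- ushape_params(0.1, 0.44, -10, 0.6, 1.5)
  w <- matrix(0.99, 1, 1)
  w2 <- trial_weight_update(w, 0.6633, 0.6633, p)  # kappa = drev
  expect_equal(w2[1, 1], 0)
  p_up <- ushape_params(0.1, 0.2, -0.5, 0.3, 10)
  w3 <- trial_weight_update(matrix(0.5, 1, 1), 0.95, 0.95, p_up)
  expect_equal(w3[1, 1], 1)
})

test_that("symmetric recurrent weights stay symmetric, diagonal untouched", {
  set.seed(1)
  w <- matrix(runif(25), 5, 5)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  mu <- runif(5)
  p <- ushape_params(0.1, 0.3, -2, 0.5, 0.5)
  w2 <- trial_weight_update(w, mu, mu, p, recurrent = TRUE)
  expect_equal(w2, t(w2))
  expect_equal(diag(w2), diag(w))
})

test_that("lrate 0 leaves weights unchanged", {
  w <- matrix(runif(6), 2, 3)
  p <- ushape_params(0.1, 0.3, -2, 0.5, 0.5)
  expect_identical(trial_weight_update(w, runif(2), runif(3), p, lrate = 0), w)
})

test_that("non-learnable projections never change during training", {
  net <- build_chanales(2L, seed = 5)
  is_oo <- vapply(net$projections, function(p) {
    p$sender == "output" && p$receiver == "output"
  }, logical(1))
  w_before <- net$projections[[which(is_oo)]]$weights
  tr <- run_trial(net, pairmate_stimulus(net, "A"), "train")
  expect_identical(tr$network$projections[[which(is_oo)]]$weights, w_before)
})

test_that("all weights remain in [0, 1] across training epochs", {
  net <- build_chanales(2L, seed = 9)
  for (i in 1:3) {
    for (s in c("A", "B")) {
      tr <- run_trial(net, pairmate_stimulus(net, s), "train")
      net <- tr$network
    }
  }
  for (p in net$projections) {
    expect_true(all(p$weights >= 0 & p$weights <= 1))
  }
})
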