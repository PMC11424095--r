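test_that("pairmate blocks have the requested overlap and sit centrally", {
  for (ov in 0:5) {
    b <- pairmate_blocks(50, ov)
    expect_length(b$a, 6)
    expect_length(b$b, 6)
    expect_length(b$shared, ov)
    expect_length(b$union, 12 - ov)
    expect_identical(b$shared, intersect(b$a, b$b))
    # centered: equal padding on both sides up to integer rounding
    lo <- min(b$union) - 1
    hi <- 50 - max(b$union)
    expect_lte(abs(lo - hi), 1)
  }
  expect_error(pairmate_blocks(50, 6), "between 0 and 5")
})

test_that("the color network is prewired as specified", {
  net <- build_chanales(2L, seed = 3)
  b <- attr(net, "blocks")
  pr <- net$projections
  names(pr) <- vapply(pr, function(p) paste(p$sender, p$receiver, sep = "_"),
                      character(1))
  # item rows project strongly to their six-unit hidden blocks
  expect_true(all(pr$item_hidden$weights[1, b$a] == 0.99))
  expect_true(all(pr$item_hidden$weights[2, b$b] == 0.99))
  # category hub connects to the union
  expect_true(all(pr$category_hidden$weights[2, b$union] == 0.99))
  # within-block recurrence is strong, symmetric, zero-diagonal
  w_hh <- pr$hidden_hidden$weights
  expect_equal(w_hh, t(w_hh))
  expect_true(all(diag(w_hh) == 0))
  expect_true(all(w_hh[b$a, b$a][upper.tri(diag(6))] == 0.99))
  # hidden blocks map all-to-all onto their output blocks,
  # non-pairmate units map one-to-one
  w_ho <- pr$hidden_output$weights
  expect_true(all(w_ho[b$a, b$a] == 0.99))
  expect_true(all(w_ho[b$b, b$b] == 0.99))
  nonpair <- setdiff(1:50, b$union)
  expect_true(all(w_ho[cbind(nonpair, nonpair)] == 0.99))
  # topographic output recurrence: every interior unit strongly linked to
  # its seven neighbors on each side, and the projection is not learnable
  w_oo <- pr$output_output$weights
  for (i in 8:43) {
    expect_equal(sum(w_oo[i, ] == 0.99), 14L)
  }
  expect_false(pr$output_output$learnable)
})

test_that("the associate networks wire the face units by condition", {
  same <- build_favila("same-face", seed = 1)
  diff <- build_favila("different-face", seed = 1)
  expect_equal(unname(attr(same, "faces")["a"]),
               unname(attr(same, "faces")["b"]))
  expect_false(attr(diff, "faces")["a"] == attr(diff, "faces")["b"])
  b <- attr(same, "blocks")
  expect_length(b$shared, 2)
  ho <- function(net) {
    i <- vapply(net$projections, function(p) {
      p$sender == "hidden" && p$receiver == "output"
    }, logical(1))
    net$projections[[which(i)]]$weights
  }
  expect_true(all(ho(same)[b$union, attr(same, "faces")["a"]] == 0.99))
  expect_true(all(ho(diff)[b$a, attr(diff, "faces")["a"]] == 0.99))
  expect_true(all(ho(diff)[setdiff(b$b, b$shared),
                           attr(diff, "faces")["b"]] == 0.99))
})

test_that("the curriculum networks encode the learning history", {
  blocked <- build_schlichting("blocked", seed = 1)
  inter <- build_schlichting("interleaved", seed = 1)
  x <- attr(blocked, "x_unit")
  b <- attr(blocked, "blocks")
  ho <- function(net) {
    i <- vapply(net$projections, function(p) {
      p$sender == "hidden" && p$receiver == "output"
    }, logical(1))
    net$projections[[which(i)]]$weights
  }
  expect_true(all(ho(blocked)[b$a, x] == 0.999))
  expect_true(all(ho(inter)[b$a, x] == 0.8))
  only_b <- setdiff(b$b, b$shared)
  expect_true(all(ho(blocked)[only_b, x] == 0.7))
  expect_true(all(ho(inter)[only_b, x] == 0.7))
  expect_error(build_schlichting("blocked", osc_variant = 0.2),
               "osc_variant")
})

test_that("an experiment records one baseline plus one test epoch per epoch", {
  r <- run_experiment("chanales", 1, n_runs = 2, n_epochs = 2, seed = 5)
  s <- r$snapshots
  expect_setequal(unique(s$epoch), 0:2)
  expect_setequal(unique(s$stimulus), c("A", "B"))
  expect_setequal(unique(s$layer), c("hidden", "output"))
  # 2 runs x 3 test epochs x 2 stimuli x 2 layers x 50 units
  expect_equal(nrow(s), 2 * 3 * 2 * 2 * 50)
  expect_length(r$run_seeds, 2)
})

test_that("the blocked curriculum trains only the new memory", {
  r <- run_experiment("schlichting", "blocked", n_runs = 3, n_epochs = 1,
                      seed = 2)
  expect_true(all(r$pairmate1$pairmate1 == "B"))
  r2 <- run_experiment("schlichting", "interleaved", n_runs = 3, n_epochs = 1,
                       seed = 2)
  expect_true(all(r2$pairmate1$pairmate1 == "B"))
})

test_that("experiments are deterministic in the master seed", {
  a <- run_experiment("chanales", 2, n_runs = 2, n_epochs = 2, seed = 7)
  b <- run_experiment("chanales", 2, n_runs = 2, n_epochs = 2, seed = 7)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$run_seeds, b$run_seeds)
  c <- run_experiment("chanales", 2, n_runs = 2, n_epochs = 2, seed = 8)
  expect_false(identical(a$snapshots, c$snapshots))
})

test_that("longer runs extend shorter ones without rewriting their prefix", {
  short <- run_experiment("chanales", 2, n_runs = 2, n_epochs = 2, seed = 3)
  long <- run_experiment("chanales", 2, n_runs = 2, n_epochs = 4, seed = 3)
  expect_identical(short$snapshots,
                   dplyr::filter(long$snapshots, epoch <= 2))
})

test_that("baseline similarity grows with pre-wired overlap", {
  cors <- vapply(0:5, function(ov) {
    r <- run_experiment("chanales", ov, n_runs = 3, n_epochs = 0,
                        seed = 11)
    m <- experiment_metrics(r)
    mean(m$within_pair_correlation[m$epoch == 0])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("a zero learning rate leaves every run unchanged", {
  r <- run_experiment("chanales", 2, n_runs = 3, n_epochs = 2, seed = 13,
                      lrate = 0)
  cls <- classify_runs(r)
  expect_true(all(cls$label == "unchanged"))
  expect_equal(cls$final, cls$baseline)
})

test_that("sweeps return one experiment per setting", {
  sw <- lrate_sweep("chanales", 2, lrates = c(0, 1), n_runs = 1,
                    n_epochs = 1, seed = 1)
  expect_named(sw, c("lrate_0", "lrate_1"))
  expect_equal(sw$lrate_0$lrate, 0)
  ow <- osc_sweep("blocked", variants = c(0.0525, 0.09), n_runs = 1,
                  n_epochs = 1, seed = 1)
  expect_named(ow, c("osc_0.0525", "osc_0.09"))
  expect_equal(ow$osc_0.09$osc_variant, 0.09)
})
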