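test_that("within-pair correlation is symmetric and affine-invariant", {
  a <- c(0.1, 0.8, 0.3, 0.0, 0.6)
  b <- c(0.2, 0.1, 0.9, 0.4, 0.5)
  expect_equal(within_pair_correlation(a, b), within_pair_correlation(b, a))
  expect_equal(within_pair_correlation(2 * a + 3, b),
               within_pair_correlation(a, b))
  expect_equal(within_pair_correlation(a, a), 1)
  expect_true(is.na(within_pair_correlation(rep(0, 5), b)))
  expect_true(is.na(within_pair_correlation(a, rep(0.4, 5))))
})

test_that("center of mass is the activity-weighted position", {
  expect_equal(center_of_mass(c(0, 1, 0)), 2)
  expect_equal(center_of_mass(c(1, 0, 0, 1)), 2.5)
  expect_true(is.na(center_of_mass(c(0, 0, 0))))
  # translation equivariance
  p <- c(0, 0.2, 0.7, 0.1, 0, 0, 0, 0)
  shifted <- c(0, 0, 0, 0.2, 0.7, 0.1, 0, 0)
  expect_equal(center_of_mass(shifted), center_of_mass(p) + 2)
})

test_that("repulsion metrics sign movement away from the competitor", {
  n <- 20
  pat <- function(i) {
    p <- numeric(n)
    p[i] <- 1
    p
  }
  # pairmate 1 at 8, pairmate 2 at 12; 1 moves away to 6, 2 stays
  m <- repulsion_metrics(pat(8), pat(12), pat(6), pat(12))
  expect_equal(m$com_distance_change, 2)
  expect_equal(m$color_error_1, -2)  # away from the competitor
  expect_equal(m$color_error_2, 0)
  # attraction: both move toward each other
  m2 <- repulsion_metrics(pat(8), pat(12), pat(9), pat(11))
  expect_equal(m2$com_distance_change, -2)
  expect_equal(m2$color_error_1, 1)
  expect_equal(m2$color_error_2, 1)
})

test_that("run classification uses the delta band and reports onset", {
  d <- classify_run(c(0.5, 0.5, 0.1, -0.2), delta = 0.1)
  expect_equal(d$label, "differentiated")
  expect_equal(d$onset_epoch, 2L)
  i <- classify_run(c(0.2, 0.9, 0.95, 0.97), delta = 0.1)
  expect_equal(i$label, "integrated")
  expect_equal(i$onset_epoch, 1L)
  u <- classify_run(c(0.3, 0.35, 0.25, 0.31), delta = 0.1)
  expect_equal(u$label, "unchanged")
  expect_true(is.na(u$onset_epoch))
  expect_equal(classify_run(c(0.3, NA, NA))$label, "unchanged")
})

test_that("asymmetry attribution follows the 2x rule", {
  expect_equal(asymmetry_label(0.05, 0.1), "neither")
  expect_equal(asymmetry_label(2.1, 1.0), "pairmate1")
  expect_equal(asymmetry_label(1.0, 2.0), "pairmate2")
  expect_equal(asymmetry_label(1.5, 1.0), "both")
})

test_that("MDS embedding is aligned and distance-preserving", {
  pad <- function(x, y) c(x, y, rep(0, 8))
  p1b <- pad(0, 0)
  p2b <- pad(3, 0)
  p1a <- pad(0, 2)
  p2a <- pad(3, 2)
  out <- mds_embed_align(p1b, p2b, p1a, p2a)
  expect_false(attr(out, "degenerate"))
  expect_equal(unlist(out[1, c("x", "y")]), c(x = 0, y = 0))
  expect_equal(out$y[2], 0)
  expect_gt(out$x[2], 0)
  expect_equal(out$x[2], 3)  # baseline distance reproduced
  emb <- as.matrix(out[, c("x", "y")])
  pts <- rbind(p1b, p2b, p1a, p2a)
  expect_equal(as.numeric(dist(emb)), as.numeric(dist(pts)),
               tolerance = 1e-8)
  # degenerate case collapses to the origin and is flagged
  deg <- mds_embed_align(p1b, p1b, p1b, p1b)
  expect_true(attr(deg, "degenerate"))
  expect_true(all(deg$x == 0 & deg$y == 0))
})

test_that("aggregates use Student-t confidence intervals", {
  metrics <- tibble::tibble(
    run = 1:2, epoch = 0L, within_pair_correlation = c(0, 1))
  agg <- aggregate_runs(metrics, vars = "within_pair_correlation")
  expect_equal(agg$mean, 0.5)
  half <- qt(0.975, df = 1) * sd(c(0, 1)) / sqrt(2)
  expect_equal(agg$ci_hi - agg$mean, half)
  expect_equal(agg$mean - agg$ci_lo, half)
  expect_equal(agg$n, 2L)
  # identical runs give zero-width intervals
  same <- tibble::tibble(run = 1:3, epoch = 0L,
                         within_pair_correlation = 0.4)
  agg2 <- aggregate_runs(same, vars = "within_pair_correlation")
  expect_equal(agg2$ci_lo, agg2$ci_hi)
  # undefined runs are excluded from the aggregate
  with_na <- tibble::tibble(run = 1:3, epoch = 0L,
                            within_pair_correlation = c(0.2, NA, 0.4))
  agg3 <- aggregate_runs(with_na, vars = "within_pair_correlation")
  expect_equal(agg3$n, 2L)
  expect_equal(agg3$mean, 0.3)
})

test_that("experiment metrics and tidiers line up", {
  r <- run_experiment("chanales", 1, n_runs = 2, n_epochs = 1, seed = 9)
  m <- experiment_metrics(r)
  expect_identical(m, generics::tidy(r))
  expect_setequal(unique(m$epoch), 0:1)
  expect_true(all(c("within_pair_correlation", "com_distance_change",
                    "color_error_1", "color_error_2") %in% names(m)))
  g <- generics::glance(r)
  expect_equal(g$n_runs, 2)
  expect_equal(g$n_differentiated + g$n_integrated + g$n_unchanged, 2)
  cls <- classify_runs(r)
  expect_equal(nrow(cls), 2)
  expect_true(all(cls$asymmetry %in%
                  c("neither", "pairmate1", "pairmate2", "both")))
})
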