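test_that("PC1 captures ramping, separates score signs, and honors the sign convention", {
  ses <- make_ramping_session(n_units = 12, n_trials = 25, slope = 0.4,
                              seed = 2)
  peths <- lapply(ses$trains, compute_peth, trial_starts = ses$starts)
  pca <- pca_ensemble(peths)
  expect_gt(pca$explained_fraction[1], 0.6)
  # loading trend is negative by convention
  expect_lt(coef(lm(pca$components[, 1] ~ pca$bin_centers_s))[2], 0)
  up <- ses$slopes > 0
  # up-ramping units score negative, down-ramping positive
  expect_true(all(pca$scores[up, 1] < 0))
  expect_true(all(pca$scores[!up, 1] > 0))
  # explained fractions are a valid spectrum
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-8)
})

test_that("explained variance is invariant to orthogonal rotation of the bins", {
  ses <- make_ramping_session(n_units = 8, n_trials = 15, seed = 3)
  peths <- lapply(ses$trains, compute_peth, trial_starts = ses$starts)
  pca <- pca_ensemble(peths)
  sel <- peths[[1]]$bin_centers_s >= 0 & peths[[1]]$bin_centers_s < 6
  mat <- t(vapply(peths, function(p) p$rate[sel], numeric(sum(sel))))
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(ncol(mat)^2), ncol(mat))))
  rot <- prcomp(mat %*% Q, center = TRUE)
  expect_equal(rot$sdev^2 / sum(rot$sdev^2), pca$explained_fraction,
               tolerance = 1e-8)
})

test_that("degenerate ensembles are rejected", {
  starts <- make_trial_starts(5, seed = 5)
  p1 <- compute_peth(numeric(), starts)
  expect_error(pca_ensemble(list(p1, p1)), "zero variance")
  expect_error(pca_ensemble(list(p1)), "at least 2")
})

test_that("random-timestamp baseline separates structure from null", {
  ses <- make_ramping_session(n_units = 8, n_trials = 20, slope = 0.4,
                              seed = 6)
  span <- c(0, ses$horizon)
  pb <- pc1_random_baseline(ses$trains, ses$starts, span, n_iter = 60,
                            seed = 7)
  expect_lte(pb$p_empirical, 0.05)
  expect_gt(pb$observed, median(pb$baseline))

  # null calibration: random observations give an unremarkable p
  set.seed(8)
  null_trains <- lapply(lengths(ses$trains), function(k)
    runif(k, span[1], span[2]))
  pb0 <- pc1_random_baseline(null_trains, ses$starts, span, n_iter = 60,
                             seed = 9)
  expect_gte(pb0$p_empirical, 0.02)

  pb1 <- pc1_random_baseline(ses$trains, ses$starts, span, n_iter = 1,
                             seed = 10)
  expect_true(pb1$p_empirical %in% c(0, 1))
})

test_that("early-epoch activity separates up and down groups; whole-window mean is zero", {
  ses <- make_ramping_session(n_units = 10, n_trials = 20, slope = 0.5,
                              seed = 11)
  peths <- lapply(ses$trains, compute_peth, trial_starts = ses$starts)
  groups <- ifelse(ses$slopes > 0, "up", "down")
  cmp <- epoch_activity_compare(peths, groups)
  early <- cmp$per_unit$early
  expect_gt(mean(early[groups == "up"]), 0)
  expect_lt(mean(early[groups == "down"]), 0)
  # a whole-window epoch on a z-scored PETH averages to ~0
  whole <- epoch_activity_compare(peths, groups, early = c(-4, 22),
                                  late = c(0, 6))
  expect_equal(mean(whole$per_unit$early), 0, tolerance = 1e-8)
  expect_error(epoch_activity_compare(peths, rep("a", 10)), "two groups")
  expect_error(epoch_activity_compare(peths, groups, early = c(50, 60)),
               "empty epoch")
})
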