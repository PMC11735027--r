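test_that("exponential-kernel convolution matches the kernel definition", {
  grid <- seq(0.1, 10, 0.1)
  at <- function(t) which.min(abs(grid - t))
  x <- exp_kernel_convolve(2, grid, kernel_w = 1)
  expect_equal(x[at(3)], exp(-1), tolerance = 1e-9)
  expect_equal(x[at(2)], 1, tolerance = 1e-9)            # w at the spike
  expect_true(all(x[grid < 2] == 0))                     # causal
  expect_identical(exp_kernel_convolve(numeric(), grid), rep(0, 100))
  # linearity: two spikes superpose
  x2 <- exp_kernel_convolve(c(2, 5), grid)
  expect_equal(x2, x + exp_kernel_convolve(5, grid), tolerance = 1e-12)
  # shift equivariance
  x3 <- exp_kernel_convolve(3, grid)
  expect_equal(x3[grid >= 3], x[grid >= 2][seq_len(sum(grid >= 3))],
               tolerance = 1e-12)
})

test_that("readout accuracy scoring is exact", {
  expect_equal(readout_accuracy(1:5, 1:5), 1)
  expect_equal(readout_accuracy(1:5 + 2, 1:5), 0)
  expect_equal(readout_accuracy(c(1, 2, 9, 9), c(1, 2, 3, 4)), 0.5)
  expect_equal(readout_accuracy(c(NA, 2), c(2, 2)), 0.5)
  expect_error(readout_accuracy(1:3, 1:4), "mismatch")
})

test_that("weight identity: thresholding the implied weighted sum reproduces the crossings", {
  ens <- make_linked_ensemble(n_trials = 15, ddm_seed = 3, ens_seed = 3)
  cfg <- readout_config()
  ro <- fit_readout(ens$spikes, ens$switch_times, cfg, fit = "pooled")
  expect_equal(ro$k, -0.5 / ro$beta_hat_0)
  expect_equal(ro$beta, ro$k * ro$beta_hat)
  units <- names(ro$beta_hat)
  grid <- ro$grid
  for (m in c(1, 7, 15)) {
    sp <- ens$spikes[ens$spikes$trial_id == m, ]
    X <- vapply(units, function(u)
      exp_kernel_convolve(sp$time_s[sp$unit_id == u], grid, cfg$kernel_w),
      numeric(length(grid)))
    lp_cross <- grid[which(ro$beta_hat_0 + X %*% ro$beta_hat >= 0)[1]]
    # k < 0 flips the inequality when dividing by it
    w_cross <- if (ro$k > 0) grid[which(X %*% ro$beta >= 0.5)[1]] else
      grid[which(X %*% ro$beta <= 0.5)[1]]
    expect_identical(lp_cross, w_cross)
    expect_identical(ro$t_pred[m], lp_cross)
  }
})

test_that("a clean constructed ramp is read out at its crossing time", {
  # two units whose summed convolved activity ramps through the level at 5 s
  grid <- seq(0.1, 20, 0.1)
  mk_spikes <- function(rate_fn, seed) {
    set.seed(seed)
    cand <- sort(runif(2000, 0, 20))
    cand[runif(2000) < rate_fn(cand) / 30]
  }
  trials <- lapply(1:6, function(m) {
    up <- mk_spikes(function(t) pmin(30, 25 * t / 10), 20 + m)
    dn <- mk_spikes(function(t) pmax(1, 25 * (1 - t / 10)), 40 + m)
    rbind(data.frame(unit_id = "up", trial_id = m, time_s = up),
          data.frame(unit_id = "dn", trial_id = m, time_s = dn))
  })
  spikes <- do.call(rbind, trials)
  ro <- fit_readout(spikes, rep(5, 6), readout_config(t_max = 20))
  expect_true(all(abs(ro$t_pred - 5) <= 1))
})

test_that("readout accuracy degrades monotonically with injected rate noise", {
  accs <- vapply(c(1, 16, 64), function(ns) {
    ens <- make_linked_ensemble(n_trials = 25, ddm_seed = 5, ens_seed = 5,
                                noise_sd = ns)
    fit_readout(ens$spikes, ens$switch_times)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1], accs[3])
})

test_that("per-trial and pooled modes both run; degenerate inputs error", {
  ens <- make_linked_ensemble(n_trials = 12, ddm_seed = 6, ens_seed = 6)
  per <- fit_readout(ens$spikes, ens$switch_times)
  pool <- fit_readout(ens$spikes, ens$switch_times, fit = "pooled")
  expect_gte(per$accuracy, pool$accuracy)
  expect_equal(dim(per$beta_hat_trials),
               c(12, length(unique(ens$spikes$unit_id))))
  loto <- fit_readout(ens$spikes, ens$switch_times, fit = "pooled",
                      loto = TRUE)
  expect_length(loto$t_pred, 12)
  expect_error(fit_readout(ens$spikes, ens$switch_times[-1]),
               "one switch time per trial")
  one_unit <- ens$spikes[ens$spikes$unit_id == "u01", ]
  expect_error(fit_readout(one_unit, ens$switch_times), "2 units")
})
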