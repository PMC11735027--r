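test_that("threshold formula matches its two algebraic renderings and the published values", {
  expect_equal(compute_threshold(1, 0.52), 0.87)
  expect_equal(compute_threshold(0, 0.48), 0.12)
  expect_identical(compute_threshold(1, 0), 1)
  expect_equal(compute_threshold(0.5, 0.8), 0.5)

  set.seed(7)
  F <- runif(50, -1, 2)
  b <- runif(50)
  expect_identical((1 - b / 4) * F + (b / 4) * (1 - F),
                   F * (1 - b / 4) + (1 - F) * b / 4)
  expect_equal(compute_threshold(F, b), (1 - b / 4) * F + (b / 4) * (1 - F))

  expect_error(compute_threshold(NA, 0.5), "finite")
  expect_error(compute_threshold(1, 1.2), "\\[0, 1\\]")
})

test_that("noise-free crossing time matches the closed form and scales as 1/D", {
  expect_equal(noise_free_crossing_time(intact_d2_params()),
               log(0.48 / 0.13) / 0.135, tolerance = 1e-12)
  expect_equal(noise_free_crossing_time(intact_d1_params()),
               log(0.48 / 0.12) / 0.141, tolerance = 1e-12)
  t1 <- noise_free_crossing_time(ddm_params(1, 0.52, 0.135, 0))
  t2 <- noise_free_crossing_time(ddm_params(1, 0.52, 0.27, 0))
  expect_equal(t2, t1 / 2)
  # threshold not between start and target under pure drift
  expect_error(noise_free_crossing_time(ddm_params(0.5, 0.1, 0.1, 0)),
               "unreachable")
})

test_that("deterministic simulation converges to the closed-form crossing time as dt shrinks", {
  t_exact <- log(0.48 / 0.13) / 0.135
  dts <- c(0.1, 0.05, 0.01, 0.005)
  errs <- vapply(dts, function(dt) {
    p <- ddm_params(1, 0.52, 0.135, sigma = 0, dt = dt)
    abs(simulate_trial(p)$t_star - t_exact)
  }, numeric(1))
  expect_lt(errs[length(errs)], 0.02)
  expect_lt(errs[length(errs)], errs[1])    # error shrinks with dt
  expect_true(all(errs <= 3 * dts))         # O(dt) error bound
})

test_that("degenerate and censored trials are reported as such", {
  # b at threshold: F = 0.5 gives T = 0.5 for any b; pick b = 0.5
  deg <- simulate_trial(ddm_params(0.5, 0.5, 0.1, 0.01))
  expect_true(deg$degenerate)
  expect_equal(deg$t_star, 0)

  still <- simulate_trial(ddm_params(1, 0.52, D = 0, sigma = 0))
  expect_true(still$censored)
  expect_true(is.na(still$t_star))

  expect_error(simulate_batch(ddm_params(1, 0.52, 0, 0, n_sims = 10)),
               "all trials censored")
})

test_that("batches are seed-reproducible and bookkeeping is consistent", {
  p <- intact_d2_params(n_sims = 200, seed = 42)
  a <- simulate_batch(p)
  b <- simulate_batch(p)
  expect_identical(a$switch_times, b$switch_times)
  expect_identical(a$censored, b$censored)
  expect_equal(sum(!a$censored) + sum(a$censored), p$n_sims)
  ok <- !a$censored
  expect_true(all(a$switch_times[ok] > 0 & a$switch_times[ok] <= p$t_max))
  expect_true(all(is.na(a$switch_times[!ok])))

  z <- simulate_batch(ddm_params(1, 0.52, 0.135, sigma = 0))
  t_grid <- simulate_trial(ddm_params(1, 0.52, 0.135, sigma = 0))$t_star
  expect_true(all(z$switch_times == t_grid))
})

test_that("lowering the drift rate lengthens switch times (disruption direction)", {
  mean_t <- function(D, sigma, F = 1, b = 0.52, seed = 5) {
    run <- simulate_batch(ddm_params(F, b, D, sigma, seed = seed))
    mean(run$switch_times[!run$censored])
  }
  # paired-seed monotonicity in D at fixed sigma
  Ds <- c(0.10, 0.135, 0.17, 0.20)
  ms <- vapply(Ds, mean_t, numeric(1), sigma = 0.052)
  expect_true(all(diff(ms) < 0))
  # disrupted vs intact, both pathways
  expect_gt(mean_t(0.129, 0.043), mean_t(0.135, 0.052))
  expect_gt(mean_t(0.122, 0.043, F = 0, b = 0.48), mean_t(0.141, 0.052, F = 0, b = 0.48))
})
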