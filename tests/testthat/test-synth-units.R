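test_that("thinning generator matches its rate function in and out of the interval", {
  starts <- make_trial_starts(30, seed = 1)
  horizon <- max(starts) + 30

  # flat unit: empirical rate within Poisson CI of baseline
  flat <- synth_unit_spec(baseline_rate = 5, ramp_slope = 0,
                          trial_gain_noise = 0, seed = 2)
  st <- gen_ramping_unit(flat, starts, horizon)
  n <- length(st)
  ci <- qpois(c(0.0005, 0.9995), 5 * horizon)
  expect_gte(n, ci[1]); expect_lte(n, ci[2])

  # ramping unit: interval rate rises above baseline, elsewhere stays at it
  ramp <- synth_unit_spec(baseline_rate = 5, ramp_slope = 0.5,
                          trial_gain_noise = 0, seed = 3)
  st2 <- gen_ramping_unit(ramp, starts, horizon)
  late_counts <- unlist(lapply(starts, function(s)
    sum(st2 >= s + 4 & st2 < s + 6)))
  expected_late <- 2 * (5 + 0.5 * 5)   # mean rate over 4-6 s
  expect_lt(abs(mean(late_counts) - expected_late) / expected_late, 0.15)

  expect_identical(st2, gen_ramping_unit(ramp, starts, horizon))
  expect_error(gen_ramping_unit(ramp, starts, -1), "horizon")
})

test_that("rates clip at zero rather than going negative", {
  steep <- synth_unit_spec(baseline_rate = 1, ramp_slope = -2,
                           trial_gain_noise = 0, seed = 4)
  starts <- make_trial_starts(20, seed = 4)
  st <- gen_ramping_unit(steep, starts, max(starts) + 30)
  # rate hits 0 at 0.5 s into the interval: essentially no late-interval spikes
  late <- sum(unlist(lapply(starts, function(s) sum(st >= s + 1 & st < s + 6))))
  expect_lte(late, 2)
})

test_that("tagging responses follow the latency spec and classify correctly", {
  tagged <- synth_unit_spec(tagged = TRUE, tag_latency_ms = 2, seed = 5)
  tg <- gen_tagging_responses(tagged, n_pulses = 30)
  res <- tag_units(tg$spikes, tg$pulse_times)
  expect_true(res$tagged)
  expect_lt(abs(res$mean_latency_ms - 2), 0.5)

  slow <- synth_unit_spec(tagged = TRUE, tag_latency_ms = 8, seed = 6)
  tg2 <- gen_tagging_responses(slow, n_pulses = 30)
  expect_false(tag_units(tg2$spikes, tg2$pulse_times)$tagged)

  untag <- synth_unit_spec(tagged = FALSE, seed = 7)
  tg3 <- gen_tagging_responses(untag, n_pulses = 10)
  expect_equal(length(tg3$spikes), 0)

  # mixed population separates perfectly at well-separated latencies
  lats <- c(1.5, 2, 3, 8, 9)
  truth <- lats <= 5
  got <- vapply(seq_along(lats), function(i) {
    sp <- synth_unit_spec(tagged = TRUE, tag_latency_ms = lats[i],
                          seed = 10 + i)
    tg <- gen_tagging_responses(sp, n_pulses = 25, latency_sd_ms = 0.3)
    tag_units(tg$spikes, tg$pulse_times)$tagged
  }, logical(1))
  expect_identical(got, truth)
  expect_error(synth_unit_spec(tag_latency_ms = -1), "tag_latency_ms")
})

test_that("blockade shrinks ramp slopes toward flat", {
  units <- lapply(1:4, function(j)
    synth_unit_spec(unit_id = j, ramp_slope = c(0.4, -0.3)[1 + j %% 2]))
  expect_identical(gen_blockade_ensemble(units, 1), units)
  flat <- gen_blockade_ensemble(units, 0)
  expect_true(all(vapply(flat, `[[`, numeric(1), "ramp_slope") == 0))
  half <- gen_blockade_ensemble(units, 0.5)
  expect_equal(vapply(half, `[[`, numeric(1), "ramp_slope"),
               vapply(units, `[[`, numeric(1), "ramp_slope") / 2)
  expect_error(gen_blockade_ensemble(units, 2), "slope_shrink")
})
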