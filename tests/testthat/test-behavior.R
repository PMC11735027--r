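test_that("event logs survive a file round trip and malformed logs are rejected", {
  spec <- synth_behavior_spec(n_trials = 20, seed = 2)
  log <- gen_event_log(spec)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(log$events, f, row.names = FALSE)
  ev <- read_event_log(f)
  recs <- extract_switch_times(ev)
  expect_equal(recs$switch_time_s, log$switch_times, tolerance = 1e-9)

  # empty file: empty collection with a warning
  f2 <- tempfile(fileext = ".csv")
  writeLines("mouse_id,session_id,trial_id,trial_type,event_type,time_s", f2)
  expect_warning(ev2 <- read_event_log(f2), "empty")
  expect_equal(nrow(ev2), 0)

  expect_error(read_event_log(tempfile()), "not found")

  # missing column
  bad <- log$events[, -6]
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f3, row.names = FALSE)
  expect_error(read_event_log(f3), "missing columns: time_s")

  # exit before entry names the trial
  ev_bad <- data.frame(mouse_id = "m1", session_id = "s1", trial_id = 7L,
                       trial_type = "long",
                       event_type = c("trial_start", "first_np_out",
                                      "first_np_in"),
                       time_s = c(0, 1, 2))
  expect_error(validate_events(ev_bad), "trial 7")
})

test_that("switch extraction uses the last first-exit before the first second-entry", {
  mk <- function(types, times, id = 1L)
    data.frame(mouse_id = "m1", session_id = "s1", trial_id = id,
               trial_type = "long", event_type = types, time_s = times)
  # two first-poke bouts: switch is the later exit (7.3), not 5.0
  tr <- mk(c("trial_start", "first_np_in", "first_np_out", "first_np_in",
             "first_np_out", "second_np_in", "reward"),
           c(0, 4.0, 5.0, 6.5, 7.3, 8.1, 18))
  recs <- extract_switch_times(validate_events(tr))
  expect_equal(recs$switch_time_s, 7.3)
  expect_equal(recs$traversal_time_s, 0.8)
  expect_equal(recs$nosepoke_duration_s, 7.3 - 6.5)

  # only first-nosepoke activity: error trial, excluded and counted
  err <- mk(c("trial_start", "first_np_in", "first_np_out"), c(0, 1, 2),
            id = 2L)
  recs2 <- extract_switch_times(validate_events(rbind(tr, err)))
  expect_equal(nrow(recs2), 1)
  expect_equal(attr(recs2, "n_error_trials"), 1L)

  # short trials never produce records
  sh <- mk(c("trial_start", "first_np_in", "reward"), c(0, 1, 6), id = 3L)
  sh$trial_type <- "short"
  expect_equal(nrow(extract_switch_times(validate_events(sh))), 0)
})

test_that("response distributions normalize and match the generating quantiles", {
  spec <- synth_behavior_spec(seed = 11)
  x <- gen_switch_times(spec, n = 10000)
  d <- response_distributions(x, bin_width = 1)
  expect_true(all(d$density >= 0))
  expect_equal(sum(d$density) * 1, 1, tolerance = 1e-8)
  med_gamma <- qgamma(0.5, 6.08, rate = 0.69)
  expect_lt(abs(stats::quantile(d$ecdf, 0.5) - med_gamma), 0.2)

  st <- response_distributions(9)
  expect_equal(st$ecdf(8.99), 0)
  expect_equal(st$ecdf(9), 1)
  expect_true(response_distributions(numeric())$empty)
})

test_that("behavioral gamma fit recovers the generating distribution", {
  spec <- synth_behavior_spec(seed = 12)
  x <- gen_switch_times(spec, n = 4000)
  f <- fit_behavior_gamma(x)
  expect_lt(abs(f$alpha - 6.08) / 6.08, 0.1)
  expect_gt(f$r2, 0.98)
  expect_error(fit_behavior_gamma(rep(9, 50)), "variance")
  # gamma-generated data fit better than uniform data (paired seed)
  set.seed(13)
  u <- runif(4000, 0.1, 20)
  expect_gt(f$r2, fit_behavior_gamma(u)$r2)
})

test_that("session summaries compute medians, Cohen's d and paired tests", {
  mk_records <- function(shift, n_mice = 8, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_mice), function(m) {
      base <- rnorm(1, 9, 0.5)
      data.frame(mouse_id = sprintf("m%d", m), session_id = "s1",
                 trial_id = 1:2,
                 switch_time_s = c(base, base + shift),
                 traversal_time_s = 1, nosepoke_duration_s = 1,
                 laser_on = c(FALSE, TRUE))
    }))
  }
  same <- mk_records(0)
  s0 <- session_summary(same, ifelse(same$laser_on, "on", "off"))
  expect_equal(s0$cohens_d, 0)

  sh <- mk_records(1)
  s1 <- session_summary(sh, ifelse(sh$laser_on, "on", "off"))
  sd_pool <- sd(sh$switch_time_s[!sh$laser_on])
  expect_equal(s1$cohens_d, 1 / sd_pool, tolerance = 0.05)
  expect_gt(s1$group$median[s1$group$condition == "on"],
            s1$group$median[s1$group$condition == "off"])
  expect_equal(s1$test, "wilcoxon signed-rank")
  expect_error(session_summary(same, rep("a", nrow(same))), "two conditions")
})
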