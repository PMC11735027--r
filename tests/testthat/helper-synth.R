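# shared builders for synthetic sessions and ensembles

intact_d2_params <- function(n_sims = 500, seed = 1L, ...) {
  ddm_params(F = 1, b = 0.52, D = 0.135, sigma = 0.052, n_sims = n_sims,
             seed = seed, ...)
}

intact_d1_params <- function(n_sims = 500, seed = 1L, ...) {
  ddm_params(F = 0, b = 0.48, D = 0.141, sigma = 0.052, n_sims = n_sims,
             seed = seed, ...)
}

# a session's trial start times on the session clock
make_trial_starts <- function(n_trials, seed = 1L) {
  set.seed(seed)
  cumsum(c(10, stats::rlnorm(n_trials - 1, log(30), 0.3) + 20))
}

# mixed up/down ramping population with spike trains and PETHs
make_ramping_session <- function(n_units = 12, n_trials = 25,
                                 slope = 0.4, baseline = 6, seed = 1L,
                                 trial_gain_noise = 0.05) {
  starts <- make_trial_starts(n_trials, seed)
  horizon <- max(starts) + 30
  slopes <- rep(c(slope, -slope), length.out = n_units)
  units <- lapply(seq_len(n_units), function(j)
    synth_unit_spec(unit_id = sprintf("u%02d", j), baseline_rate = baseline,
                    ramp_slope = slopes[j],
                    trial_gain_noise = trial_gain_noise,
                    seed = seed * 1000L + j))
  trains <- lapply(units, gen_ramping_unit, trial_starts = starts,
                   horizon = horizon)
  spikes <- do.call(rbind, lapply(seq_along(units), function(j) {
    if (!length(trains[[j]])) return(NULL)
    data.frame(unit_id = units[[j]]$unit_id, time_s = trains[[j]])
  }))
  list(units = units, trains = trains, spikes = spikes, starts = starts,
       horizon = horizon, slopes = slopes)
}

# DDM-linked ensemble at the published intact-D2 operating point
make_linked_ensemble <- function(n_trials = 40, ddm_seed = 1L,
                                 ens_seed = 1L, ...) {
  run <- simulate_batch(intact_d2_params(n_sims = n_trials, seed = ddm_seed),
                        keep_trajectories = TRUE)
  spec <- synth_ensemble_spec(seed = ens_seed, ...)
  ens <- gen_ensemble_ddm_linked(spec, run)
  ens$run <- run
  ens
}
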