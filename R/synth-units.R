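#' Specification of a synthetic ramping unit
#'
#' A rate-based stand-in for a striatal medium spiny neuron: homogeneous
#' Poisson firing at `baseline_rate` outside the timed interval, and a
#' linear ramp `baseline + slope * t` over the first 6 s of each trial
#' (clipped at zero). Slope sign encodes up- (D2-like) versus down-
#' (D1-like) ramping; the published per-unit slope medians are of order
#' 0.1–0.3 spikes/s per s in magnitude.
#'
#' @param unit_id Identifier.
#' @param baseline_rate Baseline firing rate (spikes/s); units meant to pass
#'   the session-rate filter should sit inside 0.5–20 Hz.
#' @param ramp_slope Ramp slope over 0–6 s (spikes/s per s).
#' @param trial_gain_noise SD of the multiplicative per-trial log-normal
#'   gain jitter (0 disables it).
#' @param tagged Is the unit light-responsive?
#' @param tag_latency_ms Mean light-evoked spike latency (ms).
#' @param peak_trough_ratio,half_peak_width_ms Waveform features used by the
#'   MSN/FSI separation (MSN-like defaults; FSIs are narrow).
#' @param seed Integer seed.
#' @return A `synth_unit_spec` list.
#' @export
synth_unit_spec <- function(unit_id = "u1", baseline_rate = 5,
                            ramp_slope = 0.3, trial_gain_noise = 0.1,
                            tagged = FALSE, tag_latency_ms = 3,
                            peak_trough_ratio = 2.2,
                            half_peak_width_ms = 0.25, seed = 1L) {
  check_scalar(baseline_rate, "baseline_rate", 0)
  check_scalar(trial_gain_noise, "trial_gain_noise", 0)
  if (tag_latency_ms < 0) stop("tag_latency_ms must be >= 0", call. = FALSE)
  structure(
    list(unit_id = unit_id, baseline_rate = baseline_rate,
         ramp_slope = ramp_slope, trial_gain_noise = trial_gain_noise,
         tagged = tagged, tag_latency_ms = tag_latency_ms,
         peak_trough_ratio = peak_trough_ratio,
         half_peak_width_ms = half_peak_width_ms, seed = as.integer(seed)),
    class = "synth_unit_spec"
  )
}

#' Generate a ramping unit's spike train by Poisson thinning
#'
#' Samples an inhomogeneous Poisson process whose rate is
#' `max(0, baseline + slope * t_in_interval)` during the first
#' `interval_s` seconds of each trial and `baseline` elsewhere, over a
#' session of length `horizon`. Thinning against the session-wide rate
#' maximum is exact for this piecewise-linear rate.
#'
#' @param spec A `synth_unit_spec`.
#' @param trial_starts Absolute trial start times (s).
#' @param horizon Session length (s).
#' @param interval_s Ramp duration per trial (s), default 6.
#' @return Sorted numeric vector of spike times (s).
#' @export
gen_ramping_unit <- function(spec, trial_starts, horizon, interval_s = 6) {
  stopifnot(inherits(spec, "synth_unit_spec"))
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  set.seed(derive_seed(spec$seed, "ramping_unit"))
  gains <- if (spec$trial_gain_noise > 0)
    stats::rlnorm(length(trial_starts), meanlog = 0,
                  sdlog = spec$trial_gain_noise)
  else rep(1, length(trial_starts))

  rate_fn <- function(t) {
    r <- rep(spec$baseline_rate, length(t))
    for (k in seq_along(trial_starts)) {
      rel <- t - trial_starts[k]
      inside <- rel >= 0 & rel < interval_s
      r[inside] <- pmax(0, gains[k] *
                          (spec$baseline_rate + spec$ramp_slope * rel[inside]))
    }
    r
  }
  r_max <- max(spec$baseline_rate,
               max(gains) * (spec$baseline_rate +
                               max(0, spec$ramp_slope) * interval_s),
               1e-9)
  n_cand <- stats::rpois(1, r_max * horizon)
  cand <- sort(stats::runif(n_cand, 0, horizon))
  keep <- stats::runif(n_cand) < rate_fn(cand) / r_max
  cand[keep]
}

#' Generate optogenetic tagging pulses and evoked spikes
#'
#' For a tagged unit, each stimulation pulse evokes one spike at a latency
#' drawn from a truncated-positive normal around the unit's mean latency;
#' untagged units are unmodified. Returns the pulse times and the unit's
#' spike train with evoked spikes merged in.
#'
#' @param spec A `synth_unit_spec`.
#' @param n_pulses Number of pulses (>= 1).
#' @param pulse_start_s First pulse time (s); pulses are spaced `pulse_gap_s`
#'   apart (default 1 s).
#' @param pulse_gap_s Inter-pulse gap (s).
#' @param latency_sd_ms SD of the evoked latency (ms).
#' @param base_spikes Existing spike train to merge with (optional).
#' @return List with `pulse_times` and `spikes` (sorted).
#' @export
gen_tagging_responses <- function(spec, n_pulses, pulse_start_s = 0,
                                  pulse_gap_s = 1, latency_sd_ms = 0.5,
                                  base_spikes = numeric()) {
  stopifnot(inherits(spec, "synth_unit_spec"))
  if (n_pulses < 1) stop("need at least one pulse", call. = FALSE)
  pulses <- pulse_start_s + pulse_gap_s * (seq_len(n_pulses) - 1)
  if (!spec$tagged)
    return(list(pulse_times = pulses, spikes = sort(base_spikes)))
  set.seed(derive_seed(spec$seed, "tagging"))
  lat <- stats::rnorm(n_pulses, spec$tag_latency_ms, latency_sd_ms)
  while (any(lat <= 0))
    lat[lat <= 0] <- stats::rnorm(sum(lat <= 0), spec$tag_latency_ms,
                                  latency_sd_ms)
  list(pulse_times = pulses, spikes = sort(c(base_spikes, pulses + lat / 1000)))
}

#' Shrink an ensemble's ramp slopes toward flat
#'
#' Models receptor-blockade experiments, where ramping dynamics move toward
#' zero slope: every unit's `ramp_slope` is multiplied by `slope_shrink`
#' (1 = unchanged, 0 = flat).
#'
#' @param unit_specs List of `synth_unit_spec` objects.
#' @param slope_shrink Shrinkage factor in \[0, 1\].
#' @return List of modified specs.
#' @export
gen_blockade_ensemble <- function(unit_specs, slope_shrink) {
  check_scalar(slope_shrink, "slope_shrink", 0, 1)
  lapply(unit_specs, function(s) {
    stopifnot(inherits(s, "synth_unit_spec"))
    s$ramp_slope <- s$ramp_slope * slope_shrink
    s
  })
}
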