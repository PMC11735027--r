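#' Specification of a DDM-linked synthetic ensemble
#'
#' Describes an ensemble of spiking units whose trial-by-trial rates are
#' affine functions of the trial's latent drift-diffusion trajectory, built
#' so that a known weighted combination of the units' exponential-kernel
#' convolved activity crosses 0.5 at the trial's switch time. Half the
#' units couple positively to the accumulator (up-ramping) and half
#' negatively (down-ramping), mirroring the opposing D2/D1 dynamics the
#' readout was designed around.
#'
#' @param n_units Number of units (the readout regime needs > 11; default 16).
#' @param base_rate_range Range of per-unit baseline rates (spikes/s).
#' @param gain_range Range of per-unit coupling magnitudes (spikes/s per
#'   unit of scaled accumulator).
#' @param noise_sd SD of independent per-bin rate noise (spikes/s); the
#'   published readout regime ("default noise") is emulated at 1.
#' @param rate_scale Multiplies all rates (and divides the readout weights),
#'   so the noise-free limit can be approached with high-rate units.
#' @param commit_margin After a trial's threshold crossing the latent signal
#'   is held at least `0.5 + commit_margin`, modelling the movement-related
#'   regime change that accompanies the overt switch response.
#' @param kernel_w Exponential kernel time constant (s).
#' @param seed Integer seed.
#' @return A `synth_ensemble_spec` list.
#' @export
synth_ensemble_spec <- function(n_units = 16, base_rate_range = c(4, 10),
                                gain_range = c(8, 12), noise_sd = 1,
                                rate_scale = 1, commit_margin = 0.1,
                                kernel_w = 1, seed = 1L) {
  check_scalar(n_units, "n_units", 2)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(rate_scale, "rate_scale", .Machine$double.eps)
  check_scalar(kernel_w, "kernel_w", .Machine$double.eps)
  check_scalar(commit_margin, "commit_margin", 0)
  structure(
    list(n_units = as.integer(n_units), base_rate_range = base_rate_range,
         gain_range = gain_range, noise_sd = noise_sd,
         rate_scale = rate_scale, commit_margin = commit_margin,
         kernel_w = kernel_w, seed = as.integer(seed)),
    class = "synth_ensemble_spec"
  )
}

#' Generate a DDM-linked spiking ensemble
#'
#' For each trial of a [simulate_batch()] run (with trajectories kept), the
#' latent accumulator `x(t)` is rescaled to `s(t) = 0.5 (x - b) / (T - b)`,
#' which by construction first reaches 0.5 exactly when `x` first reaches
#' the threshold `T` — at the trial's switch time. Each unit's convolved-
#' activity target is `c_j + g_j s(t)`; the matching spike rate is obtained
#' by exact discrete deconvolution of the exponential kernel, plus
#' independent Gaussian rate noise, clipped at zero, and spikes are drawn
#' by thinning. The returned weights satisfy `sum(beta * c) = 0` and
#' `sum(beta * g) = 1`, so the beta-weighted convolved ensemble activity
#' tracks `s(t)` and crosses 0.5 at the switch time (up to spiking and rate
#' noise).
#'
#' @param spec A `synth_ensemble_spec`.
#' @param ddm_run A `ddm_run` with `trajectories` (use
#'   `simulate_batch(..., keep_trajectories = TRUE)`).
#' @return List with `spikes` (data frame: unit_id, trial_id, time_s,
#'   trial-relative), `switch_times` (true t* per trial; censored trials are
#'   dropped), `weights` (the construction's beta), `unit_base`, `unit_gain`,
#'   `times` (the rate grid) and the `spec`.
#' @export
gen_ensemble_ddm_linked <- function(spec, ddm_run) {
  stopifnot(inherits(spec, "synth_ensemble_spec"),
            inherits(ddm_run, "ddm_run"))
  if (is.null(ddm_run$trajectories))
    stop("ddm_run must keep trajectories", call. = FALSE)
  keep <- !ddm_run$censored
  if (!any(keep)) stop("no uncensored trials", call. = FALSE)
  traj <- ddm_run$trajectories[keep, , drop = FALSE]
  t_star <- ddm_run$switch_times[keep]
  p <- ddm_run$params
  if (p$threshold == p$b) stop("degenerate run (b equals threshold)",
                               call. = FALSE)

  set.seed(derive_seed(spec$seed, "ensemble_units"))
  n <- spec$n_units
  cj <- stats::runif(n, spec$base_rate_range[1], spec$base_rate_range[2])
  sgn <- rep(c(1, -1), length.out = n)
  gj <- sgn * stats::runif(n, spec$gain_range[1], spec$gain_range[2])
  # down-coupled units need headroom so their rate never clips at zero
  # over the accumulator's working range
  cj[sgn < 0] <- pmax(cj[sgn < 0], 0.75 * abs(gj[sgn < 0]) + 2)
  # least-norm beta with sum(beta*c) = 0, sum(beta*g) = 1
  M <- rbind(cj, gj)
  beta <- drop(t(M) %*% solve(M %*% t(M), c(0, 1)))
  if (abs(sum(beta)) < 1e-12 && all(beta == 0))
    stop("degenerate weights", call. = FALSE)

  dt <- p$dt
  w <- spec$kernel_w
  decay <- exp(-dt / w)
  gain_a <- w^2 * (1 - decay)  # convolved mass of one grid cell of rate
  s_mat <- 0.5 * (traj - p$b) / (p$threshold - p$b)  # trials x time
  n_time <- ncol(s_mat)
  times <- ddm_run$times

  spikes <- vector("list", nrow(s_mat) * n)
  idx <- 0L
  for (m in seq_len(nrow(s_mat))) {
    s <- s_mat[m, ]
    # after commitment the ensemble does not fall back below threshold:
    # the overt response brings its own (movement-related) activity shift
    post <- times >= t_star[m]
    s[post] <- pmax(s[post], 0.5 + spec$commit_margin)
    for (j in seq_len(n)) {
      y <- cj[j] + gj[j] * s
      # steady-state start: each unit's convolved activity approaches its
      # baseline over ~3 kernel widths, but the beta-weighted transient is
      # zero because sum(beta * c) = 0
      rho <- c(y[1], (y[-1] - decay * y[-n_time]) / gain_a)
      rho <- rho + stats::rnorm(n_time, 0, spec$noise_sd)
      rho <- pmax(0, rho) * spec$rate_scale
      st <- thin_piecewise(rho, times, dt)
      idx <- idx + 1L
      if (length(st))
        spikes[[idx]] <- data.frame(unit_id = sprintf("u%02d", j),
                                    trial_id = m, time_s = st,
                                    stringsAsFactors = FALSE)
    }
  }
  list(spikes = do.call(rbind, spikes[seq_len(idx)]),
       switch_times = t_star,
       weights = beta / spec$rate_scale, unit_base = cj, unit_gain = gj,
       times = times, spec = spec)
}

# spikes from a piecewise-constant rate on a grid (thinning)
thin_piecewise <- function(rate, times, dt) {
  r_max <- max(rate)
  if (r_max <= 0) return(numeric())
  horizon <- times[length(times)] + dt
  n_cand <- stats::rpois(1, r_max * horizon)
  cand <- sort(stats::runif(n_cand, 0, horizon))
  bin <- pmin(length(rate), findInterval(cand, times))
  cand[stats::runif(n_cand) < rate[bin] / r_max]
}

#' Rate-matched homogeneous-Poisson surrogate ensemble
#'
#' Replaces each unit's spikes on each trial with homogeneous Poisson
#' spikes at that unit's trial-average firing rate, destroying all temporal
#' structure while preserving mean rates — the negative control for the
#' ensemble readout.
#'
#' @param spikes Spike table (unit_id, trial_id, time_s, trial-relative).
#' @param duration_s Trial duration used for the rate normalization and the
#'   surrogate span (s).
#' @param seed Integer seed.
#' @return Surrogate spike table in the same format.
#' @export
gen_poisson_matched_surrogate <- function(spikes, duration_s, seed = 1L) {
  check_scalar(duration_s, "duration_s", .Machine$double.eps)
  set.seed(derive_seed(seed, "poisson_surrogate"))
  counts <- stats::aggregate(time_s ~ unit_id + trial_id, data = spikes,
                             FUN = length)
  out <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    k <- stats::rpois(1, counts$time_s[i])  # same expected count
    if (k > 0)
      out[[i]] <- data.frame(unit_id = counts$unit_id[i],
                             trial_id = counts$trial_id[i],
                             time_s = sort(stats::runif(k, 0, duration_s)),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
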