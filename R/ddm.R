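#' Drift-diffusion model parameters
#'
#' Bundles the four model parameters of the interval-timing drift-diffusion
#' model (DDM) with its integration settings. The latent decision variable
#' `x(t)` starts at baseline `b` and relaxes toward the input level `F` at
#' drift rate `D` under additive Gaussian noise of strength `sigma`:
#' `dx = (F - x) D dt + sigma dW`. A switch response is emitted when `x`
#' first reaches the threshold `T = F (1 - b/4) + (1 - F) b/4`, so the
#' dynamics are up-crossing for D2-like parameters (`F = 1`) and
#' down-crossing for D1-like parameters (`F = 0`).
#'
#' @param F Target input level (dimensionless; 1 for up-ramping D2-MSN-like
#'   dynamics, 0 for down-ramping D1-MSN-like dynamics).
#' @param b Baseline initial value `x(0)`, in \[0, 1\].
#' @param D Drift rate (1/s).
#' @param sigma Noise strength (per sqrt-second); must be non-negative.
#' @param dt Integration step (s).
#' @param t_max Per-trial simulation horizon (s).
#' @param n_sims Trials per batch.
#' @param seed Integer RNG seed.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(F = 1, b = 0.52, D = 0.135, sigma = 0.052)
#' compute_threshold(p$F, p$b)
#' @export
ddm_params <- function(F, b, D, sigma, dt = 0.1, t_max = 25, n_sims = 500,
                       seed = 1L) {
  check_scalar(F, "F")
  check_scalar(b, "b", 0, 1)
  check_scalar(D, "D")
  check_scalar(sigma, "sigma", 0)
  check_scalar(dt, "dt", .Machine$double.eps)
  check_scalar(t_max, "t_max", .Machine$double.eps)
  check_scalar(n_sims, "n_sims", 1)
  structure(
    list(F = F, b = b, D = D, sigma = sigma, dt = dt, t_max = t_max,
         n_sims = as.integer(n_sims), seed = as.integer(seed),
         threshold = compute_threshold(F, b)),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: F = %g, b = %g, D = %g, sigma = %g (threshold T = %g)\n",
    x$F, x$b, x$D, x$sigma, x$threshold))
  cat(sprintf("  integration: dt = %g s, horizon = %g s, %d trials, seed %d\n",
              x$dt, x$t_max, x$n_sims, x$seed))
  invisible(x)
}

#' Decision threshold of the interval-timing DDM
#'
#' The threshold is tied to the input level and baseline,
#' `T = (1 - b/4) F + (b/4) (1 - F)`: with `F = 1` the threshold sits just
#' below the input level, with `F = 0` just above zero, so at the published
#' baselines the distance from start to threshold is comparable in the two
#' directions.
#'
#' @param F Target input level.
#' @param b Baseline initial value, in \[0, 1\].
#' @return The threshold level (dimensionless).
#' @examples
#' compute_threshold(1, 0.52)  # 0.87
#' compute_threshold(0, 0.48)  # 0.12
#' @export
compute_threshold <- function(F, b) {
  if (!all(is.finite(F)) || !all(is.finite(b)))
    stop("`F` and `b` must be finite", call. = FALSE)
  if (any(b < 0 | b > 1)) stop("`b` must lie in [0, 1]", call. = FALSE)
  (1 - b / 4) * F + (b / 4) * (1 - F)
}

#' Closed-form crossing time of the noise-free DDM
#'
#' With `sigma = 0` the model reduces to the ODE `dx/dt = (F - x) D`, whose
#' solution `x(t) = F + (b - F) exp(-D t)` reaches the threshold at
#' `t* = ln(|F - b| / |F - T|) / D`. This is the analytic oracle against
#' which the discrete Euler–Maruyama simulation converges as `dt -> 0`.
#'
#' @param params A `ddm_params` object (its `sigma` is ignored).
#' @return Crossing time in seconds.
#' @export
noise_free_crossing_time <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  F <- params$F; b <- params$b; D <- params$D; Tthr <- params$threshold
  if (D <= 0) stop("noise-free crossing requires D > 0", call. = FALSE)
  if (b == Tthr) return(0)
  # pure drift moves x monotonically from b toward F; T must lie between
  if (!((b < Tthr && Tthr < F) || (F < Tthr && Tthr < b)))
    stop("threshold unreachable under pure drift toward F", call. = FALSE)
  log(abs(F - b) / abs(F - Tthr)) / D
}

#' Simulate one DDM trial
#'
#' Euler–Maruyama integration `x_new = x_old + (F - x_old) D dt +
#' sigma sqrt(dt) N(0,1)` from `x(0) = b`, with crossing detected at the
#' first grid step at-or-beyond the threshold in the drift direction
#' (inclusive). The switch response time is `step_index * dt`; trials that
#' never cross within `t_max` are censored.
#'
#' @param params A `ddm_params` object.
#' @param keep_trajectory Return the sampled path?
#' @return A list with `t_star` (`NA` when censored), `censored`,
#'   `degenerate` (start exactly at threshold) and optionally `trajectory`
#'   (the path on the `dt` grid, including `x(0)`).
#' @export
simulate_trial <- function(params, keep_trajectory = FALSE) {
  run <- simulate_batch(params_n(params, 1L), keep_trajectories = keep_trajectory,
                        allow_all_censored = TRUE)
  list(
    t_star = if (run$censored[1]) NA_real_ else run$switch_times[1],
    censored = run$censored[1],
    degenerate = params$b == params$threshold,
    trajectory = if (keep_trajectory) run$trajectories[1, ] else NULL
  )
}

params_n <- function(params, n) {
  params$n_sims <- as.integer(n)
  params
}

#' Simulate a batch of DDM trials
#'
#' Runs `n_sims` independent Euler–Maruyama trials under a seeded RNG and
#' collects the switch response times. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params A `ddm_params` object.
#' @param keep_trajectories Keep the `n_sims x (n_steps + 1)` path matrix?
#'   Paths continue to the horizon even after crossing, so they can drive the
#'   synthetic ensemble generator.
#' @param allow_all_censored Internal: suppress the all-censored error.
#' @return An object of class `ddm_run` with `switch_times` (crossing time
#'   per trial, `NA` when censored), `censored` flags, the `params`, and
#'   optionally `trajectories`.
#' @examples
#' run <- simulate_batch(ddm_params(1, 0.52, 0.135, 0.052, seed = 7))
#' median(run$switch_times, na.rm = TRUE)
#' @export
simulate_batch <- function(params, keep_trajectories = FALSE,
                           allow_all_censored = FALSE) {
  stopifnot(inherits(params, "ddm_params"))
  n <- params$n_sims
  n_steps <- round(params$t_max / params$dt)
  Tthr <- params$threshold
  up <- params$b < Tthr
  degenerate <- params$b == Tthr

  set.seed(params$seed)
  x <- rep(params$b, n)
  t_star <- rep(NA_real_, n)
  if (degenerate) t_star[] <- 0
  alive <- !degenerate & rep(TRUE, n)
  traj <- if (keep_trajectories)
    matrix(params$b, n, n_steps + 1L) else NULL

  sdt <- params$sigma * sqrt(params$dt)
  for (i in seq_len(n_steps)) {
    # one shared draw layout per step keeps the stream independent of who is
    # still alive, so trajectories and crossing times come from one process
    eps <- stats::rnorm(n)
    x <- x + (params$F - x) * params$D * params$dt + sdt * eps
    if (keep_trajectories) traj[, i + 1L] <- x
    hit <- alive & (if (up) x >= Tthr else x <= Tthr)
    t_star[hit] <- i * params$dt
    alive <- alive & !hit
  }

  censored <- is.na(t_star)
  if (all(censored) && !allow_all_censored)
    stop("all trials censored: parameters cannot produce a switch-time distribution",
         call. = FALSE)
  structure(
    list(params = params, switch_times = t_star, censored = censored,
         degenerate = degenerate, trajectories = traj,
         times = seq(0, by = params$dt, length.out = n_steps + 1L)),
    class = "ddm_run"
  )
}

#' @export
print.ddm_run <- function(x, ...) {
  ok <- !x$censored
  cat(sprintf("DDM run: %d trials, %d censored; median switch time %.2f s\n",
              length(x$switch_times), sum(x$censored),
              stats::median(x$switch_times[ok])))
  invisible(x)
}
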