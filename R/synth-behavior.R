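#' Specification for a synthetic behavioral session
#'
#' Describes the switch task's statistics: on half the trials (the "long",
#' 18-s trials) the reward moves to the second nosepoke and the animal's
#' departure from the first nosepoke defines the switch response time; the
#' remaining short (6-s) trials are generated but flagged non-analyzed.
#' Switch times are gamma distributed with defaults matching the published
#' model fit (shape 6.08, rate 0.69 per second), and intertrial intervals
#' have a geometric mean of 30 s.
#'
#' @param n_trials Total number of trials.
#' @param gamma_shape,gamma_rate Switch-time gamma parameters.
#' @param p_long Fraction of long (switch) trials.
#' @param iti_geometric_mean_s Geometric mean of the intertrial interval (s).
#' @param p_laser Fraction of long trials with the laser on (whole-trial).
#' @param laser_shift_s Additive shift of mean switch time on laser trials
#'   (s); models disruption experiments, 0 by default.
#' @param mouse_id,session_id Identifier strings.
#' @param seed Integer seed.
#' @return A `synth_behavior_spec` list.
#' @export
synth_behavior_spec <- function(n_trials = 100, gamma_shape = 6.08,
                                gamma_rate = 0.69, p_long = 0.5,
                                iti_geometric_mean_s = 30, p_laser = 0,
                                laser_shift_s = 0,
                                mouse_id = "m1", session_id = "s1",
                                seed = 1L) {
  check_scalar(n_trials, "n_trials", 1)
  check_scalar(gamma_shape, "gamma_shape", .Machine$double.eps)
  check_scalar(gamma_rate, "gamma_rate", .Machine$double.eps)
  check_scalar(p_long, "p_long", 0, 1)
  check_scalar(iti_geometric_mean_s, "iti_geometric_mean_s",
               .Machine$double.eps)
  check_scalar(p_laser, "p_laser", 0, 1)
  structure(
    list(n_trials = as.integer(n_trials), gamma_shape = gamma_shape,
         gamma_rate = gamma_rate, p_long = p_long,
         iti_geometric_mean_s = iti_geometric_mean_s, p_laser = p_laser,
         laser_shift_s = laser_shift_s, mouse_id = mouse_id,
         session_id = session_id, seed = as.integer(seed)),
    class = "synth_behavior_spec"
  )
}

#' Draw gamma-distributed switch response times
#'
#' @param spec A `synth_behavior_spec`.
#' @param n Number of draws (default: the spec's expected number of long
#'   trials).
#' @return Numeric vector of switch times in seconds from trial start.
#' @export
gen_switch_times <- function(spec, n = NULL) {
  stopifnot(inherits(spec, "synth_behavior_spec"))
  if (is.null(n)) n <- max(1L, round(spec$n_trials * spec$p_long))
  set.seed(derive_seed(spec$seed, "switch_times"))
  stats::rgamma(n, shape = spec$gamma_shape, rate = spec$gamma_rate)
}

#' Generate a behavioral event log around given switch times
#'
#' Emits the task's event grammar per trial, with times in seconds relative
#' to trial start. Long trials carry one or more first-nosepoke bouts whose
#' final exit is exactly the trial's switch time, then a second-nosepoke
#' entry after a positive (log-normal, median ~1 s) traversal gap, and a
#' reward at `max(18 s, second entry)`. Short 6-s trials are emitted with
#' the short-latency poke-and-reward pattern and are flagged for exclusion
#' downstream. Whole-trial laser trials get `laser_on` at 0 and `laser_off`
#' at 18 s.
#'
#' @param spec A `synth_behavior_spec`.
#' @param switch_times Switch time per long trial; drawn from the spec when
#'   omitted. Laser-trial shifts (`laser_shift_s`) are applied here.
#' @return List with `events` (data frame: mouse_id, session_id, trial_id,
#'   trial_type, event_type, time_s), `trials` (trial_id, trial_type,
#'   start_abs_s, laser_on) and `switch_times` (per long trial, after any
#'   laser shift).
#' @export
gen_event_log <- function(spec, switch_times = NULL) {
  stopifnot(inherits(spec, "synth_behavior_spec"))
  set.seed(derive_seed(spec$seed, "event_log"))
  n <- spec$n_trials
  is_long <- stats::runif(n) < spec$p_long
  n_long <- sum(is_long)
  if (is.null(switch_times)) {
    switch_times <- gen_switch_times(spec, n_long)
    set.seed(derive_seed(spec$seed, "event_log_structure"))
  }
  if (length(switch_times) != n_long)
    stop("need one switch time per long trial", call. = FALSE)
  if (any(switch_times <= 0))
    stop("switch times must be positive", call. = FALSE)

  laser <- rep(FALSE, n)
  laser[is_long] <- stats::runif(n_long) < spec$p_laser
  sw <- switch_times
  sw[laser[is_long]] <- sw[laser[is_long]] + spec$laser_shift_s

  # intertrial gaps: log-normal with the requested geometric mean
  iti <- stats::rlnorm(n, meanlog = log(spec$iti_geometric_mean_s),
                       sdlog = 0.3)
  starts <- cumsum(c(0, utils::head(iti, -1) + 20))  # 20 s nominal trial span

  rows <- vector("list", n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is_long[i]) {
      k <- k + 1L
      st <- sw[k]
      ev <- long_trial_events(st, laser[i])
    } else {
      ev <- short_trial_events()
    }
    rows[[i]] <- data.frame(
      mouse_id = spec$mouse_id, session_id = spec$session_id,
      trial_id = i, trial_type = if (is_long[i]) "long" else "short",
      event_type = ev$type, time_s = ev$time,
      stringsAsFactors = FALSE)
  }
  list(
    events = do.call(rbind, rows),
    trials = data.frame(trial_id = seq_len(n),
                        trial_type = ifelse(is_long, "long", "short"),
                        start_abs_s = starts, laser_on = laser,
                        stringsAsFactors = FALSE),
    switch_times = sw
  )
}

# one long trial's ordered events; final first-nosepoke exit == switch time
long_trial_events <- function(switch_time, laser) {
  n_bouts <- 1L + stats::rpois(1, 0.7)
  final_in <- switch_time * stats::runif(1, 0.3, 0.8)
  type <- "trial_start"; time <- 0
  if (laser) { type <- c(type, "laser_on"); time <- c(time, 0) }
  if (n_bouts > 1L) {
    pts <- sort(stats::runif(2L * (n_bouts - 1L), 0.02 * switch_time,
                             0.95 * final_in))
    type <- c(type, rep(c("first_np_in", "first_np_out"), n_bouts - 1L))
    time <- c(time, pts)
  }
  traversal <- stats::rlnorm(1, meanlog = 0, sdlog = 0.4)
  second_in <- switch_time + traversal
  reward <- max(18, second_in)
  type <- c(type, "first_np_in", "first_np_out", "second_np_in", "reward",
            "second_np_out")
  time <- c(time, final_in, switch_time, second_in, reward,
            reward + stats::runif(1, 0.2, 1))
  if (laser) { type <- c(type, "laser_off"); time <- c(time, 18) }
  o <- order(time)
  list(type = type[o], time = time[o])
}

short_trial_events <- function() {
  first_in <- stats::runif(1, 0.2, 2)
  list(type = c("trial_start", "first_np_in", "reward", "first_np_out"),
       time = c(0, first_in, 6, 6 + stats::rexp(1, 2)))
}
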