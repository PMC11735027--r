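#' Trial-by-trial GLM ramp slope of one unit
#'
#' Bins each trial's spikes over the timed interval, pools the trial x bin
#' observations, and regresses firing rate on time in the interval, with
#' the per-bin nosepoke count as a movement regressor (dropped automatically
#' when no nosepokes fall inside the interval). The default family is an
#' identity-link Gaussian on binned rates, so the slope carries spikes/s
#' per s; a log-link Poisson on counts is available as an option.
#'
#' Sensitivity variants: `"outlier_excluded"` refits after dropping
#' observations outside the 95% prediction interval of the first fit;
#' `"to_switch"` truncates each trial's observations at that trial's switch
#' time.
#'
#' @param spike_times Unit's spike times (s, session clock).
#' @param trial_starts Trial start times (s).
#' @param nosepoke_times Nosepoke event times (s, session clock), optional.
#' @param switch_times Per-trial switch times (s, trial-relative); required
#'   for the `"to_switch"` variant.
#' @param interval Analysis interval (s), default 0–6.
#' @param bin_width Bin width (s), default 0.2.
#' @param variant One of `"full_interval"`, `"outlier_excluded"`,
#'   `"to_switch"`.
#' @param family `"gaussian"` (rates, identity link) or `"poisson"`
#'   (counts, log link).
#' @return A `ramp_fit` list: `slope` (spikes/s per s for the Gaussian
#'   family), `intercept`, `nosepoke_beta` (`NA` when dropped), `variant`,
#'   `family`, `n_obs`.
#' @export
glm_ramp_slope <- function(spike_times, trial_starts, nosepoke_times = NULL,
                           switch_times = NULL, interval = c(0, 6),
                           bin_width = 0.2, variant = "full_interval",
                           family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  variant <- match.arg(variant,
                       c("full_interval", "outlier_excluded", "to_switch"))
  check_scalar(bin_width, "bin_width", .Machine$double.eps)
  breaks <- seq(interval[1], interval[2], by = bin_width)
  centers <- breaks[-1] - bin_width / 2
  if (variant == "to_switch" && is.null(switch_times))
    stop("`to_switch` variant needs per-trial switch times", call. = FALSE)

  rows <- vector("list", length(trial_starts))
  for (i in seq_along(trial_starts)) {
    rel <- spike_times - trial_starts[i]
    cnt <- tabulate(findInterval(
      rel[rel >= interval[1] & rel < interval[2]], breaks), length(centers))
    npk <- if (!is.null(nosepoke_times)) {
      nrel <- nosepoke_times - trial_starts[i]
      tabulate(findInterval(
        nrel[nrel >= interval[1] & nrel < interval[2]], breaks),
        length(centers))
    } else rep(0L, length(centers))
    keep <- rep(TRUE, length(centers))
    if (variant == "to_switch") keep <- centers <= switch_times[i]
    rows[[i]] <- data.frame(time_s = centers[keep],
                            count = cnt[keep], nosepoke = npk[keep])
  }
  dat <- do.call(rbind, rows)
  dat$rate <- dat$count / bin_width
  if (length(unique(dat$time_s)) < 2)
    stop("fewer than 2 distinct time bins", call. = FALSE)

  use_np <- sum(dat$nosepoke) > 0
  fml <- if (use_np) rate ~ time_s + nosepoke else rate ~ time_s
  fit1 <- if (family == "gaussian") {
    stats::lm(fml, data = dat)
  } else {
    f2 <- if (use_np) count ~ time_s + nosepoke else count ~ time_s
    stats::glm(f2, data = dat, family = stats::poisson())
  }

  if (variant == "outlier_excluded" && family == "gaussian") {
    # prediction interval evaluated on the fitting data by design: the
    # variant drops observations the first fit cannot account for
    pi95 <- suppressWarnings(
      stats::predict(fit1, interval = "prediction", level = 0.95))
    inlier <- dat$rate >= pi95[, "lwr"] & dat$rate <= pi95[, "upr"]
    fit1 <- stats::lm(fml, data = dat[inlier, , drop = FALSE])
    dat <- dat[inlier, , drop = FALSE]
  }

  co <- stats::coef(fit1)
  structure(
    list(slope = unname(co["time_s"]), intercept = unname(co[1]),
         nosepoke_beta = if (use_np) unname(co["nosepoke"]) else NA_real_,
         variant = variant, family = family, n_obs = nrow(dat)),
    class = "ramp_fit"
  )
}
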