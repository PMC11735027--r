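#' Readout configuration
#'
#' Settings for the exponential-kernel + logistic ensemble readout: a causal
#' kernel `K(t) = w exp(-t/w)` for `t > 0` (zero otherwise) with `w = 1` s,
#' an evaluation grid, the 0.5 crossing level, and the accuracy window
#' within which a predicted switch time counts as correct.
#'
#' @param kernel_w Kernel time constant `w` (s).
#' @param grid_step Evaluation grid step (s).
#' @param t_max Evaluation horizon (s).
#' @param accuracy_window_s Tolerance `|t_pred - t*|` for a correct trial (s);
#'   the "within a 1-s window" criterion read as plus/minus 1 s (set 0.5 for
#'   the stricter reading).
#' @param lambda Ridge penalty of the logistic fit: it both handles perfect
#'   separation on clean synthetic data and bounds how much a per-trial fit
#'   can chase trial-specific noise.
#' @return A `readout_config` list.
#' @export
readout_config <- function(kernel_w = 1, grid_step = 0.1, t_max = 25,
                           accuracy_window_s = 1, lambda = 0.2) {
  check_scalar(kernel_w, "kernel_w", .Machine$double.eps)
  check_scalar(grid_step, "grid_step", .Machine$double.eps)
  check_scalar(accuracy_window_s, "accuracy_window_s", 0)
  check_scalar(lambda, "lambda", 0)
  structure(list(kernel_w = kernel_w, grid_step = grid_step, t_max = t_max,
                 accuracy_window_s = accuracy_window_s, lambda = lambda),
            class = "readout_config")
}

#' Convolve a spike train with the causal exponential kernel
#'
#' Computes `x(t) = sum over spikes of w exp(-(t - t_spike)/w)` for
#' `t >= t_spike`, evaluated on a regular grid. A single spike therefore
#' contributes `w` at its own time and `w e^(-1)` one time constant later.
#'
#' @param spike_times Sorted spike times (s).
#' @param grid Evaluation times (regular, increasing).
#' @param kernel_w Kernel time constant `w` (s).
#' @return Numeric vector `x` on the grid.
#' @export
exp_kernel_convolve <- function(spike_times, grid, kernel_w = 1) {
  check_scalar(kernel_w, "kernel_w", .Machine$double.eps)
  n <- length(grid)
  x <- numeric(n)
  if (!length(spike_times)) return(x)
  spike_times <- sort(spike_times)
  step <- if (n > 1) grid[2] - grid[1] else 1
  decay <- exp(-step / kernel_w)
  lo <- c(-Inf, grid[-n])
  acc <- 0
  for (i in seq_len(n)) {
    inbin <- spike_times[spike_times > lo[i] & spike_times <= grid[i]]
    acc <- acc * (if (i == 1) 1 else decay) +
      sum(kernel_w * exp(-(grid[i] - inbin) / kernel_w))
    x[i] <- acc
  }
  x
}

#' Fit the logistic ensemble readout of switch times
#'
#' Builds, for every trial and grid time, the binary label "has the animal
#' switched yet" (`1` when `t >= t*`) and regresses it on the per-time
#' vector of kernel-convolved unit activities with a ridge-penalized
#' logistic fit. The logistic output
#' `y(t) = 1 / (1 + exp(-(bhat0 + sum_j bhatj x_j(t))))` crosses 0.5 where
#' the linear predictor crosses 0, so each trial's predicted switch time is
#' the first grid time with non-negative linear predictor. The implied
#' ensemble weights are `beta_j = k * bhat_j` with `k = -0.5 / bhat0`, under
#' which the weighted activity `sum_j beta_j x_j(t)` crosses the level 0.5
#' at the same grid time.
#'
#' Fitting modes: `"per_trial"` (default) runs one logistic fit per trial
#' and reads that trial's crossing from its own fit; `"pooled"` fits one
#' set of weights across all trials and predicts each trial from the shared
#' fit (optionally leave-one-trial-out via `loto`).
#'
#' @param spikes Spike table (unit_id, trial_id, time_s, trial-relative).
#' @param switch_times True switch time per trial (ordered by the sorted
#'   unique trial ids in `spikes`).
#' @param config A [readout_config()].
#' @param fit `"per_trial"` or `"pooled"`.
#' @param loto Pooled mode only: leave-one-trial-out predictions instead of
#'   in-sample (refits the readout once per held-out trial).
#' @return An `ensemble_readout` list: `beta_hat_0`, `beta_hat` (per unit;
#'   per-trial medians in per-trial mode, with the full per-trial
#'   coefficient matrix in `beta_hat_trials`), `k`, `beta` (implied
#'   weights), `t_pred` (per trial, `NA` when the predictor never crosses),
#'   `t_true`, `accuracy`, `accurate` flags, `grid`, `config`.
#' @export
fit_readout <- function(spikes, switch_times, config = readout_config(),
                        fit = c("per_trial", "pooled"), loto = FALSE) {
  stopifnot(inherits(config, "readout_config"))
  fit <- match.arg(fit)
  units <- sort(unique(spikes$unit_id))
  trials <- sort(unique(spikes$trial_id))
  if (length(units) < 2) stop("need at least 2 units", call. = FALSE)
  if (length(trials) < 2) stop("need at least 2 trials", call. = FALSE)
  if (length(switch_times) != length(trials))
    stop("need one switch time per trial", call. = FALSE)

  grid <- seq(config$grid_step, config$t_max, by = config$grid_step)
  n_t <- length(grid)
  # activity array: per trial a (time x unit) matrix
  xs <- lapply(trials, function(m) {
    sm <- spikes[spikes$trial_id == m, , drop = FALSE]
    mat <- matrix(0, n_t, length(units),
                  dimnames = list(NULL, units))
    for (u in unique(sm$unit_id))
      mat[, u] <- exp_kernel_convolve(sm$time_s[sm$unit_id == u], grid,
                                      config$kernel_w)
    mat
  })
  ridge_logistic <- function(Xm, ym) {
    f <- glmnet::glmnet(Xm, ym, family = "binomial", alpha = 0,
                        lambda = config$lambda, standardize = FALSE)
    list(b0 = as.numeric(f$a0),
         b = as.numeric(as.matrix(stats::coef(f))[-1]))
  }
  first_crossing <- function(co, Xm) {
    lp <- co$b0 + drop(Xm %*% co$b)
    hit <- which(lp >= 0)
    if (length(hit)) grid[hit[1]] else NA_real_
  }

  t_pred <- numeric(length(trials))
  if (fit == "per_trial") {
    b0s <- numeric(length(trials))
    bs <- matrix(NA_real_, length(trials), length(units),
                 dimnames = list(NULL, units))
    for (i in seq_along(trials)) {
      co <- ridge_logistic(xs[[i]], as.numeric(grid >= switch_times[i]))
      b0s[i] <- co$b0
      bs[i, ] <- co$b
      t_pred[i] <- first_crossing(co, xs[[i]])
    }
    b0 <- stats::median(b0s)
    bmed <- apply(bs, 2, stats::median)
    beta_hat_trials <- bs
  } else {
    X <- do.call(rbind, xs)
    ylab <- unlist(lapply(seq_along(trials),
                          function(i) as.numeric(grid >= switch_times[i])))
    all_rows <- seq_len(nrow(X))
    full <- ridge_logistic(X, ylab)
    for (i in seq_along(trials)) {
      co <- full
      if (loto) {
        drop_rows <- ((i - 1) * n_t + 1):(i * n_t)
        co <- ridge_logistic(X[setdiff(all_rows, drop_rows), , drop = FALSE],
                             ylab[setdiff(all_rows, drop_rows)])
      }
      t_pred[i] <- first_crossing(co, xs[[i]])
    }
    b0 <- full$b0
    bmed <- full$b
    beta_hat_trials <- NULL
  }

  k <- -0.5 / b0
  acc <- readout_accuracy(t_pred, switch_times, config$accuracy_window_s)
  structure(
    list(beta_hat_0 = b0, beta_hat = stats::setNames(bmed, units),
         k = k, beta = stats::setNames(k * bmed, units),
         beta_hat_trials = beta_hat_trials,
         t_pred = t_pred, t_true = switch_times,
         accurate = !is.na(t_pred) &
           abs(t_pred - switch_times) <= config$accuracy_window_s,
         accuracy = acc, grid = grid, config = config, fit = fit,
         loto = loto),
    class = "ensemble_readout"
  )
}

#' @export
print.ensemble_readout <- function(x, ...) {
  cat(sprintf(
    "ensemble readout (%d units, %d trials, %s%s): accuracy %.1f%% within %g s\n",
    length(x$beta_hat), length(x$t_pred), x$fit,
    if (x$loto) ", leave-one-trial-out" else "",
    100 * x$accuracy, x$config$accuracy_window_s))
  invisible(x)
}

#' Fraction of trials predicted within the accuracy window
#'
#' @param t_pred Predicted switch times (`NA` allowed: counts as a miss).
#' @param t_true True switch times.
#' @param window_s Tolerance (s).
#' @return Fraction in \[0, 1\].
#' @export
readout_accuracy <- function(t_pred, t_true, window_s = 1) {
  if (length(t_pred) != length(t_true))
    stop("prediction/truth length mismatch", call. = FALSE)
  ok <- !is.na(t_pred) & abs(t_pred - t_true) <= window_s
  mean(ok)
}
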