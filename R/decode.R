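#' Temporal decoder configuration
#'
#' Naive-Bayes settings: 0.5-s bins over a (-6, 24) s window around trial
#' start (6 s of padding on either side of the 18-s trial to avoid edge
#' effects), interval epochs (0–6, 6–12, 12–18 s), a minimum of more than
#' 20 trials per unit, a per-unit-per-bin Poisson likelihood with the
#' training mean floored at a small positive count, and a uniform prior
#' over bins.
#'
#' @param bin_width_s Bin width (s).
#' @param window Decoding window around trial start (s).
#' @param epochs List of two-element epoch intervals (s).
#' @param min_trials_per_unit Units need strictly more trials than this.
#' @param rate_floor Minimum training mean count per bin.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(bin_width_s = 0.5, window = c(-6, 24),
                           epochs = list(c(0, 6), c(6, 12), c(12, 18)),
                           min_trials_per_unit = 20, rate_floor = 0.1) {
  check_scalar(bin_width_s, "bin_width_s", .Machine$double.eps)
  stopifnot(length(window) == 2, window[1] < window[2])
  for (ep in epochs)
    if (ep[1] < window[1] || ep[2] > window[2])
      stop("epochs must lie within the window", call. = FALSE)
  structure(list(bin_width_s = bin_width_s, window = window, epochs = epochs,
                 min_trials_per_unit = min_trials_per_unit,
                 rate_floor = rate_floor),
            class = "decoder_config")
}

# unit x trial x bin spike-count array
bin_counts_array <- function(spikes, trial_starts, config) {
  units <- sort(unique(spikes$unit_id))
  breaks <- seq(config$window[1], config$window[2], by = config$bin_width_s)
  centers <- breaks[-1] - config$bin_width_s / 2
  arr <- array(0, dim = c(length(units), length(trial_starts),
                          length(centers)),
               dimnames = list(units, NULL, NULL))
  for (u in seq_along(units)) {
    st <- spikes$time_s[spikes$unit_id == units[u]]
    for (m in seq_along(trial_starts)) {
      rel <- st - trial_starts[m]
      rel <- rel[rel >= config$window[1] & rel < config$window[2]]
      arr[u, m, ] <- tabulate(findInterval(rel, breaks), length(centers))
    }
  }
  list(counts = arr, centers = centers, units = units)
}

#' Naive-Bayes temporal decoding with leave-one-out cross-validation
#'
#' Learns each unit's mean spike count per time bin from all trials but
#' one, then decodes the held-out trial: for every objective bin, the
#' posterior over candidate times is the product over units of Poisson
#' likelihoods (uniform prior), and the predicted time is the
#' posterior-argmax bin center. Repeats over all trials.
#'
#' @param spikes Spike table (unit_id, time_s; session clock).
#' @param trial_starts Trial start times (s).
#' @param config A [decoder_config()].
#' @return A `decode_result` list: `predicted` (trial x bin matrix of
#'   predicted times), `objective` (bin centers), `config`, `n_units`.
#' @export
bayes_decode_loocv <- function(spikes, trial_starts,
                               config = decoder_config()) {
  stopifnot(inherits(config, "decoder_config"))
  n_trials <- length(trial_starts)
  if (n_trials < 2) stop("leave-one-out needs at least 2 trials",
                         call. = FALSE)
  if (n_trials <= config$min_trials_per_unit)
    stop(sprintf("units need more than %d trials (got %d)",
                 config$min_trials_per_unit, n_trials), call. = FALSE)
  ba <- bin_counts_array(spikes, trial_starts, config)
  decode_from_counts(ba, config)
}

decode_from_counts <- function(ba, config) {
  counts <- ba$counts
  n_units <- dim(counts)[1]; n_trials <- dim(counts)[2]
  n_bins <- dim(counts)[3]
  predicted <- matrix(NA_real_, n_trials, n_bins)
  for (m in seq_len(n_trials)) {
    lambda <- apply(counts[, -m, , drop = FALSE], c(1, 3), mean)
    lambda <- pmax(lambda, config$rate_floor)
    loglam <- log(lambda)
    for (bobs in seq_len(n_bins)) {
      k <- counts[, m, bobs]
      # Poisson log-likelihood per candidate bin, summed over units
      ll <- colSums(k * loglam - lambda)
      predicted[m, bobs] <- ba$centers[which.max(ll)]
    }
  }
  structure(list(predicted = predicted, objective = ba$centers,
                 config = config, n_units = n_units),
            class = "decode_result")
}

#' Epoch-wise decoding R-squared
#'
#' Per trial and epoch, the squared Pearson correlation between the
#' objective bin-center times and the decoder's predicted times, restricted
#' to bins inside the epoch. Constant predictions (zero variance) yield 0
#' with a flag; epochs with fewer than 3 bins are undefined.
#'
#' @param result A `decode_result`.
#' @param epochs Epoch list; defaults to the result's config.
#' @return Data frame with `trial`, `epoch` (label "lo-hi"), `r2`,
#'   `degenerate` (constant-prediction flag).
#' @export
decode_r2_by_epoch <- function(result, epochs = NULL) {
  stopifnot(inherits(result, "decode_result"))
  if (is.null(epochs)) epochs <- result$config$epochs
  out <- list()
  for (ep in epochs) {
    sel <- result$objective >= ep[1] & result$objective < ep[2]
    lab <- sprintf("%g-%g", ep[1], ep[2])
    if (sum(sel) < 3)
      stop(sprintf("epoch %s has fewer than 3 bins", lab), call. = FALSE)
    for (m in seq_len(nrow(result$predicted))) {
      pred <- result$predicted[m, sel]
      obj <- result$objective[sel]
      degen <- stats::sd(pred) == 0
      r2 <- if (degen) 0 else suppressWarnings(stats::cor(obj, pred)^2)
      out[[length(out) + 1L]] <- data.frame(trial = m, epoch = lab,
                                            r2 = r2, degenerate = degen)
    }
  }
  do.call(rbind, out)
}

#' Time-shuffled decoding control
#'
#' Permutes each trial's bin order of spike counts independently per unit
#' (seeded) before running the identical leave-one-out decoder, destroying
#' temporal structure while preserving each unit's per-trial counts.
#'
#' @param spikes Spike table (unit_id, time_s).
#' @param trial_starts Trial start times (s).
#' @param config A [decoder_config()].
#' @param seed Integer seed.
#' @return A `decode_result` on the shuffled counts.
#' @export
shuffle_control <- function(spikes, trial_starts,
                            config = decoder_config(), seed = 1L) {
  n_trials <- length(trial_starts)
  if (n_trials <= config$min_trials_per_unit)
    stop(sprintf("units need more than %d trials (got %d)",
                 config$min_trials_per_unit, n_trials), call. = FALSE)
  ba <- bin_counts_array(spikes, trial_starts, config)
  set.seed(derive_seed(seed, "shuffle_control"))
  n_bins <- dim(ba$counts)[3]
  for (u in seq_len(dim(ba$counts)[1]))
    for (m in seq_len(n_trials))
      ba$counts[u, m, ] <- ba$counts[u, m, sample.int(n_bins)]
  decode_from_counts(ba, config)
}
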