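#' Session-rate unit selection
#'
#' Keeps units whose session-wide mean firing rate lies within the
#' inclusive 0.5–20 Hz analysis band.
#'
#' @param units Data frame with a `mean_rate_hz` column.
#' @param lower,upper Inclusive bounds (Hz).
#' @return The filtered data frame.
#' @export
select_units <- function(units, lower = 0.5, upper = 20) {
  if (!"mean_rate_hz" %in% names(units))
    stop("`units` needs a mean_rate_hz column", call. = FALSE)
  units[units$mean_rate_hz >= lower & units$mean_rate_hz <= upper, ,
        drop = FALSE]
}

#' Separate putative MSNs from fast-spiking interneurons
#'
#' Two-cluster hierarchical clustering (Ward linkage on scaled features) of
#' the waveform peak-to-trough ratio and half-peak width. The cluster with
#' the larger median half-peak width is labelled MSN — fast-spiking
#' interneurons have narrow waveforms by convention.
#'
#' @param units Data frame with `peak_trough_ratio` and `half_peak_width_ms`.
#' @return Character vector of labels ("MSN"/"FSI"), one per row.
#' @export
classify_msn_fsi <- function(units) {
  need <- c("peak_trough_ratio", "half_peak_width_ms")
  if (!all(need %in% names(units)))
    stop("`units` needs peak_trough_ratio and half_peak_width_ms",
         call. = FALSE)
  if (nrow(units) < 2) stop("need at least 2 units", call. = FALSE)
  feats <- as.matrix(units[, need])
  if (all(apply(feats, 2, stats::sd) == 0))
    stop("all waveform features identical: cannot split clusters",
         call. = FALSE)
  fs <- scale(feats)
  fs[, apply(feats, 2, stats::sd) == 0] <- 0
  cl <- stats::cutree(stats::hclust(stats::dist(fs), method = "ward.D2"),
                      k = 2)
  w1 <- stats::median(units$half_peak_width_ms[cl == 1])
  w2 <- stats::median(units$half_peak_width_ms[cl == 2])
  msn_cluster <- if (w1 >= w2) 1 else 2
  unname(ifelse(cl == msn_cluster, "MSN", "FSI"))
}

#' Classify opto-tagged units by light-evoked latency
#'
#' For each unit, the mean post-stimulation latency is the average over
#' pulses of the first spike within the search window after each pulse. A
#' unit is tagged when the mean latency is at most 5 ms and its
#' stimulated-to-unstimulated waveform correlation ratio exceeds 0.9
#' (the ratio defaults to 1 when no waveforms are available, as for
#' synthetic units).
#'
#' @param spike_times Unit's spike times (s).
#' @param pulse_times Stimulation pulse times (s).
#' @param waveform_corr_ratio Correlation of the mean evoked vs mean
#'   spontaneous waveform (default 1).
#' @param search_window_ms Post-pulse search window (ms).
#' @param max_latency_ms Inclusive latency criterion (ms).
#' @return A `tag_result` list: `mean_latency_ms` (`NA` when no post-pulse
#'   spikes), `waveform_corr_ratio`, `tagged`, `n_responses`.
#' @export
tag_units <- function(spike_times, pulse_times, waveform_corr_ratio = 1,
                      search_window_ms = 10, max_latency_ms = 5) {
  if (!length(pulse_times)) stop("no pulse times", call. = FALSE)
  lat <- vapply(pulse_times, function(p) {
    s <- spike_times[spike_times > p &
                       spike_times <= p + search_window_ms / 1000]
    if (length(s)) (min(s) - p) * 1000 else NA_real_
  }, numeric(1))
  n_resp <- sum(!is.na(lat))
  mean_lat <- if (n_resp) mean(lat, na.rm = TRUE) else NA_real_
  tagged <- !is.na(mean_lat) && mean_lat <= max_latency_ms + 1e-9 &&
    waveform_corr_ratio > 0.9
  structure(list(mean_latency_ms = mean_lat,
                 waveform_corr_ratio = waveform_corr_ratio,
                 tagged = tagged, n_responses = n_resp),
            class = "tag_result")
}

#' PETH configuration
#'
#' Defaults follow the analysis conventions: a (-4, 22) s window around
#' trial start, 0.2-s bins (130 bins), Gaussian kernel smoothing with a
#' bandwidth of 1 (same units as the time axis), and z-scoring over the
#' full window.
#'
#' @param window Two-element window around trial start (s).
#' @param bin_width Bin width (s).
#' @param bandwidth Gaussian smoothing bandwidth (s); 0 disables smoothing.
#' @param zscore Z-score the smoothed rate over the window?
#' @return A `peth_config` list.
#' @export
peth_config <- function(window = c(-4, 22), bin_width = 0.2, bandwidth = 1,
                        zscore = TRUE) {
  stopifnot(length(window) == 2, window[1] < window[2])
  check_scalar(bin_width, "bin_width", .Machine$double.eps)
  check_scalar(bandwidth, "bandwidth", 0)
  structure(list(window = window, bin_width = bin_width,
                 bandwidth = bandwidth, zscore = zscore),
            class = "peth_config")
}

#' Peri-event time histogram of one unit
#'
#' Aligns spikes to each trial start, bins them on the window grid,
#' averages counts across trials, converts to a rate, smooths with a
#' Gaussian kernel, and optionally z-scores over the window. The
#' *unsmoothed* per-bin mean counts are kept alongside (their sum times the
#' trial count equals the number of in-window spikes).
#'
#' @param spike_times Unit's spike times (s, session clock).
#' @param trial_starts Trial start times (s, same clock).
#' @param config A [peth_config()].
#' @return A `peth` list: `bin_centers_s`, `rate` (smoothed, z-scored if
#'   configured), `rate_raw` (smoothed rate before z-scoring), `mean_counts`
#'   (unsmoothed), `n_trials`, `flat` (TRUE when the z-score was undefined).
#' @export
compute_peth <- function(spike_times, trial_starts, config = peth_config()) {
  stopifnot(inherits(config, "peth_config"))
  if (!length(trial_starts)) stop("need at least one trial", call. = FALSE)
  breaks <- seq(config$window[1], config$window[2], by = config$bin_width)
  centers <- breaks[-1] - config$bin_width / 2
  counts <- matrix(0, length(trial_starts), length(centers))
  for (i in seq_along(trial_starts)) {
    rel <- spike_times - trial_starts[i]
    rel <- rel[rel >= config$window[1] & rel < config$window[2]]
    counts[i, ] <- tabulate(findInterval(rel, breaks), length(centers))
  }
  mean_counts <- colMeans(counts)
  rate <- gauss_smooth(mean_counts / config$bin_width, config$bandwidth,
                       config$bin_width)
  flat <- stats::sd(rate) == 0
  z <- if (config$zscore && !flat) as.numeric(scale(rate)) else rate
  structure(list(bin_centers_s = centers, rate = z, rate_raw = rate,
                 mean_counts = mean_counts, n_trials = length(trial_starts),
                 flat = flat, config = config),
            class = "peth")
}
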