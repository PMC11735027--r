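#' Read a behavioral event log
#'
#' Reads a delimited event log with columns `mouse_id, session_id, trial_id,
#' trial_type, event_type, time_s` (times in seconds relative to trial
#' start), validates it, and returns the trial-grouped event table.
#' Malformed trials are reported with their identifiers.
#'
#' @param path Path to a delimited text file with a header.
#' @param sep Field separator (default comma).
#' @return Data frame of validated events, ordered by trial and time.
#' @export
read_event_log <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(ev) == 0) {
    warning("empty event log: ", path)
    return(ev)
  }
  validate_events(ev)
}

#' Validate an in-memory event table
#'
#' Checks the required columns, per-trial time monotonicity, and that
#' nosepoke entries and exits alternate within each port. All violations
#' are collected and reported together.
#'
#' @param ev Data frame of events.
#' @return The event table, ordered by (mouse, session, trial, time).
#' @export
validate_events <- function(ev) {
  required <- c("mouse_id", "session_id", "trial_id", "trial_type",
                "event_type", "time_s")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  known <- c("trial_start", "back_np_in", "first_np_in", "first_np_out",
             "second_np_in", "second_np_out", "reward", "laser_on",
             "laser_off")
  bad <- setdiff(unique(ev$event_type), known)
  if (length(bad))
    stop("unknown event types: ", paste(bad, collapse = ", "), call. = FALSE)

  ev <- ev[order(ev$mouse_id, ev$session_id, ev$trial_id, ev$time_s,
                 method = "radix"), , drop = FALSE]
  key <- interaction(ev$mouse_id, ev$session_id, ev$trial_id, drop = TRUE)
  problems <- character(0)
  for (tr in split(ev, key)) {
    id <- sprintf("%s/%s/trial %s", tr$mouse_id[1], tr$session_id[1],
                  tr$trial_id[1])
    if (is.unsorted(tr$time_s))
      problems <- c(problems, paste0(id, ": non-monotone times"))
    for (port in c("first_np", "second_np")) {
      io <- tr$event_type[tr$event_type %in%
                            paste0(port, c("_in", "_out"))]
      if (length(io)) {
        expect_in <- rep(c(TRUE, FALSE), length.out = length(io))
        ok <- all((io == paste0(port, "_in")) == expect_in)
        if (!ok)
          problems <- c(problems,
                        paste0(id, ": unpaired ", port, " entries/exits"))
      }
    }
  }
  if (length(problems))
    stop("malformed event log:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Extract switch records from long trials
#'
#' The switch response time is the moment the animal departs the first
#' nosepoke before arriving at the second: the time of the *last*
#' first-nosepoke exit preceding the *first* second-nosepoke entry.
#' Traversal time is first-exit to second-entry, and nosepoke duration is
#' the entry-to-exit span of the switch poke itself. Short trials, and long
#' trials without a qualifying exit-then-entry pattern (error trials), are
#' excluded.
#'
#' @param ev Validated event table (see [validate_events()]).
#' @return Data frame with one row per switch trial: `mouse_id`,
#'   `session_id`, `trial_id`, `switch_time_s`, `traversal_time_s`,
#'   `nosepoke_duration_s`, `laser_on`. The number of excluded long trials
#'   is attached as attribute `n_error_trials`.
#' @export
extract_switch_times <- function(ev) {
  key <- interaction(ev$mouse_id, ev$session_id, ev$trial_id, drop = TRUE)
  recs <- list()
  n_err <- 0L
  for (tr in split(ev, key)) {
    if (tr$trial_type[1] != "long") next
    second_in <- tr$time_s[tr$event_type == "second_np_in"]
    outs <- tr$time_s[tr$event_type == "first_np_out"]
    ins <- tr$time_s[tr$event_type == "first_np_in"]
    if (!length(second_in) || !length(outs)) { n_err <- n_err + 1L; next }
    s2 <- min(second_in)
    outs_before <- outs[outs < s2]
    if (!length(outs_before)) { n_err <- n_err + 1L; next }
    sw <- max(outs_before)
    entry <- ins[ins < sw]
    if (!length(entry)) { n_err <- n_err + 1L; next }
    entry <- max(entry)
    recs[[length(recs) + 1L]] <- data.frame(
      mouse_id = tr$mouse_id[1], session_id = tr$session_id[1],
      trial_id = tr$trial_id[1], switch_time_s = sw,
      traversal_time_s = s2 - sw, nosepoke_duration_s = sw - entry,
      laser_on = any(tr$event_type == "laser_on"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(mouse_id = character(), session_id = character(),
               trial_id = integer(), switch_time_s = numeric(),
               traversal_time_s = numeric(), nosepoke_duration_s = numeric(),
               laser_on = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$mouse_id, out$session_id, out$trial_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_error_trials") <- n_err
  out
}

#' Response-time distributions
#'
#' Normalized histogram densities and empirical CDFs of a set of response
#' times (first pokes, switch responses, or second pokes), pooled or per
#' mouse.
#'
#' @param times Numeric vector of times (s).
#' @param bin_width Histogram bin width (s), default 1.
#' @param t_max Upper range for binning.
#' @return List with `bin_centers`, `density` (integrates to 1 over the
#'   binned range), the `ecdf` function, and `n`. When `times` is empty the
#'   density is empty and `empty = TRUE`.
#' @export
response_distributions <- function(times, bin_width = 1, t_max = 25) {
  check_scalar(bin_width, "bin_width", .Machine$double.eps)
  times <- times[is.finite(times)]
  if (!length(times))
    return(list(bin_centers = numeric(), density = numeric(), ecdf = NULL,
                n = 0L, empty = TRUE))
  breaks <- seq(0, max(t_max, max(times) + bin_width), by = bin_width)
  h <- graphics::hist(times, breaks = breaks, plot = FALSE)
  list(bin_centers = h$mids, density = h$density,
       ecdf = stats::ecdf(times), n = length(times), empty = FALSE)
}

#' Gamma fit of behavioral switch times
#'
#' Delegates to [fit_gamma()] and [gamma_sample_r2()], returning the fit
#' with its goodness-of-fit r2 populated.
#'
#' @param switch_times Switch response times (s), at least 10.
#' @param bin_width,t_max Histogram settings for the r2 computation.
#' @return A `gamma_fit` with `r2` filled in.
#' @export
fit_behavior_gamma <- function(switch_times, bin_width = 0.5, t_max = 25) {
  fit <- fit_gamma(switch_times)
  fit$r2 <- gamma_sample_r2(switch_times, fit, bin_width = bin_width,
                            t_max = t_max)
  fit
}

#' Session-level behavioral summary and paired contrast
#'
#' Computes per-mouse mean switch time per condition, group medians with
#' interquartile ranges, Cohen's d between two conditions (mean difference
#' over pooled SD), and a rank-based test (Wilcoxon signed-rank when the
#' conditions pair within mouse, rank-sum otherwise).
#'
#' @param records Switch-record data frame (see [extract_switch_times()]).
#' @param condition Factor/character vector, one entry per record row (e.g.
#'   laser off/on); exactly two levels required for the contrast.
#' @return List with `per_mouse` (mouse x condition means), `group`
#'   (median and IQR per condition), `cohens_d`, `p_value`, `test`.
#' @export
session_summary <- function(records, condition) {
  if (length(condition) != nrow(records))
    stop("`condition` must have one entry per record", call. = FALSE)
  condition <- factor(condition)
  if (nlevels(condition) != 2)
    stop("need exactly two conditions for a paired comparison", call. = FALSE)

  agg <- stats::aggregate(records$switch_time_s,
                          by = list(mouse = records$mouse_id,
                                    condition = condition),
                          FUN = mean)
  names(agg)[3] <- "mean_switch_s"
  lv <- levels(condition)
  a <- agg$mean_switch_s[agg$condition == lv[1]]
  b <- agg$mean_switch_s[agg$condition == lv[2]]
  grp <- do.call(rbind, lapply(lv, function(l) {
    v <- agg$mean_switch_s[agg$condition == l]
    data.frame(condition = l, median = stats::median(v),
               iqr_lo = unname(stats::quantile(v, 0.25)),
               iqr_hi = unname(stats::quantile(v, 0.75)))
  }))
  pooled_sd <- sqrt((stats::var(a) * (length(a) - 1) +
                       stats::var(b) * (length(b) - 1)) /
                      (length(a) + length(b) - 2))
  d <- if (is.finite(pooled_sd) && pooled_sd > 0)
    (mean(b) - mean(a)) / pooled_sd else 0
  paired <- length(a) == length(b) &&
    setequal(agg$mouse[agg$condition == lv[1]],
             agg$mouse[agg$condition == lv[2]])
  wt <- suppressWarnings(stats::wilcox.test(b, a, paired = paired))
  list(per_mouse = agg, group = grp, cohens_d = d, p_value = wt$p.value,
       test = if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum")
}
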