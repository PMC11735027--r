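#' Ensemble PCA of z-scored PETH segments
#'
#' Runs PCA over units (observations) by time bins (variables) on the
#' PETH segment inside the analysis interval. The PC1 sign is fixed by
#' requiring its loading to *decrease* over the interval, matching the
#' convention under which up-ramping (D2-like) units take negative PC1
#' scores and down-ramping (D1-like) units positive scores.
#'
#' @param peths List of `peth` objects (same config).
#' @param analysis_interval Two-element interval (s), default 0–6 s.
#' @return A `pca_result` list: `components` (bins x PCs loadings),
#'   `explained_fraction`, `scores` (units x PCs), `bin_centers_s`,
#'   `n_units`.
#' @export
pca_ensemble <- function(peths, analysis_interval = c(0, 6)) {
  if (length(peths) < 2) stop("need at least 2 units", call. = FALSE)
  centers <- peths[[1]]$bin_centers_s
  sel <- centers >= analysis_interval[1] & centers < analysis_interval[2]
  if (sum(sel) < 2) stop("fewer than 2 bins in the analysis interval",
                         call. = FALSE)
  mat <- t(vapply(peths, function(p) p$rate[sel], numeric(sum(sel))))
  if (all(apply(mat, 2, stats::sd) == 0))
    stop("zero variance across units: PCA undefined", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  tt <- centers[sel]
  # orient PC1 so its loading ramps downward over the interval
  trend <- stats::coef(stats::lm(pc$rotation[, 1] ~ tt))[2]
  if (is.finite(trend) && trend > 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  structure(
    list(components = pc$rotation, explained_fraction = expl,
         scores = pc$x, bin_centers_s = tt, n_units = nrow(mat)),
    class = "pca_result"
  )
}

#' Random-timestamp baseline for PC1 variance
#'
#' Empirical null for the PC1 explained fraction: on each iteration every
#' unit's spikes are replaced by uniform random timestamps over the session
#' (same spike count), the identical PETH + PCA pipeline is re-run, and the
#' iteration's PC1 explained fraction recorded. The empirical p-value is
#' the fraction of null iterations at or above the observed fraction.
#'
#' @param spike_trains List of spike-time vectors (session clock).
#' @param trial_starts Trial start times (s).
#' @param session_span Two-element session span (s) for the uniform draw.
#' @param config A [peth_config()].
#' @param analysis_interval Interval for the PCA (s).
#' @param n_iter Number of null iterations (default 1000).
#' @param seed Integer seed.
#' @return List with `observed` (PC1 explained fraction), `baseline`
#'   (null distribution), `p_empirical`.
#' @export
pc1_random_baseline <- function(spike_trains, trial_starts,
                                session_span, config = peth_config(),
                                analysis_interval = c(0, 6),
                                n_iter = 1000, seed = 1L) {
  check_scalar(n_iter, "n_iter", 1)
  obs_peths <- lapply(spike_trains, compute_peth, trial_starts = trial_starts,
                      config = config)
  observed <- pca_ensemble(obs_peths, analysis_interval)$explained_fraction[1]
  counts <- lengths(spike_trains)
  set.seed(derive_seed(seed, "pc1_baseline"))
  baseline <- vapply(seq_len(n_iter), function(it) {
    null_peths <- lapply(counts, function(k)
      compute_peth(stats::runif(k, session_span[1], session_span[2]),
                   trial_starts, config))
    tryCatch(pca_ensemble(null_peths, analysis_interval)$explained_fraction[1],
             error = function(e) NA_real_)
  }, numeric(1))
  baseline <- baseline[is.finite(baseline)]
  list(observed = observed, baseline = baseline,
       p_empirical = mean(baseline >= observed))
}

#' Early- versus late-interval activity contrast
#'
#' Mean z-scored PETH activity per unit in an early (default 0–5 s) and a
#' late (default 5–6 s) epoch, with a rank-sum test and Cohen's d between
#' two unit groups in each epoch.
#'
#' @param peths List of `peth` objects.
#' @param groups Two-level factor/character vector, one per unit.
#' @param early,late Epoch intervals (s).
#' @return List with `per_unit` (unit x epoch means plus group) and
#'   `contrast` (per-epoch p-value and Cohen's d).
#' @export
epoch_activity_compare <- function(peths, groups, early = c(0, 5),
                                   late = c(5, 6)) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  centers <- peths[[1]]$bin_centers_s
  epoch_mean <- function(p, ep) {
    sel <- centers >= ep[1] & centers < ep[2]
    if (!any(sel)) stop("empty epoch", call. = FALSE)
    mean(p$rate[sel])
  }
  per_unit <- data.frame(
    group = groups,
    early = vapply(peths, epoch_mean, numeric(1), ep = early),
    late = vapply(peths, epoch_mean, numeric(1), ep = late))
  contrast <- do.call(rbind, lapply(c("early", "late"), function(ep) {
    a <- per_unit[[ep]][groups == levels(groups)[1]]
    b <- per_unit[[ep]][groups == levels(groups)[2]]
    sp <- sqrt((stats::var(a) * (length(a) - 1) +
                  stats::var(b) * (length(b) - 1)) /
                 (length(a) + length(b) - 2))
    data.frame(epoch = ep,
               p_value = suppressWarnings(stats::wilcox.test(a, b)$p.value),
               cohens_d = if (is.finite(sp) && sp > 0)
                 (mean(a) - mean(b)) / sp else 0)
  }))
  list(per_unit = per_unit, contrast = contrast)
}
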