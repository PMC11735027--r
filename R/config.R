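#' Default run configuration
#'
#' The full default parameter set of the pipeline, used to fill in any keys
#' a configuration file omits. Block defaults mirror the published analysis
#' settings (integration step 0.1 s, 500 trials per batch, 25 s horizon,
#' 0.2-s PETH bins, 0.5-s decoder bins, 1-s readout kernel).
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("ddm", "behavior", "ephys", "decode", "readout"),
    ddm = list(F = 1, b = 0.52, D = 0.135, sigma = 0.052, dt = 0.1,
               t_max = 25, n_sims = 500L, n_repeats = 10L),
    grid = list(D_min = 0.05, D_max = 0.25, D_step = 0.002,
                sigma_min = 0.02, sigma_max = 0.10, sigma_step = 0.002),
    synth = list(n_trials = 80L, gamma_shape = 6.08, gamma_rate = 0.69,
                 p_long = 0.5, iti_geometric_mean_s = 30,
                 n_units = 12L, baseline_rate = 5, ramp_slope = 0.3,
                 ensemble_n_units = 16L, ensemble_noise_sd = 1),
    peth = list(window = c(-4, 22), bin_width = 0.2, bandwidth = 1,
                zscore = TRUE),
    decoder = list(bin_width_s = 0.5, window = c(-6, 24),
                   min_trials_per_unit = 20L, rate_floor = 0.1),
    readout = list(kernel_w = 1, grid_step = 0.1, accuracy_window_s = 1,
                   lambda = 0.2)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified keys from
#' [default_config()], and rejects unknown keys — all of them listed at
#' once, not just the first.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  bad <- character(0)
  top_unknown <- setdiff(names(user), names(defaults))
  bad <- c(bad, top_unknown)
  for (blk in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[blk]]) && is.list(user[[blk]])) {
      unk <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
      if (length(unk)) bad <- c(bad, paste0(blk, ".", unk))
    }
  }
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  merge_config(defaults, user)
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]]) else user[[k]]
  }
  defaults
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order on synthetic data:
#' DDM simulation and gamma fit, behavioral event-log synthesis and
#' parsing, PETH/PCA/GLM on ramping units, naive-Bayes decoding, and the
#' ensemble readout. All tabular outputs are plain CSV; a manifest records
#' every stage's seed and output-file checksums, so identical
#' configurations reproduce identical manifests.
#'
#' @param config Configuration list (see [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.csv`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)),
      seed = derive_seed(config$seed, stage), stringsAsFactors = FALSE)
  }
  wants <- function(s) s %in% config$stages

  if (wants("ddm")) {
    d <- config$ddm
    p <- ddm_params(d$F, d$b, d$D, d$sigma, dt = d$dt, t_max = d$t_max,
                    n_sims = d$n_sims, seed = derive_seed(config$seed, "ddm"))
    run <- simulate_batch(p)
    f <- file.path(out_dir, "ddm_run.csv")
    utils::write.csv(data.frame(trial = seq_along(run$switch_times),
                                switch_time_s = run$switch_times,
                                censored = run$censored),
                     f, row.names = FALSE)
    fit <- fit_gamma(run$switch_times[!run$censored])
    f2 <- file.path(out_dir, "ddm_gamma_fit.csv")
    utils::write.csv(data.frame(alpha = fit$alpha, beta = fit$beta,
                                mu = fit$mu, cv = fit$cv,
                                r2 = gamma_sample_r2(
                                  run$switch_times[!run$censored], fit,
                                  t_max = d$t_max)),
                     f2, row.names = FALSE)
    note("ddm", c(f, f2))
  }

  beh <- NULL
  if (wants("behavior") || wants("ephys") || wants("decode")) {
    s <- config$synth
    spec <- synth_behavior_spec(
      n_trials = s$n_trials, gamma_shape = s$gamma_shape,
      gamma_rate = s$gamma_rate, p_long = s$p_long,
      iti_geometric_mean_s = s$iti_geometric_mean_s,
      seed = derive_seed(config$seed, "behavior"))
    beh <- gen_event_log(spec)
  }
  if (wants("behavior")) {
    f <- file.path(out_dir, "events.csv")
    utils::write.csv(beh$events, f, row.names = FALSE)
    recs <- extract_switch_times(validate_events(beh$events))
    f2 <- file.path(out_dir, "switch_records.csv")
    utils::write.csv(recs, f2, row.names = FALSE)
    note("behavior", c(f, f2))
  }

  if (wants("ephys")) {
    s <- config$synth
    seed0 <- derive_seed(config$seed, "ephys")
    long <- beh$trials$trial_type == "long"
    starts <- beh$trials$start_abs_s[long]
    horizon <- max(beh$trials$start_abs_s) + 30
    slopes <- rep(c(1, -1), length.out = s$n_units) * s$ramp_slope
    units <- lapply(seq_len(s$n_units), function(j)
      synth_unit_spec(unit_id = sprintf("u%02d", j),
                      baseline_rate = s$baseline_rate,
                      ramp_slope = slopes[j],
                      seed = derive_seed(seed0, j)))
    trains <- lapply(units, gen_ramping_unit, trial_starts = starts,
                     horizon = horizon)
    pcfg <- peth_config(window = config$peth$window,
                        bin_width = config$peth$bin_width,
                        bandwidth = config$peth$bandwidth,
                        zscore = config$peth$zscore)
    peths <- lapply(trains, compute_peth, trial_starts = starts,
                    config = pcfg)
    pmat <- t(vapply(peths, function(p) p$rate,
                     numeric(length(peths[[1]]$bin_centers_s))))
    f <- file.path(out_dir, "peth.csv")
    utils::write.csv(data.frame(unit_id = vapply(units, `[[`, "",
                                                 "unit_id"), pmat),
                     f, row.names = FALSE)
    pca <- pca_ensemble(peths)
    f2 <- file.path(out_dir, "pca_scores.csv")
    utils::write.csv(data.frame(unit_id = vapply(units, `[[`, "", "unit_id"),
                                pc1_score = pca$scores[, 1],
                                pc1_explained = pca$explained_fraction[1]),
                     f2, row.names = FALSE)
    sl <- vapply(trains, function(tr)
      glm_ramp_slope(tr, starts)$slope, numeric(1))
    f3 <- file.path(out_dir, "slopes.csv")
    utils::write.csv(data.frame(unit_id = vapply(units, `[[`, "", "unit_id"),
                                true_slope = slopes, glm_slope = sl),
                     f3, row.names = FALSE)
    note("ephys", c(f, f2, f3))
    if (wants("decode")) {
      spikes <- do.call(rbind, lapply(seq_along(trains), function(j)
        if (length(trains[[j]]))
          data.frame(unit_id = units[[j]]$unit_id, time_s = trains[[j]])))
      dcfg <- decoder_config(
        bin_width_s = config$decoder$bin_width_s,
        window = config$decoder$window,
        min_trials_per_unit = config$decoder$min_trials_per_unit,
        rate_floor = config$decoder$rate_floor)
      dec <- bayes_decode_loocv(spikes, starts, dcfg)
      r2 <- decode_r2_by_epoch(dec)
      f4 <- file.path(out_dir, "decode_r2.csv")
      utils::write.csv(r2, f4, row.names = FALSE)
      note("decode", f4)
    }
  }

  if (wants("readout")) {
    d <- config$ddm
    p <- ddm_params(d$F, d$b, d$D, d$sigma, dt = d$dt, t_max = d$t_max,
                    n_sims = 40L,
                    seed = derive_seed(config$seed, "readout_ddm"))
    run <- simulate_batch(p, keep_trajectories = TRUE)
    espec <- synth_ensemble_spec(
      n_units = config$synth$ensemble_n_units,
      noise_sd = config$synth$ensemble_noise_sd,
      kernel_w = config$readout$kernel_w,
      seed = derive_seed(config$seed, "readout"))
    ens <- gen_ensemble_ddm_linked(espec, run)
    rcfg <- readout_config(kernel_w = config$readout$kernel_w,
                           grid_step = config$readout$grid_step,
                           t_max = d$t_max,
                           accuracy_window_s = config$readout$accuracy_window_s,
                           lambda = config$readout$lambda)
    ro <- fit_readout(ens$spikes, ens$switch_times, rcfg)
    f <- file.path(out_dir, "readout.csv")
    utils::write.csv(data.frame(trial = seq_along(ro$t_pred),
                                t_true = ro$t_true, t_pred = ro$t_pred,
                                accurate = ro$accurate),
                     f, row.names = FALSE)
    f2 <- file.path(out_dir, "weights.csv")
    utils::write.csv(data.frame(unit_id = names(ro$beta_hat),
                                beta_hat = ro$beta_hat, beta = ro$beta),
                     f2, row.names = FALSE)
    note("readout", c(f, f2))
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
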