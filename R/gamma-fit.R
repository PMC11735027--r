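#' Maximum-likelihood gamma fit of a switch-time sample
#'
#' Fits a two-parameter gamma distribution (shape `alpha`, rate `beta`, no
#' location shift) by maximum likelihood and derives the implied mean
#' `mu = alpha / beta` and coefficient of variation `cv = 1 / sqrt(alpha)`.
#'
#' @param samples Positive, finite switch times (seconds); at least 10.
#' @return A `gamma_fit` list with `alpha`, `beta`, `mu`, `cv`, `n` and
#'   (once [gamma_sample_r2()] has been called) `r2`.
#' @examples
#' set.seed(1)
#' fit_gamma(rgamma(1000, shape = 6.08, rate = 0.69))
#' @export
fit_gamma <- function(samples) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop("samples must be finite (drop censored trials first)", call. = FALSE)
  if (any(samples <= 0)) stop("samples must be positive", call. = FALSE)
  if (length(samples) < 10) stop("need at least 10 samples", call. = FALSE)
  if (stats::sd(samples) < 1e-10 * mean(samples))
    stop("sample variance is (near) zero: gamma MLE diverges", call. = FALSE)
  est <- suppressWarnings(MASS::fitdistr(samples, "gamma"))$estimate
  alpha <- unname(est["shape"]); beta <- unname(est["rate"])
  structure(
    list(alpha = alpha, beta = beta, mu = alpha / beta,
         cv = 1 / sqrt(alpha), r2 = NA_real_, n = length(samples)),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "gamma fit (n = %d): shape %.3f, rate %.3f  =>  mean %.2f s, CV %.3f",
    x$n, x$alpha, x$beta, x$mu, x$cv))
  if (is.finite(x$r2)) cat(sprintf(", r2 = %.3f", x$r2))
  cat("\n")
  invisible(x)
}

#' Goodness of fit between a sample distribution and its gamma fit
#'
#' Coefficient of determination `r2 = 1 - SS_res / SS_tot` between the
#' sample's distribution and the fitted gamma, evaluated at bin centers on
#' a regular grid. Two scales are available: `"cdf"` (default) compares the
#' empirical CDF with the gamma CDF — the scale on which response-time
#' distributions are usually overlaid and the package's definition of the
#' gamma-versus-model R-squared; `"density"` compares the normalized
#' histogram with the gamma density. The density scale carries per-bin
#' sampling noise of order `1/sqrt(n * bin_width)`, which bounds its
#' attainable r2 well below 1 at a few hundred samples even for perfectly
#' gamma data; the CDF scale does not.
#'
#' @param samples Switch times (seconds).
#' @param fit A `gamma_fit` for those samples.
#' @param bin_width Grid bin width in seconds.
#' @param t_max Upper edge of the grid.
#' @param method `"cdf"` or `"density"`.
#' @return The r2 value (stored back into a returned copy of `fit` by
#'   [fit_behavior_gamma()]).
#' @export
gamma_sample_r2 <- function(samples, fit, bin_width = 0.5, t_max = 25,
                            method = c("cdf", "density")) {
  stopifnot(inherits(fit, "gamma_fit"))
  method <- match.arg(method)
  check_scalar(bin_width, "bin_width", .Machine$double.eps)
  breaks <- seq(0, t_max, by = bin_width)
  if (max(samples) > t_max) breaks <- c(breaks, max(samples))
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  if (all(h$counts == 0)) stop("all histogram bins empty", call. = FALSE)
  if (method == "density") {
    obs <- h$density
    pred <- stats::dgamma(h$mids, shape = fit$alpha, rate = fit$beta)
  } else {
    obs <- stats::ecdf(samples)(h$mids)
    pred <- stats::pgamma(h$mids, shape = fit$alpha, rate = fit$beta)
  }
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("degenerate sample (zero variance)", call. = FALSE)
  1 - ss_res / ss_tot
}

#' Simulation-based mean and CV of the switch-time distribution
#'
#' Repeats the 500-trial "experiment" `n_repeats` times (each repeat a
#' seeded [simulate_batch()]) and takes the group median of the per-repeat
#' sample mean and sample coefficient of variation of the non-censored
#' switch times.
#'
#' @param params A `ddm_params` object; its `seed` anchors the repeat seeds.
#' @param n_repeats Number of repeats (default 10).
#' @return List with `mu_S`, `cv_S` and the per-repeat values.
#' @export
summary_stats <- function(params, n_repeats = 10) {
  stopifnot(inherits(params, "ddm_params"))
  check_scalar(n_repeats, "n_repeats", 1)
  mus <- cvs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    p <- params
    p$seed <- derive_seed(params$seed, r)
    run <- simulate_batch(p)
    ts <- run$switch_times[!run$censored]
    mus[r] <- mean(ts)
    cvs[r] <- if (length(ts) > 1) stats::sd(ts) / mean(ts) else 0
  }
  list(mu_S = stats::median(mus), cv_S = stats::median(cvs),
       mu_repeats = mus, cv_repeats = cvs)
}

#' Fit errors of simulated statistics against behavioral targets
#'
#' `e_mu = |(mu_S - mu_M) / mu_M|` (relative error of the mean) and
#' `e_cv = |cv_S - cv_M|` (absolute error of the CV). A parameter pair is
#' accepted when `e_mu <= 0.05` and `e_cv <= 0.02` (inclusive).
#'
#' @param mu_S,cv_S Simulated mean and CV (group medians).
#' @param mu_M,cv_M Target mean and CV (from the behavioral gamma fit).
#' @return A `fit_error` list with `e_mu`, `e_cv`, `accepted`.
#' @export
fit_errors <- function(mu_S, cv_S, mu_M, cv_M) {
  check_scalar(mu_M, "mu_M", .Machine$double.eps)
  e_mu <- abs((mu_S - mu_M) / mu_M)
  e_cv <- abs(cv_S - cv_M)
  structure(
    list(mu_S = mu_S, cv_S = cv_S, e_mu = e_mu, e_cv = e_cv,
         accepted = e_mu <= 0.05 && e_cv <= 0.02),
    class = "fit_error"
  )
}

#' Grid search over drift rate and noise strength
#'
#' For fixed `F` and `b`, simulates the DDM over a (D, sigma) grid, computes
#' [summary_stats()] per cell and the [fit_errors()] against the behavioral
#' targets, and returns the full error surfaces plus the accepted region.
#' Each cell draws its seed deterministically from the base seed and the
#' cell index, so surfaces are reproducible cell by cell.
#'
#' @param F,b Fixed input level and baseline.
#' @param D_grid,sigma_grid Grid values (defaults bracket the published
#'   parameter fits: D in \[0.05, 0.25\], sigma in \[0.02, 0.10\]).
#' @param mu_M,cv_M Target mean (s) and CV.
#' @param n_sims Trials per batch.
#' @param n_repeats Repeats per cell.
#' @param dt,t_max Integration settings.
#' @param seed Base seed.
#' @return Data frame with one row per cell: `D`, `sigma`, `mu_S`, `cv_S`,
#'   `e_mu`, `e_cv`, `accepted`. An empty accepted region is a valid result.
#' @export
grid_search_params <- function(F, b,
                               D_grid = seq(0.05, 0.25, by = 0.002),
                               sigma_grid = seq(0.02, 0.10, by = 0.002),
                               mu_M, cv_M,
                               n_sims = 500, n_repeats = 10,
                               dt = 0.1, t_max = 25, seed = 1L) {
  if (length(D_grid) == 0 || length(sigma_grid) == 0)
    stop("grids must be non-empty", call. = FALSE)
  check_scalar(mu_M, "mu_M", .Machine$double.eps)
  check_scalar(cv_M, "cv_M", .Machine$double.eps)
  cells <- expand.grid(D = D_grid, sigma = sigma_grid,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- ddm_params(F, b, cells$D[i], cells$sigma[i], dt = dt, t_max = t_max,
                    n_sims = n_sims, seed = derive_seed(seed, i))
    res <- tryCatch(summary_stats(p, n_repeats),
                    error = function(e) NULL)
    if (is.null(res)) {       # all-censored cell: infinite error, not a crash
      out[[i]] <- data.frame(D = cells$D[i], sigma = cells$sigma[i],
                             mu_S = NA_real_, cv_S = NA_real_,
                             e_mu = Inf, e_cv = Inf, accepted = FALSE)
    } else {
      fe <- fit_errors(res$mu_S, res$cv_S, mu_M, cv_M)
      out[[i]] <- data.frame(D = cells$D[i], sigma = cells$sigma[i],
                             mu_S = res$mu_S, cv_S = res$cv_S,
                             e_mu = fe$e_mu, e_cv = fe$e_cv,
                             accepted = fe$accepted)
    }
  }
  do.call(rbind, out)
}
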