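#!/usr/bin/env Rscript
# Simulate the four-parameter drift-diffusion model at the published intact
# and disrupted parameter sets, fit gamma distributions to the switch
# response times, and tabulate the fits.

library(switchddm)
dir.create("results", showWarnings = FALSE)

sets <- list(
  intact_d2    = list(F = 1, b = 0.52, D = 0.135, sigma = 0.052),
  intact_d1    = list(F = 0, b = 0.48, D = 0.141, sigma = 0.052),
  disrupted_d2 = list(F = 1, b = 0.52, D = 0.129, sigma = 0.043),
  disrupted_d1 = list(F = 0, b = 0.48, D = 0.122, sigma = 0.043)
)

rows <- lapply(names(sets), function(nm) {
  s <- sets[[nm]]
  fits <- vapply(1:10, function(r) {
    p <- ddm_params(s$F, s$b, s$D, s$sigma,
                    seed = derive_seed(1L, paste0(nm, r)))
    run <- simulate_batch(p)
    ts <- run$switch_times[!run$censored]
    f <- fit_gamma(ts)
    c(mean = mean(ts), alpha = f$alpha, beta = f$beta,
      r2 = gamma_sample_r2(ts, f), censored = sum(run$censored))
  }, numeric(5))
  med <- apply(fits, 1, median)
  data.frame(condition = nm, threshold = compute_threshold(s$F, s$b),
             D = s$D, sigma = s$sigma, t(med))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/ddm_gamma_fits.csv", row.names = FALSE)
print(tab, digits = 3)

cat("\nDisruption lengthens switch times:\n")
cat(sprintf("  D2: %.2f s (disrupted) vs %.2f s (intact)\n",
            tab$mean[3], tab$mean[1]))
cat(sprintf("  D1: %.2f s (disrupted) vs %.2f s (intact)\n",
            tab$mean[4], tab$mean[2]))
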