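# units whose per-bin count exactly encodes the bin index decode perfectly
make_codebook_spikes <- function(n_trials = 22, config = decoder_config()) {
  starts <- seq(0, by = 40, length.out = n_trials)
  breaks <- seq(config$window[1], config$window[2], by = config$bin_width_s)
  centers <- breaks[-1] - config$bin_width_s / 2
  sp <- lapply(seq_along(centers), function(b) {
    if (b == 0) return(NULL)
    offs <- centers[b] - config$bin_width_s / 2 +
      config$bin_width_s * (seq_len(b) - 0.5) / b
    data.frame(unit_id = "code",
               time_s = as.vector(outer(offs, starts, `+`)))
  })
  list(spikes = do.call(rbind, sp), starts = starts, centers = centers)
}

test_that("a noise-free codebook ensemble decodes every bin exactly", {
  cb <- make_codebook_spikes()
  dec <- bayes_decode_loocv(cb$spikes, cb$starts)
  expect_true(all(dec$predicted == matrix(cb$centers,
                                          nrow(dec$predicted),
                                          ncol(dec$predicted),
                                          byrow = TRUE)))
  r2 <- decode_r2_by_epoch(dec)
  expect_true(all(r2$r2 == 1))
  # shuffling the codebook destroys it
  shuf <- shuffle_control(cb$spikes, cb$starts, seed = 2)
  r2s <- decode_r2_by_epoch(shuf)
  expect_lt(median(r2s$r2), 0.2)
  expect_identical(shuf$predicted,
                   shuffle_control(cb$spikes, cb$starts, seed = 2)$predicted)
})

test_that("ramping ensembles decode early epochs better than late ones", {
  ses <- make_ramping_session(n_units = 20, n_trials = 30, slope = 0.5,
                              baseline = 8, seed = 21)
  dec <- bayes_decode_loocv(ses$spikes, ses$starts)
  r2 <- decode_r2_by_epoch(dec)
  med <- tapply(r2$r2, r2$epoch, median)
  expect_gt(med[["0-6"]], med[["12-18"]])

  # time-shuffling collapses the early epoch
  r2s <- decode_r2_by_epoch(shuffle_control(ses$spikes, ses$starts,
                                            seed = 22))
  expect_gt(med[["0-6"]], median(r2s$r2[r2s$epoch == "0-6"]))

  # slope shrinkage ("blockade") degrades early decoding
  blk_units <- gen_blockade_ensemble(ses$units, 0.3)
  blk_trains <- lapply(blk_units, gen_ramping_unit,
                       trial_starts = ses$starts, horizon = ses$horizon)
  blk_spikes <- do.call(rbind, lapply(seq_along(blk_units), function(j)
    data.frame(unit_id = blk_units[[j]]$unit_id,
               time_s = blk_trains[[j]])))
  r2b <- decode_r2_by_epoch(bayes_decode_loocv(blk_spikes, ses$starts))
  expect_gt(med[["0-6"]], median(r2b$r2[r2b$epoch == "0-6"]))
})

test_that("decoder guards its preconditions and degenerate r2", {
  cb <- make_codebook_spikes(n_trials = 5)
  expect_error(bayes_decode_loocv(cb$spikes, cb$starts),
               "more than 20 trials")
  cfg_low <- decoder_config(min_trials_per_unit = 2)
  expect_error(bayes_decode_loocv(cb$spikes, cb$starts[1], cfg_low),
               "at least 2")
  # constant predictions give r2 = 0 with the degenerate flag
  fake <- structure(list(predicted = matrix(3, 2, 60),
                         objective = seq(-5.75, 23.75, by = 0.5),
                         config = decoder_config(), n_units = 1),
                    class = "decode_result")
  r2 <- decode_r2_by_epoch(fake)
  expect_true(all(r2$r2 == 0))
  expect_true(all(r2$degenerate))
  expect_error(decoder_config(epochs = list(c(0, 30))), "within the window")
})
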