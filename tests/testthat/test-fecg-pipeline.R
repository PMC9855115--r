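test_that("preprocessing masks saturated runs, filters, and resamples to 500 Hz", {
  rec <- tiny_records()[[1]]
  pp <- preprocess(rec)
  expect_identical(pp$fs, 500)
  expect_true(all(pp$valid_mask))
  # inject a 1 s clipped plateau at the dynamic-range rail
  rec2 <- rec
  rail <- max(abs(rec2$channels[1, ]))
  rec2$channels[1, 5001:5500] <- rail
  pp2 <- preprocess(rec2)
  expect_true(all(!pp2$valid_mask[5001:5500]))
  expect_gt(mean(pp2$valid_mask), 0.9)
  # 1 kHz record halves in length
  sp <- nifeadb_like_cohort(n_healthy = 1, n_arrhythmia = 0, duration = 20,
                            seed = 3, fs = 1000)
  rk <- simulate_cohort(sp)[[1]]
  ppk <- preprocess(rk)
  expect_identical(ppk$fs, 500)
  expect_lte(abs(ncol(ppk$channels) - ncol(rk$channels) / 2), 1)
  # mostly-invalid records are rejected
  rec3 <- rec
  rec3$channels[1, seq_len(round(ncol(rec3$channels) * 0.6))] <- NaN
  expect_error(preprocess(rec3), "rejected")
})

test_that("maternal R-peaks are recovered at the right rate and timing", {
  rec <- tiny_records()[[1]]
  pp <- preprocess(rec)
  mp <- detect_maternal_rpeaks(pp)
  rate <- 60000 / mean(diff(mp$times))
  expect_lt(abs(rate - 75), 1)
  gt <- rec$meta$maternal_peaks_ms
  d <- vapply(gt, function(t) min(abs(mp$times - t)), numeric(1))
  expect_gte(mean(d <= 20), 0.99)
  expect_true(all(diff(mp$times) > 0))
  # pure-noise channel: no convincing QRS structure
  set.seed(1)
  noise <- aecg_record("n", matrix(rnorm(4000, sd = 1e-4), 1, 4000),
                       channel_names = "abd1", fs = 500)
  expect_error(detect_maternal_rpeaks(noise))
})

test_that("template subtraction removes maternal energy but not fetal", {
  rec <- tiny_records()[[1]]
  pp <- preprocess(rec)
  mp <- detect_maternal_rpeaks(pp)
  fecg <- subtract_maternal_template(pp, mp)
  fs <- pp$fs
  mt <- round(rec$meta$maternal_peaks_ms / 1000 * fs) + 1L
  mt <- mt[mt > 40 & mt < ncol(pp$channels) - 40]
  idx <- unlist(lapply(mt, function(p) (p - 40):(p + 40)))
  pre <- mean(pp$channels[1, idx]^2)
  post <- mean(fecg$samples[idx]^2)
  expect_lt(post / pre, 0.05)
  # needs enough maternal beats for a template
  short <- rpeak_series(mp$times[1:5])
  expect_error(subtract_maternal_template(pp, short), "10 maternal")
})

test_that("subtraction is a no-op in the zero-maternal-amplitude limit", {
  rr <- generate_rri_sequence(subject_spec("z", "healthy", duration = 30,
                                           seed = 9))
  fe <- synthesize_fecg(rr, fs = 500, noise_sd = 0.02, seed = 9)
  n <- length(fe$fecg$samples)
  # fetal-only abdominal channel + a maternal-only thoracic channel
  mt_times <- seq(100, n / 500 * 1000 - 200, by = 800)
  thor <- numeric(n)
  thor[round(mt_times / 1000 * 500) + 1L] <- 3
  rec <- aecg_record("z", rbind(fe$fecg$samples, thor),
                     channel_names = c("abd1", "thoracic"), fs = 500)
  mp <- rpeak_series(mt_times)
  out <- subtract_maternal_template(rec, mp)
  # template fitted on the abdominal channel has ~zero maternal energy, so
  # the residual stays close to the input (small fetal leakage through the
  # per-beat scaling is tolerated)
  expect_gt(cor(out$samples, fe$fecg$samples), 0.95)
})

test_that("fetal R-peak detection is exact on a clean constant-rate trace", {
  rr <- rri_series(rep(400, 24), subject_id = "c")
  fe <- synthesize_fecg(rr, fs = 500, noise_sd = 0, seed = 1)
  fp <- detect_fetal_rpeaks(fe$fecg)
  gt <- fe$rpeaks_ms[-c(1, length(fe$rpeaks_ms))]   # edge peaks are clipped
  err <- vapply(gt, function(t) min(abs(fp$times - t)), numeric(1))
  expect_lte(max(err), 2)                            # within one sample
  expect_true(all(diff(fp$times) >= 200))
  expect_error(detect_fetal_rpeaks(
    fecg_signal(rnorm(500), fs = 500)), "shorter than 2 s")
})

test_that("fetal detection stays >= 95% sensitive at 10 dB SNR", {
  rr <- generate_rri_sequence(subject_spec("n10", "healthy", duration = 60,
                                           seed = 21))
  clean <- synthesize_fecg(rr, fs = 500, noise_sd = 0, seed = 22)
  nsd <- noise_sd_for_snr(clean$fecg$samples, 10)
  fe <- synthesize_fecg(rr, fs = 500, noise_sd = nsd, seed = 22)
  fp <- detect_fetal_rpeaks(fe$fecg)
  gt <- fe$rpeaks_ms
  d <- vapply(gt, function(t) min(abs(fp$times - t)), numeric(1))
  expect_gte(mean(d <= 20), 0.95)
})

test_that("long arrhythmic intervals survive without spurious insertions", {
  sp <- subject_spec("ae", "arrhythmia", arrhythmia_episode_rate = 6,
                     episode_rri_range = c(500, 700), duration = 300,
                     seed = 31)
  rr <- generate_rri_sequence(sp)
  clean <- synthesize_fecg(rr, fs = 500, noise_sd = 0, seed = 32)
  nsd <- noise_sd_for_snr(clean$fecg$samples, 10)
  fe <- synthesize_fecg(rr, fs = 500, noise_sd = nsd, seed = 32)
  fp <- detect_fetal_rpeaks(fe$fecg)
  long_idx <- which(rr$intervals >= 500)
  starts <- rr$start_times[long_idx]
  ends <- rr$end_times[long_idx]
  ok <- vapply(seq_along(long_idx), function(i) {
    inside <- fp$times > starts[i] + 20 & fp$times < ends[i] - 20
    !any(inside) &&
      min(abs(fp$times - starts[i])) <= 20 &&
      min(abs(fp$times - ends[i])) <= 20
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("RR intervals are successive differences with a physiological gate", {
  expect_equal(compute_rri(rpeak_series(c(0, 400, 800)))$intervals,
               c(400, 400))
  expect_equal(compute_rri(rpeak_series(c(0, 50, 450)))$intervals, 400)
  expect_error(compute_rri(rpeak_series(0)), "2 peaks")
  ex <- tiny_extracted()
  gt <- ground_truth_stats(tiny_records())
  for (i in seq_along(ex)) {
    expect_lt(abs(mean(ex[[i]]$rris$intervals) -
                    gt$gt_mean[gt$subject_id == names(ex)[i]]), 10)
  }
})
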