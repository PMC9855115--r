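## Fetal ECG extraction: preprocess -> maternal R-peaks (Pan-Tompkins) ->
## maternal template subtraction -> fetal R-peaks (derivative candidates
## weighted by a Gaussian RR-interval prior) -> RR intervals.

butter_filtfilt_ <- function(x, fs, lo = NULL, hi = NULL, order = 3) {
  nyq <- fs / 2
  filt <- if (!is.null(lo) && !is.null(hi))
    signal::butter(order, c(lo, hi) / nyq, type = "pass")
  else if (!is.null(hi))
    signal::butter(order, hi / nyq, type = "low")
  else signal::butter(order, lo / nyq, type = "high")
  as.numeric(signal::filtfilt(filt, x))
}

## runs of samples pinned at the observed dynamic-range rails for >= min_ms
saturation_mask_ <- function(x, fs, min_ms = 50, frac = 0.999) {
  rail <- max(abs(x[is.finite(x)]), na.rm = TRUE)
  if (!is.finite(rail) || rail == 0) return(rep(FALSE, length(x)))
  pinned <- is.finite(x) & abs(x) >= frac * rail
  r <- rle(pinned)
  min_run <- ceiling(min_ms / 1000 * fs)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Preprocess an abdominal ECG record
#'
#' Masks saturated runs (samples pinned at >= 99.9% of the observed dynamic
#' range for at least 50 ms) and non-finite samples as invalid, band-pass
#' filters every channel 3--45 Hz (zero-phase Butterworth), and resamples
#' 1 kHz records to 500 Hz by factor-2 decimation (the 45 Hz low-pass edge
#' is the anti-alias filter).
#'
#' @param record An `aecg_record`.
#' @param band Band-pass edges in Hz.
#' @return The filtered `aecg_record` at 500 Hz with an updated
#'   `valid_mask`.
#' @export
preprocess <- function(record, band = c(3, 45)) {
  stopifnot(inherits(record, "aecg_record"))
  n <- ncol(record$channels)
  invalid <- rep(FALSE, n)
  ch <- record$channels
  for (i in seq_len(nrow(ch))) {
    x <- ch[i, ]
    bad <- !is.finite(x) | saturation_mask_(x, record$fs)
    invalid <- invalid | bad
    x[!is.finite(x)] <- 0
    x[bad] <- 0                     # do not let rails ring through the filter
    ch[i, ] <- butter_filtfilt_(x, record$fs, band[1], band[2])
  }
  if (mean(invalid) > 0.5)
    stop(sprintf("record %s rejected: %.0f%% of samples invalid",
                 record$subject_id, 100 * mean(invalid)), call. = FALSE)
  mask <- record$valid_mask & !invalid
  fs <- record$fs
  if (fs == 1000) {
    keep <- seq(1L, n, by = 2L)
    ch <- ch[, keep, drop = FALSE]
    mask <- mask[keep]
    fs <- 500
  }
  out <- record
  out$channels <- ch
  out$fs <- fs
  out$valid_mask <- mask
  out
}

local_maxima_ <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect maternal R-peaks (Pan--Tompkins)
#'
#' Classic chain on the maternal thoracic channel (or, failing that, the
#' abdominal channel with the highest 5--15 Hz QRS-band energy): band-pass
#' 5--15 Hz, five-point derivative, squaring, 150 ms moving-window
#' integration, then adaptive signal/noise threshold tracking with a 200 ms
#' refractory period. Peak times are refined to the absolute maximum of the
#' band-passed signal within +/-60 ms.
#'
#' @param record A preprocessed `aecg_record`.
#' @return An `rpeak_series` (times in ms).
#' @export
detect_maternal_rpeaks <- function(record) {
  stopifnot(inherits(record, "aecg_record"))
  fs <- record$fs
  idx_th <- which(record$channel_roles == "maternal_thoracic")
  if (length(idx_th)) {
    x <- record$channels[idx_th[1], ]
  } else {
    abd <- which(record$channel_roles == "abdominal")
    energies <- vapply(abd, function(i)
      mean(butter_filtfilt_(record$channels[i, ], fs, 5, 15)^2), numeric(1))
    x <- record$channels[abd[which.max(energies)], ]
  }
  bp <- butter_filtfilt_(x, fs, 5, 15, order = 2)
  # five-point derivative, squaring, 150 ms moving-window integration
  d <- signal::filter(c(1, 2, 0, -2, -1) * fs / 8, 1, bp)
  sq <- as.numeric(d)^2
  w <- round(0.150 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0
  cand <- local_maxima_(mwi)
  if (!length(cand)) stop("no maternal QRS candidates found", call. = FALSE)
  # QRS trains concentrate MWI energy in narrow crests; in noise the upper
  # tail stays within a few times the median
  contrast <- stats::quantile(mwi, 0.99, names = FALSE) /
    max(stats::quantile(mwi, 0.5, names = FALSE), 1e-30)
  if (contrast < 10)
    stop("no maternal QRS activity detectable (noise-like channel, ",
         "MWI contrast ", signif(contrast, 3), ")", call. = FALSE)
  refractory <- round(0.200 * fs)
  spki <- max(mwi[cand[cand <= 2 * fs]], 0) * 0.5
  npki <- mean(mwi[seq_len(min(length(mwi), 2 * fs))])
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr && (i - last) > refractory) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(peaks))
    stop("no maternal R-peaks above threshold (noise-only channel?)",
         call. = FALSE)
  # refine on the band-passed waveform; the MWI crest lags the R wave, and
  # the complex is biphasic, so take the midpoint of its extremum pair
  half <- round(0.060 * fs)
  ref <- vapply(peaks, function(i) {
    j <- max(1L, i - 2L * half):max(1L, min(length(bp), i))
    k <- j[which.max(abs(bp[j]))]
    j2 <- max(1L, k - half):min(length(bp), k + half)
    (j2[which.max(bp[j2])] + j2[which.min(bp[j2])]) / 2
  }, numeric(1))
  ref <- sort(unique(ref))
  ref <- ref[c(TRUE, diff(ref) > refractory)]
  rpeak_series((ref - 1) / fs * 1000, subject_id = record$subject_id)
}

excess_kurtosis_ <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

#' Remove the maternal component by template subtraction
#'
#' For every abdominal channel, beat-aligned windows (-250 to +450 ms
#' around each maternal R-peak, linearly tapered over the outer 25 ms) are
#' averaged into a maternal template, which is scaled per beat by least
#' squares and subtracted. The single abdominal channel whose residual has
#' the highest 10--40 Hz excess kurtosis (spikiest fetal content) is
#' returned as the fetal ECG.
#'
#' @param record A preprocessed `aecg_record`.
#' @param mpeaks Maternal `rpeak_series` (needs >= 10 peaks).
#' @param window_ms Template window around each R-peak, ms.
#' @return An `fecg_signal`.
#' @export
subtract_maternal_template <- function(record, mpeaks,
                                       window_ms = c(-250, 450)) {
  stopifnot(inherits(record, "aecg_record"), inherits(mpeaks, "rpeak_series"))
  if (length(mpeaks$times) < 10L)
    stop("need at least 10 maternal peaks for a template", call. = FALSE)
  fs <- record$fs
  off <- round(window_ms / 1000 * fs)
  wlen <- off[2] - off[1] + 1L
  taper <- rep(1, wlen)
  tp <- round(0.025 * fs)
  taper[seq_len(tp)] <- seq(0, 1, length.out = tp)
  taper[wlen - seq_len(tp) + 1L] <- seq(0, 1, length.out = tp)
  pk <- round(mpeaks$times / 1000 * fs) + 1L   # 1-based sample index
  abd <- which(record$channel_roles == "abdominal")
  n <- ncol(record$channels)
  residuals <- matrix(NA_real_, length(abd), n)
  for (k in seq_along(abd)) {
    x <- record$channels[abd[k], ]
    full <- pk[pk + off[1] >= 1L & pk + off[2] <= n]
    if (length(full) < 10L)
      stop("fewer than 10 maternal beats fully inside the record",
           call. = FALSE)
    W <- vapply(full, function(p) x[(p + off[1]):(p + off[2])],
                numeric(wlen))
    tmpl <- rowMeans(W) * taper
    den <- sum(tmpl^2)
    res <- x
    if (den > 0) {
      for (j in seq_along(full)) {
        idx <- (full[j] + off[1]):(full[j] + off[2])
        a <- sum(res[idx] * tmpl) / den
        res[idx] <- res[idx] - a * tmpl
      }
    }
    residuals[k, ] <- res
  }
  kurt <- apply(residuals, 1, function(r)
    excess_kurtosis_(butter_filtfilt_(r, fs, 10, 40)))
  best <- which.max(kurt)
  fecg_signal(residuals[best, ], fs = fs, subject_id = record$subject_id,
              valid_mask = record$valid_mask, true_class = record$true_class)
}

#' Detect fetal R-peaks with a Gaussian RR-interval prior
#'
#' Candidates are local maxima of the smoothed absolute first derivative of
#' the fetal ECG above an adaptive (per 5 s block) threshold. Peaks are then
#' accepted greedily left to right: from the last accepted peak, each
#' candidate within the search horizon is scored by its amplitude times a
#' Gaussian weight `exp(-(dt - mu)^2 / (2 sigma^2))` (plus a small floor so
#' genuinely long arrhythmic intervals survive) on the elapsed interval
#' `dt`, with the running RR mean/SD `(mu, sigma)` initialized at
#' (400, 50) ms and updated by exponential smoothing; a 200 ms refractory
#' period is enforced throughout. Candidates far below the running peak
#' amplitude are ineligible, which suppresses noise spikes between beats.
#'
#' @param fecg An `fecg_signal` (>= 2 s long).
#' @param init_rr Initial (mean, sd) of the RR prior, ms.
#' @param weight_floor Additive floor on the Gaussian weight.
#' @param amp_gate Candidates below `amp_gate` times the running median
#'   accepted amplitude are ignored.
#' @param skip_penalty Penalty per unit of skipped-candidate amplitude when
#'   a later candidate is chosen over an earlier eligible one.
#' @return An `rpeak_series`.
#' @export
detect_fetal_rpeaks <- function(fecg, init_rr = c(400, 50),
                                weight_floor = 0.05, amp_gate = 0.4,
                                skip_penalty = 0.5) {
  stopifnot(inherits(fecg, "fecg_signal"))
  fs <- fecg$fs
  x <- fecg$samples
  if (length(x) < 2 * fs) stop("signal shorter than 2 s", call. = FALSE)
  x[!fecg$valid_mask] <- 0
  xb <- butter_filtfilt_(x, fs, 8, 45, order = 3)
  d <- c(0, diff(xb)) * fs / 1000              # per-ms slope
  sm <- round(0.020 * fs)
  env <- as.numeric(stats::filter(abs(d), rep(1 / sm, sm), sides = 2))
  env[is.na(env)] <- 0
  edge <- round(0.25 * fs)               # filtfilt edge transients
  env[seq_len(edge)] <- 0
  env[(length(env) - edge + 1L):length(env)] <- 0
  cand <- local_maxima_(env)
  # adaptive candidate gate: fraction of the strong-peak level per 5 s block
  blk <- ceiling(seq_along(env)[cand] / (5 * fs))
  thr_blk <- tapply(env[cand], blk, function(v) 0.25 * stats::quantile(v, 0.9))
  cand <- cand[env[cand] > thr_blk[as.character(blk)]]
  if (length(cand) < 2L) stop("no fetal R-peak candidates", call. = FALSE)
  amp <- env[cand]
  t_ms <- (cand - 1L) / fs * 1000
  mu <- init_rr[1]; sig <- init_rr[2]
  refr <- 200
  horizon <- 1000
  # robust beat-amplitude scale: real R-peaks dominate the upper candidate
  # amplitudes; isolated artifacts several times larger are excluded
  amp0 <- stats::quantile(amp, 0.8, names = FALSE)
  # first peak: strongest plausible candidate in the opening 1.5 s
  first_pool <- which(t_ms <= 1500 & amp >= 0.4 * amp0 & amp <= 4 * amp0)
  if (!length(first_pool)) first_pool <- which(t_ms <= 1500)
  if (!length(first_pool)) first_pool <- 1L
  acc <- first_pool[which.max(amp[first_pool])]
  accepted <- c(acc)
  amp_med <- amp0
  last_t <- t_ms[acc]
  while (TRUE) {
    pool <- which(t_ms > last_t + refr & t_ms <= last_t + horizon &
                    amp >= amp_gate * amp_med)
    if (!length(pool)) {
      nxt <- which(t_ms > last_t + refr & amp >= amp_gate * amp_med)
      if (!length(nxt)) break
      pick <- nxt[1]                            # dropout: resync on next strong peak
    } else {
      dt <- t_ms[pool] - last_t
      w <- exp(-(dt - mu)^2 / (2 * max(sig, 40)^2)) + weight_floor
      # choosing a later candidate forfeits the strong candidates it skips:
      # every real QRS should be consumed, so skipping one is evidence
      # against the later pick (keeps short tachycardic beats alive even
      # though the RR prior favors the skip-one interval)
      skipped <- c(0, cumsum(amp[pool]))[seq_along(pool)]
      pick <- pool[which.max(amp[pool] * w - skip_penalty * skipped)]
      dt_pick <- t_ms[pick] - last_t
      if (dt_pick >= 220 && dt_pick <= 650) {   # update prior on plausible beats
        mu <- 0.9 * mu + 0.1 * dt_pick
        sig <- min(max(0.9 * sig + 0.1 * abs(dt_pick - mu), 30), 90)
      }
    }
    accepted <- c(accepted, pick)
    amp_med <- if (length(accepted) >= 5L)
      stats::median(amp[utils::tail(accepted, 15L)]) else amp0
    last_t <- t_ms[pick]
  }
  # refine each peak to the center of the biphasic complex: midpoint of the
  # extremum pair of the band-passed waveform within +/-12 ms
  half_r <- round(0.012 * fs)
  ref <- vapply(cand[accepted], function(i) {
    j <- max(1L, i - half_r):min(length(xb), i + half_r)
    (j[which.max(xb[j])] + j[which.min(xb[j])]) / 2
  }, numeric(1))
  ref <- sort(ref)
  keep <- c(TRUE, diff(ref) > refr / 1000 * fs)
  rpeak_series((ref[keep] - 1) / fs * 1000, subject_id = fecg$subject_id)
}

#' Compute RR intervals from R-peak times
#'
#' Successive differences of the peak times; intervals outside the
#' physiological gate (default 100--900 ms) are dropped.
#'
#' @param peaks An `rpeak_series` with >= 2 peaks.
#' @param gate_ms Physiological interval gate `(lo, hi)` in ms.
#' @param true_class Subject class to attach.
#' @return An `rri_series`.
#' @export
compute_rri <- function(peaks, gate_ms = c(100, 900), true_class = "unknown") {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$times) < 2L) stop("need at least 2 peaks", call. = FALSE)
  iv <- diff(peaks$times)
  st <- peaks$times[-length(peaks$times)]
  en <- peaks$times[-1]
  keep <- iv >= gate_ms[1] & iv <= gate_ms[2]
  if (!any(keep)) stop("no intervals inside the physiological gate", call. = FALSE)
  rri_series(iv[keep], start_times = st[keep], end_times = en[keep],
             subject_id = peaks$subject_id, true_class = true_class)
}

#' Run the whole extraction chain on one record
#'
#' [preprocess()] then [detect_maternal_rpeaks()],
#' [subtract_maternal_template()], [detect_fetal_rpeaks()] and
#' [compute_rri()].
#'
#' @param record An `aecg_record`.
#' @return List with `fecg` (`fecg_signal`), `fpeaks` (`rpeak_series`) and
#'   `rris` (`rri_series`).
#' @export
extract_fecg <- function(record) {
  pp <- preprocess(record)
  mp <- detect_maternal_rpeaks(pp)
  fecg <- subtract_maternal_template(pp, mp)
  fp <- detect_fetal_rpeaks(fecg)
  rr <- compute_rri(fp, true_class = record$true_class)
  list(fecg = fecg, fpeaks = fp, rris = rr)
}
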