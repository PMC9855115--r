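#' Multichannel abdominal ECG record
#'
#' @param subject_id Character identifier.
#' @param channels Numeric matrix, one row per channel.
#' @param channel_names Character vector, one per channel.
#' @param channel_roles Per-channel role, `"abdominal"` or
#'   `"maternal_thoracic"`.
#' @param fs Sampling frequency in Hz.
#' @param true_class `"healthy"`, `"arrhythmia"` or `"unknown"`.
#' @param valid_mask Optional logical vector (TRUE = usable sample).
#' @param meta Optional list of extra metadata (e.g. ground-truth peaks).
#' @return An `aecg_record`.
#' @export
aecg_record <- function(subject_id, channels, channel_names = NULL,
                        channel_roles = NULL, fs,
                        true_class = "unknown", valid_mask = NULL,
                        meta = list()) {
  if (!is.matrix(channels)) channels <- matrix(channels, nrow = 1L)
  nc <- nrow(channels)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (is.null(channel_roles)) channel_roles <- infer_channel_roles(channel_names)
  stopifnot(length(channel_names) == nc, length(channel_roles) == nc)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!any(channel_roles == "abdominal"))
    stop("record needs at least one abdominal channel", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, ncol(channels))
  stopifnot(length(valid_mask) == ncol(channels))
  structure(
    list(subject_id = subject_id, channels = channels,
         channel_names = channel_names, channel_roles = channel_roles,
         fs = fs, true_class = true_class, valid_mask = valid_mask,
         meta = meta),
    class = "aecg_record")
}

#' @export
print.aecg_record <- function(x, ...) {
  cat(sprintf("<aecg_record> %s: %d ch x %d samples @ %g Hz (%.1f s), class=%s\n",
              x$subject_id, nrow(x$channels), ncol(x$channels), x$fs,
              ncol(x$channels) / x$fs, x$true_class))
  cat("  channels:", paste(sprintf("%s[%s]", x$channel_names,
                                   substr(x$channel_roles, 1, 3)),
                           collapse = " "), "\n")
  invisible(x)
}

#' Extracted fetal ECG signal
#'
#' @param samples Numeric vector, signal units.
#' @param fs Sampling frequency (500 Hz after preprocessing).
#' @param subject_id Identifier.
#' @param valid_mask Logical per-sample validity.
#' @param true_class Subject class if known.
#' @return An `fecg_signal`.
#' @export
fecg_signal <- function(samples, fs, subject_id = "unknown",
                        valid_mask = NULL, true_class = "unknown") {
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(samples))
  stopifnot(length(valid_mask) == length(samples))
  if (any(!is.finite(samples[valid_mask])))
    stop("samples must be finite where valid", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, valid_mask = valid_mask,
                 true_class = true_class),
            class = "fecg_signal")
}

#' @export
print.fecg_signal <- function(x, ...) {
  cat(sprintf("<fecg_signal> %s: %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Series of R-peak times
#'
#' @param times Strictly increasing peak times in ms from record start.
#' @param subject_id Identifier.
#' @return An `rpeak_series`.
#' @export
rpeak_series <- function(times, subject_id = "unknown") {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  structure(list(times = times, subject_id = subject_id),
            class = "rpeak_series")
}

#' Series of RR intervals
#'
#' Each interval is attached to the (start, end) times of its defining
#' R-peak pair; `interval = end - start > 0`.
#'
#' @param intervals Numeric, ms.
#' @param start_times,end_times Numeric, ms; `end_times - start_times`
#'   must equal `intervals`.
#' @param subject_id Identifier.
#' @param true_class Subject class if known.
#' @return An `rri_series`.
#' @export
rri_series <- function(intervals, start_times = NULL, end_times = NULL,
                       subject_id = "unknown", true_class = "unknown") {
  intervals <- as.numeric(intervals)
  if (is.null(start_times)) {
    start_times <- cumsum(c(0, intervals))[seq_along(intervals)]
    end_times <- start_times + intervals
  }
  if (any(intervals <= 0)) stop("intervals must be positive", call. = FALSE)
  stopifnot(length(start_times) == length(intervals),
            length(end_times) == length(intervals))
  structure(list(intervals = intervals, start_times = as.numeric(start_times),
                 end_times = as.numeric(end_times), subject_id = subject_id,
                 true_class = true_class),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %s (%s): %d intervals, mean %.1f ms, sd %.1f ms\n",
              x$subject_id, x$true_class, length(x$intervals),
              mean(x$intervals), stats::sd(x$intervals)))
  invisible(x)
}
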