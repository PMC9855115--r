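#' Cut a fetal ECG into fixed sliding windows
#'
#' Windows of `window_s` seconds advance by `step_s` seconds, giving
#' `floor((duration - window_s) / step_s) + 1` segments of exactly
#' `window_s * fs` samples. A segment's contained RR intervals are those
#' whose *both* defining R-peaks lie inside `[start, start + window)`;
#' boundary-straddling intervals belong to no segment. Segments overlapping
#' any invalid-mask region are dropped.
#'
#' @param fecg An `fecg_signal`.
#' @param rris The subject's `rri_series`.
#' @param window_s Window length, s.
#' @param step_s Step size, s.
#' @return A `segment_set`: list with `samples` (matrix, one row per
#'   segment), `meta` (data frame: `subject_id`, `start_ms`, `n_rri`,
#'   `subject_class`) and `rris` (list of per-segment interval vectors).
#' @export
segment_signal <- function(fecg, rris, window_s = 3, step_s = 1) {
  stopifnot(inherits(fecg, "fecg_signal"))
  fs <- fecg$fs
  wlen <- round(window_s * fs)
  slen <- round(step_s * fs)
  n <- length(fecg$samples)
  if (n < wlen) {
    warning("signal shorter than one window; no segments")
    return(segment_set_(matrix(numeric(0), 0, wlen), list(),
                        character(0), numeric(0), fecg$true_class))
  }
  n_seg <- (n - wlen) %/% slen + 1L
  starts <- (seq_len(n_seg) - 1L) * slen          # 0-based sample offsets
  keep <- vapply(starts, function(s)
    all(fecg$valid_mask[(s + 1L):(s + wlen)]), logical(1))
  starts <- starts[keep]
  samples <- t(vapply(starts, function(s)
    fecg$samples[(s + 1L):(s + wlen)], numeric(wlen)))
  if (length(starts) == 1L) samples <- matrix(samples, nrow = 1L)
  start_ms <- starts / fs * 1000
  win_ms <- window_s * 1000
  seg_rris <- lapply(start_ms, function(s0) {
    sel <- rris$start_times >= s0 & rris$end_times < s0 + win_ms
    rris$intervals[sel]
  })
  segment_set_(samples, seg_rris, fecg$subject_id, start_ms,
               fecg$true_class)
}

segment_set_ <- function(samples, rri_list, subject_id, start_ms,
                         subject_class) {
  n <- nrow(samples)
  meta <- data.frame(
    subject_id = rep(if (length(subject_id)) subject_id else "unknown", n),
    start_ms = if (n) start_ms else numeric(0),
    n_rri = if (n) vapply(rri_list, length, integer(1)) else integer(0),
    subject_class = rep(if (length(subject_class)) subject_class else
                          "unknown", n),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, meta = meta, rris = rri_list),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples (%s)\n",
              nrow(x$samples), ncol(x$samples),
              paste(unique(x$meta$subject_id), collapse = ",")))
  invisible(x)
}

#' Concatenate segment sets from several subjects
#'
#' @param sets List of `segment_set` objects with equal window lengths.
#' @return A single `segment_set`.
#' @export
bind_segment_sets <- function(sets) {
  sets <- sets[vapply(sets, function(s) nrow(s$samples) > 0L, logical(1))]
  if (!length(sets)) stop("no non-empty segment sets", call. = FALSE)
  structure(list(samples = do.call(rbind, lapply(sets, `[[`, "samples")),
                 meta = do.call(rbind, lapply(sets, `[[`, "meta")),
                 rris = do.call(c, lapply(sets, `[[`, "rris"))),
            class = "segment_set")
}

#' Subset a segment set by row index
#'
#' @param set A `segment_set`.
#' @param idx Integer or logical index.
#' @return A `segment_set`.
#' @export
subset_segments <- function(set, idx) {
  structure(list(samples = set$samples[idx, , drop = FALSE],
                 meta = set$meta[idx, , drop = FALSE],
                 rris = set$rris[idx]),
            class = "segment_set")
}

#' Write / read a segment store
#'
#' Plain-text store: a CSV metadata table (with label column if present)
#' and a gzip-compressed CSV of the sample matrix.
#'
#' @param set A `segment_set`.
#' @param dir Directory to write into.
#' @param labels Optional factor/character of segment labels.
#' @return Invisibly, `dir`.
#' @export
write_segments <- function(set, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- set$meta
  if (!is.null(labels)) meta$label <- as.character(labels)
  utils::write.csv(meta, file.path(dir, "segments_meta.csv"),
                   row.names = FALSE)
  con <- gzfile(file.path(dir, "segments_samples.csv.gz"), "w")
  utils::write.table(set$samples, con, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  close(con)
  invisible(dir)
}
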