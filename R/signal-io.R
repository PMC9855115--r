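## Minimal WFDB (format 16) and CSV record I/O with JSON sidecars.
## Sample values are digitized as int16 with a per-channel gain chosen to
## use most of the 16-bit range; physical = adc / gain.

WFDB_ADC_TARGET <- 30000

#' Infer channel roles from channel names
#'
#' Default pattern table maps names containing "thoracic", "chest", "mat"
#' or "mecg" (case-insensitive) to `maternal_thoracic`, everything else to
#' `abdominal`. Supply your own named vector of regex -> role to override.
#'
#' @param channel_names Character vector.
#' @param role_patterns Named character vector `c(regex = role, ...)`,
#'   tried in order; first match wins.
#' @return Character vector of roles.
#' @export
infer_channel_roles <- function(channel_names,
                                role_patterns = c("thoracic|chest|mat|mecg" =
                                                    "maternal_thoracic")) {
  roles <- rep("abdominal", length(channel_names))
  for (pat in names(role_patterns)) {
    hit <- grepl(pat, channel_names, ignore.case = TRUE)
    roles[hit] <- role_patterns[[pat]]
  }
  roles
}

sidecar_path_ <- function(base) paste0(base, ".json")

write_sidecar_ <- function(record, base) {
  side <- list(subject_id = record$subject_id, true_class = record$true_class,
               fs = record$fs, channel_roles = record$channel_roles)
  if (!is.null(record$meta$rpeaks_ms))
    side$rpeaks_ms <- record$meta$rpeaks_ms
  if (!is.null(record$meta$maternal_peaks_ms))
    side$maternal_peaks_ms <- record$meta$maternal_peaks_ms
  jsonlite::write_json(side, sidecar_path_(base), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar_ <- function(base) {
  p <- sidecar_path_(base)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Write an AECG record
#'
#' WFDB output writes `<path>.hea` (text header), `<path>.dat` (format 16,
#' interleaved little-endian int16) and a `<path>.json` sidecar with
#' subject id, class, sampling rate and any ground-truth peak times. CSV
#' output writes one column per channel with a header row plus the same
#' sidecar. Digitization quantizes each channel to its gain grid; a second
#' write/read cycle is bit-exact.
#'
#' @param record An `aecg_record`.
#' @param path Output path without extension (WFDB) or with/without `.csv`.
#' @param format `"wfdb"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "aecg_record"))
  if (ncol(record$channels) == 0L) stop("record has no samples", call. = FALSE)
  if (format == "csv") {
    base <- sub("\\.csv$", "", path)
    df <- as.data.frame(t(record$channels))
    names(df) <- record$channel_names
    utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
    write_sidecar_(record, base)
    return(invisible(path))
  }
  base <- path
  rec_name <- basename(base)
  nsig <- nrow(record$channels)
  nsamp <- ncol(record$channels)
  gains <- apply(record$channels, 1, function(x) {
    mx <- max(abs(x), na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) 1000 else max(1, floor(WFDB_ADC_TARGET / mx))
  })
  adc <- round(record$channels * gains)   # rows scaled by per-row gain
  adc[!is.finite(adc)] <- 0
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- c(sprintf("%s %d %g %d", rec_name, nsig, record$fs, nsamp),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                   rec_name, gains, as.integer(adc[, 1]),
                   record$channel_names))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(as.vector(adc)), con, size = 2L, endian = "little")
  write_sidecar_(record, base)
  invisible(path)
}

parse_hea_ <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed WFDB header: ", hea_path, call. = FALSE)
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  sig <- lines[1 + seq_len(nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- 0
    if (grepl("\\(", gain_spec))
      baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_spec))
    list(file = f[1], fmt = f[2], gain = gain, baseline = baseline,
         name = if (length(f) >= 9) f[length(f)] else NA_character_)
  }
  info <- lapply(sig, parse_sig)
  fmts <- vapply(info, `[[`, character(1), "fmt")
  if (!all(fmts == "16"))
    stop("unsupported WFDB signal format (only 16 supported): ",
         paste(unique(fmts), collapse = ","), call. = FALSE)
  list(nsig = nsig, fs = fs, nsamp = nsamp, info = info)
}

#' Read an AECG record
#'
#' Accepts a WFDB record (`<path>.hea` + `<path>.dat`, format 16) or a CSV
#' file with a header row and one column per channel. Channel roles are
#' inferred from names via [infer_channel_roles()] unless overridden.
#' Subject class, sampling rate (CSV) and ground-truth peaks are taken from
#' a `<path>.json` sidecar when present; the class is `"unknown"` without
#' one.
#'
#' @param path Record path: `<base>` or `<base>.hea` for WFDB, `<base>.csv`
#'   for CSV.
#' @param fs Sampling rate override (required for CSV without sidecar).
#' @param role_patterns Passed to [infer_channel_roles()].
#' @return An `aecg_record`.
#' @export
read_record <- function(path, fs = NULL, role_patterns = NULL) {
  ext <- tolower(tools::file_ext(path))
  base <- if (ext %in% c("hea", "dat", "csv")) tools::file_path_sans_ext(path) else path
  is_csv <- ext == "csv" || (!file.exists(paste0(base, ".hea")) &&
                               file.exists(paste0(base, ".csv")))
  side <- read_sidecar_(base)
  roles_args <- if (is.null(role_patterns)) list() else
    list(role_patterns = role_patterns)
  if (is_csv) {
    csv_path <- paste0(base, ".csv")
    if (!file.exists(csv_path)) stop("no such record: ", path, call. = FALSE)
    df <- utils::read.csv(csv_path, check.names = FALSE)
    if (is.null(fs)) fs <- as.numeric(side$fs)
    if (is.null(fs))
      stop("CSV record needs fs from the sidecar or the fs argument",
           call. = FALSE)
    ch <- t(as.matrix(df))
    names_ <- names(df)
  } else {
    hea_path <- paste0(base, ".hea")
    if (!file.exists(hea_path))
      stop("missing WFDB header: ", hea_path, call. = FALSE)
    h <- parse_hea_(hea_path)
    dat_path <- file.path(dirname(base), h$info[[1]]$file)
    if (!file.exists(dat_path))
      stop("missing WFDB signal file: ", dat_path, call. = FALSE)
    raw <- readBin(dat_path, integer(), n = h$nsig * h$nsamp + h$nsig,
                   size = 2L, endian = "little")
    if (length(raw) != h$nsig * h$nsamp)
      stop("WFDB signal length inconsistent with header (", length(raw),
           " vs ", h$nsig * h$nsamp, " samples)", call. = FALSE)
    adc <- matrix(raw, nrow = h$nsig, ncol = h$nsamp)
    gains <- vapply(h$info, `[[`, numeric(1), "gain")
    base_l <- vapply(h$info, `[[`, numeric(1), "baseline")
    ch <- (adc - base_l) / gains
    names_ <- vapply(h$info, `[[`, character(1), "name")
    if (anyNA(names_)) names_ <- paste0("ch", seq_len(h$nsig))
    fs <- h$fs
  }
  roles <- if (!is.null(side$channel_roles) && length(side$channel_roles) == nrow(ch))
    side$channel_roles else do.call(infer_channel_roles, c(list(names_), roles_args))
  meta <- list()
  if (!is.null(side$rpeaks_ms)) meta$rpeaks_ms <- side$rpeaks_ms
  if (!is.null(side$maternal_peaks_ms))
    meta$maternal_peaks_ms <- side$maternal_peaks_ms
  aecg_record(subject_id = if (!is.null(side$subject_id)) side$subject_id
                           else basename(base),
              channels = ch, channel_names = names_, channel_roles = roles,
              fs = fs,
              true_class = if (!is.null(side$true_class)) side$true_class
                           else "unknown",
              meta = meta)
}

#' Read a cohort manifest
#'
#' @param dir Directory containing `manifest.csv` as written by
#'   [write_cohort()].
#' @return Data frame with columns `subject_id`, `path`, `true_class`.
#' @export
read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.csv")
  if (!file.exists(p)) stop("no manifest.csv in ", dir, call. = FALSE)
  m <- utils::read.csv(p, stringsAsFactors = FALSE)
  if (anyDuplicated(m$subject_id))
    stop("manifest subject_ids must be unique", call. = FALSE)
  m
}

#' Read precomputed R-peak times from CSV
#'
#' Bypass for the detection stage: a CSV with columns `subject_id` and
#' `time_ms` yields one `rpeak_series` per subject, so labeling and
#' classification can be exercised independently of peak detection.
#'
#' @param path CSV path.
#' @return Named list of `rpeak_series`.
#' @export
read_rpeaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "time_ms") %in% names(df)))
    stop("expected columns subject_id, time_ms", call. = FALSE)
  lapply(split(df$time_ms, df$subject_id), function(t)
    rpeak_series(sort(t)))
}
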