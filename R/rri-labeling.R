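## Weak labeling of segments from the cohort RR-interval histogram:
## 25 ms bins, per-bin healthy/arrhythmia counts and their ratio, bin
## classes A/M/N driven by a threshold x, and the per-subject
## mean +/- y*SD band variant.

#' Build the pooled RR-interval range table
#'
#' Pools all healthy-subject and all arrhythmia-subject RRIs into
#' contiguous bins of `bin_ms` (default 25 ms) over `support` and computes
#' the per-bin ratio healthy_count / arrhythmia_count (`Inf` when only
#' healthy intervals fall in a bin, `NaN` when the bin is empty).
#'
#' @param cohort_rris List of `rri_series`, each with a known `true_class`.
#' @param bin_ms Bin width, ms.
#' @param support Histogram support `(lo, hi)`, ms.
#' @return An `rri_range_table` data frame with columns `lo`, `hi`,
#'   `healthy_count`, `arrhythmia_count`, `ratio`.
#' @export
build_rri_histogram <- function(cohort_rris, bin_ms = 25,
                                support = c(100, 900)) {
  if (!length(cohort_rris)) stop("empty cohort", call. = FALSE)
  cls <- vapply(cohort_rris, function(r) r$true_class, character(1))
  if (!all(cls %in% c("healthy", "arrhythmia")))
    stop("every series needs true_class healthy or arrhythmia", call. = FALSE)
  breaks <- seq(support[1], support[2], by = bin_ms)
  pool <- function(klass) {
    v <- unlist(lapply(cohort_rris[cls == klass], `[[`, "intervals"))
    v <- v[v >= support[1] & v < support[2]]
    if (!length(v)) return(integer(length(breaks) - 1L))
    as.integer(table(cut(v, breaks, right = FALSE,
                         include.lowest = FALSE)))
  }
  h <- pool("healthy")
  a <- pool("arrhythmia")
  tab <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    healthy_count = h, arrhythmia_count = a,
                    ratio = h / a)
  class(tab) <- c("rri_range_table", "data.frame")
  tab
}

#' Classify RRI ranges as arrhythmic / moderate / normal
#'
#' A bin is `N` (normal) when healthy intervals outnumber arrhythmic ones
#' (ratio > 1), `A` (arrhythmic) when the ratio is strictly below the
#' threshold `x`, `M` (moderate) when `x <= ratio <= 1`, and `unobserved`
#' when both counts are zero. The strict `< x` reading is the one consistent
#' with published range tables of this labeling scheme (a bin with ratio
#' exactly equal to x stays moderate).
#'
#' @param table An `rri_range_table`.
#' @param x Ratio threshold in (0, 1].
#' @return The table with a `range_class` column (factor
#'   A/M/N/unobserved).
#' @export
classify_rri_ranges <- function(table, x) {
  stopifnot(inherits(table, "rri_range_table"))
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
    stop("x must lie in (0, 1]", call. = FALSE)
  r <- table$ratio
  cls <- rep("M", nrow(table))
  cls[which(r > 1)] <- "N"          # Inf ratios (healthy only) are normal
  cls[which(r < x)] <- "A"
  cls[which(table$healthy_count == 0 & table$arrhythmia_count == 0)] <-
    "unobserved"
  table$range_class <- factor(cls, levels = c("A", "M", "N", "unobserved"))
  attr(table, "x") <- x
  table
}

bin_class_of_ <- function(rri, table) {
  i <- findInterval(rri, c(table$lo, table$hi[nrow(table)]))
  out <- rep("unobserved", length(rri))
  ok <- i >= 1L & i <= nrow(table) & rri < table$hi[nrow(table)]
  out[ok] <- as.character(table$range_class[i[ok]])
  out
}

#' Label one segment from the range table
#'
#' Precedence arrhythmia > moderate > normal over the classes of the
#' contained RRIs; intervals in unobserved bins count as moderate; segments
#' with fewer than 2 contained RRIs are unlabelable and treated as
#' moderate; and an arrhythmia-labeled segment of a *healthy* subject is
#' reassigned to moderate (the rhythm evidence contradicts the subject
#' record, so the segment must not train either class).
#'
#' @param contained_rris Numeric vector of the segment's RRIs, ms.
#' @param table An `rri_range_table` with `range_class` (see
#'   [classify_rri_ranges()]).
#' @param subject_class `"healthy"` or `"arrhythmia"`.
#' @return `"normal"`, `"moderate"` or `"arrhythmia"`.
#' @export
label_segment <- function(contained_rris, table, subject_class) {
  if (is.null(table$range_class))
    stop("run classify_rri_ranges() first", call. = FALSE)
  if (length(contained_rris) < 2L) return("moderate")
  bc <- bin_class_of_(contained_rris, table)
  lab <- if (any(bc == "A")) "arrhythmia"
         else if (any(bc %in% c("M", "unobserved"))) "moderate"
         else "normal"
  if (lab == "arrhythmia" && subject_class == "healthy") lab <- "moderate"
  lab
}

#' Label every segment of a segment set
#'
#' @param set A `segment_set`.
#' @param table A classified `rri_range_table`.
#' @return Factor of labels (normal/moderate/arrhythmia), one per segment.
#' @export
label_segments <- function(set, table) {
  stopifnot(inherits(set, "segment_set"))
  labs <- mapply(label_segment, set$rris, set$meta$subject_class,
                 MoreArgs = list(table = table))
  factor(labs, levels = c("normal", "moderate", "arrhythmia"))
}

#' Simple labeling baseline
#'
#' Every segment of an arrhythmia subject is labeled arrhythmia, every
#' segment of a healthy subject normal — the baseline the histogram-based
#' labeling is measured against.
#'
#' @param set A `segment_set`.
#' @return Factor of labels.
#' @export
label_segments_simple <- function(set) {
  stopifnot(inherits(set, "segment_set"))
  labs <- ifelse(set$meta$subject_class == "arrhythmia", "arrhythmia",
                 "normal")
  factor(labs, levels = c("normal", "moderate", "arrhythmia"))
}

#' Per-subject moderate band (mean +/- y * SD)
#'
#' The band `[mean - y*sd, mean + y*sd]` of a subject's own RRIs
#' (population SD); intervals inside the band are moderate, all others
#' arrhythmic, in the per-subject labeling variant.
#'
#' @param rris The subject's `rri_series` (>= 2 intervals).
#' @param y Positive band half-width multiplier.
#' @return A `subject_band`: list with `subject_id`, `moderate_min`,
#'   `moderate_max`, `y`.
#' @export
subject_band <- function(rris, y) {
  stopifnot(inherits(rris, "rri_series"))
  if (length(rris$intervals) < 2L) stop("need >= 2 RRIs", call. = FALSE)
  if (!is.numeric(y) || y < 0) stop("y must be non-negative", call. = FALSE)
  m <- mean(rris$intervals)
  s <- pop_sd_(rris$intervals)
  structure(list(subject_id = rris$subject_id,
                 moderate_min = m - y * s, moderate_max = m + y * s, y = y),
            class = "subject_band")
}

pop_sd_ <- function(x) sqrt(mean((x - mean(x))^2))

#' Calibrate the band multiplier y to a target moderate fraction
#'
#' Smallest `y` (bisection to `tol`) such that at least
#' `target_moderate_fraction` of the subject's RRIs lie within
#' `mean +/- y * SD`. With all intervals identical the target is already
#' met at `y = 0` (a warning notes the degenerate case).
#'
#' @param rris The subject's `rri_series`.
#' @param target_moderate_fraction One of 0.5, 0.6, 0.7, 0.8, 0.9 (other
#'   values in (0, 1] are accepted).
#' @param tol Bisection tolerance on y.
#' @return Numeric `y`.
#' @export
calibrate_y <- function(rris, target_moderate_fraction, tol = 1e-4) {
  stopifnot(inherits(rris, "rri_series"))
  tf <- target_moderate_fraction
  if (!is.numeric(tf) || tf <= 0 || tf > 1)
    stop("target_moderate_fraction must lie in (0, 1]", call. = FALSE)
  v <- rris$intervals
  s <- pop_sd_(v)
  if (s == 0) {
    warning("all RRIs identical; y = 0 already makes every interval moderate")
    return(0)
  }
  frac <- function(y) {
    b <- subject_band(rris, y)
    mean(v >= b$moderate_min & v <= b$moderate_max)
  }
  lo <- 0; hi <- 1
  while (frac(hi) < tf) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (frac(mid) >= tf) hi <- mid else lo <- mid
  }
  hi
}

#' Label a segment with the per-subject band variant
#'
#' Segments of healthy subjects are always normal. For arrhythmia
#' subjects, a segment is arrhythmic when any contained RRI falls outside
#' the subject's moderate band, moderate otherwise (segments with < 2
#' contained RRIs are moderate).
#'
#' @param contained_rris Numeric vector of the segment's RRIs, ms.
#' @param band A `subject_band`.
#' @param subject_class `"healthy"` or `"arrhythmia"`.
#' @return `"normal"`, `"moderate"` or `"arrhythmia"`.
#' @export
label_segment_per_subject <- function(contained_rris, band, subject_class) {
  if (subject_class == "healthy") return("normal")
  if (length(contained_rris) < 2L) return("moderate")
  outside <- contained_rris < band$moderate_min |
    contained_rris > band$moderate_max
  if (any(outside)) "arrhythmia" else "moderate"
}

#' Label every segment with the per-subject band variant
#'
#' Bands are calibrated per arrhythmia subject with [calibrate_y()] at
#' `moderate_fraction`; healthy subjects bypass to normal.
#'
#' @param set A `segment_set` (possibly multiple subjects).
#' @param subject_rris Named list of `rri_series` keyed by subject_id.
#' @param moderate_fraction Target moderate fraction for [calibrate_y()].
#' @return Factor of labels.
#' @export
label_segments_per_subject <- function(set, subject_rris,
                                       moderate_fraction = 0.5) {
  stopifnot(inherits(set, "segment_set"))
  bands <- list()
  labs <- character(nrow(set$meta))
  for (i in seq_len(nrow(set$meta))) {
    sid <- set$meta$subject_id[i]
    cls <- set$meta$subject_class[i]
    if (cls == "arrhythmia" && is.null(bands[[sid]])) {
      y <- calibrate_y(subject_rris[[sid]], moderate_fraction)
      bands[[sid]] <- subject_band(subject_rris[[sid]], y)
    }
    labs[i] <- label_segment_per_subject(set$rris[[i]], bands[[sid]], cls)
  }
  factor(labs, levels = c("normal", "moderate", "arrhythmia"))
}

#' Bundled reference RRI-range ratio table
#'
#' The published pooled 25 ms RRI-range ratios of the public non-invasive
#' fetal-arrhythmia cohort (nifeadb, 14 healthy / 12 arrhythmia subjects),
#' with the expected A/M/N classification at each ratio threshold
#' x in {0.50, 0.60, 0.63, 0.65, 0.70}; useful for diffing
#' [classify_rri_ranges()] output against the reference.
#'
#' @return Data frame with `lo`, `hi`, `ratio` and one `x_*` column per
#'   threshold.
#' @export
reference_rri_ranges <- function() {
  p <- system.file("extdata", "nifeadb_rri_ranges.tsv", package = "fetalarr",
                   mustWork = TRUE)
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Classify a printed ratio column at several thresholds
#'
#' Reconstructs an A/M/N table from pre-computed per-bin ratios (no counts
#' needed): for each `x`, bins are `N` if ratio > 1, `A` if ratio < x,
#' else `M`.
#'
#' @param lo,hi Bin edges, ms.
#' @param ratio Per-bin healthy/arrhythmia count ratio.
#' @param x_grid Thresholds to classify at.
#' @return Data frame `lo`, `hi`, `ratio`, plus a factor column `x_<value>`
#'   per threshold.
#' @export
classify_ratio_column <- function(lo, hi, ratio,
                                  x_grid = c(0.50, 0.60, 0.63, 0.65, 0.70)) {
  tab <- data.frame(lo = lo, hi = hi, healthy_count = NA_integer_,
                    arrhythmia_count = NA_integer_, ratio = ratio)
  class(tab) <- c("rri_range_table", "data.frame")
  out <- data.frame(lo = lo, hi = hi, ratio = ratio)
  for (x in x_grid) {
    cls <- rep("M", length(ratio))
    cls[ratio > 1] <- "N"
    cls[ratio < x] <- "A"
    out[[sprintf("x_%.2f", x)]] <- cls
  }
  out
}

#' Write an RRI range table as TSV
#'
#' Emits the bin range, counts, ratio and the class at each threshold in a
#' layout suitable for direct diffing against published range tables.
#'
#' @param table An `rri_range_table`.
#' @param path Output TSV path.
#' @param x_grid Thresholds to classify at.
#' @return Invisibly, the written data frame.
#' @export
write_rri_range_tsv <- function(table, path,
                                x_grid = c(0.50, 0.60, 0.63, 0.65, 0.70)) {
  stopifnot(inherits(table, "rri_range_table"))
  out <- classify_ratio_column(table$lo, table$hi, table$ratio, x_grid)
  out <- cbind(out[, c("lo", "hi")],
               healthy_count = table$healthy_count,
               arrhythmia_count = table$arrhythmia_count,
               out[, -(1:2)])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
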