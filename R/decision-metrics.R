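## Subject-level decisions from segment predictions, the
## specificity/recall/accuracy formulas, threshold sweeps, and
## leave-one-subject-out evaluation with per-fold relabeling.

#' Arrhythmia-segment ratio (binary method)
#'
#' Fraction of a subject's segments the classifier calls arrhythmia, over
#' *all* segments (labels are a training device; at inference every
#' segment receives a binary prediction).
#'
#' @param predicted Factor/character of per-segment predictions.
#' @return Ratio in \[0, 1\].
#' @export
subject_ratio_binary <- function(predicted) {
  predicted <- as.character(predicted)
  if (!length(predicted)) stop("no segment predictions", call. = FALSE)
  mean(predicted == "arrhythmia")
}

#' Arrhythmia-to-(arrhythmia+normal) ratio (ternary method)
#'
#' `ARR / (ARR + NR)`: segments the ternary classifier calls moderate are
#' excluded from the denominator. When no segment is called arrhythmia or
#' normal the ratio is undefined; `NA` is returned with a warning and the
#' subject should default to healthy.
#'
#' @param predicted Factor/character of per-segment ternary predictions.
#' @return Ratio in \[0, 1\], or `NA` if undefined.
#' @export
subject_ratio_ternary <- function(predicted) {
  predicted <- as.character(predicted)
  if (!length(predicted)) stop("no segment predictions", call. = FALSE)
  arr <- sum(predicted == "arrhythmia")
  nr <- sum(predicted == "normal")
  if (arr + nr == 0L) {
    warning("all segments classified moderate; ratio undefined")
    return(NA_real_)
  }
  arr / (arr + nr)
}

#' Subject decision from the arrhythmia ratio
#'
#' Strictly greater than `th` means arrhythmia; ties and undefined (`NA`)
#' ratios give healthy.
#'
#' @param ratio Arrhythmia-segment ratio.
#' @param th Decision threshold in \[0, 1\].
#' @return `"healthy"` or `"arrhythmia"`.
#' @export
classify_subject <- function(ratio, th) {
  if (!is.numeric(th) || th < 0 || th > 1)
    stop("th must lie in [0, 1]", call. = FALSE)
  if (is.na(ratio)) return("healthy")
  if (ratio > th) "arrhythmia" else "healthy"
}

#' Confusion counts over subject decisions
#'
#' @param predicted,truth Character vectors over
#'   `{healthy, arrhythmia}`; arrhythmia is the positive class.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  list(TP = sum(predicted == "arrhythmia" & truth == "arrhythmia"),
       TN = sum(predicted == "healthy" & truth == "healthy"),
       FP = sum(predicted == "arrhythmia" & truth == "healthy"),
       FN = sum(predicted == "healthy" & truth == "arrhythmia"))
}

#' Specificity, recall and accuracy
#'
#' `specificity = TN / (TN + FP)`, `recall = TP / (TP + FN)`,
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`. A zero denominator yields
#' `NA` for that metric (flagged, not silently zeroed).
#'
#' @param decisions Data frame with columns `predicted` and `true_class`,
#'   or a list of confusion counts from [confusion_counts()].
#' @return List with `specificity`, `recall`, `accuracy`, `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
compute_metrics <- function(decisions) {
  cc <- if (is.data.frame(decisions)) {
    if (any(!decisions$true_class %in% c("healthy", "arrhythmia")))
      stop("every decision needs a known true class", call. = FALSE)
    confusion_counts(decisions$predicted, decisions$true_class)
  } else decisions
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  with(cc, list(
    specificity = div(TN, TN + FP),
    recall = div(TP, TP + FN),
    accuracy = div(TP + TN, TP + FP + TN + FN),
    TP = TP, TN = TN, FP = FP, FN = FN))
}

#' Sweep the subject-decision threshold
#'
#' @param ratios Data frame with `subject_id`, `ratio`, `true_class`.
#' @param th_grid Thresholds (default 0.00 to 1.00 by 0.05).
#' @return Data frame with one row per threshold: th, specificity, recall,
#'   accuracy, TP, TN, FP, FN, n_arrhythmia_calls.
#' @export
sweep_thresholds <- function(ratios, th_grid = seq(0, 1, by = 0.05)) {
  rows <- lapply(th_grid, function(th) {
    pred <- vapply(ratios$ratio, classify_subject, character(1), th = th)
    m <- compute_metrics(data.frame(predicted = pred,
                                    true_class = ratios$true_class))
    data.frame(th = th, specificity = m$specificity, recall = m$recall,
               accuracy = m$accuracy, TP = m$TP, TN = m$TN, FP = m$FP,
               FN = m$FN, n_arrhythmia_calls = sum(pred == "arrhythmia"))
  })
  do.call(rbind, rows)
}

## label a training segment_set according to the requested mode
label_for_mode_ <- function(set, mode, rris_by_subject, x, moderate_fraction) {
  switch(mode,
    histogram = {
      tab <- build_rri_histogram(unname(rris_by_subject))
      tab <- classify_rri_ranges(tab, x)
      label_segments(set, tab)
    },
    simple = label_segments_simple(set),
    per_subject = label_segments_per_subject(set, rris_by_subject,
                                             moderate_fraction),
    stop("unknown labeling mode: ", mode, call. = FALSE))
}

#' Leave-one-subject-out evaluation
#'
#' For each held-out subject the RRI range table (or per-subject bands)
#' and all training labels are rebuilt from the remaining subjects only,
#' the CNN is trained on those labels, the held-out subject's segments are
#' classified, and the arrhythmia ratio computed — so nothing derived from
#' the held-out subject ever touches its fold's training. Decisions are
#' then swept over `th_grid` on the per-fold ratios.
#'
#' @param extracted Named list (by subject id), each element holding
#'   `segset` (a `segment_set`), `rris` (`rri_series`) and `true_class`
#'   (as produced by [extract_cohort()]).
#' @param x Ratio threshold for histogram labeling.
#' @param th_grid Subject-decision thresholds to sweep.
#' @param config A [cnn_config()]; `n_classes` is forced to match the
#'   mode.
#' @param mode `"histogram"`, `"simple"` (both binary) or `"per_subject"`
#'   (ternary).
#' @param moderate_fraction Target moderate fraction for the per-subject
#'   mode.
#' @return List with `ratios` (per-subject data frame) and `metrics`
#'   (threshold sweep data frame).
#' @export
loso_evaluate <- function(extracted, x = 0.63,
                          th_grid = seq(0, 1, by = 0.05),
                          config = cnn_config(),
                          mode = c("histogram", "simple", "per_subject"),
                          moderate_fraction = 0.5) {
  mode <- match.arg(mode)
  ids <- names(extracted)
  stopifnot(length(ids) >= 2L)
  cls <- vapply(extracted, `[[`, character(1), "true_class")
  if (length(unique(cls)) < 2L)
    stop("need both classes in the cohort", call. = FALSE)
  config$n_classes <- if (mode == "per_subject") 3L else 2L
  train_mode <- if (mode == "per_subject") "ternary" else "binary"
  rows <- list()
  for (held in ids) {
    tr_ids <- setdiff(ids, held)
    if (length(unique(cls[tr_ids])) < 2L) {
      warning("fold ", held, " skipped: a training class is empty")
      next
    }
    tr_set <- bind_segment_sets(lapply(extracted[tr_ids], `[[`, "segset"))
    tr_rris <- lapply(extracted[tr_ids], `[[`, "rris")
    labs <- label_for_mode_(tr_set, mode, tr_rris, x, moderate_fraction)
    ts <- build_training_set(tr_set, labs, mode = train_mode)
    model <- train_cnn(config, ts$X, ts$y, levels = ts$levels,
                       class_weights = ts$class_weights)
    pred <- predict_cnn(model, extracted[[held]]$segset)
    ratio <- if (mode == "per_subject")
      subject_ratio_ternary(pred$predicted)
    else subject_ratio_binary(pred$predicted)
    rows[[held]] <- data.frame(subject_id = held, ratio = ratio,
                               n_segments = nrow(pred),
                               true_class = cls[[held]],
                               stringsAsFactors = FALSE)
  }
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  list(ratios = ratios, metrics = sweep_thresholds(ratios, th_grid))
}

#' Extract segments and RRIs for every record of a cohort
#'
#' Runs [extract_fecg()] and [segment_signal()] on each record.
#'
#' @param records List of `aecg_record`s.
#' @param window_s,step_s Segmentation parameters.
#' @return Named list keyed by subject id; each element has `segset`,
#'   `rris`, `fpeaks`, `true_class`.
#' @export
extract_cohort <- function(records, window_s = 3, step_s = 1) {
  out <- lapply(records, function(rec) {
    ex <- extract_fecg(rec)
    segset <- segment_signal(ex$fecg, ex$rris, window_s, step_s)
    list(segset = segset, rris = ex$rris, fpeaks = ex$fpeaks,
         true_class = rec$true_class)
  })
  names(out) <- vapply(records, `[[`, character(1), "subject_id")
  out
}
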