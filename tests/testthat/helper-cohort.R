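# Shared fixtures, built once per test run and memoized.

.fa_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fa_cache[[key]])) .fa_cache[[key]] <- force(expr)
  .fa_cache[[key]]
}

# small mixed cohort exercising the full extraction chain
tiny_records <- function() memo("tiny_records", {
  spec <- nifeadb_like_cohort(n_healthy = 2, n_arrhythmia = 2,
                              duration = 60, seed = 11)
  simulate_cohort(spec)
})

tiny_extracted <- function() memo("tiny_extracted", {
  extract_cohort(tiny_records())
})

# study-scale cohort shared by the acceptance checks (26 subjects, 60 s)
study_spec <- function() memo("study_spec", nifeadb_like_cohort(duration = 60,
                                                               seed = 1))

study_records <- function() memo("study_records", simulate_cohort(study_spec()))

study_extracted <- function() memo("study_extracted",
                                   extract_cohort(study_records()))

# ground-truth per-subject interval stats from the simulator sidecars
ground_truth_stats <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
    iv <- diff(rec$meta$rpeaks_ms)
    data.frame(subject_id = rec$subject_id, true_class = rec$true_class,
               gt_mean = mean(iv), gt_sd = stats::sd(iv),
               stringsAsFactors = FALSE)
  }))
}
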