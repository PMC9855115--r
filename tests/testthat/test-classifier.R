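# toy separable inputs: clean impulse trains at 400 ms vs 600 ms periods,
# cut into 3 s windows
toy_segments <- function(n_per_class = 40) {
  memo("toy_segments", {
    build <- function(period, cls, n) {
      rr <- rri_series(rep(period, ceiling(n * 1500 / (period / 2))),
                       subject_id = paste0("toy", period), true_class = cls)
      fe <- synthesize_fecg(rr, fs = 500, noise_sd = 0.01, seed = period)
      seg <- segment_signal(fe$fecg, rr)
      subset_segments(seg, seq_len(n))
    }
    segs <- bind_segment_sets(list(build(400, "healthy", n_per_class),
                                   build(600, "arrhythmia", n_per_class)))
    labs <- label_segments_simple(segs)
    list(segs = segs, labs = labs)
  })
}

test_that("training-set assembly drops moderate segments in binary mode only", {
  set.seed(1)
  fake <- structure(list(samples = matrix(rnorm(22 * 1500), 22, 1500),
                         meta = data.frame(subject_id = "s",
                                           start_ms = seq_len(22) * 1000,
                                           n_rri = 4,
                                           subject_class = "arrhythmia"),
                         rris = replicate(22, c(400, 400), simplify = FALSE)),
                    class = "segment_set")
  labs <- factor(rep(c("normal", "moderate", "arrhythmia"), c(10, 5, 7)),
                 levels = c("normal", "moderate", "arrhythmia"))
  bin <- build_training_set(fake, labs, "binary")
  expect_identical(nrow(bin$X), 17L)
  expect_identical(sort(unique(bin$y)), c(1L, 2L))
  expect_false("moderate" %in% bin$levels)
  ter <- build_training_set(fake, labs, "ternary")
  expect_identical(nrow(ter$X), 22L)
  expect_identical(ter$levels, c("normal", "moderate", "arrhythmia"))
  # inverse-frequency weights
  expect_equal(bin$class_weights, 17 / (2 * c(10, 7)))
  # missing retained class errors
  labs2 <- factor(rep("normal", 22), levels = levels(labs))
  expect_error(build_training_set(fake, labs2, "binary"), "zero segments")
})

test_that("z-scoring normalizes rows and guards constant segments", {
  X <- rbind(c(1, 2, 3, 4), rep(7, 4))
  Z <- zscore_rows(X)
  expect_equal(mean(Z[1, ]), 0)
  expect_equal(sqrt(mean(Z[1, ]^2)), 1)
  expect_equal(Z[2, ], rep(0, 4))
})

test_that("the CNN separates clean rhythm classes and its loss decreases", {
  toy <- toy_segments()
  ts <- build_training_set(toy$segs, toy$labs, "binary")
  cfg <- cnn_config(seed = 3, epochs = 8, batch = 16)
  m <- train_cnn(cfg, ts$X, ts$y, ts$levels, ts$class_weights)
  expect_gte(tail(m$log$accuracy, 1), 0.99)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
  pred <- predict_cnn(m, toy$segs)
  expect_gte(mean(pred$predicted == ifelse(toy$labs == "arrhythmia",
                                           "arrhythmia", "normal")), 0.99)
  .fa_cache$toy_model <- m
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_segments()
  ts <- build_training_set(toy$segs, toy$labs, "binary")
  cfg <- cnn_config(seed = 9, epochs = 2, batch = 16)
  m1 <- train_cnn(cfg, ts$X, ts$y, ts$levels)
  m2 <- train_cnn(cfg, ts$X, ts$y, ts$levels)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$par$W1, m2$par$W1)
})

test_that("prediction contracts: scores sum to 1, shape checked, metadata inert", {
  m <- .fa_cache$toy_model
  toy <- toy_segments()
  pred <- predict_cnn(m, toy$segs)
  sums <- rowSums(pred[, paste0("score_", m$levels)])
  expect_equal(sums, rep(1, nrow(pred)), tolerance = 1e-12)
  # metadata does not affect scores: feed the bare matrix
  pred2 <- predict_cnn(m, toy$segs$samples)
  expect_equal(pred2$score_normal, pred$score_normal)
  expect_error(predict_cnn(m, matrix(0, 2, 100)), "1500")
  expect_error(train_cnn(cnn_config(), matrix(0, 3, 1500), rep(1L, 3)),
               "single class")
})

test_that("held-out segment classification beats the majority baseline", {
  ex <- study_extracted()
  rris <- lapply(ex, `[[`, "rris")
  test_ids <- c("h03", "h11", "a04", "a07", "a09", "a12")
  tr_ids <- setdiff(names(ex), test_ids)
  tr_set <- bind_segment_sets(lapply(ex[tr_ids], `[[`, "segset"))
  tr_tab <- classify_rri_ranges(build_rri_histogram(unname(rris[tr_ids])),
                                0.63)
  ts <- build_training_set(tr_set, label_segments(tr_set, tr_tab), "binary")
  m <- train_cnn(cnn_config(seed = 2), ts$X, ts$y, ts$levels,
                 ts$class_weights)
  te_set <- bind_segment_sets(lapply(ex[test_ids], `[[`, "segset"))
  te_tab <- classify_rri_ranges(build_rri_histogram(unname(rris)), 0.63)
  te_labs <- label_segments(te_set, te_tab)
  keep <- te_labs != "moderate"
  truth <- ifelse(te_labs[keep] == "arrhythmia", "arrhythmia", "normal")
  pred <- predict_cnn(m, subset_segments(te_set, keep))$predicted
  # balanced accuracy: the majority-class baseline scores 0.5 regardless of
  # the normal/arrhythmia imbalance; require a >= 20-point margin
  tpr <- mean(pred[truth == "arrhythmia"] == "arrhythmia")
  tnr <- mean(pred[truth == "normal"] == "normal")
  expect_gte((tpr + tnr) / 2, 0.70)
})

test_that("models round-trip through the checkpoint files", {
  m <- .fa_cache$toy_model
  d <- withr::local_tempdir()
  base <- file.path(d, "model")
  save_cnn(m, base)
  m2 <- load_cnn(base)
  expect_identical(m2$par, m$par)
  expect_true(file.exists(paste0(base, "_config.json")))
  expect_identical(nrow(read.csv(paste0(base, "_log.csv"))), nrow(m$log))
})
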