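ref_tab <- reference_rri_ranges()

# range table rebuilt from the published ratio column: ratios are printed
# to 4 decimals, so counts of (ratio*10000, 10000) reproduce them exactly
ref_as_table <- function() {
  tab <- data.frame(lo = ref_tab$lo, hi = ref_tab$hi,
                    healthy_count = as.integer(round(ref_tab$ratio * 10000)),
                    arrhythmia_count = 10000L)
  tab$ratio <- tab$healthy_count / tab$arrhythmia_count
  class(tab) <- c("rri_range_table", "data.frame")
  tab
}

test_that("histogram pooling counts per class and forms ratios", {
  h <- rri_series(c(401, 410), subject_id = "h", true_class = "healthy")
  a <- rri_series(c(405, 560), subject_id = "a", true_class = "arrhythmia")
  tab <- build_rri_histogram(list(h, a))
  b400 <- tab[tab$lo == 400, ]
  expect_identical(b400$healthy_count, 2L)
  expect_identical(b400$arrhythmia_count, 1L)
  expect_equal(b400$ratio, 2)
  b550 <- tab[tab$lo == 550, ]
  expect_identical(c(b550$healthy_count, b550$arrhythmia_count), c(0L, 1L))
  expect_equal(b550$ratio, 0)
  # healthy-only bin has infinite ratio and classifies normal
  h2 <- rri_series(c(390, 391), subject_id = "h2", true_class = "healthy")
  tab2 <- classify_rri_ranges(build_rri_histogram(list(h2, a)), 0.63)
  expect_true(is.infinite(tab2$ratio[tab2$lo == 375]))
  expect_identical(as.character(tab2$range_class[tab2$lo == 375]), "N")
  expect_error(build_rri_histogram(list()), "empty")
})

test_that("range classification reproduces the published A/M/N cells at every threshold", {
  tab <- ref_as_table()
  for (x in c(0.50, 0.60, 0.63, 0.65, 0.70)) {
    got <- as.character(classify_rri_ranges(tab, x)$range_class)
    expected <- ref_tab[[sprintf("x_%.2f", x)]]
    expect_identical(got, expected, label = sprintf("x = %.2f", x))
  }
})

test_that("a ratio exactly at the threshold stays moderate (strict inequality)", {
  tab <- ref_as_table()
  r5 <- classify_rri_ranges(tab, 0.50)
  expect_identical(as.character(r5$range_class[r5$lo == 850]), "M")
  r6 <- classify_rri_ranges(tab, 0.60)
  expect_identical(as.character(r6$range_class[r6$lo == 850]), "A")
  # borderline row 450-475 flips between x = 0.63 and 0.65
  expect_identical(as.character(
    classify_rri_ranges(tab, 0.63)$range_class[tab$lo == 450]), "M")
  expect_identical(as.character(
    classify_rri_ranges(tab, 0.65)$range_class[tab$lo == 450]), "A")
  expect_error(classify_rri_ranges(tab, 0), "0, 1")
  expect_error(classify_rri_ranges(tab, 1.2), "0, 1")
})

test_that("the arrhythmic bin set is non-decreasing in x", {
  tab <- ref_as_table()
  grid <- c(0.50, 0.60, 0.63, 0.65, 0.70)
  prev <- NULL
  for (x in grid) {
    a_set <- which(classify_rri_ranges(tab, x)$range_class == "A")
    if (!is.null(prev)) expect_true(all(prev %in% a_set))
    prev <- a_set
  }
})

test_that("segment labels follow precedence A > M > N with healthy reassignment", {
  tab <- classify_rri_ranges(ref_as_table(), 0.63)
  n_rris <- c(390, 410)                 # both in N bins
  m_rri <- 460                          # M bin at x = 0.63
  a_rri <- 510                          # A bin
  expect_identical(label_segment(n_rris, tab, "healthy"), "normal")
  expect_identical(label_segment(c(n_rris, m_rri), tab, "arrhythmia"),
                   "moderate")
  expect_identical(label_segment(c(n_rris, a_rri), tab, "arrhythmia"),
                   "arrhythmia")
  # arrhythmia-looking segment of a healthy subject is reassigned moderate
  expect_identical(label_segment(c(n_rris, a_rri), tab, "healthy"),
                   "moderate")
  # fewer than 2 intervals -> unlabelable -> moderate
  expect_identical(label_segment(400, tab, "arrhythmia"), "moderate")
  # interval outside the table support -> moderate
  expect_identical(label_segment(c(390, 950), tab, "arrhythmia"), "moderate")
})

test_that("adding an arrhythmic RRI never makes a segment more normal", {
  tab <- classify_rri_ranges(ref_as_table(), 0.63)
  rank <- c(normal = 1, moderate = 2, arrhythmia = 3)
  set.seed(8)
  for (i in 1:25) {
    rris <- runif(sample(2:6, 1), 350, 470)
    for (cls in c("healthy", "arrhythmia")) {
      base <- label_segment(rris, tab, cls)
      more <- label_segment(c(rris, 510), tab, cls)
      expect_gte(rank[more], rank[base])
    }
  }
})

test_that("per-subject bands implement mean +/- y * SD with population SD", {
  v <- c(350, 450, 350, 450)            # mean 400, population SD 50
  rr <- rri_series(v, subject_id = "b", true_class = "arrhythmia")
  b <- subject_band(rr, 1)
  expect_equal(b$moderate_min, 350)
  expect_equal(b$moderate_max, 450)
  # huge y makes everything moderate
  b9 <- subject_band(rr, 100)
  expect_identical(label_segment_per_subject(v, b9, "arrhythmia"), "moderate")
  # an interval just outside the band flips the segment to arrhythmia
  expect_identical(label_segment_per_subject(c(v, 451), b, "arrhythmia"),
                   "arrhythmia")
  expect_identical(label_segment_per_subject(c(v, 451), b, "healthy"),
                   "normal")
})

test_that("calibrate_y matches the normal-quantile oracle and is monotone", {
  set.seed(2)
  v <- rnorm(4000, 400, 30)
  rr <- rri_series(v, subject_id = "c", true_class = "arrhythmia")
  y68 <- calibrate_y(rr, 0.683)
  expect_lt(abs(y68 - 1), 0.08)         # ~68.3% of a normal lies within 1 SD
  y50 <- calibrate_y(rr, 0.5)
  expect_lt(abs(y50 - qnorm(0.75)), 0.08)
  # moderate fraction is non-decreasing in y
  fr <- vapply(c(0.2, 0.5, 1, 1.5, 2), function(y) {
    b <- subject_band(rr, y)
    mean(v >= b$moderate_min & v <= b$moderate_max)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
  # each target is met tightly: achieved fraction >= target
  for (tf in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    y <- calibrate_y(rr, tf)
    b <- subject_band(rr, y)
    got <- mean(v >= b$moderate_min & v <= b$moderate_max)
    expect_gte(got, tf)
    expect_lt(got, tf + 0.02)
  }
  rc <- rri_series(rep(400, 50), subject_id = "k", true_class = "arrhythmia")
  expect_warning(y0 <- calibrate_y(rc, 0.5), "identical")
  expect_identical(y0, 0)
})

test_that("a nifeadb-like cohort gives a healthy-dominated 375-400 ms bin", {
  spec <- nifeadb_like_cohort(duration = 60, seed = 19)
  rris <- lapply(spec$subjects, generate_rri_sequence)
  tab <- build_rri_histogram(rris)
  expect_gt(tab$ratio[tab$lo == 375], 1)
  expect_gt(tab$ratio[tab$lo == 400], 1)
})

test_that("simple labeling maps subject class straight onto segments", {
  ex <- tiny_extracted()
  segs <- bind_segment_sets(lapply(ex, `[[`, "segset"))
  labs <- label_segments_simple(segs)
  expect_true(all(labs[segs$meta$subject_class == "healthy"] == "normal"))
  expect_true(all(labs[segs$meta$subject_class == "arrhythmia"] ==
                    "arrhythmia"))
})

test_that("range-table TSV export mirrors the published layout", {
  d <- withr::local_tempdir()
  tab <- ref_as_table()
  p <- file.path(d, "ranges.tsv")
  write_rri_range_tsv(tab, p)
  back <- read.delim(p)
  expect_identical(back$x_0.50, ref_tab$x_0.50)
  expect_identical(back$x_0.70, ref_tab$x_0.70)
})
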