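make_seq <- function(labels, classes, tnames = c("C+", "E-", "A+"),
                     starts = seq(0, by = 0.025, length.out = ncol(labels))) {
  label_sequence(labels, starts, classes, tnames)
}

test_that("occurrence frequency is the count-over-trials ratio", {
  # 3 trials, one window, labels {C+, C+, E-}
  sq <- make_seq(matrix(c(0L, 0L, 1L), 3, 1), rep("target", 3)) %>%
    suppressWarnings()
  fm <- occurrence_frequency(sq, by_class = FALSE)
  expect_equal(fm$freq[fm$template == "C+"], 2 / 3)
  expect_equal(fm$freq[fm$template == "E-"], 1 / 3)
  expect_equal(fm$freq[fm$template == "A+"], 0)

  # single trial: every column one-hot; sentinel-free columns sum to 1
  sq1 <- make_seq(matrix(c(2L, 1L, 0L), 1, 3), "target") %>% suppressWarnings()
  fm1 <- occurrence_frequency(sq1, by_class = FALSE)
  sums <- fm1 %>% dplyr::group_by(time) %>% dplyr::summarise(s = sum(freq))
  expect_equal(sums$s, rep(1, 3))
})

test_that("frequency differences are elementwise and antisymmetric", {
  ses <- quick_session(seed = 13, n_standard = 10, n_target = 10, noise_sd_uv = 1)
  sq <- label_epochs(ses$epochs, expand_polarity(ses$config$template_set),
                     window_spec(0, 0.4, 0.05, 0.025))
  fm <- occurrence_frequency(sq)
  d1 <- frequency_difference(fm)
  d2 <- frequency_difference(fm, positive = "standard", negative = "target")
  expect_equal(d1$diff, -d2$diff, tolerance = 1e-12)
  expect_equal(frequency_difference(fm, fm)$diff, rep(0, nrow(fm)))
  # planted boost: C+ more frequent for targets in 0-200 ms
  ses0 <- quick_session(seed = 14, n_standard = 60, n_target = 60,
                        noise_sd_uv = 0, mean_segment_ms = 40)
  sq0 <- label_epochs(ses0$epochs, expand_polarity(ses0$config$template_set),
                      window_spec(0, 0.4, 0.05, 0.025))
  d0 <- frequency_difference(occurrence_frequency(sq0))
  cplus <- d0 %>% dplyr::filter(template == "C+", time >= 0.05, time < 0.15)
  expect_true(all(cplus$diff > 0))
})

test_that("one-hot averages equal occurrence frequencies and stay in [0,1]", {
  ses <- quick_session(seed = 15, n_standard = 8, n_target = 8, noise_sd_uv = 2)
  sq <- label_epochs(ses$epochs, expand_polarity(ses$config$template_set),
                     window_spec(0, 0.4, 0.05, 0.025))
  oh <- time_resolved_onehot(sq)
  fm <- occurrence_frequency(sq)
  for (cl in c("standard", "target")) {
    m <- oh[[cl]]
    expect_true(all(m >= 0 & m <= 1))
    fcl <- fm %>% dplyr::filter(class == cl) %>% dplyr::arrange(time, label)
    expect_equal(as.vector(m), fcl$freq, tolerance = 1e-12)
  }
  # single trial gives a one-hot time course
  one <- subset_trials(sq, 1)
  m1 <- time_resolved_onehot(one)[[one$classes[1]]]
  expect_true(all(colSums(m1) == 1) && all(m1 %in% c(0, 1)))
})

test_that("cluster permutation test finds planted clusters and nothing in null data", {
  # all-zero differences: no clusters at all
  z <- matrix(0, 8, 30)
  cl0 <- permutation_cluster_test(z, n_perm = 100, seed = 1)
  expect_equal(nrow(cl0), 0)
  expect_equal(attr(cl0, "n_excluded"), 30)

  # constant large difference over windows 10-20 (tiny per-participant
  # magnitude spread keeps the pointwise t finite), zero elsewhere
  D <- matrix(0, 12, 30)
  D[, 10:20] <- 1 + 0.01 * seq_len(12)
  cl <- permutation_cluster_test(D, n_perm = 500, seed = 2)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(10, 20))
  expect_equal(cl$p, 1 / 501)

  # permuting participant order leaves observed clusters identical
  clp <- permutation_cluster_test(D[sample(12), ], n_perm = 500, seed = 2)
  expect_equal(clp$start, cl$start)
  expect_equal(clp$end, cl$end)
  expect_equal(clp$mass, cl$mass, tolerance = 1e-10)
})

test_that("BH correction matches an independent step-up enumeration", {
  expect_equal(fdr_across_labels(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_across_labels(0.2), 0.2)
  expect_equal(fdr_across_labels(rep(1, 5)), rep(1, 5))
  set.seed(123)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(fdr_across_labels(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("label_cluster_stats flags the planted class effect with FDR control", {
  # participants = independent small sessions with the oddball target boost
  seqs <- lapply(1:6, function(s) {
    ses <- quick_session(seed = 100 + s, n_standard = 30, n_target = 30,
                         noise_sd_uv = 0, mean_segment_ms = 40)
    label_epochs(ses$epochs, expand_polarity(ses$config$template_set),
                 window_spec(0, 0.4, 0.05, 0.025))
  })
  res <- label_cluster_stats(seqs, n_perm = 200, seed = 5)
  expect_true(all(res$q >= res$p))
  expect_true(all(res$p >= 1 / 201 & res$p <= 1))
  # the C+ boost in 0-200 ms should surface as a significant cluster
  cplus <- res %>% dplyr::filter(template == "C+", q < 0.05, t_start < 0.2)
  expect_gte(nrow(cplus), 1)
})

test_that("prediction splits partition the trials", {
  ses <- quick_session(seed = 16, n_standard = 6, n_target = 6, noise_sd_uv = 1)
  sq <- label_epochs(ses$epochs, expand_polarity(ses$config$template_set),
                     window_spec(0, 0.4, 0.05, 0.025))
  pred <- c(rep("standard", 6), rep("standard", 3), rep("target", 3))
  sp <- split_by_prediction(sq, pred)
  expect_equal(nrow(sp$correct$labels) + nrow(sp$incorrect$labels), 12)
  expect_equal(nrow(sp$incorrect$labels), 3)
  all_right <- split_by_prediction(sq, sq$classes)
  expect_equal(nrow(all_right$incorrect$labels), 0)
  expect_error(split_by_prediction(sq, pred[-1]), "one non-missing prediction")
})
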