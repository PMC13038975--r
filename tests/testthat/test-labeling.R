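test_that("window enumeration reproduces the overlap arithmetic", {
  w1 <- window_spec(-0.2, 1.0, 0.100, 0.025)
  expect_equal((w1$length - w1$step) / w1$length, 0.75)
  w2 <- window_spec(0, 0.4, 0.010, 0.001)
  expect_equal((w2$length - w2$step) / w2$length, 0.90)
  expect_equal(nrow(make_windows(w2)), 391)
  # every window fits inside the span, half-open
  mw <- make_windows(w1)
  expect_true(all(mw$end <= 1.0 + 1e-12))
  expect_equal(mw$start[2] - mw$start[1], 0.025)
  expect_error(window_spec(0, 0.05, 0.1, 0.025), "no window fits")
})

test_that("window means are per-channel arithmetic means over half-open windows", {
  # two samples (0,2) and (2,0) -> (1,1)
  trial <- matrix(c(0, 2, 2, 0), nrow = 2)      # channels x samples
  expect_equal(window_mean_map(trial, c(0, 0.02), sfreq = 100, tmin = 0), c(1, 1))
  # singleton window returns the sample
  expect_equal(window_mean_map(trial, c(0.01, 0.02), sfreq = 100, tmin = 0), c(2, 0))
  # constant trial returns the constant vector
  const <- matrix(5, 3, 10)
  expect_equal(window_mean_map(const, c(0, 0.1), 100, 0), rep(5, 3))
  expect_error(window_mean_map(trial, c(0.5, 0.6), 100, 0), "outside the epoch")
})

test_that("winner-take-all labeling matches the exhaustive correlation oracle", {
  ts <- expand_polarity(tiny_templates(k = 5, nc = 32, seed = 12))
  base <- tiny_templates(k = 5, nc = 32, seed = 12)
  set.seed(99)
  for (i in 1:1000) {
    map <- rnorm(32)
    expect_identical(label_map(map, ts, polarity = TRUE)$label,
                     oracle_label(map, ts, TRUE))
    expect_identical(label_map(map, base, polarity = FALSE)$label,
                     oracle_label(map, base, FALSE))
  }
})

test_that("labeling is invariant to positive scaling and channel offsets", {
  ts <- expand_polarity(tiny_templates(k = 3, nc = 10, seed = 2))
  set.seed(5)
  for (i in 1:50) {
    map <- rnorm(10)
    ref <- label_map(map, ts)
    expect_equal(label_map(3.5 * map, ts), ref)
    expect_equal(label_map(map + 7, ts)$label, ref$label)
  }
  # self-match at correlation 1, and negation maps to the polarity partner
  expect_equal(label_map(3.5 * ts$maps[3, ], ts),
               list(label = 2L, correlation = 1), tolerance = 1e-12)
  expect_equal(label_map(-ts$maps[3, ], ts),
               list(label = 2L + ts$base_k, correlation = 1), tolerance = 1e-12)
})

test_that("signed winner agrees with the absolute winner plus the correlation sign", {
  base <- tiny_templates(k = 4, nc = 12, seed = 3)
  exp4 <- expand_polarity(base)
  set.seed(17)
  for (i in 1:200) {
    map <- rnorm(12)
    signed <- label_map(map, exp4, polarity = TRUE)$label
    r <- unname(apply(base$maps, 1, function(tm) stats::cor(map, tm)))
    unsigned <- which.max(abs(r)) - 1L
    expected <- if (r[unsigned + 1] >= 0) unsigned else unsigned + base$base_k
    expect_identical(signed, expected)
  }
})

test_that("noiseless epochs recover planted signed labels inside segments", {
  ses <- quick_session(seed = 4, n_standard = 10, n_target = 10, noise_sd_uv = 0)
  tsx <- expand_polarity(ses$config$template_set)
  spec <- window_spec(0, 0.4, 0.01, 0.005)
  sq <- label_epochs(ses$epochs, tsx, spec)
  win <- make_windows(spec)
  es <- ses$epochs
  n_checked <- 0
  for (tr in seq_len(nrow(sq$labels))) {
    for (w in seq_len(nrow(win))) {
      i0 <- round((win$start[w] - es$tmin) * es$sfreq) + 1
      i1 <- round((win$end[w] - es$tmin) * es$sfreq)
      seg <- es$ground_truth[tr, i0:i1]
      if (length(unique(seg)) == 1) {
        n_checked <- n_checked + 1
        expect_identical(sq$labels[tr, w], seg[1])
      }
    }
  }
  expect_gt(n_checked, 500)
})

test_that("polarity-ignored labeling is blind to sign flips of the data", {
  ses <- quick_session(seed = 6, n_standard = 5, n_target = 5, noise_sd_uv = 1)
  base <- ses$config$template_set
  es_flip <- ses$epochs
  es_flip$data <- -es_flip$data
  spec <- window_spec(0, 0.4, 0.05, 0.025)
  s1 <- label_epochs(ses$epochs, base, spec, polarity = FALSE)
  s2 <- label_epochs(es_flip, base, spec, polarity = FALSE)
  expect_identical(s1$labels, s2$labels)
  # 10 signed templates produce labels zero to nine
  sq <- label_epochs(ses$epochs, expand_polarity(base), spec)
  expect_true(all(sq$labels %in% 0:9))
  # mode mismatches are refused
  expect_error(label_epochs(ses$epochs, base, spec, polarity = TRUE),
               "polarity-expanded")
  expect_error(label_epochs(ses$epochs, expand_polarity(base), spec,
                            polarity = FALSE), "base")
})

test_that("balancing subsamples the majority class to the minority count", {
  ses <- quick_session(seed = 8, n_standard = 16, n_target = 5, noise_sd_uv = 1)
  bal <- balance_trials(ses$epochs, seed = 3)
  expect_equal(as.integer(table(bal$classes)), c(5L, 5L))
  # determinism and order preservation
  bal2 <- balance_trials(ses$epochs, seed = 3)
  expect_identical(bal$data, bal2$data)
  expect_identical(bal$classes, bal2$classes)
  # already-balanced input is returned unchanged
  sq <- label_epochs(balance_trials(ses$epochs, 1),
                     expand_polarity(ses$config$template_set),
                     window_spec(0, 0.4, 0.05, 0.025))
  expect_identical(balance_trials(sq, 9)$labels, sq$labels)
})
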