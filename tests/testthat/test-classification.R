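test_that("F1 follows the confusion-count formula", {
  expect_equal(f1_score(list(TP = 5, FP = 0, TN = 4, FN = 0)), 1)
  expect_equal(f1_score(list(TP = 2, FP = 1, TN = 0, FN = 1)), 2 / 3)
  expect_equal(f1_score(list(TP = 0, FP = 3, TN = 0, FN = 2)), 0)
  expect_warning(z <- f1_score(list(TP = 0, FP = 0, TN = 4, FN = 0)), "undefined")
  expect_equal(z, 0)
  # harmonic-mean identity on random counts
  set.seed(2)
  for (i in 1:30) {
    cc <- list(TP = sample(1:20, 1), FP = sample(0:20, 1),
               TN = sample(0:20, 1), FN = sample(0:20, 1))
    prec <- cc$TP / (cc$TP + cc$FP)
    rec <- cc$TP / (cc$TP + cc$FN)
    expect_equal(f1_score(cc), 2 * prec * rec / (prec + rec), tolerance = 1e-12)
  }
})

test_that("confusion counts take 'target' as the positive class", {
  truth <- c("target", "target", "standard", "standard")
  pred <- c("target", "standard", "target", "standard")
  cc <- confusion_counts(truth, pred)
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_equal(sum(unlist(cc)), 4)
})

test_that("AUC equals the brute-force pair count with half-weight ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1),
                         c("target", "target", "standard", "standard")), 1)
  expect_equal(auc_score(c(0.6, 0.2, 0.5, 0.1),
                         c("target", "target", "standard", "standard")), 0.75)
  expect_equal(auc_score(rep(0.4, 6), rep(c("target", "standard"), 3)), 0.5)
  expect_error(auc_score(1:3, rep("target", 3)), "both classes")
  set.seed(4)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    truth <- sample(c("standard", "target"), n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, TRUE)    # coarse grid to force ties
    expect_equal(auc_score(scores, truth), oracle_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("nested CV bookkeeping: stratified 20% outer folds covering every trial once", {
  set.seed(6)
  labels <- matrix(sample(0:9, 100 * 20, TRUE), 100, 20)
  sq <- label_sequence(labels, seq(0, by = 0.01, length.out = 20),
                       rep(c("standard", "target"), each = 50),
                       template_names = paste0("T", 1:10))
  fit <- nested_cv_classify(sq, "logistic_regression",
                            grid = list(lambda = c(0.1, 1)), seed = 3)
  expect_equal(sort(fit$predictions$trial), 1:100)
  expect_equal(as.integer(table(fit$predictions$fold)), rep(20L, 5))
  # stratification: each fold holds 10 of each class
  strat <- table(fit$predictions$fold, fit$predictions$class)
  expect_true(all(strat == 10))
  expect_equal(fit$folds$n_test, rep(20L, 5))
  expect_true(all(fit$folds$f1 >= 0 & fit$folds$f1 <= 1))
  expect_true(fit$auc >= 0 && fit$auc <= 1)
  # determinism given the seed
  fit2 <- nested_cv_classify(sq, "logistic_regression",
                             grid = list(lambda = c(0.1, 1)), seed = 3)
  expect_equal(fit$predictions, fit2$predictions)
  # tidy/glance accessors
  expect_equal(nrow(tidy(fit)), 5)
  expect_equal(glance(fit)$mean_f1, fit$mean_f1)
})

test_that("a strong planted class effect is perfectly separable", {
  # classes live on disjoint label blocks in every window
  labels <- rbind(matrix(0:1, 20, 12), matrix(8:9, 20, 12))
  sq <- label_sequence(labels, seq(0, by = 0.025, length.out = 12),
                       rep(c("standard", "target"), each = 20),
                       template_names = paste0("T", 1:10))
  for (fam in c("random_forest", "svm", "xgboost")) {
    fit <- nested_cv_classify(sq, fam, grid = lapply(default_grid(fam), `[`, 1),
                              seed = 2)
    expect_equal(fit$mean_f1, 1, tolerance = 1e-12)
    expect_equal(fit$auc, 1, tolerance = 1e-12)
  }
})

test_that("the k-means baseline stays near chance on class-independent sequences", {
  set.seed(10)
  labels <- matrix(sample(0:9, 120 * 15, TRUE), 120, 15)
  sq <- label_sequence(labels, seq(0, by = 0.01, length.out = 15),
                       rep(c("standard", "target"), 60),
                       template_names = paste0("T", 1:10))
  fits <- lapply(1:5, function(s) {
    suppressWarnings(nested_cv_classify(sq, "kmeans_baseline", seed = s))
  })
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "mean_f1")), 0.5,
               tolerance = 0.3)
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "auc")), 0.5,
               tolerance = 0.25)
})

test_that("temporal generalization trims boundaries and exceeds chance on-diagonal", {
  ses <- quick_session(seed = 18, n_standard = 30, n_target = 30,
                       noise_sd_uv = 0.5, mean_segment_ms = 60)
  sq <- label_epochs(ses$epochs, expand_polarity(ses$config$template_set),
                     window_spec(-0.2, 0.6, 0.1, 0.05))
  nw <- ncol(sq$labels)
  tg <- temporal_generalization(sq, family = "logistic_regression",
                                grid = list(lambda = 0.1), seed = 1)
  expect_equal(dim(tg$f1), c(nw - 2, nw - 2))
  expect_equal(nrow(tidy(tg)), (nw - 2)^2)
  # post-stimulus diagonal beats the pre-stimulus off-diagonal cells
  post <- which(tg$train_time >= 0.05 & tg$train_time <= 0.35)
  pre <- which(tg$train_time < -0.05)
  expect_gt(mean(diag(tg$f1)[post]), mean(tg$f1[pre, pre]))
  expect_error(
    temporal_generalization(restrict_windows(sq, 0, 0.05), "svm"),
    ">= 3 windows"
  )
})

test_that("condition comparison emits the long-format fold table", {
  set.seed(11)
  labels <- matrix(sample(0:9, 40 * 10, TRUE), 40, 10)
  sq <- label_sequence(labels, seq(0, by = 0.01, length.out = 10),
                       rep(c("standard", "target"), 20), paste0("T", 1:10))
  fits <- list(
    a = nested_cv_classify(sq, "logistic_regression", grid = list(lambda = 0.1)),
    b = nested_cv_classify(sq, "logistic_regression", grid = list(lambda = 1))
  )
  cmp <- compare_conditions(fits, tibble::tibble(
    variant = c("5", "5"), polarity = c("polar", "non")
  ))
  expect_equal(nrow(cmp$scores), 10)          # runs x folds
  expect_equal(nrow(cmp$summary), 2)
  expect_true(all(c("variant", "polarity", "model", "fold", "f1", "auc")
                  %in% names(cmp$scores)))
})
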