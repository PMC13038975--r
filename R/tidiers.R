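#' Broom-style tidiers for classification results
#'
#' `tidy()` on an `ms_classif` returns the per-fold table (fold, test-set
#' size, F1, chosen hyperparameters as a list column); `glance()` a one-row
#' summary (family, mean F1, pooled out-of-fold AUC, trial count).
#'
#' @param x An `ms_classif` object from [nested_cv_classify()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ms_classif <- function(x, ...) {
  x$folds %>% mutate(family = x$family, .before = 1)
}

#' @rdname tidy.ms_classif
#' @export
glance.ms_classif <- function(x, ...) {
  tibble(family = x$family, mean_f1 = x$mean_f1, auc = x$auc,
         n_folds = nrow(x$folds), n_trials = nrow(x$predictions))
}

#' @rdname tidy.ms_classif
#' @export
tidy.ms_tgm <- function(x, ...) {
  tibble(
    train_time = rep(x$train_time, times = length(x$test_time)),
    test_time = rep(x$test_time, each = length(x$train_time)),
    f1 = as.vector(x$f1)
  )
}

#' @rdname tidy.ms_classif
#' @export
glance.ms_tgm <- function(x, ...) {
  tibble(family = x$family, n_train_windows = nrow(x$f1),
         n_test_windows = ncol(x$f1), diag_mean_f1 = mean(diag(x$f1)),
         max_f1 = max(x$f1))
}
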