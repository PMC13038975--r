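#' Confusion counts and F1 score
#'
#' `confusion_counts()` tallies true/false positives and negatives with
#' "target" as the positive class; `f1_score()` computes
#' `2TP / (2TP + FP + FN)`, the harmonic mean of precision and recall. When
#' the denominator is zero (no positives anywhere) the score is defined as 0
#' with a warning.
#'
#' @param truth,pred Character vectors of true and predicted classes.
#' @param positive Positive class name.
#' @return `confusion_counts` returns a list `TP`, `FP`, `TN`, `FN`;
#'   `f1_score` a scalar in `[0, 1]`.
#' @export
confusion_counts <- function(truth, pred, positive = "target") {
  stopifnot(length(truth) == length(pred))
  list(
    TP = sum(truth == positive & pred == positive),
    FP = sum(truth != positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FN = sum(truth == positive & pred != positive)
  )
}

#' @rdname confusion_counts
#' @param counts A list with elements `TP`, `FP`, `FN` (e.g. from
#'   `confusion_counts()`).
#' @export
f1_score <- function(counts) {
  denom <- 2 * counts$TP + counts$FP + counts$FN
  if (denom == 0) {
    warn("F1 undefined (no positives in truth or prediction); returning 0")
    return(0)
  }
  2 * counts$TP / denom
}

#' Area under the ROC curve (rank formulation)
#'
#' The Mann-Whitney estimate: the probability that a randomly chosen
#' positive trial scores higher than a randomly chosen negative trial, with
#' ties counted 1/2. Computed from midranks, so tied scores are handled
#' exactly.
#'
#' @param scores Numeric classifier scores (higher = more "target"-like).
#' @param truth Character vector of true classes.
#' @param positive Positive class name.
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth, positive = "target") {
  pos <- truth == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC needs both classes present", class = "microlabel_error")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified k-fold assignment: within each class, shuffled round-robin
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# feature matrix from a label sequence: ordinal integers, sentinel -> NA
feature_matrix <- function(seq) {
  x <- seq$labels
  storage.mode(x) <- "double"
  x[x < 0] <- NA_real_
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  x
}

# columnwise modal value of the training rows; used to impute sentinels
impute_by_train_mode <- function(x_train, x_test) {
  modes <- vapply(seq_len(ncol(x_train)), function(j) {
    v <- x_train[, j]
    v <- v[!is.na(v)]
    if (!length(v)) return(0)
    as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  }, numeric(1))
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- modes[j]
    m
  }
  list(train = fill(x_train), test = fill(x_test))
}

# inner grid search maximizing mean F1; returns the best params (first on tie)
inner_grid_search <- function(x, y, family, grid, n_folds, seed) {
  rows <- grid_rows(grid)
  if (!length(rows)) abort("empty hyperparameter grid", class = "microlabel_error")
  if (length(rows) == 1) return(rows[[1]])
  fold <- make_folds(y, n_folds, seed)
  mean_f1 <- vapply(rows, function(params) {
    f1s <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
      params$.fit_seed <- seed
      model <- fit_family(family, x[tr, , drop = FALSE], y[tr], params)
      pr <- predict_family(model, x[te, , drop = FALSE])
      suppressWarnings(f1_score(confusion_counts(y[te], pr$class)))
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  rows[[which.max(mean_f1)]]
}

#' Nested cross-validated classification of label sequences
#'
#' Classifies standard vs target trials from their integer microstate label
#' sequences. Trials are split into `n_outer_folds` stratified outer folds;
#' within each outer-training set a `n_inner_folds`-fold grid search selects
#' the hyperparameters maximizing mean F1, the model is refit on the full
#' outer-training set with those parameters, and predictions plus continuous
#' scores are produced for the held-out outer fold (20% of trials at the
#' default 5 folds). Per-fold F1 scores are averaged into the mean F1; AUC is
#' computed on the pooled out-of-fold scores. Sentinel windows are imputed
#' with the outer-training-set modal label per window.
#'
#' @param seq A [label_sequence()] (typically balanced and restricted to
#'   0-400 ms; a class-imbalanced input triggers a warning).
#' @param family Model family, see [default_grid()].
#' @param grid Hyperparameter grid (named list of candidate vectors);
#'   defaults to `default_grid(family)`.
#' @param n_outer_folds,n_inner_folds Fold counts (>= 2).
#' @param seed Seed for fold assignment, inner search and stochastic fits.
#' @return An `ms_classif` object: list with `family`, `mean_f1`, `auc`,
#'   `folds` (per-fold tibble with chosen hyperparameters), `predictions`
#'   (per-trial out-of-fold tibble), `seed`.
#' @export
nested_cv_classify <- function(seq, family = "random_forest", grid = NULL,
                               n_outer_folds = 5, n_inner_folds = 5, seed = 1L) {
  stopifnot(inherits(seq, "label_sequence"), n_outer_folds >= 2, n_inner_folds >= 2)
  family <- match.arg(family, model_families())
  if (is.null(grid)) grid <- default_grid(family)
  y <- seq$classes
  if (length(unique(y)) != 2) {
    abort("classification needs exactly two classes", class = "microlabel_error")
  }
  if (diff(range(table(y))) > 0) {
    warn("classes are imbalanced; consider balance_trials() first")
  }
  x <- feature_matrix(seq)
  fold <- make_folds(y, n_outer_folds, seed)

  pred_class <- character(length(y))
  pred_score <- numeric(length(y))
  fold_rows <- list()
  for (f in seq_len(n_outer_folds)) {
    tr <- fold != f; te <- fold == f
    imp <- impute_by_train_mode(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    best <- inner_grid_search(imp$train, y[tr], family, grid,
                              n_inner_folds, seed = seed + f)
    best$.fit_seed <- seed + f
    model <- fit_family(family, imp$train, y[tr], best)
    pr <- predict_family(model, imp$test)
    pred_class[te] <- pr$class
    pred_score[te] <- pr$score
    f1 <- suppressWarnings(f1_score(confusion_counts(y[te], pr$class)))
    best$.fit_seed <- NULL
    fold_rows[[f]] <- tibble(fold = f, n_test = sum(te), f1 = f1,
                             params = list(best))
  }
  folds <- bind_rows(fold_rows)
  structure(
    list(
      family = family,
      mean_f1 = mean(folds$f1),
      auc = auc_score(pred_score, y),
      folds = folds,
      predictions = tibble(trial = seq_along(y), class = y, fold = fold,
                           pred = pred_class, score = pred_score),
      seed = seed
    ),
    class = "ms_classif"
  )
}

#' @export
print.ms_classif <- function(x, ...) {
  cat("<ms_classif> ", x$family, ": mean F1 = ", round(x$mean_f1, 3),
      ", pooled OOF AUC = ", round(x$auc, 3), " (", nrow(x$folds),
      " outer folds, ", nrow(x$predictions), " trials)\n", sep = "")
  invisible(x)
}

#' Temporal generalization matrix
#'
#' Trains a classifier at each interior window `t` of a coarse grid using the
#' labels of the three consecutive windows `(t-1, t, t+1)` as features, and
#' evaluates it at every interior test position `t'` with the corresponding
#' three-window features. F1 is averaged over the outer folds per
#' train/test cell; the first and last windows have no neighbours and are
#' excluded. A high diagonal that spreads off-diagonal reveals a neural code
#' that persists or recurs over time.
#'
#' @param seq A [label_sequence()] on a coarse grid (100 ms / 25 ms windows
#'   in the reference design) with at least 3 windows.
#' @param family Model family (the reference analysis used an SVM).
#' @param grid Hyperparameter grid; by default a reduced SVM grid. Set
#'   `hyper = "per_window"` to rerun the inner search at every training
#'   window, or `"global"` to search once at the first training window and
#'   reuse the result.
#' @param n_outer_folds,n_inner_folds,seed As in [nested_cv_classify()].
#' @param hyper Hyperparameter handling (see above).
#' @return An `ms_tgm` object: list with `f1` matrix
#'   `[(n_windows-2) x (n_windows-2)]`, `train_time`, `test_time`, `family`.
#' @export
temporal_generalization <- function(seq, family = "svm", grid = NULL,
                                    n_outer_folds = 5, n_inner_folds = 5,
                                    seed = 1L,
                                    hyper = c("per_window", "global")) {
  stopifnot(inherits(seq, "label_sequence"))
  hyper <- match.arg(hyper)
  family <- match.arg(family, model_families())
  if (is.null(grid)) {
    grid <- if (family == "svm") {
      list(cost = c(0.1, 1, 10), kernel = "linear", gamma = "scale")
    } else default_grid(family)
  }
  nw <- ncol(seq$labels)
  if (nw < 3) abort("temporal generalization needs >= 3 windows", class = "microlabel_error")
  interior <- 2:(nw - 1)
  y <- seq$classes
  x_full <- feature_matrix(seq)
  fold <- make_folds(y, n_outer_folds, seed)
  feats <- function(t) x_full[, (t - 1):(t + 1), drop = FALSE]

  f1 <- matrix(NA_real_, length(interior), length(interior))
  global_best <- NULL
  for (ti in seq_along(interior)) {
    t <- interior[ti]
    xt <- feats(t)
    preds <- vector("list", n_outer_folds)
    for (f in seq_len(n_outer_folds)) {
      tr <- fold != f
      imp_tr <- impute_by_train_mode(xt[tr, , drop = FALSE], xt[tr, , drop = FALSE])$train
      best <- if (hyper == "global" && !is.null(global_best)) global_best else {
        b <- inner_grid_search(imp_tr, y[tr], family, grid, n_inner_folds,
                               seed = seed + f)
        if (hyper == "global") global_best <- b
        b
      }
      best$.fit_seed <- seed + f
      preds[[f]] <- list(model = fit_family(family, imp_tr, y[tr], best), train = tr)
    }
    for (si in seq_along(interior)) {
      s <- interior[si]
      xs <- feats(s)
      f1s <- vapply(seq_len(n_outer_folds), function(f) {
        te <- !preds[[f]]$train
        imp_te <- impute_by_train_mode(xs[preds[[f]]$train, , drop = FALSE],
                                       xs[te, , drop = FALSE])$test
        pr <- predict_family(preds[[f]]$model, imp_te)
        suppressWarnings(f1_score(confusion_counts(y[te], pr$class)))
      }, numeric(1))
      f1[ti, si] <- mean(f1s)
    }
  }
  structure(
    list(f1 = f1, train_time = seq$window_starts[interior],
         test_time = seq$window_starts[interior], family = family),
    class = "ms_tgm"
  )
}

#' @export
print.ms_tgm <- function(x, ...) {
  cat("<ms_tgm> ", nrow(x$f1), " x ", ncol(x$f1), " train x test windows (",
      x$family, "), diagonal mean F1 = ", round(mean(diag(x$f1)), 3), "\n",
      sep = "")
  invisible(x)
}

#' Tidy score table across template variants, polarity settings and models
#'
#' Aggregates a set of classification results (e.g. the 4 / 5 / 7-template
#' variants crossed with polarity-considered and polarity-ignored labeling)
#' into the long-format per-fold table used for downstream ANOVA, plus a
#' variant-by-polarity summary of mean F1.
#'
#' @param results Named list of `ms_classif` objects.
#' @param meta Tibble/data frame with one row per result (same order) giving
#'   at least `variant` and `polarity`; a `model` column defaults to each
#'   result's family.
#' @return List with `scores` (variant, polarity, model, fold, f1, auc) and
#'   `summary` (variant, polarity, model, mean_f1, mean_auc).
#' @export
compare_conditions <- function(results, meta) {
  stopifnot(length(results) >= 1, nrow(meta) == length(results))
  meta <- as_tibble(meta)
  if (!"model" %in% names(meta)) {
    meta$model <- vapply(results, `[[`, character(1), "family")
  }
  scores <- bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tibble(variant = meta$variant[i], polarity = meta$polarity[i],
           model = meta$model[i], fold = r$folds$fold, f1 = r$folds$f1,
           auc = r$auc)
  }))
  summary <- scores %>%
    group_by(.data$variant, .data$polarity, .data$model) %>%
    summarise(mean_f1 = mean(.data$f1), mean_auc = mean(.data$auc),
              .groups = "drop")
  list(scores = scores, summary = summary)
}
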