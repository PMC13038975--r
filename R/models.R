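# Model family backends for label-sequence classification.
#
# Each family exposes fit(x, y, params) -> object and
# predict(object, x) -> list(class = character, score = numeric), where
# score is a continuous quantity increasing with confidence in the positive
# class ("target"). Features are the ordinal integer label vectors.

POSITIVE_CLASS <- "target"

#' Default hyperparameter grids per model family
#'
#' The SVM grid follows the published search space (C in 0.01-100; linear,
#' rbf and sigmoid kernels; gamma scale/auto/1). Grids for the remaining
#' families are modest package defaults and fully user-overridable through
#' the `grid` argument of [nested_cv_classify()].
#'
#' @param family One of `"svm"`, `"random_forest"`, `"logistic_regression"`,
#'   `"xgboost"`, `"kmeans_baseline"`.
#' @return Named list of candidate values; the grid is their cross product.
#' @export
default_grid <- function(family) {
  switch(family,
    svm = list(cost = c(0.01, 0.1, 1, 10, 100),
               kernel = c("linear", "radial", "sigmoid"),
               gamma = c("scale", "auto", "1")),
    random_forest = list(num_trees = c(100, 300), max_depth = c(0, 6)),
    logistic_regression = list(lambda = c(0.01, 0.1, 1, 10)),
    xgboost = list(nrounds = c(50, 100), eta = c(0.05, 0.1), max_depth = c(3, 6)),
    kmeans_baseline = list(dummy = 1),
    abort(paste0("unknown model family '", family, "'"), class = "microlabel_error")
  )
}

model_families <- function() {
  c("svm", "random_forest", "logistic_regression", "xgboost", "kmeans_baseline")
}

supervised_families <- function() {
  setdiff(model_families(), "kmeans_baseline")
}

grid_rows <- function(grid) {
  g <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# numeric gamma following the scikit-learn conventions
resolve_gamma <- function(gamma, x) {
  if (is.numeric(gamma)) return(gamma)
  switch(gamma,
    scale = {
      v <- var(as.vector(x))
      1 / (ncol(x) * max(v, 1e-12))
    },
    auto = 1 / ncol(x),
    as.numeric(gamma)
  )
}

fit_family <- function(family, x, y, params) {
  y <- factor(y, levels = c(setdiff(unique(y), POSITIVE_CLASS), POSITIVE_CLASS))
  switch(family,
    svm = {
      fit <- e1071::svm(x = x, y = y, cost = params$cost, kernel = params$kernel,
                        gamma = resolve_gamma(params$gamma, x), scale = FALSE)
      list(family = family, fit = fit, levels = levels(y))
    },
    random_forest = {
      df <- data.frame(x)
      df$.y <- y
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = params$num_trees, max.depth = params$max_depth,
        probability = TRUE, num.threads = 1,
        seed = params$.fit_seed %||% 1L
      )
      list(family = family, fit = fit, levels = levels(y))
    },
    logistic_regression = {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = params$lambda)
      list(family = family, fit = fit, levels = levels(y))
    },
    xgboost = {
      fit <- xgboost::xgboost(
        x, y, nrounds = params$nrounds, learning_rate = params$eta,
        max_depth = params$max_depth, nthreads = 1, verbosity = 0
      )
      list(family = family, fit = fit, levels = levels(y))
    },
    kmeans_baseline = {
      km <- kmeans(x, centers = 2, nstart = 5)
      # map each cluster to its majority training class; when both clusters
      # share a majority, the one with the weaker margin takes the other
      # class so that the baseline still partitions the label space
      counts <- vapply(1:2, function(cl) {
        vapply(levels(y), function(lv) sum(y[km$cluster == cl] == lv), numeric(1))
      }, numeric(2))                              # [levels x clusters]
      cl_class <- levels(y)[apply(counts, 2, which.max)]
      if (cl_class[1] == cl_class[2]) {
        margin <- abs(counts[1, ] - counts[2, ])
        weaker <- which.min(margin)
        cl_class[weaker] <- setdiff(levels(y), cl_class[weaker])
      }
      list(family = family, centers = km$centers, cl_class = cl_class,
           levels = levels(y))
    }
  )
}

predict_family <- function(model, x) {
  pos <- POSITIVE_CLASS
  neg <- setdiff(model$levels, pos)
  switch(model$family,
    svm = {
      pr <- predict(model$fit, x, decision.values = TRUE)
      dv <- as.vector(attr(pr, "decision.values"))
      # decision value is oriented toward the first class of its colname
      first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
      score <- if (identical(first, pos)) dv else -dv
      list(class = as.character(pr), score = score)
    },
    random_forest = {
      pr <- predict(model$fit, data.frame(x), num.threads = 1)$predictions
      score <- pr[, pos]
      list(class = ifelse(score > 0.5, pos, neg), score = score)
    },
    logistic_regression = {
      # glmnet's binomial response models P(second factor level) = P(target)
      score <- as.vector(predict(model$fit, x, type = "response"))
      list(class = ifelse(score > 0.5, pos, neg), score = score)
    },
    xgboost = {
      # response = P(second factor level) = P(target)
      score <- as.vector(predict(model$fit, x, type = "response"))
      list(class = ifelse(score > 0.5, pos, neg), score = score)
    },
    kmeans_baseline = {
      d <- vapply(1:2, function(cl) {
        sqrt(rowSums(sweep(x, 2, model$centers[cl, ])^2))
      }, numeric(nrow(x)))
      cls <- model$cl_class[max.col(-d, ties.method = "first")]
      # signed distance difference toward the cluster(s) mapped to target
      w <- ifelse(model$cl_class == pos, 1, -1)
      score <- as.vector(d %*% (-w))           # closer to target cluster => higher
      list(class = cls, score = score)
    }
  )
}
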