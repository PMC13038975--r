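#' Label occurrence frequency over the window grid
#'
#' For each stimulus class, analysis window and template label, the fraction
#' of trials carrying that label in that window (count divided by the class's
#' trial count). Sentinel (`-1`) windows are excluded from the counts, so a
#' column can sum to slightly less than 1 when sentinels are present.
#'
#' @param seq A [label_sequence()].
#' @param by_class Split by stimulus class (default) or pool all trials
#'   (class `"all"`).
#' @return A tibble with columns `class`, `template`, `label`, `time`, `freq`,
#'   of class `frequency_map`.
#' @export
occurrence_frequency <- function(seq, by_class = TRUE) {
  stopifnot(inherits(seq, "label_sequence"))
  if (nrow(seq$labels) == 0) {
    abort("empty label sequence", class = "microlabel_error")
  }
  classes <- if (by_class) unique(seq$classes) else "all"
  k <- length(seq$template_names)
  out <- lapply(classes, function(cl) {
    idx <- if (by_class) which(seq$classes == cl) else seq_len(nrow(seq$labels))
    lab <- seq$labels[idx, , drop = FALSE]
    counts <- vapply(seq_len(ncol(lab)), function(w) {
      tabulate(lab[, w] + 1L, nbins = k)         # -1 sentinel drops out
    }, numeric(k))                               # [k x n_windows]
    tibble(
      class = cl,
      template = rep(seq$template_names, times = ncol(lab)),
      label = rep(seq_len(k) - 1L, times = ncol(lab)),
      time = rep(seq$window_starts, each = k),
      freq = as.vector(counts) / length(idx)
    )
  })
  structure(bind_rows(out), class = c("frequency_map", class(tibble())))
}

#' Target-minus-standard occurrence-frequency difference
#'
#' @param fm A `frequency_map` from [occurrence_frequency()] containing both
#'   classes, or the map of the positive class alone.
#' @param fm_negative When `fm` holds a single class, the map to subtract.
#' @param positive,negative Class names (ignored when two maps are given).
#' @return Tibble with columns `template`, `label`, `time`, `diff`.
#' @export
frequency_difference <- function(fm, fm_negative = NULL,
                                 positive = "target", negative = "standard") {
  if (is.null(fm_negative)) {
    a <- fm %>% filter(.data$class == positive)
    b <- fm %>% filter(.data$class == negative)
  } else {
    a <- fm
    b <- fm_negative
  }
  if (nrow(a) == 0 || nrow(a) != nrow(b)) {
    abort("frequency maps have mismatched shapes", class = "microlabel_error")
  }
  keys <- c("template", "label", "time")
  # two multi-class maps (e.g. fm vs itself) must also match on class;
  # a positive-vs-negative pair has disjoint class values and joins without
  if ("class" %in% names(a) && "class" %in% names(b) &&
      setequal(unique(a$class), unique(b$class))) {
    keys <- c("class", keys)
  }
  ab <- left_join(
    a %>% select(dplyr::all_of(keys), "freq"),
    b %>% select(dplyr::all_of(keys), freq_b = "freq"),
    by = keys, relationship = "one-to-one"
  )
  if (anyNA(ab$freq_b)) {
    abort("frequency maps have mismatched shapes", class = "microlabel_error")
  }
  ab %>% mutate(diff = .data$freq - .data$freq_b) %>%
    select(dplyr::all_of(setdiff(keys, "class")), "diff")
}

#' Trial-averaged one-hot label time courses
#'
#' One-hot encodes the labels of one participant's trials and averages across
#' trials per class, giving a `[n_templates x n_windows]` probability array
#' per class - numerically identical to [occurrence_frequency()] on that
#' participant when no sentinel labels are present. Windows with sentinel
#' labels are excluded from the trial average (renormalized denominator);
#' the number of affected cells is recorded in the `n_sentinel` attribute.
#'
#' @param seq A [label_sequence()] (one participant).
#' @return Named list, one `[n_templates x n_windows]` matrix per class, with
#'   attribute `n_sentinel`.
#' @export
time_resolved_onehot <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  k <- length(seq$template_names)
  classes <- unique(seq$classes)
  sentinel <- 0L
  out <- lapply(classes, function(cl) {
    lab <- seq$labels[seq$classes == cl, , drop = FALSE]
    if (nrow(lab) == 0) {
      abort(paste0("no trials for class '", cl, "'"), class = "microlabel_error")
    }
    m <- vapply(seq_len(ncol(lab)), function(w) {
      x <- lab[, w]
      ok <- x >= 0
      sentinel <<- sentinel + sum(!ok)
      tabulate(x[ok] + 1L, nbins = k) / max(sum(ok), 1L)
    }, numeric(k))
    dimnames(m) <- list(seq$template_names, NULL)
    m
  })
  names(out) <- classes
  attr(out, "n_sentinel") <- sentinel
  attr(out, "time") <- seq$window_starts
  out
}

# vectorized one-sample t over [n x W] under a [P x n] matrix of sign flips;
# returns [P x W] t values (NA where pointwise variance is zero)
signflip_t <- function(D, S) {
  n <- nrow(D)
  sumsq <- colSums(D^2)                     # invariant under sign flips
  M <- (S %*% D) / n                        # [P x W] means
  V <- (rep(sumsq, each = nrow(S)) - n * M^2) / (n - 1)
  V[V < 1e-24] <- NA_real_
  M / sqrt(V / n)
}

# maximal runs of TRUE; returns list of (start, end) index pairs
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

#' Cluster-based permutation test on per-participant difference time series
#'
#' One-sample test of whether a label's target-minus-standard occurrence
#' difference departs from zero anywhere along the window grid, correcting
#' over time by cluster mass. Pointwise one-sample t statistics across
#' participants are thresholded at the two-sided critical value for
#' `alpha_cluster`; maximal supra-threshold runs form clusters with mass
#' `sum(|t|)`. The null distribution of the maximum cluster mass is built by
#' randomly sign-flipping whole participant difference series
#' (`scheme = "signflip"`, the standard exchangeability argument preserving
#' temporal autocorrelation) or by random circular time shifts per
#' participant (`scheme = "circshift"`, the literal time-shuffling reading);
#' cluster p-values use the `+1`-corrected Monte Carlo estimate
#' `(1 + #[null >= observed]) / (1 + n_perm)`.
#'
#' Windows where the pointwise variance is zero (t undefined) are excluded
#' from cluster formation; their count is reported in the result.
#'
#' @param diffs Numeric matrix `[n_participants x n_windows]` of differences.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha_cluster Two-sided cluster-forming alpha.
#' @param seed Integer seed for the permutation draws.
#' @param scheme `"signflip"` (default) or `"circshift"`.
#' @param time Optional window start times for reporting.
#' @return Tibble of clusters (`start`, `end` window indices, `t_start`,
#'   `t_end` seconds if `time` given, `mass`, `p`) with attributes
#'   `n_excluded`, `n_perm`, `alpha_cluster`.
#' @export
permutation_cluster_test <- function(diffs, n_perm = 1000, alpha_cluster = 0.05,
                                     seed = 1L, scheme = c("signflip", "circshift"),
                                     time = NULL) {
  scheme <- match.arg(scheme)
  diffs <- as.matrix(diffs)
  n <- nrow(diffs); W <- ncol(diffs)
  if (n < 2) abort("need >= 2 participants", class = "microlabel_error")
  if (n_perm < 100) abort("need n_perm >= 100", class = "microlabel_error")
  tcrit <- qt(1 - alpha_cluster / 2, df = n - 1)

  t_obs <- as.vector(signflip_t(diffs, matrix(1, 1, n)))
  excluded <- is.na(t_obs)
  mask <- !excluded & abs(t_obs) > tcrit
  runs <- true_runs(mask)
  obs_mass <- vapply(runs, function(r) sum(abs(t_obs[r[1]:r[2]])), numeric(1))

  max_mass <- function(tv) {
    m <- !is.na(tv) & abs(tv) > tcrit
    if (!any(m)) return(0)
    max(vapply(true_runs(m), function(r) sum(abs(tv[r[1]:r[2]])), numeric(1)))
  }

  null_max <- withr::with_seed(seed, {
    if (scheme == "signflip") {
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      Tm <- signflip_t(diffs, S)
      apply(Tm, 1, max_mass)
    } else {
      vapply(seq_len(n_perm), function(p) {
        shifted <- t(vapply(seq_len(n), function(i) {
          s <- sample.int(W, 1) - 1L
          if (s == 0) diffs[i, ] else diffs[i, c((s + 1):W, 1:s)]
        }, numeric(W)))
        max_mass(as.vector(signflip_t(shifted, matrix(1, 1, n))))
      }, numeric(1))
    }
  })

  p <- vapply(obs_mass, function(m) (1 + sum(null_max >= m)) / (1 + n_perm),
              numeric(1))
  res <- tibble(
    start = vapply(runs, `[`, integer(1), 1),
    end = vapply(runs, `[`, integer(1), 2),
    mass = obs_mass,
    p = p
  )
  if (!is.null(time)) {
    res$t_start <- time[res$start]
    res$t_end <- time[res$end]
  }
  attr(res, "n_excluded") <- sum(excluded)
  attr(res, "n_perm") <- n_perm
  attr(res, "alpha_cluster") <- alpha_cluster
  res
}

#' Benjamini-Hochberg correction of cluster p-values across labels
#'
#' Pools the cluster p-values of all microstate labels and applies the BH
#' step-up procedure (monotone q-values), the multiplicity correction across
#' the label dimension.
#'
#' @param p Numeric vector of p-values (pooled across labels by default).
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_across_labels <- function(p) {
  if (!length(p)) abort("no p-values given", class = "microlabel_error")
  p.adjust(p, method = "BH")
}

#' Time-resolved label comparison between stimulus classes
#'
#' The full label-distribution analysis: per participant, trial-averaged
#' one-hot label time courses per class; per label, a cluster-based
#' permutation test on the participant-level target-minus-standard
#' differences; then BH correction pooled across labels.
#'
#' @param seqs List of [label_sequence()] objects, one per participant, all
#'   on the same window grid and template set.
#' @param n_perm,alpha_cluster,seed,scheme Passed to
#'   [permutation_cluster_test()]; each label uses the same seed so the null
#'   draws are shared.
#' @param positive,negative Class names for the difference.
#' @return Tibble of clusters with columns `template`, `label`, `start`,
#'   `end`, `t_start`, `t_end`, `mass`, `p`, `q`; class `ms_cluster_result`.
#' @export
label_cluster_stats <- function(seqs, n_perm = 1000, alpha_cluster = 0.05,
                                seed = 1L, scheme = "signflip",
                                positive = "target", negative = "standard") {
  stopifnot(length(seqs) >= 2)
  onehots <- lapply(seqs, time_resolved_onehot)
  tnames <- seqs[[1]]$template_names
  time <- seqs[[1]]$window_starts
  res <- lapply(seq_along(tnames), function(l) {
    D <- t(vapply(onehots, function(oh) oh[[positive]][l, ] - oh[[negative]][l, ],
                  numeric(length(time))))
    cl <- permutation_cluster_test(D, n_perm = n_perm,
                                   alpha_cluster = alpha_cluster, seed = seed,
                                   scheme = scheme, time = time)
    if (nrow(cl)) cl %>% mutate(template = tnames[l], label = l - 1L, .before = 1)
    else NULL
  })
  out <- bind_rows(res)
  if (nrow(out)) out$q <- fdr_across_labels(out$p) else out$q <- numeric(0)
  structure(out, class = c("ms_cluster_result", class(tibble())),
            n_perm = n_perm, alpha_cluster = alpha_cluster, seed = seed)
}

#' Split trials by out-of-fold classifier correctness
#'
#' Partitions the trials of a label sequence into those the classifier's
#' out-of-fold predictions got right and those it got wrong, so the label
#' statistics can be recomputed separately for each subset.
#'
#' @param seq A [label_sequence()].
#' @param predictions Character vector of out-of-fold predicted classes, one
#'   per trial (e.g. `tidy(fit)$pred` ordered by trial).
#' @return List with `correct` and `incorrect` label sequences (either may
#'   have zero trials).
#' @export
split_by_prediction <- function(seq, predictions) {
  stopifnot(inherits(seq, "label_sequence"))
  if (length(predictions) != nrow(seq$labels) || anyNA(predictions)) {
    abort("one non-missing prediction per trial is required",
          class = "microlabel_error")
  }
  ok <- as.character(predictions) == seq$classes
  list(correct = subset_trials(seq, which(ok)),
       incorrect = subset_trials(seq, which(!ok)))
}
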