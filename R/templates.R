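#' Global field power of a scalp map
#'
#' The spatial standard deviation of the average-referenced map: the square
#' root of the mean squared deviation from the channel mean. Zero exactly for
#' a constant map; homogeneous of degree one in the map amplitude.
#'
#' @param map Numeric channel vector (length >= 2).
#' @return Non-negative scalar (same units as the map).
#' @export
gfp <- function(map) {
  stopifnot(length(map) >= 2)
  sqrt(mean((map - mean(map))^2))
}

# GFP series of a [channels x samples] matrix
gfp_series <- function(mat) {
  centered <- sweep(mat, 2, colMeans(mat))
  sqrt(colMeans(centered^2))
}

#' Extract GFP-peak maps from epoched EEG
#'
#' Global field power peaks mark moments of high topographic signal-to-noise;
#' microstate templates are customarily clustered from maps sampled at those
#' peaks. Peaks are strict local maxima of the per-trial GFP series, thinned
#' so that retained peaks are at least `min_dist_ms` apart (greedy, keeping
#' the larger peak). When more than `n_per_subject` peaks survive, a seeded
#' uniform subset of that size is returned; when fewer survive, all are
#' returned with a warning.
#'
#' @param es An [epoch_set()]. Epochs are treated as a concatenation of
#'   independent segments: peaks never span trial boundaries.
#' @param min_dist_ms Minimum peak-to-peak interval in milliseconds.
#' @param n_per_subject Maximum number of peak maps to return (2500 in the
#'   reference template-derivation procedure).
#' @param seed Seed for the subsampling draw.
#' @return Numeric matrix `[n_peaks x n_channels]` of average-referenced maps.
#' @export
gfp_peaks <- function(es, min_dist_ms = 10, n_per_subject = 2500, seed = 1L) {
  stopifnot(inherits(es, "epoch_set"), min_dist_ms > 0)
  min_dist <- max(1L, round(min_dist_ms * es$sfreq / 1000))
  out <- list()
  for (tr in seq_len(n_trials(es))) {
    mat <- es$data[tr, , ]                       # [nc x ns]
    g <- gfp_series(mat)
    ns <- length(g)
    if (ns < 3) next
    cand <- which(g[2:(ns - 1)] > g[1:(ns - 2)] & g[2:(ns - 1)] > g[3:ns]) + 1L
    if (!length(cand)) next
    keep <- integer(0)
    for (i in cand[order(g[cand], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
    }
    keep <- sort(keep)
    m <- t(mat[, keep, drop = FALSE])
    out[[length(out) + 1L]] <- sweep(m, 1, rowMeans(m))
  }
  if (!length(out)) {
    abort("no GFP local maxima found", class = "microlabel_error")
  }
  peaks <- do.call(rbind, out)
  if (nrow(peaks) > n_per_subject) {
    idx <- withr::with_seed(seed, sort(sample(nrow(peaks), n_per_subject)))
    peaks <- peaks[idx, , drop = FALSE]
  } else if (nrow(peaks) < n_per_subject) {
    warn(paste0("only ", nrow(peaks), " GFP peaks available (< ", n_per_subject, ")"))
  }
  peaks
}

# rows centered and unit-normalized; drops the all-constant degenerate rows
normalize_rows <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm > .Machine$double.eps * ncol(m) * 10
  sweep(m[ok, , drop = FALSE], 1, nrm[ok], "/")
}

# explained variance: mean over maps of squared correlation to the assigned
# centroid (maps and centroids zero-mean unit-norm, so corr = dot product)
kmeans_ev <- function(X, centroids, assign) {
  mean(rowSums(X * centroids[assign, , drop = FALSE])^2)
}

#' Polarity-invariant modified K-means clustering of scalp maps
#'
#' The microstate flavour of K-means: a map belongs to the centroid with the
#' largest *squared* spatial correlation (so a map and its negation are
#' equivalent), and each centroid is updated to the dominant eigenvector of
#' the scatter matrix of its assigned maps, the unit map maximizing the sum
#' of squared correlations. Iterations stop when the explained variance
#' (mean squared correlation to the assigned centroid) changes by less than
#' `tol` or after `max_iter` sweeps; the best of `restarts` seeded random
#' initializations (k maps sampled without replacement) is kept. An empty
#' cluster is reseeded with the currently worst-explained map.
#'
#' Returned maps are zero-mean, unit-norm, signed so the channel with the
#' largest absolute loading is positive (polarity semantics are introduced
#' only by [expand_polarity()]).
#'
#' @param maps Numeric matrix `[n_maps x n_channels]` (e.g. from
#'   [gfp_peaks()]).
#' @param k Number of clusters.
#' @param montage [montage()] for the returned template set; defaults to
#'   generic channel names.
#' @param restarts,tol,max_iter,seed Clustering controls.
#' @param names Template names (default `LETTERS[1:k]`).
#' @return A base [template_set()] with attribute `explained_variance`.
#' @export
modified_kmeans <- function(maps, k, montage = NULL, restarts = 20,
                            tol = 1e-6, max_iter = 500, seed = 1L,
                            names = LETTERS[seq_len(k)]) {
  maps <- as.matrix(maps)
  if (k > nrow(maps)) {
    abort("k exceeds the number of maps", class = "microlabel_error")
  }
  X <- normalize_rows(maps)
  if (nrow(X) < k) {
    abort("fewer non-degenerate maps than clusters", class = "microlabel_error")
  }
  n <- nrow(X); nc <- ncol(X)
  if (is.null(montage)) montage <- montage(paste0("ch", seq_len(nc)))
  stopifnot(montage$n_channels == nc)

  dominant_eig <- function(M) {
    e <- eigen(crossprod(M), symmetric = TRUE)
    v <- e$vectors[, 1]
    v / sqrt(sum(v^2))
  }

  run_once <- function(init_idx) {
    centroids <- X[init_idx, , drop = FALSE]
    ev_prev <- -Inf
    ev_trace <- numeric(0)
    assign <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      corr <- X %*% t(centroids)               # [n x k]
      assign <- max.col(corr^2, ties.method = "first")
      fit <- corr[cbind(seq_len(n), assign)]^2
      for (j in seq_len(k)) {
        members <- which(assign == j)
        if (!length(members)) {                # reseed with worst-explained map
          worst <- which.min(fit)
          assign[worst] <- j
          members <- worst
          fit[worst] <- 1
        }
        centroids[j, ] <- dominant_eig(X[members, , drop = FALSE])
      }
      corr <- X %*% t(centroids)
      assign <- max.col(corr^2, ties.method = "first")
      ev <- kmeans_ev(X, centroids, assign)
      ev_trace <- c(ev_trace, ev)
      if (ev - ev_prev < tol && it > 1) break
      ev_prev <- ev
    }
    list(centroids = centroids, ev = ev, ev_trace = ev_trace)
  }

  inits <- withr::with_seed(seed, {
    lapply(seq_len(restarts), function(r) sample(n, k))
  })
  runs <- lapply(inits, run_once)
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "ev"))]]

  cent <- best$centroids
  for (j in seq_len(k)) {                       # deterministic sign convention
    peak <- which.max(abs(cent[j, ]))
    if (cent[j, peak] < 0) cent[j, ] <- -cent[j, ]
  }
  ts <- template_set(cent, names, montage, normalized = TRUE)
  attr(ts, "explained_variance") <- best$ev
  attr(ts, "ev_trace") <- best$ev_trace
  ts
}

#' Expand a base template set with polarity-inverted maps
#'
#' Appends the exact negation of every base map, turning `k` polarity-blind
#' templates into `2k` signed templates (`A+ ... E+, A- ... E-`). Labeling
#' against the expanded set distinguishes a topography from its inverse.
#'
#' @param ts A base (non-expanded) [template_set()].
#' @return A polarity-expanded `template_set` with `2 * base_k` maps.
#' @export
expand_polarity <- function(ts) {
  stopifnot(inherits(ts, "template_set"))
  if (ts$polarity_expanded) {
    abort("template set is already polarity-expanded", class = "microlabel_error")
  }
  template_set(rbind(ts$maps, -ts$maps),
               c(paste0(ts$names, "+"), paste0(ts$names, "-")),
               ts$montage, polarity_expanded = TRUE, normalized = TRUE)
}

#' Append artificial templates by averaging centroid pairs
#'
#' Creates extra base templates as the re-normalized mean of existing base
#' map pairs (e.g. A with B and D with E, yielding the 7-template
#' "artificial" variant from a 5-map set).
#'
#' @param ts A base (non-expanded) [template_set()].
#' @param pairs List of length-2 vectors of base map indices or names.
#' @return A base `template_set` with `base_k + length(pairs)` maps.
#' @export
average_centroids <- function(ts, pairs) {
  stopifnot(inherits(ts, "template_set"))
  if (ts$polarity_expanded) {
    abort("average_centroids operates on base maps; expand polarity afterwards",
          class = "microlabel_error")
  }
  new_maps <- ts$maps
  new_names <- ts$names
  for (p in pairs) {
    if (is.character(p)) p <- match(p, ts$names)
    if (length(p) != 2 || anyNA(p) || any(p < 1) || any(p > ts$base_k)) {
      abort("each pair must reference two valid base map indices",
            class = "microlabel_error")
    }
    avg <- (ts$maps[p[1], ] + ts$maps[p[2], ]) / 2
    if (sqrt(sum(center_map(avg)^2)) < 1e-10) {
      abort(paste0("average of '", ts$names[p[1]], "' and '", ts$names[p[2]],
                   "' is the zero map and cannot be normalized"),
            class = "microlabel_error")
    }
    new_maps <- rbind(new_maps, normalize_map(avg))
    new_names <- c(new_names, paste0(ts$names[p[1]], ts$names[p[2]]))
  }
  template_set(new_maps, new_names, ts$montage, normalized = TRUE)
}
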