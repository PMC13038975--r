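#' Global map dissimilarity (DISS)
#'
#' The Euclidean distance between two L2-normalized scalp maps,
#' `|| u/||u|| - v/||v|| ||`, ranging from 0 (identical spatial
#' configuration) to 2 (polarity-inverted configuration); equivalently
#' `sqrt(2 - 2 r)` with `r` the cosine similarity of the two maps. Scale-free
#' and symmetric.
#'
#' Both maps are channel-mean-subtracted before normalization by default
#' (`center = TRUE`): every map in the pipeline is average-referenced
#' already, and centering makes the measure well-defined for raw imports.
#' `center = FALSE` gives the plain normalized-vector distance.
#'
#' @param u,v Numeric channel vectors of equal length (>= 2).
#' @param center Subtract the channel mean of each map first.
#' @return Scalar in `[0, 2]`.
#' @export
diss <- function(u, v, center = TRUE) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  prep <- function(x, nm) {
    if (center) x <- x - mean(x)
    nrm <- sqrt(sum(x^2))
    if (nrm < .Machine$double.eps * length(x) * 10) {
      abort(paste0("map '", nm, "' is zero after average reference; DISS undefined"),
            class = "microlabel_error")
    }
    x / nrm
  }
  sqrt(sum((prep(u, "u") - prep(v, "v"))^2))
}

#' Reconstruct topographies from label distributions
#'
#' The template-weighted linear sum: at each window, the reconstructed map is
#' `sum_l dist[l, w] * template_map[l]`, with `dist` the trial-averaged
#' one-hot label distribution. Linear in the distribution; a one-hot column
#' returns the template map itself, and equal weight on a template and its
#' polarity partner cancels to the zero map.
#'
#' @param dist Numeric matrix `[n_templates x n_windows]` with entries in
#'   `[0, 1]` (e.g. one class of [time_resolved_onehot()]).
#' @param ts The [template_set()] the labels refer to (same order).
#' @return Numeric matrix `[n_windows x n_channels]`.
#' @export
reconstruct_topographies <- function(dist, ts) {
  dist <- as.matrix(dist)
  if (nrow(dist) != nrow(ts$maps)) {
    abort("distribution rows must match the template count", class = "microlabel_error")
  }
  if (any(dist < -1e-12) || any(dist > 1 + 1e-12)) {
    abort("distribution entries must lie in [0, 1]", class = "microlabel_error")
  }
  out <- t(dist) %*% ts$maps                 # [n_windows x n_channels]
  colnames(out) <- ts$montage$channels
  out
}

#' Reconstruction fidelity: DISS against the grand-averaged EEG
#'
#' For each class and analysis window: (i) the grand-average window-mean
#' topography across trials (given several sessions, an unweighted mean of
#' per-participant means, so each participant counts equally); (ii) the
#' template-weighted reconstruction from the trial-averaged one-hot label
#' distribution; (iii) the DISS between the two. Windows whose grand-average
#' map is zero (e.g. trials split evenly between a template and its
#' negation) are flagged `NA` and excluded from the summary mean, with the
#' count reported.
#'
#' @param es An [epoch_set()], or list of epoch sets (one per participant).
#' @param seqs Matching [label_sequence()] (or list thereof) on the window
#'   grid of `spec`.
#' @param ts The [template_set()] used for labeling.
#' @param spec The [window_spec()] of the sequences.
#' @param pooled Use pooled-trial averaging across participants instead of
#'   the per-participant first stage.
#' @return An `ms_fidelity` object: tibble `class`, `time`, `diss` with
#'   attributes `summary` (named mean DISS per class) and `n_flagged`.
#' @export
reconstruction_fidelity <- function(es, seqs, ts, spec, pooled = FALSE) {
  if (inherits(es, "epoch_set")) es <- list(es)
  if (inherits(seqs, "label_sequence")) seqs <- list(seqs)
  stopifnot(length(es) == length(seqs))
  win <- make_windows(spec)
  classes <- unique(es[[1]]$classes)

  # per participant: [n_windows x n_channels] grand mean per class
  grand_one <- function(e, cl) {
    idx <- which(e$classes == cl)
    ns <- n_samples(e)
    W <- matrix(0, ns, nrow(win))
    for (w in seq_len(nrow(win))) {
      rg <- window_sample_range(win$start[w], win$end[w], e$sfreq, e$tmin, ns)
      W[rg[1]:rg[2], w] <- 1 / (rg[2] - rg[1] + 1)
    }
    acc <- 0
    for (tr in idx) acc <- acc + t(e$data[tr, , ] %*% W)
    acc / length(idx)
  }

  n_flagged <- 0L
  rows <- lapply(classes, function(cl) {
    grands <- lapply(es, grand_one, cl = cl)
    grand <- if (pooled) {
      ntr <- vapply(es, function(e) sum(e$classes == cl), numeric(1))
      Reduce(`+`, Map(`*`, grands, ntr)) / sum(ntr)
    } else {
      Reduce(`+`, grands) / length(grands)
    }
    dists <- lapply(seqs, function(s) time_resolved_onehot(s)[[cl]])
    dist <- Reduce(`+`, dists) / length(dists)
    recon <- reconstruct_topographies(dist, ts)
    d <- vapply(seq_len(nrow(win)), function(w) {
      g <- grand[w, ]
      if (sqrt(sum(center_map(g)^2)) < 1e-10) {
        n_flagged <<- n_flagged + 1L
        return(NA_real_)
      }
      r <- recon[w, ]
      if (sqrt(sum(center_map(r)^2)) < 1e-10) {
        n_flagged <<- n_flagged + 1L
        return(NA_real_)
      }
      diss(r, g)
    }, numeric(1))
    tibble(class = cl, time = win$start, diss = d)
  })
  out <- bind_rows(rows)
  summ <- vapply(classes, function(cl) {
    mean(out$diss[out$class == cl], na.rm = TRUE)
  }, numeric(1))
  structure(out, class = c("ms_fidelity", class(tibble())),
            summary = summ, n_flagged = n_flagged)
}
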