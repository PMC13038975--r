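#' Sliding analysis-window specification
#'
#' Windows are half-open intervals `[start, start + length)` laid out from
#' `t_start` in steps of `step`, keeping every window that fits entirely
#' inside `[t_start, t_end]`. Consecutive windows overlap by
#' `(length - step) / length` (100 ms / 25 ms steps give the 75%-overlap
#' occurrence-frequency grid; 10 ms / 1 ms the 90%-overlap classification
#' grid).
#'
#' @param t_start,t_end Analysis span in seconds.
#' @param length Window length in seconds (> 0).
#' @param step Step between window starts in seconds (0 < step <= length).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(t_start, t_end, length, step) {
  stopifnot(length > 0, step > 0, step <= length + 1e-12)
  if (t_start + length > t_end + 1e-12) {
    abort("no window fits inside [t_start, t_end]", class = "microlabel_error")
  }
  structure(list(t_start = t_start, t_end = t_end, length = length, step = step),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("<window_spec> [", x$t_start, ", ", x$t_end, "] s, length ",
      x$length * 1000, " ms, step ", x$step * 1000, " ms (",
      round(100 * (x$length - x$step) / x$length), "% overlap)\n", sep = "")
  invisible(x)
}

#' Enumerate the windows of a specification
#'
#' @param spec A [window_spec()].
#' @return Tibble with columns `start` and `end` (seconds, half-open).
#' @export
make_windows <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  n <- floor((spec$t_end - spec$t_start - spec$length) / spec$step + 1e-9) + 1
  starts <- spec$t_start + (seq_len(n) - 1) * spec$step
  tibble(start = starts, end = starts + spec$length)
}

# sample index (1-based) of time t: round((t - tmin) * sfreq) + 1
time_to_sample <- function(t, sfreq, tmin) round((t - tmin) * sfreq) + 1

# index range of the half-open window [start, end)
window_sample_range <- function(start, end, sfreq, tmin, n_samples) {
  i0 <- time_to_sample(start, sfreq, tmin)
  i1 <- time_to_sample(end, sfreq, tmin) - 1L
  if (i0 < 1 || i1 > n_samples || i1 < i0) {
    abort("window outside the epoch (empty sample range)", class = "microlabel_error")
  }
  c(i0, i1)
}

#' Mean topography within one window of one trial
#'
#' @param trial_data Numeric matrix `[n_channels x n_samples]`.
#' @param window Length-2 numeric `(start, end)` in seconds, half-open.
#' @param sfreq,tmin Sampling rate and epoch start of the trial.
#' @return Channel vector of per-channel arithmetic means over the window's
#'   samples.
#' @export
window_mean_map <- function(trial_data, window, sfreq, tmin) {
  rg <- window_sample_range(window[1], window[2], sfreq, tmin, ncol(trial_data))
  rowMeans(trial_data[, rg[1]:rg[2], drop = FALSE])
}

#' Winner-take-all template assignment of one map
#'
#' Correlates the average-referenced map with every template (Pearson spatial
#' correlation) and returns the winning label. With `polarity = TRUE` the
#' template set must be polarity-expanded and the argmax is over the *signed*
#' correlations of the `2k` signed maps; with `polarity = FALSE` it is over
#' the *absolute* correlations of the `k` base maps. Exact ties go to the
#' lowest template index. Labels are 0-based integers in template order.
#'
#' @param map Channel vector.
#' @param ts A [template_set()] (expanded iff `polarity`).
#' @param polarity Logical labeling mode.
#' @return List with `label` (0-based integer) and `correlation` (the winning
#'   signed correlation, or absolute correlation when `polarity = FALSE`).
#' @export
label_map <- function(map, ts, polarity = TRUE) {
  check_polarity_mode(ts, polarity)
  v <- center_map(map)
  nrm <- sqrt(sum(v^2))
  if (nrm < .Machine$double.eps * length(v) * 10) {
    abort("degenerate (constant) map: correlation undefined", class = "microlabel_error")
  }
  r <- as.vector(ts$maps %*% v) / nrm          # templates are zero-mean unit-norm
  score <- if (polarity) r else abs(r)
  win <- which.max(score)                      # which.max: first maximum wins
  list(label = win - 1L, correlation = score[win])
}

check_polarity_mode <- function(ts, polarity) {
  if (polarity && !ts$polarity_expanded) {
    abort("polarity-considered labeling needs a polarity-expanded template set",
          class = "microlabel_error")
  }
  if (!polarity && ts$polarity_expanded) {
    abort("polarity-ignored labeling uses the base (non-expanded) template set",
          class = "microlabel_error")
  }
  invisible(TRUE)
}

#' Encode epochs as microstate label sequences
#'
#' The core encoding step: per trial, compute the window-mean topography on
#' the sliding grid and assign each one to a template by winner-take-all
#' spatial correlation, producing one integer label per window ("integers
#' from zero to nine" for a 10-map signed set: 0-4 the "+" maps in template
#' order, 5-9 their "-" partners). A degenerate (zero-variance) window
#' inherits the previous window's label (`degenerate = "ffill"`); a
#' degenerate first window gets the sentinel `-1`.
#'
#' @param es An [epoch_set()].
#' @param ts A [template_set()] (expanded iff `polarity`).
#' @param spec A [window_spec()]; defaults to the 10 ms / 1 ms grid on
#'   0-400 ms used for classification.
#' @param polarity Logical labeling mode.
#' @param degenerate `"ffill"` (default) or `"sentinel"`: policy for
#'   zero-variance windows.
#' @return A [label_sequence()].
#' @export
label_epochs <- function(es, ts, spec = window_spec(0, 0.4, 0.010, 0.001),
                         polarity = TRUE, degenerate = c("ffill", "sentinel")) {
  stopifnot(inherits(es, "epoch_set"), inherits(ts, "template_set"))
  degenerate <- match.arg(degenerate)
  check_polarity_mode(ts, polarity)
  if (!identical(es$montage$channels, ts$montage$channels)) {
    abort("epoch and template montages differ", class = "microlabel_error")
  }
  win <- make_windows(spec)
  ns <- n_samples(es)
  # window-averaging matrix: [n_samples x n_windows], column w averages the
  # samples of window w
  W <- matrix(0, ns, nrow(win))
  for (w in seq_len(nrow(win))) {
    rg <- window_sample_range(win$start[w], win$end[w], es$sfreq, es$tmin, ns)
    W[rg[1]:rg[2], w] <- 1 / (rg[2] - rg[1] + 1)
  }
  eps <- .Machine$double.eps * es$montage$n_channels * 10
  labels <- matrix(-1L, n_trials(es), nrow(win))
  for (tr in seq_len(n_trials(es))) {
    means <- es$data[tr, , ] %*% W                 # [nc x n_windows]
    centered <- sweep(means, 2, colMeans(means))
    nrm <- sqrt(colSums(centered^2))
    r <- (ts$maps %*% centered) / rep(pmax(nrm, eps), each = nrow(ts$maps))
    score <- if (polarity) r else abs(r)
    lab <- max.col(t(score), ties.method = "first") - 1L
    lab[nrm <= eps] <- -1L
    if (degenerate == "ffill") {
      for (w in seq_along(lab)) {
        if (lab[w] == -1L && w > 1) lab[w] <- lab[w - 1]
      }
    }
    labels[tr, ] <- lab
  }
  label_sequence(labels, win$start, es$classes, ts$names,
                 window = spec, polarity = polarity)
}

#' Restrict a label sequence to an analysis span
#'
#' @param seq A [label_sequence()].
#' @param t_start,t_end Closed span in seconds; windows starting inside it
#'   are kept.
#' @return The restricted `label_sequence`.
#' @export
restrict_windows <- function(seq, t_start, t_end) {
  keep <- which(seq$window_starts >= t_start - 1e-9 &
                  seq$window_starts <= t_end + 1e-9)
  if (!length(keep)) {
    abort("no windows inside the requested span", class = "microlabel_error")
  }
  label_sequence(seq$labels[, keep, drop = FALSE], seq$window_starts[keep],
                 seq$classes, seq$template_names, window = seq$window,
                 polarity = seq$polarity)
}
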