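#' Electrode montage
#'
#' An ordered set of channel names defining the dimensionality and ordering of
#' every scalp map handled by the package. At least two channels are required:
#' with a single channel the average reference annihilates the signal and
#' global field power is identically zero.
#'
#' @param channels Character vector of unique channel names, in scalp-map
#'   column order.
#' @return An object of class `montage` with elements `channels` and
#'   `n_channels`.
#' @examples
#' montage(c("Fz", "Cz", "Pz", "Oz"))
#' @export
montage <- function(channels) {
  channels <- as.character(channels)
  if (length(channels) < 2) {
    abort("a montage needs at least 2 channels", class = "microlabel_error")
  }
  if (anyDuplicated(channels)) {
    abort("montage channel names must be unique", class = "microlabel_error")
  }
  structure(
    list(channels = channels, n_channels = length(channels)),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", x$n_channels, " channels: ",
      paste(head(x$channels, 6), collapse = ", "),
      if (x$n_channels > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' The 32-channel 10-10 montage used by the oddball recordings
#'
#' @return A [montage()] with the 32 electrode positions of the international
#'   10-10 system used throughout the package's default simulations.
#' @export
montage_10_10_32 <- function() {
  montage(c(
    "Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "F9", "F10",
    "FC1", "FC2", "FC5", "FC6", "Cz", "C3", "C4", "T7", "T8",
    "CP1", "CP2", "CP5", "CP6", "Pz", "P3", "P4", "P7", "P8",
    "P9", "P10", "Oz", "O1", "O2"
  ))
}

# subtract the channel mean from a map (column vector semantics)
center_map <- function(x) x - mean(x)

# zero-mean, unit-L2 version of a map; error on degenerate input
normalize_map <- function(x, what = "map") {
  x <- center_map(x)
  nrm <- sqrt(sum(x^2))
  if (nrm < .Machine$double.eps * length(x) * 10) {
    abort(paste0(what, " is constant across channels (zero after average reference)"),
          class = "microlabel_error")
  }
  x / nrm
}

#' Microstate template set
#'
#' A set of scalp-potential template maps. Maps are stored average-referenced
#' (zero channel mean) and L2-normalized; a polarity-expanded set of `2k`
#' signed maps stores the base maps followed by their exact negations, so that
#' `maps[base_k + i, ] == -maps[i, ]` holds to machine precision.
#'
#' @param maps Numeric matrix, templates in rows, channels in columns.
#' @param names Character vector of unique template names, one per row.
#' @param montage A [montage()] whose channels match the columns of `maps`.
#' @param polarity_expanded Logical; `TRUE` when `maps` already holds the
#'   signed pairs (second half the exact negation of the first).
#' @param normalized Logical; set `FALSE` to have the constructor re-normalize
#'   with a warning when rows are not already zero-mean unit-norm.
#' @return An object of class `template_set` with elements `maps`, `names`,
#'   `base_k`, `polarity_expanded`, `montage`.
#' @seealso [expand_polarity()], [read_templates()]
#' @export
template_set <- function(maps, names, montage, polarity_expanded = FALSE,
                         normalized = FALSE) {
  maps <- as.matrix(maps)
  stopifnot(is.numeric(maps))
  if (ncol(maps) != montage$n_channels) {
    abort("template map columns do not match the montage", class = "microlabel_error")
  }
  names <- as.character(names)
  if (length(names) != nrow(maps)) {
    abort("one name per template map is required", class = "microlabel_error")
  }
  if (anyDuplicated(names)) {
    abort("template names must be unique", class = "microlabel_error")
  }
  if (polarity_expanded && nrow(maps) %% 2 != 0) {
    abort("a polarity-expanded set must have an even number of maps",
          class = "microlabel_error")
  }
  base_k <- if (polarity_expanded) nrow(maps) / 2 else nrow(maps)

  norm_one <- function(i) normalize_map(maps[i, ], what = paste0("template '", names[i], "'"))
  if (polarity_expanded) {
    # normalize the base half, derive the negations to keep pairing exact
    base <- t(vapply(seq_len(base_k), norm_one, numeric(ncol(maps))))
    candidate <- rbind(base, -base)
  } else {
    candidate <- t(vapply(seq_len(nrow(maps)), norm_one, numeric(ncol(maps))))
  }
  dev <- max(abs(candidate - maps))
  if (dev > 1e-12) {
    # genuinely un-normalized input; replace (already-normalized maps are
    # kept bitwise so that file round trips are exact)
    if (!normalized && dev > 1e-8) {
      warn("template maps were not average-referenced/unit-norm (or pairs not exact negations); re-normalized")
    }
    maps <- candidate
  }
  rownames(maps) <- names
  colnames(maps) <- montage$channels
  structure(
    list(maps = maps, names = names, base_k = base_k,
         polarity_expanded = polarity_expanded, montage = montage),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> ", nrow(x$maps), " maps (base_k = ", x$base_k,
      if (x$polarity_expanded) ", polarity-expanded" else "",
      ") over ", x$montage$n_channels, " channels\n", sep = "")
  cat("  names: ", paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.template_set <- function(x, ...) {
  tb <- as_tibble(x$maps, .name_repair = "minimal")
  dplyr::bind_cols(tibble(template = x$names), tb)
}

#' Epoched EEG recordings
#'
#' A set of fixed-length EEG epochs time-locked to stimulus onset, stored as a
#' `trials x channels x samples` array in microvolts.
#'
#' @param data Numeric 3-d array `[n_trials, n_channels, n_samples]` (uV).
#' @param sfreq Sampling frequency in samples per second.
#' @param tmin Epoch start time in seconds relative to stimulus onset
#'   (non-positive; stimulus onset must fall inside the epoch).
#' @param classes Character vector of per-trial stimulus classes; exactly two
#'   distinct values are expected ("standard"/"target" in the oddball task).
#'   A different number of distinct values triggers a warning, not an error.
#' @param montage A [montage()] matching the channel dimension.
#' @param ground_truth Optional integer matrix `[n_trials, n_samples]` of
#'   planted signed-template labels (synthetic sessions only).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, tmin, classes, montage, ground_truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (d[2] != montage$n_channels) {
    abort("epoch channel dimension does not match the montage", class = "microlabel_error")
  }
  if (length(classes) != d[1]) {
    abort("one class per trial is required", class = "microlabel_error")
  }
  classes <- as.character(classes)
  if (length(unique(classes)) != 2) {
    warn(paste0("expected exactly 2 stimulus classes, found ", length(unique(classes))))
  }
  sfreq <- as.numeric(sfreq)
  tmin <- as.numeric(tmin)
  stopifnot(sfreq > 0)
  if (!(tmin <= 0 && tmin + d[3] / sfreq > 0)) {
    abort("stimulus onset (t = 0) must lie inside the epoch", class = "microlabel_error")
  }
  if (!is.null(ground_truth)) {
    stopifnot(is.matrix(ground_truth), nrow(ground_truth) == d[1],
              ncol(ground_truth) == d[3])
  }
  structure(
    list(data = data, sfreq = sfreq, tmin = tmin, classes = classes,
         montage = montage, ground_truth = ground_truth),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cls <- table(x$classes)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$sfreq, " Hz, tmin = ", x$tmin, " s\n", sep = "")
  cat("  classes: ", paste(names(cls), cls, sep = " = ", collapse = ", "),
      if (!is.null(x$ground_truth)) "  [ground truth present]" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(es) dim(es$data)[1]
n_samples <- function(es) dim(es$data)[3]

#' Per-sample time axis of an epoch set
#'
#' @param es An [epoch_set()].
#' @return Numeric vector of sample times in seconds relative to stimulus
#'   onset.
#' @export
epoch_times <- function(es) es$tmin + (seq_len(n_samples(es)) - 1) / es$sfreq

#' Re-reference epochs to the average reference
#'
#' Subtracts, at every sample of every trial, the mean across channels, so
#' each instantaneous scalp map has zero channel mean. Idempotent, and leaves
#' all inter-channel differences untouched.
#'
#' @param es An [epoch_set()].
#' @return The `epoch_set` with average-referenced data.
#' @export
average_reference <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  m <- apply(es$data, c(1, 3), mean)              # [trials x samples]
  nc <- dim(es$data)[2]
  es$data <- es$data - aperm(
    array(m, c(dim(m), nc)), c(1, 3, 2)
  )
  es
}

#' Subset trials of an epoch set or label sequence
#'
#' @param x An [epoch_set()] or `label_sequence`.
#' @param idx Integer vector of trial indices to keep (order preserved).
#' @return An object of the same class restricted to those trials.
#' @export
subset_trials <- function(x, idx) UseMethod("subset_trials")

#' @export
subset_trials.epoch_set <- function(x, idx) {
  x$data <- x$data[idx, , , drop = FALSE]
  x$classes <- x$classes[idx]
  if (!is.null(x$ground_truth)) x$ground_truth <- x$ground_truth[idx, , drop = FALSE]
  x
}

#' @export
subset_trials.label_sequence <- function(x, idx) {
  x$labels <- x$labels[idx, , drop = FALSE]
  x$classes <- x$classes[idx]
  x
}

#' Balance stimulus classes by subsampling the majority class
#'
#' The oddball paradigm presents many more standard than target stimuli
#' (320 vs 80 in the reference design), so before classification a random
#' subset of the majority class is drawn, without replacement, to match the
#' minority count. Trial order is otherwise preserved.
#'
#' @param x An [epoch_set()] or `label_sequence`.
#' @param seed Integer seed for the subsample draw.
#' @return An object of the same class with equal class counts.
#' @export
balance_trials <- function(x, seed = 1L) {
  classes <- x$classes
  tab <- table(classes)
  if (length(tab) != 2 || any(tab == 0)) {
    abort("balance_trials needs two non-empty classes", class = "microlabel_error")
  }
  n_min <- min(tab)
  keep <- withr::with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      idx <- which(classes == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  subset_trials(x, sort(keep))
}

#' Label sequence
#'
#' The one-dimensional encoding of an epoch set: per trial and analysis
#' window, one integer microstate label. Labels run from 0 to
#' `n_templates - 1` (0 to 9 for a polarity-expanded 5-template set: 0-4 the
#' "+" maps in template order, 5-9 their "-" partners); `-1` is the sentinel
#' for a degenerate window that could not be labeled.
#'
#' @param labels Integer matrix `[n_trials, n_windows]`.
#' @param window_starts Window start times in seconds (strictly increasing,
#'   constant step).
#' @param classes Per-trial stimulus class.
#' @param template_names Character vector naming the label integers in order.
#' @param window Optional [window_spec()] echo.
#' @param polarity Logical echo of the labeling mode.
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(labels, window_starts, classes, template_names,
                           window = NULL, polarity = NA) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  dimnames(labels) <- NULL
  if (ncol(labels) != length(window_starts)) {
    abort("one window start per label column is required", class = "microlabel_error")
  }
  if (nrow(labels) != length(classes)) {
    abort("one class per trial is required", class = "microlabel_error")
  }
  rng <- range(labels)
  if (rng[1] < -1L || rng[2] >= length(template_names)) {
    abort("labels out of 0..n_templates-1 range (or sentinel -1)", class = "microlabel_error")
  }
  if (length(window_starts) > 1) {
    steps <- diff(window_starts)
    if (any(steps <= 0) || diff(range(steps)) > 1e-9) {
      abort("window starts must be strictly increasing with constant step",
            class = "microlabel_error")
    }
  }
  structure(
    list(labels = labels, window_starts = as.numeric(window_starts),
         classes = as.character(classes), template_names = template_names,
         window = window, polarity = polarity),
    class = "label_sequence"
  )
}

#' @export
print.label_sequence <- function(x, ...) {
  cat("<label_sequence> ", nrow(x$labels), " trials x ", ncol(x$labels),
      " windows, ", length(x$template_names), " templates",
      if (isTRUE(x$polarity)) " (polarity-considered)" else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn label_sequence Long-format view: one row per trial and window,
#'   with the integer label and its template name.
#' @param x,... For `as_tibble`: a `label_sequence` and ignored dots.
#' @export
as_tibble.label_sequence <- function(x, ...) {
  nw <- ncol(x$labels)
  nt <- nrow(x$labels)
  lab <- as.vector(x$labels)        # column-major: trial fastest
  tibble(
    trial = rep(seq_len(nt), times = nw),
    class = rep(x$classes, times = nw),
    time = rep(x$window_starts, each = nt),
    label = lab,
    template = ifelse(lab >= 0, x$template_names[lab + 1L], NA_character_)
  )
}
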