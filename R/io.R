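#' Read a microstate template set from TSV
#'
#' Expects a header row `name<TAB>ch1<TAB>...<TAB>chN` and one template per
#' row. Maps are re-normalized (zero channel mean, unit L2 norm) on read, with
#' a warning when the stored rows were not already normalized. A set whose
#' second half is the exact negation of its first half is recognized as
#' polarity-expanded.
#'
#' @param path Path to the TSV file.
#' @return A [template_set()].
#' @export
read_templates <- function(path) {
  # base parser: strtod is correctly rounded, so the round trip is exact
  tb <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(tb)[1], "name")) {
    abort("template TSV must start with a 'name' column", class = "microlabel_error")
  }
  if (anyDuplicated(tb$name)) {
    abort("duplicate template names in file", class = "microlabel_error")
  }
  maps <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(maps) <- "double"
  if (anyNA(maps)) {
    abort("template TSV has missing/short rows", class = "microlabel_error")
  }
  mnt <- montage(names(tb)[-1])
  k <- nrow(maps)
  expanded <- FALSE
  if (k %% 2 == 0 && k >= 2) {
    half <- k / 2
    if (max(abs(maps[half + seq_len(half), , drop = FALSE] +
                maps[seq_len(half), , drop = FALSE])) < 1e-8) {
      expanded <- TRUE
    }
  }
  template_set(maps, tb$name, mnt, polarity_expanded = expanded)
}

#' Write a template set to TSV
#'
#' Writes all rows (including derived negative-polarity rows of an expanded
#' set) at full double precision, so `read_templates(write_templates(ts))`
#' reproduces the maps elementwise.
#'
#' @param ts A [template_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(ts, path) {
  stopifnot(inherits(ts, "template_set"))
  readr::write_tsv(as_tibble(ts) %>% rename(name = "template"), path)
  invisible(path)
}

epochs_meta_path <- function(path) paste0(path, ".meta.json")

#' Read / write epoched EEG
#'
#' The epoch container is a long-format TSV (`trial`, `channel`, `sample`,
#' `value`, one row per trial/channel/sample; `sample` is a 1-based index)
#' with a JSON sidecar `<path>.meta.json` carrying `sfreq`, `tmin`,
#' `channels`, `classes` and, optionally, planted ground-truth label tracks.
#' The round trip is lossless for data, sampling metadata and classes.
#'
#' @param path Path of the TSV container.
#' @return `read_epochs` returns an [epoch_set()]; `write_epochs` returns
#'   `path` invisibly.
#' @export
read_epochs <- function(path) {
  meta_path <- epochs_meta_path(path)
  if (!file.exists(meta_path)) {
    abort(paste0("epoch sidecar not found: ", meta_path), class = "microlabel_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("sfreq", "tmin", "channels", "classes")) {
    if (is.null(meta[[field]])) {
      abort(paste0("epoch container is missing required attribute '", field, "'"),
            class = "microlabel_error")
    }
  }
  tb <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(tb), c("trial", "channel", "sample", "value"))) {
    abort("epoch TSV must have columns trial, channel, sample, value",
          class = "microlabel_error")
  }
  nt <- max(tb$trial); nc <- max(tb$channel); ns <- max(tb$sample)
  if (nrow(tb) != nt * nc * ns) {
    abort("epoch TSV is not a complete trial x channel x sample grid",
          class = "microlabel_error")
  }
  dat <- array(NA_real_, c(nt, nc, ns))
  dat[cbind(tb$trial, tb$channel, tb$sample)] <- tb$value
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    gt <- if (is.matrix(g)) g else matrix(as.integer(unlist(g)), nrow = nt, byrow = TRUE)
    storage.mode(gt) <- "integer"
  }
  epoch_set(dat, sfreq = meta$sfreq, tmin = meta$tmin,
            classes = as.character(meta$classes),
            montage = montage(meta$channels), ground_truth = gt)
}

#' @rdname read_epochs
#' @param es An [epoch_set()].
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$data)
  grid <- expand.grid(trial = seq_len(d[1]), channel = seq_len(d[2]),
                      sample = seq_len(d[3]))
  tb <- tibble(trial = grid$trial, channel = grid$channel,
               sample = grid$sample, value = as.vector(es$data))
  readr::write_tsv(tb, path)
  meta <- list(sfreq = es$sfreq, tmin = es$tmin,
               channels = es$montage$channels, classes = es$classes)
  if (!is.null(es$ground_truth)) {
    meta$ground_truth <- lapply(seq_len(d[1]), function(i) es$ground_truth[i, ])
  }
  jsonlite::write_json(meta, epochs_meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write label sequences
#'
#' One row per trial; the TSV header holds window start times in
#' milliseconds. A JSON sidecar `<path>.meta.json` stores template names,
#' per-trial classes and the labeling mode.
#'
#' @param path Path of the label TSV.
#' @return `read_labels` returns a [label_sequence()]; `write_labels` returns
#'   `path` invisibly.
#' @export
read_labels <- function(path) {
  meta <- jsonlite::read_json(epochs_meta_path(path), simplifyVector = TRUE)
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_integer()),
                        progress = FALSE)
  starts_ms <- as.numeric(names(tb))
  label_sequence(as.matrix(tb), starts_ms / 1000,
                 classes = as.character(meta$classes),
                 template_names = meta$template_names,
                 polarity = isTRUE(meta$polarity))
}

#' @rdname read_labels
#' @param seq A [label_sequence()].
#' @export
write_labels <- function(seq, path) {
  stopifnot(inherits(seq, "label_sequence"))
  tb <- as_tibble(as.data.frame(seq$labels),
                  .name_repair = ~ format(seq$window_starts * 1000, trim = TRUE))
  readr::write_tsv(tb, path)
  jsonlite::write_json(
    list(template_names = seq$template_names, classes = seq$classes,
         polarity = isTRUE(seq$polarity)),
    epochs_meta_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
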