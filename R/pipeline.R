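#' End-to-end pipeline on a synthetic or imported session
#'
#' Runs the full analysis chain: simulate (or load) epochs, polarity-expand
#' the templates, label on the coarse (100 ms / 25 ms) and fine
#' (10 ms / 1 ms) window grids, balance trials, compute occurrence-frequency
#' maps and their target-minus-standard difference, classify with nested
#' cross-validation, and score the topographic reconstruction by DISS.
#' Optionally computes the temporal generalization matrix. Every artifact is
#' written under `out_dir` together with a manifest carrying the seed and a
#' configuration fingerprint, making reruns reproducible and identifiable.
#'
#' @param cfg A [sim_config()] (the session to simulate), or an
#'   [epoch_set()] plus `templates` for imported data.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param templates Base [template_set()] when `cfg` is an `epoch_set`;
#'   ignored for a `sim_config` (its own templates are used).
#' @param model Model family for classification.
#' @param freq_spec,classif_spec Window specifications of the two grids.
#' @param run_tgm Also compute the temporal generalization matrix on the
#'   coarse grid (slower).
#' @param seed Global seed for balancing, folds and fits.
#' @return A result bundle (list): `session`, `templates_signed`,
#'   `seq_coarse`, `seq_fine`, `freq`, `freq_diff`, `classif`, `fidelity`,
#'   optional `tgm`, and `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, templates = NULL,
                         model = "random_forest",
                         freq_spec = NULL, classif_spec = NULL,
                         run_tgm = FALSE, seed = 1L) {
  if (inherits(cfg, "sim_config")) {
    session <- simulate_session(cfg)
    es <- session$epochs
    base_ts <- cfg$template_set
  } else if (inherits(cfg, "epoch_set")) {
    if (is.null(templates)) {
      abort("an epoch_set input needs a base template_set", class = "microlabel_error")
    }
    session <- list(epochs = cfg, config = NULL)
    es <- cfg
    base_ts <- templates
  } else {
    abort("cfg must be a sim_config or epoch_set", class = "microlabel_error")
  }
  tmax <- es$tmin + n_samples(es) / es$sfreq
  if (is.null(freq_spec)) freq_spec <- window_spec(es$tmin, tmax, 0.100, 0.025)
  if (is.null(classif_spec)) {
    classif_spec <- window_spec(0, min(0.4, tmax), 0.010, 0.001)
  }
  ts_signed <- expand_polarity(base_ts)

  seq_coarse <- label_epochs(es, ts_signed, freq_spec, polarity = TRUE)
  seq_fine <- label_epochs(es, ts_signed, classif_spec, polarity = TRUE)
  seq_fine_bal <- balance_trials(seq_fine, seed = seed)

  freq <- occurrence_frequency(seq_coarse)
  freq_diff <- frequency_difference(freq)
  classif <- nested_cv_classify(seq_fine_bal, family = model, seed = seed)
  fidelity <- reconstruction_fidelity(es, seq_coarse, ts_signed, freq_spec)
  tgm <- if (run_tgm) {
    temporal_generalization(balance_trials(seq_coarse, seed = seed), seed = seed)
  }
  # cluster statistics need several sessions (participants); use
  # label_cluster_stats() on a list of per-participant sequences

  manifest <- list(
    package_version = as.character(utils::packageVersion("microlabel")),
    seed = seed,
    model = model,
    config_hash = rlang::hash(list(
      if (inherits(cfg, "sim_config")) cfg else dim(es$data),
      freq_spec, classif_spec, model, seed
    )),
    n_trials = n_trials(es),
    n_windows_coarse = ncol(seq_coarse$labels),
    n_windows_fine = ncol(seq_fine$labels)
  )

  bundle <- list(session = session, templates_signed = ts_signed,
                 seq_coarse = seq_coarse, seq_fine = seq_fine_bal,
                 freq = freq, freq_diff = freq_diff, classif = classif,
                 fidelity = fidelity, tgm = tgm, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_templates(ts_signed, file.path(out_dir, "templates.tsv"))
    write_labels(seq_fine_bal, file.path(out_dir, "labels_fine.tsv"))
    write_labels(seq_coarse, file.path(out_dir, "labels_coarse.tsv"))
    readr::write_tsv(freq, file.path(out_dir, "occurrence_frequency.tsv"))
    readr::write_tsv(freq_diff, file.path(out_dir, "frequency_difference.tsv"))
    readr::write_tsv(as_tibble(fidelity), file.path(out_dir, "diss.tsv"))
    jsonlite::write_json(
      list(manifest = manifest, glance = glance(classif),
           folds = classif$folds %>% select(-"params")),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA
    )
    if (!is.null(tgm)) readr::write_tsv(tidy(tgm), file.path(out_dir, "tgm.tsv"))
  }
  bundle
}
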