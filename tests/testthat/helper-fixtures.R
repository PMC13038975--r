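# Shared fixtures, built in code at test time.

tiny_montage <- function(n = 4) montage(paste0("ch", seq_len(n)))

# orthogonal unit zero-mean maps for hand-checkable labeling tests
tiny_templates <- function(k = 3, nc = 8, seed = 42) {
  random_templates(tiny_montage(nc), k = k, seed = seed)
}

# small synthetic epoch set with arbitrary (non-microstate) content
tiny_epochs <- function(n_trials = 6, nc = 4, ns = 50, sfreq = 100,
                        tmin = -0.1, seed = 7) {
  dat <- withr::with_seed(seed, array(rnorm(n_trials * nc * ns), c(n_trials, nc, ns)))
  classes <- rep(c("standard", "target"), length.out = n_trials)
  epoch_set(dat, sfreq = sfreq, tmin = tmin, classes = classes,
            montage = tiny_montage(nc))
}

# quick simulated session at reduced scale
quick_session <- function(seed = 1, n_standard = 20, n_target = 10,
                          noise_sd_uv = 0, profile = NULL, base_k = 5,
                          sfreq = 500, tmax = 0.6, ...) {
  mnt <- tiny_montage(12)
  ts <- random_templates(mnt, k = base_k, seed = seed)
  if (is.null(profile)) profile <- oddball_prior_profile(base_k, tmin = -0.2, tmax = tmax)
  cfg <- sim_config(mnt, ts, profile, n_standard = n_standard,
                    n_target = n_target, sfreq = sfreq, tmin = -0.2,
                    tmax = tmax, noise_sd_uv = noise_sd_uv, seed = seed, ...)
  simulate_session(cfg)
}

# independent Pearson-correlation argmax oracle for winner-take-all labels
oracle_label <- function(map, ts, polarity) {
  r <- unname(apply(ts$maps, 1, function(tm) stats::cor(map, tm)))
  if (polarity) which.max(r) - 1L else which.max(abs(r)) - 1L
}

# brute-force pairwise AUC with ties counted 1/2
oracle_auc <- function(scores, truth, positive = "target") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# direct Benjamini-Hochberg step-up, written independently of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
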