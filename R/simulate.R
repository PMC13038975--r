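#' Smooth random base templates
#'
#' Generates `k` synthetic base template maps: Gaussian channel noise smoothed
#' along the channel order, pairwise orthogonalized (Gram-Schmidt), then
#' average-referenced and unit-normalized. These stand in for canonical
#' microstate classes A-E, whose published template values are not available;
#' they are synthetic fixtures, not estimates of the canonical maps.
#'
#' @param montage A [montage()].
#' @param k Number of base maps.
#' @param seed Integer seed.
#' @param smooth Half-width (in channel-order units) of the Gaussian kernel
#'   used to induce spatial smoothness.
#' @return A base (non-expanded) [template_set()] named `A`, `B`, ...
#' @export
random_templates <- function(montage, k = 5, seed = 1L, smooth = 3) {
  nc <- montage$n_channels
  stopifnot(k >= 1, k <= nc - 1)
  idx <- seq_len(nc)
  kern <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * smooth^2)))
  maps <- withr::with_seed(seed, {
    raw <- matrix(rnorm(k * nc), k, nc) %*% kern
    for (i in seq_len(k)) {
      v <- center_map(raw[i, ])
      if (i > 1) {
        for (j in seq_len(i - 1)) v <- v - sum(v * raw[j, ]) * raw[j, ]
      }
      raw[i, ] <- v / sqrt(sum(v^2))
    }
    raw
  })
  template_set(maps, LETTERS[seq_len(k)], montage, normalized = TRUE)
}

# --- class-conditional label prior profiles -------------------------------

check_profile_matrix <- function(m, n_breaks, k2, what) {
  if (!is.matrix(m) || nrow(m) != n_breaks - 1 || ncol(m) != k2) {
    abort(paste0(what, " prior must be [n_intervals x 2*base_k]"),
          class = "microlabel_error")
  }
  if (any(m < 0) || max(abs(rowSums(m) - 1)) > 1e-8) {
    abort(paste0(what, " prior rows must be nonnegative and sum to 1"),
          class = "microlabel_error")
  }
}

#' Piecewise-constant label prior profiles
#'
#' A prior profile assigns, for each stimulus class and epoch time, a
#' categorical distribution over the `2k` signed template labels; microstate
#' segments drawn at time `t` take their label from the class's distribution
#' at `t`. `prior_profile()` builds one from explicit interval matrices;
#' the helpers construct the study conditions:
#'
#' * `oddball_prior_profile()` - standard class near-uniform at all times;
#'   target class biased toward C+/E+ in 0-200 ms, C-/D-/E- in 200-400 ms,
#'   and back to C+/E+ after 500 ms, emulating the N200/P300-linked label
#'   dynamics of visual oddball targets.
#' * `uniform_prior_profile()` - identical uniform priors for both classes
#'   (a null generator with no class effect).
#' * `polarity_contrast_profile()` - both classes share the same distribution
#'   over base maps, but the standard class occupies the "+" block and the
#'   target class the "-" block, so the classes differ only by topographic
#'   polarity.
#'
#' @param breaks Increasing time boundaries (seconds) covering the epoch.
#' @param standard,target Matrices `[length(breaks)-1, 2k]`, rows summing to 1.
#' @param base_k Number of base templates (signed label space has `2*base_k`).
#' @param tmin,tmax Epoch limits in seconds.
#' @param boost Weight ratio of boosted to non-boosted labels in the target
#'   intervals of the oddball profile.
#' @return An object of class `prior_profile`.
#' @export
prior_profile <- function(breaks, standard, target) {
  breaks <- as.numeric(breaks)
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  k2 <- ncol(standard)
  check_profile_matrix(standard, length(breaks), k2, "standard")
  check_profile_matrix(target, length(breaks), k2, "target")
  structure(list(breaks = breaks, standard = standard, target = target, k2 = k2),
            class = "prior_profile")
}

#' Label distribution of a prior profile at one time point
#'
#' @param profile A [prior_profile()].
#' @param class `"standard"` or `"target"`.
#' @param t Time in seconds.
#' @return Probability vector over the `2k` signed labels.
#' @export
prior_at <- function(profile, class, t) {
  i <- findInterval(t, profile$breaks, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(profile[[class]]))
  profile[[class]][i, ]
}

#' @rdname prior_profile
#' @export
oddball_prior_profile <- function(base_k = 5, tmin = -0.2, tmax = 1.0, boost = 4) {
  k2 <- 2L * base_k
  breaks <- c(tmin, 0, 0.2, 0.4, 0.5, tmax)
  uni <- matrix(1 / k2, length(breaks) - 1, k2)
  boosted_row <- function(idx) {
    w <- rep(1, k2); w[idx] <- boost; w / sum(w)
  }
  # label order: base maps "+" (1..k), then "-" partners (k+1..2k);
  # C = 3rd, D = 4th, E = 5th base map
  stopifnot(base_k >= 5)
  tgt <- uni
  tgt[2, ] <- boosted_row(c(3, 5))                       # 0-200 ms: C+, E+
  tgt[3, ] <- boosted_row(base_k + c(3, 4, 5))           # 200-400 ms: C-, D-, E-
  tgt[5, ] <- boosted_row(c(3, 5))                       # after 500 ms: C+, E+
  prior_profile(breaks, standard = uni, target = tgt)
}

#' @rdname prior_profile
#' @export
uniform_prior_profile <- function(base_k = 5, tmin = -0.2, tmax = 1.0) {
  k2 <- 2L * base_k
  uni <- matrix(1 / k2, 1, k2)
  prior_profile(c(tmin, tmax), standard = uni, target = uni)
}

#' @rdname prior_profile
#' @export
polarity_contrast_profile <- function(base_k = 5, tmin = -0.2, tmax = 1.0) {
  k2 <- 2L * base_k
  std <- matrix(0, 1, k2); std[1, seq_len(base_k)] <- 1 / base_k
  tgt <- matrix(0, 1, k2); tgt[1, base_k + seq_len(base_k)] <- 1 / base_k
  prior_profile(c(tmin, tmax), standard = std, target = tgt)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_session()] needs to generate an oddball EEG
#' session with planted microstate dynamics.
#'
#' @param montage A [montage()].
#' @param template_set Base (non-expanded) [template_set()]; the generator
#'   works in the signed space of `2*base_k` maps.
#' @param prior_profile A [prior_profile()] over the signed labels.
#' @param n_standard,n_target Trial counts per class.
#' @param sfreq Sampling rate (Hz).
#' @param tmin,tmax Epoch limits (seconds) relative to stimulus onset.
#' @param mean_segment_ms Mean microstate segment duration (ms); segment
#'   lengths are geometric at sample resolution with this mean.
#' @param amplitude_uv Mean template amplitude (uV) scaling the envelope.
#' @param envelope `"rectified_sin"` (default) or `"constant"`; the rectified
#'   sinusoid makes global field power wax and wane within a segment without
#'   flipping the topography (polarity lives in the signed map, not in the
#'   envelope).
#' @param envelope_freq Envelope frequency in Hz.
#' @param noise_sd_uv Standard deviation of the additive spatially correlated
#'   Gaussian noise, per channel (uV).
#' @param noise_smoothness Channel-correlation parameter in `[0, 1)`:
#'   neighbouring channels' noise correlates as
#'   `noise_smoothness^|channel distance|`.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(montage, template_set, prior_profile,
                       n_standard = 320, n_target = 80,
                       sfreq = 1000, tmin = -0.2, tmax = 1.0,
                       mean_segment_ms = 80, amplitude_uv = 10,
                       envelope = c("rectified_sin", "constant"),
                       envelope_freq = 10,
                       noise_sd_uv = 5, noise_smoothness = 0.5, seed = 1L) {
  envelope <- match.arg(envelope)
  stopifnot(inherits(template_set, "template_set"), !template_set$polarity_expanded)
  if (prior_profile$k2 != 2L * template_set$base_k) {
    abort("prior profile dimension must equal 2 * base_k", class = "microlabel_error")
  }
  stopifnot(mean_segment_ms > 0, n_target >= 1, n_standard >= n_target,
            noise_smoothness >= 0, noise_smoothness < 1, noise_sd_uv >= 0,
            tmin < 0, tmax > 0, sfreq > 0)
  structure(
    list(montage = montage, template_set = template_set,
         prior_profile = prior_profile, n_standard = n_standard,
         n_target = n_target, sfreq = sfreq, tmin = tmin, tmax = tmax,
         mean_segment_ms = mean_segment_ms, amplitude_uv = amplitude_uv,
         envelope = envelope, envelope_freq = envelope_freq,
         noise_sd_uv = noise_sd_uv, noise_smoothness = noise_smoothness,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default oddball simulation: the study design in synthetic form
#'
#' 32 channels (10-10 montage), 5 smooth random orthogonal base templates,
#' 320 standard / 80 target trials, epochs from -200 to 1000 ms at 1000 Hz,
#' with the oddball target-class label dynamics of [oddball_prior_profile()].
#'
#' @param seed Integer seed (drives both template generation and the session).
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
default_oddball_config <- function(seed = 1L, ...) {
  mnt <- montage_10_10_32()
  ts <- random_templates(mnt, k = 5, seed = seed)
  args <- list(montage = mnt, template_set = ts,
               prior_profile = oddball_prior_profile(), seed = seed)
  do.call(sim_config, modifyList(args, list(...)))
}

# symmetric square root of the channel noise correlation rho^|i-j|
noise_mixing_matrix <- function(nc, rho) {
  if (rho == 0) return(diag(nc))
  C <- outer(seq_len(nc), seq_len(nc), function(i, j) rho^abs(i - j))
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# one piecewise-constant signed-label track of length n_samples (0-based labels)
sample_label_track <- function(n_samples, class, cfg, times) {
  L <- cfg$mean_segment_ms * cfg$sfreq / 1000
  p <- 1 / L                                   # E[1 + geom(p)] = 1/p = L
  track <- integer(n_samples)
  s <- 1L
  while (s <= n_samples) {
    len <- 1L + rgeom(1, p)
    pr <- prior_at(cfg$prior_profile, class, times[s])
    lab <- sample.int(length(pr), 1, prob = pr) - 1L
    e <- min(s + len - 1L, n_samples)
    track[s:e] <- lab
    s <- e + 1L
  }
  track
}

#' Simulate an oddball EEG session with planted microstate dynamics
#'
#' Each trial gets a piecewise-constant signed-template label track (segment
#' lengths geometric at sample resolution; segment labels drawn from the
#' class prior at segment onset). The EEG at each sample is
#' `amplitude * envelope(t) * signed_template_map` plus spatially correlated
#' Gaussian noise; all data are average-referenced. Fully reproducible given
#' the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_session`: list with `epochs` (an [epoch_set()] carrying
#'   ground-truth label tracks) and `config`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nc <- cfg$montage$n_channels
  ns <- round((cfg$tmax - cfg$tmin) * cfg$sfreq)
  ntr <- cfg$n_standard + cfg$n_target
  classes <- c(rep("standard", cfg$n_standard), rep("target", cfg$n_target))
  times <- cfg$tmin + (seq_len(ns) - 1) / cfg$sfreq
  env <- switch(cfg$envelope,
    constant = rep(cfg$amplitude_uv, ns),
    rectified_sin = cfg$amplitude_uv * abs(sin(2 * pi * cfg$envelope_freq * (times - cfg$tmin)))
  )
  signed <- rbind(cfg$template_set$maps, -cfg$template_set$maps)  # [2k x nc]
  mix <- noise_mixing_matrix(nc, cfg$noise_smoothness)

  dat <- array(0, c(ntr, nc, ns))
  gt <- matrix(0L, ntr, ns)
  withr::with_seed(cfg$seed, {
    for (i in seq_len(ntr)) {
      track <- sample_label_track(ns, classes[i], cfg, times)
      gt[i, ] <- track
      sig <- t(signed[track + 1L, , drop = FALSE]) * rep(env, each = nc)  # [nc x ns]
      if (cfg$noise_sd_uv > 0) {
        sig <- sig + mix %*% matrix(rnorm(nc * ns, sd = cfg$noise_sd_uv), nc, ns)
      }
      dat[i, , ] <- sig
    }
  })
  es <- epoch_set(dat, sfreq = cfg$sfreq, tmin = cfg$tmin, classes = classes,
                  montage = cfg$montage, ground_truth = gt)
  es <- average_reference(es)
  structure(list(epochs = es, config = cfg), class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session>\n")
  print(x$epochs)
  invisible(x)
}
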