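---
title: "Polarity-considered microstate labeling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarity-considered microstate labeling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microlabel)
```

## The problem

In an oddball paradigm, rare "target" stimuli elicit event-related
potential components (N200 around 200 ms, P300 around 300 ms) that frequent
"standard" stimuli do not. Detecting these responses in single trials is the
core problem of P300-based brain-computer interfaces. `microlabel`
implements a compact alternative to waveform-based decoding: each epoch of
multichannel EEG is reduced to a one-dimensional sequence of *microstate
labels*, and the standard/target decision is made from that integer sequence
alone.

A microstate label is the index of the template scalp map most similar to
the instantaneous (window-averaged) topography. The package's distinguishing
choice is to treat topographic *polarity* as meaningful: a map `u` and its
negation `-u` receive different labels (`A+` vs `A-`). Classic microstate
analysis deliberately discards this sign; here it is retained because
polarity-inverted topographies track distinct ERP components, and a signed
label space doubles the granularity available to the classifier.

## The pipeline and its model

1. **Window-mean topographies.** Each trial is averaged channel-wise inside
   sliding half-open windows `[start, start + length)`. Two grids are used:
   100 ms windows stepped by 25 ms (75% overlap) for occurrence-frequency
   maps and the temporal generalization matrix, and 10 ms windows stepped by
   1 ms (90% overlap) over 0-400 ms for classification.
2. **Winner-take-all labeling.** The window map is average-referenced and
   correlated (Pearson, across channels) with every template. With polarity
   considered, the argmax of the *signed* correlation over the `2k` signed
   maps wins; with polarity ignored, the argmax of the *absolute*
   correlation over the `k` base maps. Because `cor(u, -T) = -cor(u, T)`,
   the signed winner is always the absolute winner plus the sign decision -
   a property the test suite asserts on random maps.
3. **Integer encoding.** Labels are integers 0 to `2k - 1` (0 to 9 for five
   base maps): 0-4 the base maps in template-file order with positive
   polarity, 5-9 their negations. The encoding order is fixed by file order
   to keep sequences reproducible.
4. **Balancing and classification.** The majority class is subsampled to
   the minority count (320/80 becomes 80/80 in the reference design), and
   nested 5-fold cross-validation (stratified outer folds; inner 5-fold grid
   search maximizing F1; refit on the full outer-training set) produces
   per-fold F1 scores and pooled out-of-fold AUC, with "target" as the
   positive class.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window length / step (frequency grid) | 100 / 25 | ms | the analysis grid for occurrence maps; 75% overlap |
| window length / step (classification) | 10 / 1 | ms | finer temporal precision for decoding; 90% overlap |
| analysis span for classification | 0-400 | ms | where oddball class information peaks |
| base template count `k` | 5 | maps | the conventional microstate inventory (A-E) |
| `n_standard` / `n_target` | 320 / 80 | trials | the oddball session design |
| cluster-forming alpha | 0.05 | two-sided | pointwise t threshold for cluster formation |
| permutations | 1000 | draws | `+1`-corrected Monte Carlo p-values |
| K-means restarts / tol / max_iter | 20 / 1e-6 / 500 | - | clustering controls; the procedure's source leaves them open |

## Template derivation

`gfp_peaks()` samples scalp maps at peaks of the global field power (the
spatial standard deviation of the average-referenced map), at least 10 ms
apart, at most 2,500 per subject. `modified_kmeans()` clusters them
polarity-invariantly: assignment by maximal *squared* spatial correlation,
centroid update as the dominant eigenvector of the assigned maps' scatter
matrix, convergence on the explained variance (mean squared correlation to
the assigned centroid). Design choices the literature leaves open were fixed
as follows:

* **Initialization** - `k` maps sampled without replacement, 20 seeded
  restarts, best explained variance kept.
* **Empty clusters** - reseeded with the currently worst-explained map.
* **Sign convention** - each returned base map is flipped so its largest
  absolute channel loading is positive. Polarity semantics enter only via
  `expand_polarity()`, which appends exact negations (`maps[k + i] ==
  -maps[i]` to machine precision, because the negative half is *derived*,
  never stored independently).
* **Explained variance** - unweighted mean squared correlation; a
  GFP-weighted variant was considered and rejected as the default to keep
  the criterion independent of amplitude scaling.

Template-count variants for sensitivity analyses come from running the
clustering at `k = 4` or `k = 7`, or from `average_centroids()`, which
appends re-normalized means of base-map pairs (A with B, D with E) to form
the seven-map "artificial" variant.

## The synthetic-data generator

The study's recordings are not deposited, so the package ships a generator
whose defaults emulate the published design: 32 channels (10-10 montage),
1,000 Hz, epochs from -200 to 1,000 ms, 320 standard and 80 target trials.
Each trial is a piecewise-constant sequence of signed microstate segments:

* **Segment durations** are geometric at sample resolution (mean 80 ms by
  default) - the memoryless choice, fully characterized by the mean, which
  sits in the range microstate duration statistics usually report.
* **Segment labels** are drawn from a class-conditional, piecewise
  time-varying prior. The standard class is uniform over all 10 signed
  labels at all times. The target class boosts C+/E+ in 0-200 ms, C-/D-/E-
  in 200-400 ms, and C+/E+ again after 500 ms (boosted labels carry 4x the
  weight of the rest), mirroring the N200/P300-linked label dynamics of
  visual oddball targets. The boost magnitude is a desk-scale choice made
  for clear recovery, not an estimate of any published effect size.
* **Amplitude** is a rectified 10 Hz sinusoid scaled to 10 uV: global field
  power waxes and wanes within a segment without ever flipping the
  topography, so polarity remains a property of the signed map.
* **Noise** is Gaussian per channel (default SD 5 uV), spatially correlated
  by mixing with the symmetric square root of a `rho^|i-j|` channel
  correlation matrix (`rho = 0.5`), then average-referenced.
* **Base maps** are smooth random orthogonalized maps, *not* replicas of
  canonical A-E (whose values are not published); they are labelled
  synthetic throughout.

What passing tests on this generator do show: the labeling, statistics,
classification and reconstruction machinery recovers planted structure at
realistic SNR, is calibrated under the null, and respects polarity
contrasts. What they do not show: performance on real EEG, whose noise is
neither Gaussian nor stationary, whose microstate dynamics are not
memoryless, and whose class effects are far subtler than the planted ones.
The published headline numbers (F1 around 0.75-0.83, AUC above 0.8, about
20% polarity improvement) derive from 40 participants' recordings and are
not reproducible from synthetic sessions; the package's acceptance checks
therefore target analytic identities, structural counts and null
calibration instead.

## Statistics

`label_cluster_stats()` compares time-resolved one-hot label averages
between classes across participants. The phrase "shuffling restricted to
the temporal dimension" admits more than one reading; the default null is
participant-level random sign flips of whole difference series - the
standard cluster-permutation scheme, exact for symmetric null distributions
and preserving temporal autocorrelation - with random per-participant
circular time shifts available as `scheme = "circshift"` for the literal
reading. Cluster p-values use the `+1`-corrected estimate
`(1 + #[null >= obs]) / (1 + n_perm)`, so no cluster can report p = 0.
Benjamini-Hochberg correction is applied to the *cluster-level* p-values
pooled across all labels (applying it pointwise was the other candidate;
cluster-level was chosen because clusters are the inferential unit).
Windows with zero pointwise variance have no defined t statistic; they are
excluded from cluster formation and counted in the result's metadata.

## Classification models

Five families are built in: SVM (`e1071`), Random Forest (`ranger`),
L2-regularized logistic regression (`glmnet`), gradient boosting
(`xgboost`), and an unsupervised k-means baseline. The SVM grid follows the
published search space (C in 0.01-100, linear/rbf/sigmoid kernels, gamma
scale/auto/1, with the scikit-learn conventions for `scale` and `auto`);
the other grids are modest package defaults, fully overridable, because the
original search spaces are not published. The k-means baseline fits two
clusters on training features, maps each to its majority training class
(forcing a bipartition when both majorities coincide), and scores by signed
centroid-distance difference - it has no access to labels during fitting
and sits at chance by construction, which the tests assert.

Features are the raw ordinal integer sequences. A one-hot representation
was considered; the ordinal coding was kept as the faithful reading of
"encoded as integers", with the arbitrary-order caveat acknowledged: any
information the models extract from integer *order* is an artifact of the
encoding, which is exactly why the tree ensembles (invariant to monotone
feature maps only, not to permutations) are the interesting comparison.
Degenerate (zero-variance) windows are labeled by forward fill; a remaining
leading sentinel is imputed with the training-set modal label of that
window, keeping feature vectors fixed-length without test-set leakage.

AUC is computed on the pooled out-of-fold scores (per-fold AUC on 16 test
trials per class would be too noisy); per-fold F1 is averaged, matching the
published evaluation. The temporal generalization matrix trains at each
interior window on the labels of three consecutive windows and tests at
every interior position, with the boundary windows excluded rather than
padded; the inner hyperparameter search runs per training window by
default (`hyper = "global"` reuses the first window's choice).

## Reconstruction and DISS

`reconstruct_topographies()` forms each window's map as the one-hot-average
weighted sum of template maps; `diss()` scores it against the grand-averaged
EEG: the Euclidean distance between L2-normalized maps, 0 for identical
configurations, 2 for polarity-inverted ones, equal to `sqrt(2 - 2r)` with
`r` the spatial correlation. Both maps are channel-mean-subtracted before
normalization - the displayed formula does not subtract means, but every
map in this pipeline is already average-referenced, and centering makes the
measure well-defined for raw imports (`center = FALSE` recovers the plain
convention). Grand averaging across participants takes the unweighted mean
of participant means, so each participant counts equally
(`pooled = TRUE` switches to trial-pooled averaging). Windows whose grand
average is numerically zero (possible when trials split between a template
and its negation) are flagged and excluded from summary means rather than
producing an undefined DISS.

## Numerical conventions

* Time is in seconds internally; the sample index of time `t` is
  `round((t - tmin) * sfreq) + 1`, and windows are half-open, so adjacent
  windows never share samples at equal length and step.
* Correlation ties in winner-take-all labeling go to the lowest template
  index (deterministic).
* Stored template maps are zero-mean and unit-norm; maps already normalized
  to within 1e-12 are kept bitwise so file round trips are exact.
* All stochastic steps (simulation, balancing, fold assignment, restarts,
  permutations) take explicit seeds, and results echo them.

## Problem sizes

The test suite and the reproduction script run at desk scale by design:
null-calibration checks use 100 + 100 trials over 10 generator seeds;
type-I-error calibration uses 200 replicates of 12 participants by 40
windows at 500 permutations; template-recovery checks use 2,000 maps at 20
restarts; polarity-contrast checks use 40 + 40 trials over 5 seeds. These
sizes were chosen as the smallest at which the binomial/Monte-Carlo error
of each check is comfortably below its acceptance band.

## Known limitations

* Epoched input only: GFP peak extraction treats epochs as a concatenation
  of independent segments, standing in for the continuous recordings the
  original template-derivation procedure used (peaks never span trial
  boundaries, but slow dynamics across trials are invisible).
* No CatBoost family: the comparison covers the four supervised families
  with R implementations plus the k-means baseline.
* No temporal smoothing or minimum-duration relabeling of sequences, no
  threshold-free cluster enhancement, and no spatial (channel-level)
  clustering - temporal clusters only.
* The epoch container is a long-format TSV with a JSON sidecar; it is
  lossless and diff-friendly but not suited to very large recordings.
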