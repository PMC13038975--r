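test_that("gfp is the spatial standard deviation of the map", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(rep(3.7, 8)), 0)
  u <- rnorm(16)
  expect_equal(gfp(2 * u), 2 * gfp(u), tolerance = 1e-12)
  expect_equal(gfp(u + 5), gfp(u), tolerance = 1e-12)
})

test_that("gfp_peaks finds separated strict local maxima and caps the count", {
  # craft one trial whose GFP series is 0,1,0,1,0: channels (+a,-a)
  a <- c(0, 1, 0, 1, 0)
  dat <- array(0, c(1, 2, 5))
  dat[1, 1, ] <- a
  dat[1, 2, ] <- -a
  es <- suppressWarnings(epoch_set(dat, 1000, -0.001, "standard", tiny_montage(2)))
  pk <- suppressWarnings(gfp_peaks(es, min_dist_ms = 1, n_per_subject = 10))
  expect_equal(nrow(pk), 2)

  # monotone GFP: no interior maximum anywhere
  dat[1, 1, ] <- 1:5
  dat[1, 2, ] <- -(1:5)
  es2 <- suppressWarnings(epoch_set(dat, 1000, -0.001, "standard", tiny_montage(2)))
  expect_error(gfp_peaks(es2, min_dist_ms = 1), "no GFP local maxima")

  # subsampling to n_per_subject, seeded
  ses <- quick_session(seed = 2, n_standard = 10, n_target = 5, noise_sd_uv = 3)
  pk1 <- gfp_peaks(ses$epochs, min_dist_ms = 10, n_per_subject = 50, seed = 4)
  pk2 <- gfp_peaks(ses$epochs, min_dist_ms = 10, n_per_subject = 50, seed = 4)
  expect_equal(nrow(pk1), 50)
  expect_identical(pk1, pk2)
  # retained peaks respect the spacing within each trial (checked via count:
  # 10 ms spacing at 500 Hz allows at most ns/5 peaks per trial)
  expect_lte(nrow(suppressWarnings(
    gfp_peaks(ses$epochs, min_dist_ms = 100, n_per_subject = 1e6)
  )), 15 * ceiling(400 / 50))
})

test_that("modified K-means matches eigen/brute-force oracles on small inputs", {
  set.seed(31)
  maps <- matrix(rnorm(20 * 6), 20, 6)
  # k = 1: centroid is the dominant eigenvector of the full scatter matrix
  ts1 <- modified_kmeans(maps, k = 1, restarts = 3, seed = 1, names = "A")
  X <- t(apply(maps, 1, function(r) { r <- r - mean(r); r / sqrt(sum(r^2)) }))
  ev <- eigen(crossprod(X), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(ts1$maps[1, ] * ev)), 1, tolerance = 1e-8)

  # assignment step equals the brute-force squared-correlation argmax
  cents <- modified_kmeans(maps, k = 2, restarts = 5, seed = 1)$maps
  for (i in 1:4) {
    r2 <- apply(cents, 1, function(cc) stats::cor(maps[i, ], cc)^2)
    corr <- (X %*% t(cents))[i, ]
    expect_equal(which.max(corr^2), which.max(r2))
  }
})

test_that("modified K-means recovers planted orthogonal maps regardless of sign", {
  ts <- tiny_templates(k = 3, nc = 16, seed = 8)
  signs <- rep(c(1, -1), length.out = 60)
  maps <- ts$maps[rep(1:3, each = 20), ] * signs
  fit <- modified_kmeans(maps, k = 3, restarts = 5, seed = 2)
  corr <- abs(fit$maps %*% t(ts$maps))
  # each planted map matched by exactly one centroid with |r| = 1
  expect_equal(sort(unname(apply(corr, 2, max))), rep(1, 3), tolerance = 1e-8)
  expect_gte(attr(fit, "explained_variance"), 1 - 1e-10)
})

test_that("explained variance is non-decreasing within a run and sign-flip invariant", {
  set.seed(77)
  ts <- tiny_templates(k = 4, nc = 16, seed = 5)
  maps <- ts$maps[sample(1:4, 200, TRUE), ] + matrix(rnorm(200 * 16, sd = 0.2), 200, 16)
  fit <- modified_kmeans(maps, k = 4, restarts = 3, seed = 3)
  trace <- attr(fit, "ev_trace")
  expect_true(all(diff(trace) >= -1e-10))

  flipped <- maps * sample(c(-1, 1), 200, TRUE)
  fit2 <- modified_kmeans(flipped, k = 4, restarts = 3, seed = 3)
  expect_equal(attr(fit2, "explained_variance"),
               attr(fit, "explained_variance"), tolerance = 1e-8)
  # maps equal up to per-map sign
  agreement <- unname(abs(rowSums(fit$maps * fit2$maps)))
  expect_equal(agreement, rep(1, 4), tolerance = 1e-8)
})

test_that("polarity expansion doubles the set with exact negations and refuses twice", {
  ts5 <- tiny_templates(k = 5, nc = 12)
  e5 <- expand_polarity(ts5)
  expect_equal(nrow(e5$maps), 10)
  expect_equal(e5$names, c(paste0(LETTERS[1:5], "+"), paste0(LETTERS[1:5], "-")))
  ts4 <- tiny_templates(k = 4, nc = 12)
  expect_equal(nrow(expand_polarity(ts4)$maps), 8)
  expect_identical(e5$maps[1:5, ] + e5$maps[6:10, ], matrix(0, 5, 12,
                   dimnames = dimnames(e5$maps[1:5, ] + e5$maps[6:10, ])))
  expect_error(expand_polarity(e5), "already polarity-expanded")
})

test_that("centroid averaging appends normalized means and rejects cancelling pairs", {
  ts <- tiny_templates(k = 5, nc = 12)
  t7 <- average_centroids(ts, list(c("A", "B"), c("D", "E")))
  expect_equal(t7$base_k, 7)
  expect_equal(nrow(expand_polarity(t7)$maps), 14)
  # the appended map is the renormalized mean
  expected <- (ts$maps[1, ] + ts$maps[2, ]) / 2
  expected <- expected - mean(expected)
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(unname(t7$maps[6, ]), unname(expected), tolerance = 1e-12)

  # averaging a map with itself is idempotent
  tsame <- average_centroids(ts, list(c(1, 1)))
  expect_equal(unname(tsame$maps[6, ]), unname(ts$maps[1, ]), tolerance = 1e-12)

  # u and -u average to the zero map
  both <- template_set(rbind(ts$maps[1, ], -ts$maps[1, ]), c("P", "N"),
                       ts$montage, normalized = TRUE)
  expect_error(average_centroids(both, list(c(1, 2))), "zero map")
  # signed (expanded) indices are rejected outright
  expect_error(average_centroids(expand_polarity(ts), list(c(1, 2))), "base maps")
})
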