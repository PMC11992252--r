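test_that("PVC matches the hand-evaluated cosine form and its invariances", {
  # 2 neurons: lambda1(x) = (1, 0), lambda2(y) = (1, 1) -> 1 / sqrt(2)
  m1 <- matrix(c(1, 0), 2, 1)
  m2 <- matrix(c(1, 1), 2, 1)
  expect_equal(pvc_matrix(m1, m2)[1, 1], 1 / sqrt(2))
  set.seed(3)
  m <- matrix(runif(40 * 20), 40)
  p_self <- pvc_matrix(m, m)
  expect_equal(unname(diag(p_self)), rep(1, 20))
  # scale invariance and neuron-permutation invariance
  expect_equal(pvc_matrix(m, 2.5 * m), p_self)
  perm <- sample(40)
  expect_equal(pvc_matrix(m[perm, ], m[perm, ]), p_self)
  # zero population vector: entries flagged missing
  mz <- m; mz[, 5] <- 0
  expect_true(all(is.na(pvc_matrix(mz, m)[5, ])))
})

test_that("PVC curves summarize offsets with intercept and initial slope", {
  cfg <- corridor_config()
  set.seed(4)
  m <- matrix(runif(60 * 80), 60)
  res <- pvc_curve_stats(pvc_matrix(m, m), cfg)
  expect_equal(nrow(res$curve), 56) # offsets 0..275 cm
  expect_equal(res$y_intercept, 1)
  # constructed linear decay: 1.0 at 0 cm to 0.8 at 100 cm offset
  lin <- matrix(NA_real_, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    lin[i, j] <- max(1 - 0.002 * abs(i - j) * 5, 0)
  }
  res2 <- pvc_curve_stats(lin, cfg)
  expect_equal(res2$initial_slope, 0.2, tolerance = 1e-9)
  flat <- matrix(0.7, 80, 80)
  expect_equal(pvc_curve_stats(flat, cfg)$initial_slope, 0)
  expect_equal(length(pvc_curve_stats(flat, cfg)$rpp), 0)
})

test_that("relative peak prominence quantifies curve periodicity", {
  expect_identical(rpp(rep(0.5, 10)), numeric(0))
  expect_identical(rpp(seq(1, 0, length.out = 10)), numeric(0))
  tri <- rep(c(0.5, 0.75, 1, 0.75), 5)[1:18]
  expect_equal(rpp(tri), rep(0.5, length(rpp(tri))))
  # cells tuned to the same offset from every reward zone make the
  # population code periodic: the PVC curve peaks near the ~107-cm spacing
  cfg <- corridor_config()
  x <- bin_centers(cfg)
  set.seed(12)
  offs <- runif(40, -20, 20)
  maps <- t(vapply(offs, function(o) {
    rowSums(vapply(c(30, 137, 243, 350) + o, function(cc) {
      exp(-(x - cc)^2 / (2 * 81))
    }, numeric(80)))
  }, numeric(80)))
  res <- pvc_curve_stats(pvc_matrix(maps, maps), cfg)
  first_peak <- res$curve$offset_cm[which(diff(sign(diff(res$curve$pvc))) == -2) + 1][1]
  expect_gte(first_peak, 100)
  expect_lte(first_peak, 115)
  expect_gt(length(res$rpp), 0)
})

test_that("pairwise correlations handle self, anti-phase and hand cases", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 2, 3, 4))
  m <- pairwise_correlations(x, "trace")
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m[1, 2], -1)
  expect_equal(m[1, 3], 1)
  expect_equal(m, t(m))
  # hand-computed Pearson r = 0.5 between (1,2,3) and (2,1,3)
  y <- rbind(c(1, 2, 3), c(2, 1, 3))
  expect_equal(pairwise_correlations(y)[1, 2], 0.5)
  # zero-variance neuron: its row/column is missing, diagonal kept
  z <- rbind(c(1, 2, 3), c(5, 5, 5))
  mz <- pairwise_correlations(z)
  expect_true(is.na(mz[1, 2]))
  expect_equal(unname(diag(mz)), c(1, 1))
})

test_that("the synchronous pool holds the top 5% of pairs", {
  set.seed(6)
  n <- 30
  x <- matrix(rnorm(n * 200), n)
  cm <- pairwise_correlations(x)
  classes <- sample(c("stable_pc", "noncoding"), n, TRUE)
  pool <- sync_pool_composition(cm, classes, percentile = 95)
  n_pairs <- n * (n - 1) / 2
  expect_lte(abs(nrow(pool$pool) - ceiling(0.05 * n_pairs)), 1)
  expect_true(all(pool$pool$r > pool$threshold))
  # brute-force pool membership on a small matrix
  v <- cm[upper.tri(cm)]
  manual <- sort(v, decreasing = TRUE)[seq_len(nrow(pool$pool))]
  expect_equal(sort(pool$pool$r, decreasing = TRUE), manual)
  # by-construction composition: give PC-PC pairs the top correlations
  cm2 <- matrix(0.1, 10, 10); diag(cm2) <- 1
  cls2 <- c(rep("stable_pc", 2), rep("noncoding", 8))
  cm2[1, 2] <- cm2[2, 1] <- 0.9 # the single PC-PC pair: top of 45
  pool2 <- sync_pool_composition(cm2, cls2, percentile = 95)
  comp <- pool2$composition
  expect_equal(comp$frac_in_pool[comp$pair_class == "stable_pc-stable_pc"], 1)
})

test_that("correlation structure similarity is a cosine on upper triangles", {
  set.seed(8)
  a <- pairwise_correlations(matrix(rnorm(20 * 100), 20))
  expect_equal(correlation_similarity(a, a), 1)
  b <- -a; diag(b) <- 1
  expect_equal(correlation_similarity(a, b), -1)
  # independent structures: near-zero similarity
  c1 <- pairwise_correlations(matrix(rnorm(50 * 150), 50))
  c2 <- pairwise_correlations(matrix(rnorm(50 * 150), 50))
  expect_lt(abs(correlation_similarity(c1, c2)), 0.15)
  expect_true(is.na(correlation_similarity(matrix(0, 3, 3), a[1:3, 1:3])))
})

test_that("phase-averaged pairwise regressions detect shared structure", {
  fx <- expert_session()
  s1 <- fx$session
  s2 <- s1; s2$day <- 3L # same activity, different phase
  res <- phase_averaged_pairwise(list(a = s1, b = s2))
  expect_equal(res$regressions$r, 1, tolerance = 1e-9)
  expect_equal(res$regressions$slope, 1, tolerance = 1e-9)
  expect_false(res$regressions$excluded)
  # independent activity: flagged excluded
  set.seed(9)
  s3 <- s2
  s3$dff <- matrix(rnorm(length(s2$dff), 0, 0.1), nrow(s2$dff))
  res2 <- phase_averaged_pairwise(list(a = s1, b = s3))
  expect_gt(res2$regressions$p, 0.001) # no real shared structure
  # hand-built regression check via the normal equations
  av <- res2$pair_means
  x <- av$mean_r[av$phase == "healthy"]
  y <- av$mean_r[av$phase == "early_post"]
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res2$regressions$slope, beta, tolerance = 1e-9)
})

test_that("field geometry categorizes distance to the nearest reward zone", {
  cfg <- corridor_config()
  fields <- tibble::tibble(
    neuron = 1:4,
    center_cm = c(30, 60, 90, 137),
    class = c("stable_pc", "unstable_pc", "stable_pc", "unstable_pc"))
  geo <- field_rz_geometry(fields, cfg, close_threshold_cm = 25)
  expect_equal(geo$fields$rz_distance_cm, c(0, 10, 27, 0))
  expect_equal(geo$fields$category, c("in", "close", "far", "in"))
  # equal distance distributions: contrast ~ 0
  eq <- tibble::tibble(neuron = 1:4, center_cm = c(60, 70, 60, 70),
                       class = c("stable_pc", "unstable_pc",
                                 "unstable_pc", "stable_pc"))
  expect_equal(field_rz_geometry(eq, cfg)$stability_contrast_cm, 0)
})

test_that("pair distances are Euclidean and unrelated synchrony stays flat", {
  cents <- rbind(c(0, 0), c(3, 4), c(0, 0))
  cm <- diag(3); cm[upper.tri(cm)] <- cm[lower.tri(cm)] <- 0.5
  res <- pair_euclidean_distance(cents, cm)
  expect_equal(res$pairs$distance_um[1], 5) # 3-4-5 triangle
  expect_equal(res$pairs$distance_um[2], 0) # coincident centroids
  set.seed(10)
  cents2 <- matrix(runif(80, 0, 830), ncol = 2)
  cm2 <- pairwise_correlations(matrix(rnorm(40 * 200), 40))
  res2 <- pair_euclidean_distance(cents2, cm2)
  expect_lt(abs(res2$distance_synchrony_r), 0.15)
})
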