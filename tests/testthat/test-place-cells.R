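test_that("FWHM noise estimate tracks the noise floor", {
  set.seed(3)
  x <- rnorm(10000, 0, 0.1)
  expect_equal(noise_sigma_fwhm(x), 0.1, tolerance = 0.01)
  # sparse large transients (<5% of frames) barely move the estimate
  y <- x
  starts <- sample(9950, 25)
  for (st in starts) y[st:(st + 20)] <- y[st:(st + 20)] + 1.5
  expect_equal(noise_sigma_fwhm(y), 0.1, tolerance = 0.015)
  expect_warning(s0 <- noise_sigma_fwhm(rep(1, 200)), "constant")
  expect_equal(s0, 0)
})

test_that("significant transients require 3 sigma for at least 0.5 s", {
  sigma <- 0.1
  tr <- rep(0, 200)
  tr[50:69] <- 4 * sigma # 20 frames >= ceil(0.5 * 30) = 15
  runs <- significant_transients(tr, sigma, frame_rate_hz = 30)
  expect_equal(nrow(runs), 1)
  expect_equal(unname(runs[1, ]), c(50L, 69L))
  tr2 <- rep(0, 200); tr2[50:59] <- 4 * sigma # 10 < 15 frames
  expect_equal(nrow(significant_transients(tr2, sigma, 30)), 0)
  expect_equal(nrow(significant_transients(rep(0, 200), sigma, 30)), 0)
})

test_that("candidate screening thresholds at 25% above the lower-quartile baseline", {
  expect_equal(nrow(candidate_fields(rep(0.3, 80))), 0)
  m <- rep(0, 80); m[31:36] <- 1
  runs <- candidate_fields(m)
  expect_equal(nrow(runs), 1)
  expect_equal(unname(runs[1, ]), c(31L, 36L))
  m2 <- rep(0, 80); m2[11:15] <- 1; m2[51:56] <- 0.8
  runs2 <- candidate_fields(m2)
  expect_equal(nrow(runs2), 2)
  expect_equal(unname(runs2[, "start"]), c(11L, 51L))
})

test_that("the three field criteria are enforced at their documented thresholds", {
  row <- rep(0.1, 80); row[41:42] <- 0.6
  mask <- rep(TRUE, 1000)
  kept <- 1:1000
  bins <- rep(1:80, length.out = 1000)
  # width 10 cm < 15 cm fails criterion 1
  f <- field_criteria(c(41L, 42L), row, mask, kept, bins)
  expect_false(f$pass_width)
  # exactly 6x in/out passes criterion 2 (0.6 vs 0.1)
  row2 <- rep(0.1, 80); row2[41:44] <- 0.6
  f2 <- field_criteria(c(41L, 44L), row2, mask, kept, bins)
  expect_true(f2$pass_width)
  expect_equal(f2$mean_in / f2$mean_out, 6, tolerance = 1e-9)
  expect_true(f2$pass_ratio)
  # sparse transients fail criterion 3: 3 of the 48 in-field frames
  mask3 <- rep(FALSE, 1000); mask3[c(41, 121, 201)] <- TRUE
  f3 <- field_criteria(c(41L, 44L), row2, mask3, kept, bins)
  expect_equal(f3$coverage, 3 / 48)
  expect_lt(f3$coverage, 0.2)
  expect_false(f3$pass_coverage)
  expect_false(f3$pass)
  # non-positive out-of-field mean: criterion 2 iff positive in-field mean
  row4 <- rep(-0.01, 80); row4[41:44] <- 0.5
  f4 <- field_criteria(c(41L, 44L), row4, mask, kept, bins)
  expect_true(f4$pass_ratio)
})

test_that("detection is invariant to positive rescaling of the trace", {
  fx <- expert_session()
  s <- fx$session
  i <- which(fx$population$class == "stable_pc")[1]
  pc1 <- local({
    s1 <- s; s1$dff <- s$dff[i, , drop = FALSE]
    detect_place_cells(s1, fx$config, n_shuffles = 50, seed = 9)
  })
  pc2 <- local({
    s2 <- s; s2$dff <- 5 * s$dff[i, , drop = FALSE]
    detect_place_cells(s2, fx$config, n_shuffles = 50, seed = 9)
  })
  expect_equal(pc1$is_pc, pc2$is_pc)
  expect_equal(pc1$field_start, pc2$field_start)
  expect_equal(pc1$field_end, pc2$field_end)
  expect_equal(pc1$p_pf, pc2$p_pf)
})

test_that("bootstrap p-values are seeded and near-uniform for noncoding cells", {
  fx <- expert_session()
  s <- fx$session
  i <- which(fx$population$class == "stable_pc")[2]
  p1 <- bootstrap_pvalue(s$dff[i, ], s, fx$config, n_shuffles = 50, seed = 4)
  p2 <- bootstrap_pvalue(s$dff[i, ], s, fx$config, n_shuffles = 50, seed = 4)
  expect_identical(p1, p2)
  # a strong place cell beats its shuffle null decisively
  expect_lte(p1, 0.05)
  # noncoding cells are called place cells (observed pass + p_pf <= alpha)
  # no more often than alpha allows, up to 3 binomial SEs
  pc <- memo("expert_pc", function() {
    detect_place_cells(fx$session, fx$config, n_shuffles = 100, seed = 7)
  })
  nc <- fx$population$class == "noncoding"
  alpha <- 0.05
  frac <- mean(pc$is_pc[nc])
  expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / sum(nc)))
})

test_that("place-cell detection recovers the generated classes", {
  fx <- expert_session()
  pc <- memo("expert_pc", function() {
    detect_place_cells(fx$session, fx$config, n_shuffles = 100, seed = 7)
  })
  truth <- fx$population$class
  stable <- truth == "stable_pc"
  nc <- truth == "noncoding"
  expect_gte(mean(pc$is_pc[stable]), 0.75)
  expect_lte(mean(pc$is_pc[nc]), 0.1)
  # detected field center near the true center for detected stable cells
  det <- which(stable & pc$is_pc)
  centers_bin <- (pc$field_start[det] + pc$field_end[det]) / 2
  true_bin <- fx$population$field_center_cm[det] / 5 + 0.5
  expect_lt(median(abs(centers_bin - true_bin)), 3)
})

test_that("Fisher-averaged stability matches hand-computed values", {
  # r = 0.3 and 0.7: tanh(mean(atanh)) = 0.5288 (direct evaluation)
  expect_equal(tanh(mean(atanh(c(0.3, 0.7)))), 0.5288, tolerance = 5e-4)
  # identical per-trial maps: both split correlations are 1 (clipped)
  maps <- matrix(rep(c(0, 0.2, 0.9, 0.4, 0.1), 6), nrow = 6, byrow = TRUE)
  expect_equal(within_session_stability(maps), 1, tolerance = 1e-4)
  expect_true(is.na(within_session_stability(maps[1:3, ])))
  # cross-session: only pairs exactly 3 days apart, Fisher-averaged
  m <- rbind(c(0, 0.2, 0.9, 0.4, 0.1), c(0, 0.2, 0.9, 0.4, 0.1))
  expect_equal(cross_session_stability(m, days = c(-4, -1)), 1,
               tolerance = 1e-4)
  expect_true(is.na(cross_session_stability(m, days = c(-4, -2))))
  # two qualifying pairs with r = 0.2 and 0.6 combine to 0.42008
  base <- c(0.1, 0.5, 1, 0.5, 0.1, 0.05, 0.3, 0.2)
  mk_with_r <- function(target) {
    # rotate noise until the correlation with base is near the target
    best <- NULL; bestd <- Inf
    set.seed(42)
    for (k in 1:4000) {
      cand <- base + rnorm(8, 0, 1.1)
      d <- abs(cor(base, cand) - target)
      if (d < bestd) { bestd <- d; best <- cand }
    }
    best
  }
  v2 <- mk_with_r(0.2); v6 <- mk_with_r(0.6)
  m2 <- rbind(base, v2, base, v6)
  got <- cross_session_stability(m2, days = c(-6, -3, 0, 3))
  # pairs: (-6,-3) r~0.2, (0,3)... (-3,0) also 3 days apart (r(v2, base))
  expected <- tanh(mean(atanh(c(cor(base, v2), cor(v2, base),
                                cor(base, v6)))))
  expect_equal(got, expected, tolerance = 1e-10)
  expect_equal(tanh(mean(atanh(c(0.2, 0.6)))), 0.4202, tolerance = 5e-4)
})

test_that("stability classification splits place cells at the healthy median", {
  scores <- tibble::tibble(
    neuron = rep(1:5, 2),
    phase = rep(c("healthy", "early_post"), each = 5),
    score = c(0.1, 0.2, 0.3, 0.4, 0.5, # healthy: median 0.3
              0.3, 0.31, 0.5, 0.29, 0.3))
  is_pc <- tibble::tibble(neuron = rep(1:5, 2),
                          phase = rep(c("healthy", "early_post"), each = 5),
                          is_pc = c(rep(TRUE, 9), FALSE))
  cls <- classify_stability(scores, is_pc)
  expect_equal(attr(cls, "baseline"), 0.3)
  early <- cls[cls$phase == "early_post", ]
  # tie at the median is unstable; above is stable; non-PC is noncoding
  expect_equal(early$class,
               c("unstable_pc", "stable_pc", "stable_pc", "unstable_pc",
                 "noncoding"))
  # optional persistence reading: healthy stable cells must also have kept
  # a field across the healthy sessions; post phases are untouched
  cls2 <- classify_stability(scores, is_pc,
                             healthy_persistent = c(TRUE, TRUE, FALSE,
                                                    FALSE, TRUE))
  healthy2 <- cls2[cls2$phase == "healthy", ]
  expect_equal(healthy2$class,
               c("unstable_pc", "unstable_pc", "unstable_pc",
                 "unstable_pc", "stable_pc"))
  expect_equal(cls2$class[cls2$phase == "early_post"], early$class)
})
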