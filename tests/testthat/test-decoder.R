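# Build a decoder_model by hand for worked examples.
manual_model <- function(mu, sigma, occ, config) {
  structure(list(neuron_ids = seq_len(nrow(mu)), mu = mu, sigma = sigma,
                 occ = occ, stability = rep(NA_real_, nrow(mu)),
                 config = config),
            class = "decoder_model")
}

toy_config <- function(n_bins = 2) {
  corridor_config(length_cm = n_bins * 5, bin_size_cm = 5, lick_bin_count = n_bins,
                  rz_centers_cm = n_bins * 5 / 2, rz_width_cm = 5)
}

test_that("SD flooring raises below-average bins to the neuron's mean SD", {
  # one neuron, 3 bins, 3 trials with per-bin SDs (0.1, 0.3, 0.2)
  pts <- array(NA_real_, c(3, 1, 3))
  pts[, 1, 1] <- c(0.0, 0.1, 0.2) # sd 0.1
  pts[, 1, 2] <- c(0.0, 0.3, 0.6) # sd 0.3
  pts[, 1, 3] <- c(0.0, 0.2, 0.4) # sd 0.2
  occ <- matrix(1, 3, 3)
  model <- placecode:::fit_decoder_from_maps(pts, occ, toy_config(3),
                                             n_neurons = 1)
  expect_equal(unname(model$sigma[1, ]), c(0.2, 0.3, 0.2))
  # identical trials: sigma collapses to the epsilon floor, with a warning
  pts0 <- array(0.5, c(3, 1, 3))
  expect_warning(m0 <- placecode:::fit_decoder_from_maps(pts0, occ,
                                                         toy_config(3),
                                                         n_neurons = 1),
                 "zero cross-trial variance")
  expect_true(all(m0$sigma == 1e-6))
})

test_that("the model keeps the 100 most stable of 150 candidate neurons", {
  fx <- expert_session()
  s150 <- fx$session
  set.seed(5)
  extra <- s150$dff[sample(nrow(s150$dff), 90, replace = TRUE), ] +
    matrix(rnorm(90 * ncol(s150$dff), 0, 0.05), 90)
  s150$dff <- rbind(s150$dff, extra)
  model <- fit_decoder(s150, fx$config)
  expect_equal(nrow(model$mu), 100)
  expect_equal(length(model$stability), 150)
  kept <- model$neuron_ids
  # every kept neuron is at least as stable as every dropped one
  expect_gte(min(model$stability[kept], na.rm = TRUE),
             max(model$stability[-kept][1:10], na.rm = TRUE) - 1e-9)
})

test_that("the two-neuron worked example gives the e^3.2 posterior ratio", {
  cfg <- toy_config(2)
  model <- manual_model(mu = rbind(c(1, 0), c(0, 1)),
                        sigma = matrix(0.5, 2, 2),
                        occ = c(0.5, 0.5), config = cfg)
  dff <- matrix(c(0.9, 0.1), 2, 1)
  traj <- decode_frames(model, dff, frame_rate_hz = 30, frames = 1,
                        return_confidence = TRUE)
  expect_equal(traj$x_hat, 1L)
  ratio <- exp(traj$confidence[1, 1] - traj$confidence[1, 2])
  expect_equal(ratio, exp(3.2), tolerance = 1e-9)
})

test_that("one-hot tuning decodes the true bin; a one-hot prior dominates", {
  cfg <- toy_config(8)
  mu <- diag(8)[1:5, ] # 5 neurons, one-hot tuning at bins 1..5
  model <- manual_model(mu, matrix(0.3, 5, 8), rep(1 / 8, 8), cfg)
  # activity equals the tuning column for the true bin
  for (b in 1:5) {
    traj <- decode_frames(model, matrix(mu[, b], 5, 1), 30, frames = 1)
    expect_equal(traj$x_hat, b)
  }
  prior <- rep(0, 8); prior[7] <- 1
  model7 <- manual_model(mu, matrix(0.3, 5, 8), prior, cfg)
  traj7 <- decode_frames(model7, matrix(mu[, 2], 5, 1), 30, frames = 1)
  expect_equal(traj7$x_hat, 7L)
})

test_that("log-space decoding matches a direct-product oracle", {
  set.seed(9)
  cfg <- toy_config(8)
  n <- 5; nb <- 8; tf <- 12
  mu <- matrix(runif(n * nb), n)
  sigma <- matrix(runif(n * nb, 0.2, 0.6), n)
  occ <- runif(nb); occ <- occ / sum(occ)
  model <- manual_model(mu, sigma, occ, cfg)
  dff <- matrix(runif(n * tf), n)
  traj <- decode_frames(model, dff, 30, delta_t_s = 0, frames = 1:tf,
                        return_confidence = TRUE)
  # oracle: plain products of Gaussian densities, each neuron's row
  # normalized by its max over bins, times the prior
  for (t in 1:tf) {
    post <- occ
    for (i in 1:n) {
      p <- dnorm(dff[i, t], mu[i, ], sigma[i, ])
      post <- post * (p / max(p))
    }
    expect_equal(which.max(post), traj$x_hat[t])
    got <- exp(traj$confidence[t, ] - max(traj$confidence[t, ]))
    expect_equal(got, post / max(post), tolerance = 1e-9)
  }
  # each neuron's normalized likelihood row has maximum exactly 1
  single <- manual_model(mu[1, , drop = FALSE], sigma[1, , drop = FALSE],
                         rep(1 / nb, nb), cfg)
  tr1 <- decode_frames(single, dff[1, , drop = FALSE], 30, delta_t_s = 0,
                       frames = 1:tf, return_confidence = TRUE)
  norm_rows <- exp(tr1$confidence - log(1 / nb)) # remove the flat prior
  expect_equal(apply(norm_rows, 1, max), rep(1, tf), tolerance = 1e-12)
})

test_that("decoding is invariant to neuron order", {
  set.seed(13)
  cfg <- toy_config(8)
  mu <- matrix(runif(4 * 8), 4)
  sigma <- matrix(0.4, 4, 8)
  dff <- matrix(runif(4 * 10), 4)
  m1 <- manual_model(mu, sigma, rep(1 / 8, 8), cfg)
  perm <- c(3, 1, 4, 2)
  m2 <- manual_model(mu[perm, ], sigma[perm, ], rep(1 / 8, 8), cfg)
  t1 <- decode_frames(m1, dff, 30, delta_t_s = 0)
  t2 <- decode_frames(m2, dff[perm, ], 30, delta_t_s = 0)
  expect_identical(t1$x_hat, t2$x_hat)
})

test_that("leave-one-out decoding beats chance by an order of magnitude", {
  loo <- memo("loo_expert", function() {
    loo_within_session(expert_session()$session, expert_session()$config)
  })
  expect_equal(nrow(loo$per_trial), 15)
  expect_gt(loo$session$accuracy, 10 / 80) # >= 10x the 1/80 chance
  expect_gt(loo$session$sensitivity, 0.5)
  expect_error(loo_within_session(ramp_session(n_trials = 2)), "3 trials")
})

test_that("cross-session decoding on itself equals a plain decode", {
  fx <- expert_session()
  m <- cross_session_decode(fx$session, fx$session, config = fx$config)
  model <- fit_decoder(fx$session, fx$config)
  fr <- trial_frames(fx$session)
  traj <- decode_frames(model, fx$session$dff, frames = fr)
  direct <- decoder_metrics(traj, fx$session$position_cm[fr], fx$config)
  expect_equal(m$accuracy, direct$accuracy)
  expect_gt(m$accuracy, 10 / 80)
})

test_that("decoder metrics count exact matches and reward-zone hits", {
  cfg <- corridor_config()
  truth <- c(12, 30, 30, 200, 30, 137, 300, 350, 30, 101)
  true_bin <- position_to_bin(truth, cfg)
  pred <- true_bin
  pred[1:6] <- 1L # bin 1 is outside every reward zone
  m <- decoder_metrics(pred, truth, cfg)
  expect_equal(m$accuracy, 0.4)
  # frames truly in a zone: positions 12, 30 (x4), 137, 350 -> 7 frames,
  # of which predictions land in a zone only for the 2 untouched ones
  expect_equal(m$sensitivity, 2 / 7)
  m2 <- decoder_metrics(true_bin, truth, cfg)
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$sensitivity, 1)
  # no reward-zone frames: sensitivity undefined
  m3 <- decoder_metrics(c(1L, 2L), c(60, 61), cfg)
  expect_true(is.na(m3$sensitivity))
})

test_that("empirical chance converges to 1 over n_bins", {
  set.seed(17)
  cfg <- toy_config(4)
  mu <- matrix(runif(6 * 4), 6)
  model <- manual_model(mu, matrix(0.3, 6, 4), rep(0.25, 4), cfg)
  dff <- matrix(runif(6 * 400), 6)
  truth <- runif(400, 0, 20)
  ch <- empirical_chance(model, dff, 1:400, truth, n_shuffles = 400,
                         seed = 18)
  expect_equal(ch$accuracy, 0.25, tolerance = 3 * 0.25 / sqrt(400))
  # deterministic given the seed
  ch2 <- empirical_chance(model, dff, 1:400, truth, n_shuffles = 400,
                          seed = 18)
  expect_identical(ch$accuracy, ch2$accuracy)
})
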