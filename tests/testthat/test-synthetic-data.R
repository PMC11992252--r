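test_that("expert agents concentrate licks in reward zones, naive agents do not", {
  cfg <- corridor_config()
  tr <- generate_trajectory(cfg, 20, "expert", seed = 11)
  lick_pos <- tr$position_cm[tr$lick_frames]
  expect_gt(mean(rz_distance(lick_pos, cfg) == 0), 0.6)
  # spatial concentration of licking: expert far above naive
  mk_session <- function(t) {
    session_data(matrix(0, 1, length(t$position_cm)), t$position_cm,
                 t$velocity_cm_s, t$lick_frames, t$reward_frames,
                 t$trial_bounds, day = -1)
  }
  si_expert <- spatial_information(lick_histogram(mk_session(tr), cfg))
  nv <- generate_trajectory(cfg, 20, "naive", seed = 12)
  si_naive <- spatial_information(lick_histogram(mk_session(nv), cfg))
  expect_gt(si_expert, 1)
  expect_lt(si_naive, si_expert / 2)
})

test_that("trajectories are deterministic given a seed and internally consistent", {
  cfg <- corridor_config()
  t1 <- generate_trajectory(cfg, 5, "expert", seed = 3)
  t2 <- generate_trajectory(cfg, 5, "expert", seed = 3)
  expect_identical(t1, t2)
  t3 <- generate_trajectory(cfg, 5, "expert", seed = 4)
  expect_false(identical(t1$position_cm, t3$position_cm))
  # velocity matches the finite difference of position within trials
  tb <- t1$trial_bounds[1, ]
  pos <- t1$position_cm[tb[1]:(tb[2] - 1)]
  vel <- t1$velocity_cm_s[tb[1]:(tb[2] - 1)]
  # final frame clamps at the corridor end, so compare all but the last
  n <- length(pos)
  fd <- diff(pos[1:(n - 1)]) * cfg$frame_rate_hz
  expect_equal(fd, vel[2:(n - 1)], tolerance = 1e-6)
  expect_error(generate_trajectory(cfg, 5, "confused"), "arg")
})

test_that("population draws respect proportions and tuning invariants", {
  expect_error(generate_population(10, proportions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  all_stable <- generate_population(20, proportions = c(1, 0, 0), seed = 1)
  expect_true(all(all_stable$class == "stable_pc"))
  pop <- generate_population(1000, proportions = c(0.2, 0.2, 0.6), seed = 2)
  counts <- table(factor(pop$class, c("stable_pc", "unstable_pc", "noncoding")))
  # each count within the 99% binomial interval of its expectation
  for (k in seq_along(counts)) {
    p <- c(0.2, 0.2, 0.6)[k]
    expect_gte(counts[[k]], qbinom(0.005, 1000, p))
    expect_lte(counts[[k]], qbinom(0.995, 1000, p))
  }
  expect_true(all(pop$field_center_cm[pop$class != "noncoding"] >= 0))
  expect_true(all(pop$field_center_cm[pop$class != "noncoding"] < 400))
  p2 <- generate_population(1000, proportions = c(0.2, 0.2, 0.6), seed = 3)
  expect_false(identical(pop$field_center_cm, p2$field_center_cm))
})

test_that("a noiseless stable cell's smoothed map peaks at its true field bin", {
  cfg <- corridor_config()
  tr <- generate_trajectory(cfg, 30, "expert", seed = 21)
  pop <- generate_population(1, proportions = c(1, 0, 0), noise_sd = 0,
                             seed = 22)
  pop$field_center_cm <- 202.5 # center of bin 41
  pop$field_width_cm <- 20
  # near-instant indicator: the map peak is exactly the true field bin
  dff <- generate_dff(pop, tr, cfg, seed = 23, decay_tau_s = 0.02)
  s <- session_data(dff, tr$position_cm, tr$velocity_cm_s,
                    trial_bounds = tr$trial_bounds, day = -1)
  sam <- smooth_map(bin_activity(s, cfg), reflag = FALSE)
  expect_equal(which.max(sam$lambda_smooth[1, ]), 41)
  # the GCaMP6f kernel drags the peak forward in the running direction
  dff2 <- generate_dff(pop, tr, cfg, seed = 23)
  s2 <- session_data(dff2, tr$position_cm, tr$velocity_cm_s,
                     trial_bounds = tr$trial_bounds, day = -1)
  sam2 <- smooth_map(bin_activity(s2, cfg), reflag = FALSE)
  lag_bins <- which.max(sam2$lambda_smooth[1, ]) - 41
  expect_gte(lag_bins, 0)
  expect_lte(lag_bins, 4)
})

test_that("zero event rates yield pure noise with mean near zero", {
  cfg <- corridor_config()
  tr <- generate_trajectory(cfg, 3, "expert", seed = 31)
  pop <- generate_population(2, proportions = c(0, 0, 1), seed = 32,
                             noncoding_event_rate = 0, noise_sd = 0.1)
  pop$baseline_event_rate <- 0
  dff <- generate_dff(pop, tr, cfg, seed = 33)
  expect_lt(abs(mean(dff)), 0.01)
  expect_equal(sd(as.vector(dff)), 0.1, tolerance = 0.05)
})

test_that("experiments apply class turnover at onset with binomial counts", {
  cfg <- corridor_config()
  pop <- generate_population(100, proportions = c(1, 0, 0), seed = 41)
  ex <- generate_experiment(
    c(-1L, 0L, 3L), pop, cfg,
    perturbation_spec(onset_day = 0, class_turnover_prob = 0.5),
    n_trials = 2, seed = 42)
  post <- ex$registry[ex$registry$day == 3, ]
  n_switched <- sum(post$true_class != "stable_pc")
  expect_gte(n_switched, qbinom(0.005, 100, 0.5))
  expect_lte(n_switched, qbinom(0.995, 100, 0.5))
  # pre-onset sessions untouched
  pre <- ex$registry[ex$registry$day <= 0, ]
  expect_true(all(pre$true_class == "stable_pc"))
  # registry is complete: every neuron in every session
  expect_equal(nrow(ex$registry), 100 * 3)
})

test_that("an inert perturbation leaves the generative parameters alone", {
  cfg <- corridor_config()
  pop <- generate_population(20, seed = 51)
  expect_warning(
    ex <- generate_experiment(c(-1L, 0L), pop, cfg,
                              perturbation_spec(onset_day = 10,
                                                class_turnover_prob = 0.9),
                              n_trials = 2, seed = 52),
    "inert")
  expect_true(all(ex$registry$true_class == pop$class[ex$registry$neuron_uid]))
  # unstable cells remap between sessions, stable cells do not
  pop2 <- generate_population(30, proportions = c(0.5, 0.5, 0), seed = 53)
  ex2 <- generate_experiment(c(-4L, -1L), pop2, cfg, n_trials = 2, seed = 54)
  r <- tidyr::pivot_wider(ex2$registry[, c("neuron_uid", "day", "field_center_cm")],
                          names_from = "day", values_from = "field_center_cm")
  stable <- pop2$class == "stable_pc"
  expect_true(all(r$`-4`[stable] == r$`-1`[stable]))
  expect_true(all(r$`-4`[!stable] != r$`-1`[!stable]))
})
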