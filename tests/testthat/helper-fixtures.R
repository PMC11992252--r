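# Shared fixtures, generated in code. The expensive expert session is built
# once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# A deterministic "hand-built" session: linear position ramps, constant
# velocity, no blackout. Useful when a test must control every frame.
ramp_session <- function(n_trials = 4, frames_per_trial = 400,
                         n_neurons = 1, dff = NULL, lick_frames = integer(),
                         velocity = 20, config = corridor_config(),
                         day = -1) {
  n_frames <- n_trials * frames_per_trial
  pos <- rep(seq(0, config$length_cm - 1e-6, length.out = frames_per_trial),
             n_trials)
  vel <- rep(velocity, n_frames)
  tb <- cbind(start = seq(1L, n_frames, by = frames_per_trial),
              end = seq(frames_per_trial + 1L, n_frames + 1L,
                        by = frames_per_trial))
  if (is.null(dff)) dff <- matrix(0, n_neurons, n_frames)
  session_data(dff, pos, vel, lick_frames = lick_frames,
               trial_bounds = tb, day = day,
               frame_rate_hz = config$frame_rate_hz)
}

# Standard mixed-population expert session used across modules.
expert_session <- function() {
  memo("expert_session", function() {
    cfg <- corridor_config()
    tr <- generate_trajectory(cfg, 15, "expert", seed = 101)
    pop <- generate_population(60, proportions = c(0.35, 0.15, 0.5),
                               seed = 102)
    dff <- generate_dff(pop, tr, cfg, seed = 103)
    s <- session_data(dff, tr$position_cm, tr$velocity_cm_s, tr$lick_frames,
                      tr$reward_frames, tr$trial_bounds, day = -1)
    list(session = s, population = pop, trajectory = tr, config = cfg)
  })
}

# Exact sub-pixel image translation via the Fourier shift theorem
# (periodic boundaries) - the independent ground truth for shift recovery.
fourier_shift <- function(img, dy, dx) {
  n <- dim(img)
  ky <- c(0:(n[1] %/% 2), -(((n[1] + 1) %/% 2 - 1):1))
  kx <- c(0:(n[2] %/% 2), -(((n[2] + 1) %/% 2 - 1):1))
  ph <- exp(-2i * pi * (outer(ky, rep(1, n[2])) * dy / n[1] +
                          outer(rep(1, n[1]), kx) * dx / n[2]))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE) / length(img))
}

# All permutations of seq_len(n) (tiny n only) for exhaustive null oracles.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
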