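#' Stroke-like perturbation of a synthetic population
#'
#' Parameterizes how sessions after `onset_day` differ from baseline:
#' neurons may switch functional class once at onset, transient rates are
#' scaled down, formerly stable cells may remap between sessions, and an
#' optional recovery half-life relaxes the rate/stability effects back
#' toward baseline. The defaults are inert (no perturbation). Post-lesion
#' effect sizes are free generator parameters, not measured quantities.
#'
#' @param onset_day Sessions with `day > onset_day` are perturbed.
#' @param class_turnover_prob Probability that a neuron switches to a
#'   different functional class at onset.
#' @param rate_scale Multiplier in `(0, 1]` on transient event rates after
#'   onset (1 = unchanged).
#' @param stability_scale In `(0, 1]`; a stable place cell remaps its field
#'   between consecutive post-onset sessions with probability
#'   `1 - stability_scale` (before recovery scaling).
#' @param recovery_halflife_days Half-life (days) over which the rate and
#'   stability effects decay back to baseline; `NULL` for no recovery.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(onset_day = 0L, class_turnover_prob = 0,
                              rate_scale = 1, stability_scale = 1,
                              recovery_halflife_days = NULL) {
  stopifnot(class_turnover_prob >= 0, class_turnover_prob <= 1,
            rate_scale > 0, rate_scale <= 1,
            stability_scale > 0, stability_scale <= 1,
            is.null(recovery_halflife_days) || recovery_halflife_days > 0)
  structure(list(onset_day = as.integer(onset_day),
                 class_turnover_prob = class_turnover_prob,
                 rate_scale = rate_scale, stability_scale = stability_scale,
                 recovery_halflife_days = recovery_halflife_days),
            class = "perturbation_spec")
}

#' Imaging timeline with the study's session cadence
#'
#' Five daily baseline sessions ending on injection day 0, then sessions
#' every third day up to four weeks.
#' @return Integer vector of session days.
#' @export
default_timeline <- function() {
  c(-4L, -3L, -2L, -1L, 0L, seq(3L, 27L, by = 3L))
}

#' Simulate a virtual-corridor running and licking trajectory
#'
#' Produces frame-wise position and velocity plus lick/reward events for one
#' session of `n_trials` corridor traversals. Running speed fluctuates around
#' a target; expert agents pause inside each reward zone, lick in bursts
#' while pausing and anticipatorily just before zone entry, so well over 60%
#' of licks fall inside reward zones. Naive agents run at constant target
#' speed and lick at uniformly random frames. Trials are separated by a 1 s
#' screen blackout (position and velocity 0, outside all trial bounds).
#'
#' @param config A [corridor_config()].
#' @param n_trials Number of corridor traversals (>= 1).
#' @param agent `"expert"` or `"naive"`.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param base_speed_cm_s Mean target running speed.
#' @param lick_rate_hz Lick rate during an expert reward-zone stop.
#' @return A list with `position_cm`, `velocity_cm_s`, `lick_frames`,
#'   `reward_frames`, `trial_bounds` (half-open, 1-based), and `config`.
#' @export
generate_trajectory <- function(config, n_trials, agent = c("expert", "naive"),
                                seed = NULL, base_speed_cm_s = 18,
                                lick_rate_hz = 8) {
  agent <- match.arg(agent)
  stopifnot(n_trials >= 1)
  local_seed(seed)
  fr <- config$frame_rate_hz
  blackout <- as.integer(round(fr)) # 1 s between trials
  rz <- config$rz_intervals
  pos_all <- numeric(0); vel_all <- numeric(0)
  lick_all <- integer(0); reward_all <- integer(0)
  bounds <- matrix(0L, n_trials, 2, dimnames = list(NULL, c("start", "end")))
  frame0 <- 0L
  for (tr in seq_len(n_trials)) {
    pos <- 0; v <- base_speed_cm_s
    p_tr <- numeric(0); v_tr <- numeric(0)
    lick_tr <- integer(0); reward_tr <- integer(0)
    pause_left <- 0L
    entered <- rep(FALSE, nrow(rz)); rewarded <- rep(FALSE, nrow(rz))
    f <- 0L
    max_frames <- as.integer(120 * fr)
    while (pos < config$length_cm && f < max_frames) {
      f <- f + 1L
      zone <- which(pos >= rz[, 1] & pos <= rz[, 2])
      if (agent == "expert" && length(zone) == 1 && !entered[zone]) {
        entered[zone] <- TRUE
        pause_left <- as.integer(round(fr * runif(1, 0.5, 1.2)))
      }
      target <- if (pause_left > 0L) 1 else base_speed_cm_s
      if (pause_left > 0L) pause_left <- pause_left - 1L
      v <- max(0, v + 0.35 * (target - v) + rnorm(1, 0, 1.2))
      pos <- min(pos + v / fr, config$length_cm - 1e-9)
      p_tr[f] <- pos; v_tr[f] <- v
      # licking
      p_lick <- if (agent == "naive") {
        1.0 / fr
      } else if (length(zone) == 1 && v < 5) {
        lick_rate_hz / fr
      } else if (any(pos >= rz[, 1] - 10 & pos < rz[, 1])) {
        3 / fr # anticipatory licking just before zone entry
      } else {
        0.1 / fr
      }
      if (runif(1) < p_lick) {
        lick_tr <- c(lick_tr, f)
        if (length(zone) == 1 && !rewarded[zone]) {
          rewarded[zone] <- TRUE
          reward_tr <- c(reward_tr, f)
        }
      }
      if (pos >= config$length_cm - 1e-6) break
    }
    bounds[tr, ] <- c(frame0 + 1L, frame0 + f + 1L)
    pos_all <- c(pos_all, p_tr, rep(0, blackout))
    vel_all <- c(vel_all, v_tr, rep(0, blackout))
    lick_all <- c(lick_all, frame0 + lick_tr)
    reward_all <- c(reward_all, frame0 + reward_tr)
    frame0 <- frame0 + f + blackout
  }
  list(position_cm = pos_all, velocity_cm_s = vel_all,
       lick_frames = lick_all, reward_frames = reward_all,
       trial_bounds = bounds, config = config, agent = agent)
}

#' Draw a ground-truth neuronal population
#'
#' Assigns each neuron a functional class (`stable_pc`, `unstable_pc`,
#' `noncoding`) and tuning parameters: field center and width (Gaussian
#' tuning, FWHM in cm), peak transient rate at the field center, baseline
#' (position-independent) event rate, and additive noise SD in
#' \eqn{\Delta F/F} units. Non-coding cells carry no field but a higher
#' baseline event rate so they are active without being spatial.
#'
#' @param n_neurons Number of neurons.
#' @param proportions Named or positional numeric of length 3 summing to 1:
#'   stable_pc, unstable_pc, noncoding.
#' @param config A [corridor_config()].
#' @param field_width_cm Range (length-2) of tuning-curve FWHM in cm.
#' @param peak_rate Transient rate (events/s) at the field center.
#' @param baseline_event_rate Off-field event rate for place cells (events/s).
#' @param noncoding_event_rate Event rate of non-coding cells (events/s).
#' @param noise_sd Additive Gaussian noise SD (\eqn{\Delta F/F}).
#' @param seed Optional seed.
#' @return A tibble, one row per neuron, of class `ground_truth_population`.
#' @export
generate_population <- function(n_neurons,
                                proportions = c(stable_pc = 0.2,
                                                unstable_pc = 0.2,
                                                noncoding = 0.6),
                                config = corridor_config(),
                                field_width_cm = c(15, 30),
                                peak_rate = 2,
                                baseline_event_rate = 0.02,
                                noncoding_event_rate = 0.08,
                                noise_sd = 0.15, seed = NULL) {
  stopifnot(length(proportions) == 3, n_neurons >= 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  local_seed(seed)
  classes <- c("stable_pc", "unstable_pc", "noncoding")
  cls <- sample(classes, n_neurons, replace = TRUE, prob = proportions)
  is_pc <- cls != "noncoding"
  pop <- tibble::tibble(
    neuron = seq_len(n_neurons),
    class = cls,
    field_center_cm = ifelse(is_pc, runif(n_neurons, 0, config$length_cm), NA),
    field_width_cm = ifelse(is_pc, runif(n_neurons, field_width_cm[1],
                                         field_width_cm[2]), NA),
    peak_rate = ifelse(is_pc, peak_rate * rlnorm(n_neurons, 0, 0.2), 0),
    baseline_event_rate = ifelse(is_pc, baseline_event_rate,
                                 noncoding_event_rate),
    noise_sd = noise_sd * rlnorm(n_neurons, 0, 0.1)
  )
  class(pop) <- c("ground_truth_population", class(pop))
  attr(pop, "config") <- config
  pop
}

#' Simulate \eqn{\Delta F/F} traces for a population on a trajectory
#'
#' Place cells emit Poisson transient events at a rate
#' `peak_rate * exp(-(pos - center)^2 / (2 sd^2))` (tuning SD from the FWHM)
#' while the animal runs (>= 5 cm/s) inside a trial, plus position-independent
#' baseline events. Each event is an impulse of roughly unit
#' \eqn{\Delta F/F} amplitude convolved with a GCaMP6f-like kernel
#' (one-frame rise, exponential decay, tau = 0.7 s), with additive Gaussian
#' noise.
#'
#' @param population A [generate_population()] tibble; rows define neurons.
#'   A `field_center_cm` column gives the (session-specific) field center.
#' @param trajectory A [generate_trajectory()] result.
#' @param config A [corridor_config()].
#' @param seed Optional seed.
#' @param decay_tau_s Transient decay time constant in seconds.
#' @param amplitude Mean event amplitude (\eqn{\Delta F/F}).
#' @return Numeric matrix, neurons x frames.
#' @export
generate_dff <- function(population, trajectory, config = trajectory$config,
                         seed = NULL, decay_tau_s = 0.7, amplitude = 1) {
  local_seed(seed)
  fr <- config$frame_rate_hz
  pos <- trajectory$position_cm
  n_frames <- length(pos)
  in_trial <- rep(FALSE, n_frames)
  tb <- trajectory$trial_bounds
  for (t in seq_len(nrow(tb))) in_trial[tb[t, 1]:(tb[t, 2] - 1L)] <- TRUE
  running <- in_trial & trajectory$velocity_cm_s >= 5
  a_decay <- exp(-1 / (decay_tau_s * fr))
  dff <- matrix(0, nrow(population), n_frames)
  for (i in seq_len(nrow(population))) {
    p <- population[i, ]
    rate <- rep(p$baseline_event_rate, n_frames)
    if (!is.na(p$field_center_cm) && p$peak_rate > 0) {
      sd_cm <- p$field_width_cm / (2 * sqrt(2 * log(2)))
      tuning <- exp(-(pos - p$field_center_cm)^2 / (2 * sd_cm^2))
      rate <- rate + p$peak_rate * tuning * running
    }
    n_ev <- rpois(n_frames, rate / fr)
    amp <- numeric(n_frames)
    idx <- which(n_ev > 0)
    if (length(idx)) {
      amp[idx] <- vapply(n_ev[idx], function(k) {
        sum(amplitude * rlnorm(k, 0, 0.25))
      }, numeric(1))
    }
    sig <- as.numeric(stats::filter(amp, a_decay, method = "recursive"))
    dff[i, ] <- sig + rnorm(n_frames, 0, p$noise_sd)
  }
  dff
}

#' Simulate a multi-session experiment with ground truth
#'
#' Generates one session per day of `timeline` from a shared ground-truth
#' population, applying a [perturbation_spec()] to sessions after its onset:
#' a one-time class turnover at onset, rate scaling, and session-to-session
#' remapping of stable cells, all optionally relaxing with the recovery
#' half-life. Unstable place cells resample their field center every session
#' throughout. All neurons are tracked in every session (the registry is
#' complete), and the per-session true class and field center are recorded.
#'
#' @param timeline Sorted integer days (relative to injection).
#' @param population A [generate_population()] tibble.
#' @param config A [corridor_config()].
#' @param perturbation A [perturbation_spec()].
#' @param n_trials Trials per session.
#' @param agent Behavioral agent for baseline sessions.
#' @param post_agent Agent for post-onset sessions (`NULL` = same as
#'   `agent`); set `"naive"` to emulate a behavioral deficit.
#' @param seed Optional seed; per-session substreams are derived from it.
#' @return A list of class `synthetic_experiment` with `sessions` (named
#'   list of [session_data()]), `registry` (tibble: neuron_uid, session_id,
#'   day, roi_index, true_class, field_center_cm), `population`, `config`,
#'   `perturbation`, `timeline`.
#' @export
generate_experiment <- function(timeline, population,
                                config = corridor_config(),
                                perturbation = perturbation_spec(),
                                n_trials = 20, agent = "expert",
                                post_agent = NULL, seed = NULL) {
  stopifnot(!is.unsorted(timeline))
  local_seed(seed)
  pert <- perturbation
  if (pert$onset_day < min(timeline) - 28 || pert$onset_day > max(timeline)) {
    if (pert$class_turnover_prob > 0 || pert$rate_scale < 1 ||
        pert$stability_scale < 1) {
      warning("perturbation onset outside timeline span; perturbation inert")
    }
    pert$class_turnover_prob <- 0
    pert$rate_scale <- 1
    pert$stability_scale <- 1
  }
  n <- nrow(population)
  classes <- c("stable_pc", "unstable_pc", "noncoding")
  class_now <- population$class
  center_now <- population$field_center_cm
  switched <- FALSE
  sessions <- list(); registry <- list()
  for (k in seq_along(timeline)) {
    day <- timeline[k]
    post <- day > pert$onset_day
    decay <- 1
    if (post && !is.null(pert$recovery_halflife_days)) {
      decay <- 0.5^((day - pert$onset_day) / pert$recovery_halflife_days)
    }
    if (post && !switched) { # one-time class turnover at onset
      switched <- TRUE
      flip <- runif(n) < pert$class_turnover_prob
      for (i in which(flip)) {
        class_now[i] <- sample(setdiff(classes, class_now[i]), 1)
      }
      center_now[class_now != "noncoding" & is.na(center_now)] <-
        runif(sum(class_now != "noncoding" & is.na(center_now)),
              0, config$length_cm)
      center_now[class_now == "noncoding"] <- NA
    }
    # unstable cells remap every session; perturbed stable cells may too
    remap <- class_now == "unstable_pc"
    if (post) {
      p_remap <- (1 - pert$stability_scale) * decay
      remap <- remap | (class_now == "stable_pc" & runif(n) < p_remap)
    }
    if (k > 1 && any(remap)) {
      center_now[remap] <- runif(sum(remap), 0, config$length_cm)
    }
    rate_factor <- if (post) 1 - (1 - pert$rate_scale) * decay else 1
    pop_k <- population
    pop_k$class <- class_now
    pop_k$field_center_cm <- ifelse(class_now == "noncoding", NA, center_now)
    pop_k$peak_rate <- ifelse(class_now == "noncoding", 0,
                              population$peak_rate * rate_factor)
    # baseline rate follows the current class (noncoding cells are busier)
    base_nc <- max(population$baseline_event_rate)
    base_pc <- min(population$baseline_event_rate)
    pop_k$baseline_event_rate <- rate_factor *
      ifelse(class_now == "noncoding", base_nc, base_pc)
    agent_k <- if (post && !is.null(post_agent)) post_agent else agent
    traj <- generate_trajectory(config, n_trials, agent = agent_k,
                                seed = child_seed(seed, 2L * k))
    dff <- generate_dff(pop_k, traj, config,
                        seed = child_seed(seed, 2L * k + 1L))
    sid <- sprintf("day_%+03d", day)
    sessions[[sid]] <- session_data(
      dff = dff, position_cm = traj$position_cm,
      velocity_cm_s = traj$velocity_cm_s, lick_frames = traj$lick_frames,
      reward_frames = traj$reward_frames, trial_bounds = traj$trial_bounds,
      day = day, mouse_id = "sim", frame_rate_hz = config$frame_rate_hz)
    registry[[sid]] <- tibble::tibble(
      neuron_uid = seq_len(n), session_id = sid, day = day,
      roi_index = seq_len(n), true_class = class_now,
      field_center_cm = pop_k$field_center_cm)
  }
  structure(list(sessions = sessions,
                 registry = dplyr::bind_rows(registry),
                 population = population, config = config,
                 perturbation = perturbation, timeline = timeline),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> ", length(x$sessions), " sessions (days ",
      paste(range(x$timeline), collapse = " to "), "), ",
      nrow(x$population), " neurons\n", sep = "")
  invisible(x)
}
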