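#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the standard defaults:
#' 5-cm bins, 5 cm/s velocity filter, 5-cm smoothing kernel, 15-cm minimum
#' field width, 6x in/out-field ratio, 20% transient coverage, 3-sigma
#' transients of at least 0.5 s, 50-frame bootstrap chunks, 100 decoder
#' neurons with a 0.5-s activity window, 500 chance shuffles, 95th-
#' percentile synchrony pool, and the 75% outcome threshold. Bootstrap and
#' shuffle counts are scaled down by default so a full synthetic run stays
#' desk-sized; raise them for production analyses.
#'
#' @param corridor A [corridor_config()].
#' @param n_neurons,proportions,n_trials,timeline Synthetic-experiment size.
#' @param perturbation A [perturbation_spec()].
#' @param agent,post_agent Behavioral agents (see [generate_experiment()]).
#' @param velocity_threshold,smooth_sigma_cm,alpha,chunk_frames Analysis
#'   thresholds.
#' @param n_shuffles_bootstrap,n_shuffles_transition,n_shuffles_chance
#'   Resampling sizes.
#' @param n_decoder_neurons,delta_t_s Decoder settings.
#' @param sync_percentile,outcome_threshold Population/behavior settings.
#' @param stages Named logical vector enabling pipeline stages.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(corridor = corridor_config(), n_neurons = 200,
                       proportions = c(stable_pc = 0.2, unstable_pc = 0.2,
                                       noncoding = 0.6),
                       n_trials = 15,
                       timeline = c(-4L, -3L, -2L, -1L, 0L, 3L, 6L),
                       perturbation = perturbation_spec(),
                       agent = "expert", post_agent = NULL,
                       velocity_threshold = 5, smooth_sigma_cm = 5,
                       alpha = 0.05, chunk_frames = 50,
                       n_shuffles_bootstrap = 200,
                       n_shuffles_transition = 1000,
                       n_shuffles_chance = 500,
                       n_decoder_neurons = 100, delta_t_s = 0.5,
                       sync_percentile = 95, outcome_threshold = 75,
                       stages = c(behavior = TRUE, place_cells = TRUE,
                                  transitions = TRUE, decoder = TRUE,
                                  population = TRUE),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[c("velocity_threshold", "smooth_sigma_cm",
                             "alpha", "chunk_frames")],
                       function(v) v > 0, logical(1))))
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on a (synthetic) experiment
#'
#' Simulates an experiment from the configuration (or analyzes a supplied
#' one) and runs the enabled stages in dependency order: behavioral
#' scoring, place-cell detection and stability classification, class
#' transitions against the shuffled null, leave-one-out decoding with
#' empirical chance, and population-structure metrics. Per-stage failures
#' are caught and reported in the `failures` table while the remaining
#' stages proceed. All result tables plus a JSON manifest are written to
#' `out_dir` when it is given.
#'
#' @param config A [run_config()].
#' @param experiment Optional [generate_experiment()] result; `NULL`
#'   simulates one from `config`.
#' @param out_dir Optional output directory for CSV results + manifest.
#' @return Invisibly, a named list of result tables.
#' @export
run_pipeline <- function(config = run_config(), experiment = NULL,
                         out_dir = NULL) {
  stages <- config$stages
  seed <- config$seed
  tables <- list()
  failures <- list()
  note_failure <- function(stage, e) {
    failures[[length(failures) + 1L]] <<-
      tibble::tibble(stage = stage, error = conditionMessage(e))
  }
  if (is.null(experiment)) {
    pop <- generate_population(config$n_neurons, config$proportions,
                               config$corridor, seed = child_seed(seed, 1L))
    experiment <- generate_experiment(
      config$timeline, pop, config$corridor, config$perturbation,
      n_trials = config$n_trials, agent = config$agent,
      post_agent = config$post_agent, seed = child_seed(seed, 2L))
  }
  # a corrupt session is reported and dropped; the others proceed
  ok <- vapply(names(experiment$sessions), function(sid) {
    tryCatch({
      validate_session(experiment$sessions[[sid]])
      TRUE
    }, error = function(e) {
      note_failure(paste0("session:", sid), e)
      FALSE
    })
  }, logical(1))
  sessions <- experiment$sessions[ok]
  if (!length(sessions)) stop("no valid sessions to analyze")
  days <- vapply(sessions, function(s) s$day, numeric(1))
  cfg <- config$corridor

  if (isTRUE(stages[["behavior"]])) {
    tryCatch({
      si <- purrr::imap_dfr(sessions, function(s, sid) {
        tibble::tibble(session_id = sid, day = s$day,
                       si_bits = spatial_information(lick_histogram(s, cfg)))
      })
      perf <- relative_performance(si)
      tables$behavior <- perf
      if (any(perf$phase == "early_post") && any(perf$phase == "late_post")) {
        tables$outcome <- tibble::tibble(
          mouse_id = sessions[[1]]$mouse_id,
          outcome = classify_outcome(perf, injected = TRUE,
                                     threshold = config$outcome_threshold))
      }
    }, error = function(e) note_failure("behavior", e))
  }

  pc_by_session <- NULL
  maps_by_session <- NULL
  if (isTRUE(stages[["place_cells"]])) {
    tryCatch({
      maps_by_session <- lapply(sessions, function(s) {
        smooth_map(bin_activity(s, cfg, config$velocity_threshold),
                   sigma_cm = config$smooth_sigma_cm, reflag = FALSE)
      })
      pc_by_session <- purrr::imap(sessions, function(s, sid) {
        k <- which(names(sessions) == sid)
        detect_place_cells(s, cfg, n_shuffles = config$n_shuffles_bootstrap,
                           seed = child_seed(seed, 100L + k),
                           alpha = config$alpha,
                           velocity_threshold = config$velocity_threshold,
                           chunk_frames = config$chunk_frames)
      })
      tables$place_cells <- purrr::imap_dfr(pc_by_session, function(p, sid) {
        dplyr::mutate(p, session_id = sid,
                      day = sessions[[sid]]$day, .before = 1)
      })
      scores <- stability_scores(
        lapply(maps_by_session, function(m) m$lambda_smooth), days)
      is_pc_phase <- tables$place_cells |>
        dplyr::mutate(phase = session_phase(.data$day)) |>
        dplyr::group_by(neuron = .data$neuron, phase = .data$phase) |>
        dplyr::summarise(is_pc = any(.data$is_pc), .groups = "drop")
      tables$stability <- classify_stability(scores, is_pc_phase)
    }, error = function(e) note_failure("place_cells", e))
  }

  if (isTRUE(stages[["transitions"]]) && is.null(tables$stability)) {
    note_failure("transitions",
                 simpleError("skipped: requires the place_cells stage"))
  }
  if (isTRUE(stages[["transitions"]]) && !is.null(tables$stability)) {
    tryCatch({
      phases <- unique(tables$stability$phase)
      wide <- tidyr::pivot_wider(tables$stability[, c("neuron", "phase", "class")],
                                 names_from = "phase", values_from = "class")
      combos <- utils::combn(intersect(c("healthy", "early_post", "late_post"),
                                       phases), 2, simplify = FALSE)
      tables$transitions <- purrr::map_dfr(seq_along(combos), function(k) {
        pp <- combos[[k]]
        ts <- shuffled_delta_p(wide[[pp[1]]], wide[[pp[2]]],
                               n_shuffles = config$n_shuffles_transition,
                               seed = child_seed(seed, 200L + k))
        dplyr::mutate(tidy(ts), phase_from = pp[1], phase_to = pp[2],
                      .before = 1)
      })
    }, error = function(e) note_failure("transitions", e))
  }

  if (isTRUE(stages[["decoder"]])) {
    tryCatch({
      target <- which(days == max(days[days <= 0]))[1] # last healthy session
      s <- sessions[[target]]
      loo <- loo_within_session(s, cfg, n_neurons = config$n_decoder_neurons,
                                delta_t_s = config$delta_t_s)
      model <- fit_decoder(s, cfg, n_neurons = config$n_decoder_neurons)
      fr <- trial_frames(s)
      chance <- empirical_chance(model, s$dff, fr, s$position_cm[fr],
                                 n_shuffles = config$n_shuffles_chance,
                                 seed = child_seed(seed, 300L))
      tables$decoder <- dplyr::mutate(loo$session,
                                      session_id = names(sessions)[target],
                                      chance_accuracy = chance$accuracy,
                                      chance_sensitivity = chance$sensitivity)
    }, error = function(e) note_failure("decoder", e))
  }

  if (isTRUE(stages[["population"]]) && is.null(maps_by_session)) {
    note_failure("population",
                 simpleError("skipped: requires the place_cells stage"))
  }
  if (isTRUE(stages[["population"]]) && !is.null(maps_by_session)) {
    tryCatch({
      pairs <- list()
      for (a in seq_along(days)) {
        for (b in seq_along(days)) {
          if (b <= a || days[b] - days[a] != 3) next
          if (session_phase(days[a]) != session_phase(days[b])) next
          pairs[[length(pairs) + 1L]] <- c(a, b)
        }
      }
      tables$pvc <- purrr::map_dfr(pairs, function(p) {
        m1 <- maps_by_session[[p[1]]]$lambda_smooth
        m2 <- maps_by_session[[p[2]]]$lambda_smooth
        res <- pvc_curve_stats(pvc_matrix(m1, m2), cfg)
        tibble::tibble(day_a = days[p[1]], day_b = days[p[2]],
                       phase = session_phase(days[p[1]]),
                       y_intercept = res$y_intercept,
                       initial_slope = res$initial_slope,
                       max_rpp = if (length(res$rpp)) max(res$rpp) else NA_real_)
      })
      if (!is.null(tables$stability)) {
        last_healthy <- which(days == max(days[days <= 0]))[1]
        cls <- tables$stability |>
          dplyr::filter(.data$phase == "healthy") |>
          dplyr::arrange(.data$neuron)
        corr <- pairwise_correlations(sessions[[last_healthy]]$dff, "trace")
        pool <- sync_pool_composition(corr, cls$class,
                                      percentile = config$sync_percentile)
        tables$sync_pool <- pool$composition
      }
    }, error = function(e) note_failure("population", e))
  }

  if (length(failures)) tables$failures <- dplyr::bind_rows(failures)
  if (!is.null(out_dir)) {
    keep <- purrr::keep(tables, is.data.frame)
    cfg_manifest <- config
    cfg_manifest$corridor <- unclass(cfg_manifest$corridor)
    cfg_manifest$perturbation <- unclass(cfg_manifest$perturbation)
    save_results(keep, out_dir,
                 config = cfg_manifest[!vapply(cfg_manifest, is.function,
                                               logical(1))],
                 seed = seed)
  }
  invisible(tables)
}
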