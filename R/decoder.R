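#' Fit a Gaussian naive-Bayes position decoder
#'
#' From the training trials' smoothed per-trial spatial maps, computes each
#' neuron's per-bin cross-trial mean `mu` and SD `sigma`, floors per-bin SDs
#' below the neuron's mean per-bin SD to that mean (and everything to a
#' small positive epsilon), estimates the occupancy prior `occ` from
#' velocity-filtered frame counts, and keeps the `n_neurons` neurons with
#' the highest within-session stability among those provided.
#'
#' @param session A [session_data()].
#' @param config A [corridor_config()].
#' @param trials Integer indices of training trials (`NULL` = all).
#' @param stability Optional per-neuron stability used for ranking
#'   (defaults to [within_session_stability()] on the training trials).
#' @param n_neurons Maximum number of neurons kept (default 100).
#' @param sigma_floor Hard lower bound on `sigma` (\eqn{\Delta F/F}).
#' @param velocity_threshold Running-velocity filter for map construction.
#' @return Object of class `decoder_model`: `neuron_ids`, `mu`, `sigma`
#'   (neurons x bins), `occ` (length `n_bins`, sums to 1), `stability`,
#'   `config`.
#' @export
fit_decoder <- function(session, config = corridor_config(), trials = NULL,
                        stability = NULL, n_neurons = 100,
                        sigma_floor = 1e-6, velocity_threshold = 5) {
  sam <- bin_activity(session, config, velocity_threshold)
  sam <- smooth_map(sam, sigma_cm = 5, reflag = FALSE)
  fit_decoder_from_maps(sam$per_trial_smooth, sam$occupancy, config,
                        trials = trials, stability = stability,
                        n_neurons = n_neurons, sigma_floor = sigma_floor)
}

# Core fit from precomputed smoothed per-trial maps (trials x neurons x
# bins) and per-trial occupancy counts (trials x bins); shared with the
# leave-one-out driver so smoothing happens once per session.
fit_decoder_from_maps <- function(per_trial_smooth, occupancy, config,
                                  trials = NULL, stability = NULL,
                                  n_neurons = 100, sigma_floor = 1e-6) {
  nt <- dim(per_trial_smooth)[1]
  if (is.null(trials)) trials <- seq_len(nt)
  if (length(trials) < 2) stop("at least 2 training trials are required")
  pts <- per_trial_smooth[trials, , , drop = FALSE]
  n <- dim(pts)[2]; nb <- dim(pts)[3]
  mu <- apply(pts, c(2, 3), mean, na.rm = TRUE)
  sg <- apply(pts, c(2, 3), sd, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  sg[is.na(sg)] <- 0
  # floor per-bin SDs below the neuron's mean per-bin SD to that mean
  row_mean_sd <- rowMeans(sg)
  for (i in seq_len(n)) {
    sg[i, sg[i, ] < row_mean_sd[i]] <- row_mean_sd[i]
  }
  if (any(row_mean_sd <= 0)) {
    warning("neuron(s) with zero cross-trial variance: sigma floored to epsilon")
  }
  sg <- pmax(sg, sigma_floor)
  occ <- colSums(occupancy[trials, , drop = FALSE])
  occ <- occ / sum(occ)
  if (is.null(stability)) {
    stability <- vapply(seq_len(n), function(i) {
      within_session_stability(pts[, i, , drop = FALSE][, 1, ])
    }, numeric(1))
  }
  keep <- order(stability, decreasing = TRUE, na.last = TRUE)
  keep <- keep[seq_len(min(n_neurons, n))]
  structure(list(neuron_ids = sort(keep),
                 mu = mu[sort(keep), , drop = FALSE],
                 sigma = sg[sort(keep), , drop = FALSE],
                 occ = occ, stability = stability, config = config),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat("<decoder_model> ", nrow(x$mu), " neurons x ", ncol(x$mu),
      " bins\n", sep = "")
  invisible(x)
}

#' @rdname fit_decoder
#' @param x A `decoder_model`.
#' @param ... Unused.
#' @method glance decoder_model
#' @export
glance.decoder_model <- function(x, ...) {
  tibble::tibble(n_neurons = nrow(x$mu), n_bins = ncol(x$mu),
                 min_sigma = min(x$sigma),
                 occ_entropy_bits = -sum(ifelse(x$occ > 0,
                                                x$occ * log2(x$occ), 0)))
}

# Log-likelihood sum over neurons, each neuron's likelihood row normalized
# by its maximum over bins (so every normalized row peaks at 1). Returns
# the frames x bins matrix of summed normalized log-likelihoods.
decoder_loglik <- function(model, s_act) {
  n <- nrow(model$mu); nb <- ncol(model$mu)
  tf <- ncol(s_act)
  acc <- matrix(0, tf, nb)
  for (i in seq_len(n)) {
    inv2s2 <- 1 / (2 * model$sigma[i, ]^2)
    lognorm <- -log(model$sigma[i, ]) - 0.5 * log(2 * pi)
    e <- outer(s_act[i, ], model$mu[i, ], "-")^2
    logp <- -e * rep(inv2s2, each = tf) + rep(lognorm, each = tf)
    rowmax <- logp[cbind(seq_len(tf), max.col(logp, ties.method = "first"))]
    acc <- acc + logp - rowmax
  }
  acc
}

#' Decode position from neural activity
#'
#' For every requested frame, the instantaneous activity `S_i(t)` (mean
#' \eqn{\Delta F/F} over `t +/- delta_t_s`, truncated at the record edges)
#' is scored against each neuron's tuning Gaussian, each neuron's
#' likelihood is normalized by its maximum over bins, and the decoded bin
#' is the argmax of the occupancy-weighted product (computed in log space;
#' ties resolve to the lowest bin index).
#'
#' @param model A [fit_decoder()] model.
#' @param dff Full neurons x frames \eqn{\Delta F/F} matrix of the session
#'   being decoded (rows indexed by the model's `neuron_ids`).
#' @param frame_rate_hz Sampling rate of `dff`.
#' @param delta_t_s Half-width of the activity averaging window (s).
#' @param frames Frames to decode (default: all).
#' @param return_confidence Also return the frames x bins normalized
#'   log-posterior matrix.
#' @return Object of class `decoded_trajectory`: `x_hat` (decoded bin per
#'   frame), `frames`, `delta_t_s`, and optionally `confidence`.
#' @export
decode_frames <- function(model, dff, frame_rate_hz = model$config$frame_rate_hz,
                          delta_t_s = 0.5, frames = NULL,
                          return_confidence = FALSE) {
  if (any(!is.finite(dff))) stop("non-finite values in dff")
  if (is.null(frames)) frames <- seq_len(ncol(dff))
  hw <- round(delta_t_s * frame_rate_hz)
  dm <- dff[model$neuron_ids, , drop = FALSE]
  s_full <- matrix(0, nrow(dm), ncol(dm))
  for (i in seq_len(nrow(dm))) s_full[i, ] <- running_mean(dm[i, ], hw)
  s_act <- s_full[, frames, drop = FALSE]
  acc <- decoder_loglik(model, s_act)
  logocc <- log(model$occ)
  post <- acc + rep(logocc, each = nrow(acc))
  x_hat <- max.col(post, ties.method = "first")
  out <- list(x_hat = x_hat, frames = frames, delta_t_s = delta_t_s,
              config = model$config)
  if (return_confidence) out$confidence <- post
  structure(out, class = "decoded_trajectory")
}

#' Decoder accuracy and reward-zone sensitivity
#'
#' Accuracy is the fraction of frames whose decoded bin equals the true
#' bin. Sensitivity is, among frames where the animal is truly inside a
#' reward zone, the fraction whose decoded bin is also in a reward zone.
#'
#' @param predicted_bins Decoded bin per frame (or a `decoded_trajectory`).
#' @param true_positions_cm True position per decoded frame, in cm.
#' @param config A [corridor_config()].
#' @return One-row tibble: `accuracy`, `sensitivity`, `n_frames`.
#' @export
decoder_metrics <- function(predicted_bins, true_positions_cm,
                            config = corridor_config()) {
  if (inherits(predicted_bins, "decoded_trajectory")) {
    predicted_bins <- predicted_bins$x_hat
  }
  stopifnot(length(predicted_bins) == length(true_positions_cm))
  true_bin <- position_to_bin(true_positions_cm, config)
  rzb <- which(rz_bins(config))
  in_rz <- true_bin %in% rzb
  tibble::tibble(
    accuracy = mean(predicted_bins == true_bin),
    sensitivity = if (any(in_rz)) {
      mean(predicted_bins[in_rz] %in% rzb)
    } else {
      NA_real_
    },
    n_frames = length(true_bin))
}

#' Leave-one-out position decoding within a session
#'
#' Each trial is decoded once by a model fitted on the remaining trials;
#' neuron ranking uses within-session stability computed over all trials.
#' All frames of the held-out trial (including sub-threshold-velocity
#' frames) are decoded.
#'
#' @param session A [session_data()] with >= 3 trials.
#' @param config A [corridor_config()].
#' @param n_neurons,delta_t_s,sigma_floor,velocity_threshold See
#'   [fit_decoder()] / [decode_frames()].
#' @return List of class `loo_decode`: `per_trial` tibble (trial, accuracy,
#'   sensitivity, n_frames) and `session` (fold-mean metrics).
#' @export
loo_within_session <- function(session, config = corridor_config(),
                               n_neurons = 100, delta_t_s = 0.5,
                               sigma_floor = 1e-6, velocity_threshold = 5) {
  nt <- nrow(session$trial_bounds)
  if (nt < 3) stop("leave-one-out decoding requires at least 3 trials")
  sam <- bin_activity(session, config, velocity_threshold)
  sam <- smooth_map(sam, sigma_cm = 5, reflag = FALSE)
  stability <- vapply(seq_len(nrow(session$dff)), function(i) {
    within_session_stability(sam$per_trial_smooth[, i, , drop = FALSE][, 1, ])
  }, numeric(1))
  res <- vector("list", nt)
  for (t in seq_len(nt)) {
    model <- fit_decoder_from_maps(sam$per_trial_smooth, sam$occupancy,
                                   config, trials = setdiff(seq_len(nt), t),
                                   stability = stability,
                                   n_neurons = n_neurons,
                                   sigma_floor = sigma_floor)
    fr <- session$trial_bounds[t, 1]:(session$trial_bounds[t, 2] - 1L)
    traj <- decode_frames(model, session$dff, session$frame_rate_hz,
                          delta_t_s, frames = fr)
    m <- decoder_metrics(traj, session$position_cm[fr], config)
    res[[t]] <- dplyr::mutate(m, trial = t, .before = 1)
  }
  per_trial <- dplyr::bind_rows(res)
  structure(list(
    per_trial = per_trial,
    session = tibble::tibble(
      accuracy = mean(per_trial$accuracy),
      sensitivity = mean(per_trial$sensitivity, na.rm = TRUE),
      n_trials = nt)),
    class = "loo_decode")
}

#' @export
print.loo_decode <- function(x, ...) {
  cat("<loo_decode> ", x$session$n_trials, " folds: accuracy ",
      sprintf("%.3f", x$session$accuracy), ", RZ sensitivity ",
      sprintf("%.3f", x$session$sensitivity), "\n", sep = "")
  invisible(x)
}

#' Cross-session decoding with tracked neurons
#'
#' Fits the decoder on all trials of the training session and decodes every
#' trial frame of the test session, restricted to neurons tracked in both
#' sessions.
#'
#' @param train_session,test_session [session_data()] objects.
#' @param registry Optional tibble with `neuron_uid`, `session_id`,
#'   `roi_index` rows for both sessions (session ids taken from
#'   `sprintf("day_%+03d", day)`); `NULL` assumes identical row ordering.
#' @param config A [corridor_config()].
#' @param ... Passed to [fit_decoder()].
#' @return One-row tibble of decoder metrics.
#' @export
cross_session_decode <- function(train_session, test_session,
                                 registry = NULL,
                                 config = corridor_config(), ...) {
  if (is.null(registry)) {
    if (nrow(train_session$dff) != nrow(test_session$dff)) {
      stop("sessions differ in neuron count; a registry is required")
    }
    roi_train <- roi_test <- seq_len(nrow(train_session$dff))
  } else {
    sid_tr <- sprintf("day_%+03d", train_session$day)
    sid_te <- sprintf("day_%+03d", test_session$day)
    a <- registry[registry$session_id == sid_tr, c("neuron_uid", "roi_index")]
    b <- registry[registry$session_id == sid_te, c("neuron_uid", "roi_index")]
    shared <- intersect(a$neuron_uid, b$neuron_uid)
    if (!length(shared)) stop("no tracked neurons shared between sessions")
    roi_train <- a$roi_index[match(shared, a$neuron_uid)]
    roi_test <- b$roi_index[match(shared, b$neuron_uid)]
  }
  tr <- train_session; tr$dff <- tr$dff[roi_train, , drop = FALSE]
  te <- test_session; te$dff <- te$dff[roi_test, , drop = FALSE]
  model <- fit_decoder(tr, config, ...)
  fr <- trial_frames(te)
  traj <- decode_frames(model, te$dff, te$frame_rate_hz, frames = fr)
  decoder_metrics(traj, te$position_cm[fr], config)
}

#' Empirical chance level of the decoder
#'
#' Shuffles the spatial-bin identity of the training data (`mu`, `sigma`,
#' and the occupancy prior are relabelled by one random bin permutation per
#' shuffle), decodes the target frames with each shuffled model, and
#' averages the metrics. With the full training set relabelled the decoded
#' bin is uniform over bins, so chance accuracy converges to `1/n_bins`.
#'
#' @param model A [fit_decoder()] model.
#' @param dff Session activity matrix (as in [decode_frames()]).
#' @param frames Frames to decode.
#' @param true_positions_cm True positions of those frames.
#' @param n_shuffles Number of bin permutations.
#' @param seed Optional seed.
#' @param delta_t_s Activity window half-width (s).
#' @return List: `accuracy`, `sensitivity` (shuffle means), `se_accuracy`
#'   (Monte-Carlo SE), `per_shuffle` tibble.
#' @export
empirical_chance <- function(model, dff, frames, true_positions_cm,
                             n_shuffles = 500, seed = NULL,
                             delta_t_s = 0.5) {
  local_seed(seed)
  cfg <- model$config
  # posterior of the unshuffled model; a bin relabelling permutes its
  # columns, so each shuffle only remaps the argmax through the inverse
  # permutation
  traj <- decode_frames(model, dff, cfg$frame_rate_hz, delta_t_s,
                        frames = frames)
  x0 <- traj$x_hat
  true_bin <- position_to_bin(true_positions_cm, cfg)
  rzb <- which(rz_bins(cfg))
  in_rz <- true_bin %in% rzb
  nb <- cfg$n_bins
  res <- matrix(NA_real_, n_shuffles, 2,
                dimnames = list(NULL, c("accuracy", "sensitivity")))
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(nb)
    inv <- integer(nb); inv[perm] <- seq_len(nb)
    xs <- inv[x0]
    res[s, 1] <- mean(xs == true_bin)
    res[s, 2] <- if (any(in_rz)) mean(xs[in_rz] %in% rzb) else NA_real_
  }
  list(accuracy = mean(res[, 1]),
       sensitivity = mean(res[, 2], na.rm = TRUE),
       se_accuracy = sd(res[, 1]) / sqrt(n_shuffles),
       per_shuffle = tibble::as_tibble(res))
}
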