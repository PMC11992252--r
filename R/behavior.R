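#' Spatial lick histogram of a session
#'
#' Bins the corridor into `config$lick_bin_count` positions and computes, for
#' each bin, the lick probability `lambda` (fraction of trials with at least
#' one lick in that bin), the occupancy time `t_s` (seconds spent in the bin
#' across trials, no velocity filter), and the normalized occupancy `p`.
#' Bins the animal never visited have `p = 0` and are excluded from
#' occupancy-weighted summaries.
#'
#' @param session A [session_data()].
#' @param config A [corridor_config()].
#' @return A tibble of class `lick_histogram` with columns `bin`,
#'   `center_cm`, `lambda`, `t_s`, `p`; the occupancy-weighted mean lick
#'   probability is stored in attribute `"lambda_bar"`.
#' @export
lick_histogram <- function(session, config = corridor_config()) {
  if (nrow(session$trial_bounds) < 1) stop("session has no trials")
  nb <- config$lick_bin_count
  frames <- trial_frames(session)
  trial <- attr(frames, "trial")
  n_trials <- nrow(session$trial_bounds)
  bin <- position_to_bin(session$position_cm[frames], config, n_bins = nb)
  # occupancy time per bin (s)
  t_s <- tabulate(bin, nbins = nb) / session$frame_rate_hz
  # lick probability: fraction of trials with >= 1 lick in the bin
  lick_idx <- match(session$lick_frames, frames)
  lick_idx <- lick_idx[!is.na(lick_idx)] # licks outside trials are dropped
  lambda <- numeric(nb)
  if (length(lick_idx)) {
    hits <- unique(cbind(trial[lick_idx], bin[lick_idx]))
    cnt <- tabulate(hits[, 2], nbins = nb)
    lambda <- cnt / n_trials
  }
  p <- if (sum(t_s) > 0) t_s / sum(t_s) else t_s
  out <- tibble::tibble(bin = seq_len(nb),
                        center_cm = bin_centers(config, nb),
                        lambda = lambda, t_s = t_s, p = p)
  class(out) <- c("lick_histogram", class(out))
  attr(out, "lambda_bar") <- sum(p * lambda)
  attr(out, "config") <- config
  out
}

#' Spatial information of a lick histogram
#'
#' Occupancy-weighted spatial information content (in bits) of the lick
#' probability profile:
#' \deqn{SI = \sum_i p_i (\lambda_i/\bar\lambda) \log_2(\lambda_i/\bar\lambda)}
#' with \eqn{p_i = t_i / \sum t_i} and
#' \eqn{\bar\lambda = \sum_i p_i \lambda_i}. Bins with zero lick probability
#' contribute nothing (the \eqn{x \log x \to 0} limit), as do unvisited bins
#' (`p = 0`). A session without any licks has undefined concentration and is
#' scored 0 bits with a warning.
#'
#' @param h A [lick_histogram()], or a data frame with columns `lambda` and
#'   `t_s` (or `p`).
#' @return Spatial information in bits (a single number, >= 0).
#' @examples
#' h <- tibble::tibble(lambda = c(1, 0, 0, 0), t_s = rep(1, 4), p = rep(.25, 4))
#' spatial_information(h) # licking confined to 1 of 4 equal bins: 2 bits
#' @export
spatial_information <- function(h) {
  p <- if ("p" %in% names(h)) h$p else h$t_s / sum(h$t_s)
  lambda <- h$lambda
  lambda_bar <- sum(p * lambda)
  if (lambda_bar <= 0) {
    warning("no licks: spatial information defined as 0 bits")
    return(0)
  }
  rel <- lambda / lambda_bar
  term <- ifelse(lambda > 0 & p > 0, p * rel * log2(pmax(rel, .Machine$double.xmin)), 0)
  sum(term)
}

#' Session performance relative to the healthy baseline
#'
#' Expresses each session's spatial-information score as a percentage of the
#' mean score across the healthy (pre-injection) sessions.
#'
#' @param si_by_session A data frame with columns `day` and `si_bits` (one
#'   row per session).
#' @return The input tibble with added columns `phase` and `rel_perf`
#'   (percent of healthy baseline).
#' @export
relative_performance <- function(si_by_session) {
  stopifnot(all(c("day", "si_bits") %in% names(si_by_session)))
  d <- dplyr::mutate(tibble::as_tibble(si_by_session),
                     phase = session_phase(.data$day))
  base <- d$si_bits[d$phase == "healthy"]
  if (length(base) < 1) stop("no healthy session to form a baseline")
  m <- mean(base)
  if (m <= 0) stop("healthy baseline mean is zero; relative performance undefined")
  dplyr::mutate(d, rel_perf = 100 * .data$si_bits / m)
}

#' Behavioral outcome group of a mouse
#'
#' Injected mice at or below 75% of their pre-injection performance in both
#' post-injection phases are `no_recovery`; at or below 75% only early (not
#' late) is `recovery`; above 75% in both phases pools with the shams
#' (`pooled_sham`, optionally gated by a histology override); non-injected
#' mice are `sham`. The 75% boundary is inclusive: a tie goes to the
#' impaired label.
#'
#' @param rel_perf_by_session Output of [relative_performance()] (needs
#'   `phase` and `rel_perf`), or a named vector/list with phase means
#'   `early_post` and `late_post`.
#' @param injected Did the mouse receive a microsphere injection?
#' @param threshold Percent-of-baseline cutoff (default 75).
#' @param sphere_override Pooling an uninjured-looking injected mouse with
#'   the shams additionally requires a sham-like lesion load, which needs
#'   histology; pass `FALSE` to veto pooling (the mouse is then labelled
#'   `"recovery"`). Default `TRUE` (pool on behavior alone).
#' @return One of `"sham"`, `"recovery"`, `"no_recovery"`, `"pooled_sham"`.
#' @export
classify_outcome <- function(rel_perf_by_session, injected = TRUE,
                             threshold = 75, sphere_override = TRUE) {
  if (!injected) return("sham")
  if (is.data.frame(rel_perf_by_session)) {
    ph <- tapply(rel_perf_by_session$rel_perf, rel_perf_by_session$phase, mean)
  } else {
    ph <- unlist(rel_perf_by_session)
  }
  if (!all(c("early_post", "late_post") %in% names(ph)) ||
      anyNA(ph[c("early_post", "late_post")])) {
    stop("phase means for early_post and late_post are required")
  }
  early <- ph[["early_post"]]; late <- ph[["late_post"]]
  if (early <= threshold && late <= threshold) return("no_recovery")
  if (early <= threshold && late > threshold) return("recovery")
  if (isTRUE(sphere_override)) "pooled_sham" else "recovery"
}

#' @rdname lick_histogram
#' @param x A `lick_histogram`.
#' @param ... Unused.
#' @method glance lick_histogram
#' @export
glance.lick_histogram <- function(x, ...) {
  tibble::tibble(si_bits = spatial_information(x),
                 lambda_bar = attr(x, "lambda_bar"),
                 n_bins = nrow(x),
                 occupied_bins = sum(x$p > 0))
}

#' Plot a lick histogram with reward zones shaded
#' @param object A [lick_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lick_histogram
#' @export
autoplot.lick_histogram <- function(object, ...) {
  cfg <- attr(object, "config")
  rz <- tibble::tibble(xmin = cfg$rz_intervals[, 1],
                       xmax = cfg$rz_intervals[, 2])
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(data = rz,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = 0, ymax = Inf),
                       fill = "skyblue", alpha = 0.3) +
    ggplot2::geom_col(ggplot2::aes(x = .data$center_cm, y = .data$lambda),
                      width = cfg$length_cm / cfg$lick_bin_count) +
    ggplot2::labs(x = "corridor position (cm)", y = "lick probability") +
    ggplot2::theme_minimal()
}
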