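#' Corridor geometry and binning configuration
#'
#' Single source of truth for the virtual-corridor coordinate system: track
#' length, spatial binning for neural activity maps, the finer binning used
#' for lick histograms, reward-zone layout, and the imaging frame rate.
#' Positions are in cm from the corridor start; spatial bins are half-open
#' `[k * bin_size, (k + 1) * bin_size)` and indexed from 1 in R.
#'
#' @param length_cm Corridor length in cm.
#' @param bin_size_cm Width of a spatial bin for neural maps, in cm. Must
#'   divide `length_cm` exactly.
#' @param lick_bin_count Number of (finer) bins used for lick histograms.
#' @param rz_centers_cm Centers of the reward zones, in cm.
#' @param rz_width_cm Width of each reward zone, in cm.
#' @param frame_rate_hz Imaging/behavior sampling rate in Hz.
#'
#' @return An object of class `corridor_config`.
#' @examples
#' cfg <- corridor_config()
#' cfg$n_bins # 80 bins of 5 cm
#' @export
corridor_config <- function(length_cm = 400, bin_size_cm = 5,
                            lick_bin_count = 120,
                            rz_centers_cm = c(30, 137, 243, 350),
                            rz_width_cm = 40, frame_rate_hz = 30) {
  stopifnot(length_cm > 0, bin_size_cm > 0, lick_bin_count >= 1,
            rz_width_cm > 0, frame_rate_hz > 0)
  n_bins <- length_cm / bin_size_cm
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("`bin_size_cm` must divide `length_cm` into an integer number of bins",
         call. = FALSE)
  }
  rz <- cbind(start = rz_centers_cm - rz_width_cm / 2,
              end = rz_centers_cm + rz_width_cm / 2)
  if (any(rz[, "start"] < 0) || any(rz[, "end"] > length_cm)) {
    stop("reward zones must lie fully inside the corridor", call. = FALSE)
  }
  structure(list(
    length_cm = length_cm, bin_size_cm = bin_size_cm,
    lick_bin_count = as.integer(lick_bin_count),
    rz_centers_cm = rz_centers_cm, rz_width_cm = rz_width_cm,
    frame_rate_hz = frame_rate_hz,
    n_bins = as.integer(round(n_bins)), rz_intervals = rz
  ), class = "corridor_config")
}

#' @export
print.corridor_config <- function(x, ...) {
  cat("<corridor_config> ", x$length_cm, " cm, ", x$n_bins, " bins of ",
      x$bin_size_cm, " cm, ", nrow(x$rz_intervals), " reward zones, ",
      x$frame_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Map positions to spatial bin indices
#'
#' @param position_cm Numeric vector of positions in cm.
#' @param config A [corridor_config()].
#' @param n_bins Override the bin count (used for lick-histogram binning).
#' @return Integer bin indices in `1:n_bins`; positions at or beyond the
#'   corridor end fall into the last bin.
#' @export
position_to_bin <- function(position_cm, config, n_bins = config$n_bins) {
  w <- config$length_cm / n_bins
  b <- floor(position_cm / w) + 1L
  pmin(pmax(as.integer(b), 1L), as.integer(n_bins))
}

#' Bin centers in cm
#' @inheritParams position_to_bin
#' @return Numeric vector of bin-center positions.
#' @export
bin_centers <- function(config, n_bins = config$n_bins) {
  w <- config$length_cm / n_bins
  (seq_len(n_bins) - 0.5) * w
}

#' Which spatial bins fall inside a reward zone?
#'
#' A bin counts as a reward-zone bin when its center lies inside one of the
#' reward-zone intervals.
#' @inheritParams position_to_bin
#' @return Logical vector of length `n_bins`.
#' @export
rz_bins <- function(config, n_bins = config$n_bins) {
  centers <- bin_centers(config, n_bins)
  in_any <- rep(FALSE, n_bins)
  for (k in seq_len(nrow(config$rz_intervals))) {
    in_any <- in_any | (centers >= config$rz_intervals[k, 1] &
                          centers <= config$rz_intervals[k, 2])
  }
  in_any
}

#' Distance from a position to the nearest reward zone
#'
#' Zero for positions inside a zone, otherwise the distance to the nearest
#' zone edge.
#' @inheritParams position_to_bin
#' @return Numeric vector of distances in cm.
#' @export
rz_distance <- function(position_cm, config) {
  d <- rep(Inf, length(position_cm))
  for (k in seq_len(nrow(config$rz_intervals))) {
    lo <- config$rz_intervals[k, 1]; hi <- config$rz_intervals[k, 2]
    dk <- pmax(pmax(lo - position_cm, position_cm - hi), 0)
    d <- pmin(d, dk)
  }
  d
}

#' Experimental phase of a session day
#'
#' Days are counted relative to the (sham or microsphere) injection:
#' `healthy` up to and including day 0, `early_post` for days 1-7, and
#' `late_post` thereafter.
#'
#' @param day Integer day(s) relative to injection.
#' @return Character vector in `{"healthy", "early_post", "late_post"}`.
#' @examples
#' session_phase(c(-3, 0, 3, 9))
#' @export
session_phase <- function(day) {
  ifelse(day <= 0, "healthy", ifelse(day <= 7, "early_post", "late_post"))
}
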