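#' Rolling mode-percentile of a fluorescence trace
#'
#' Estimates, for a raw fluorescence trace, at which percentile of the data
#' its mode sits. The trace is cut into sliding windows (stride = half the
#' window); in each window the mode is located as the peak of a Gaussian
#' kernel density estimate (Silverman bandwidth) and its percentile rank
#' within the window is computed; the median across windows is returned.
#' For sparse, positively skewed calcium traces this lands below the median
#' (typically around the 40-50th percentile) and is the percentile at which
#' the rolling baseline `F0`/`B0` should be set.
#'
#' @param trace Numeric vector, length >= `window_frames`.
#' @param window_frames Sliding-window length in frames.
#' @return A percentile in (0, 100); 50 by convention for a constant trace.
#' @export
rolling_mode_percentile <- function(trace, window_frames = 1000) {
  n <- length(trace)
  if (n < window_frames) stop("trace shorter than the window")
  stride <- max(1L, as.integer(window_frames / 2))
  starts <- seq(1L, n - window_frames + 1L, by = stride)
  pct <- vapply(starts, function(s) {
    w <- trace[s:(s + window_frames - 1L)]
    if (diff(range(w)) < .Machine$double.eps * 10) return(50)
    d <- density(w, n = 512)
    mode_w <- d$x[which.max(d$y)]
    100 * mean(w <= mode_w)
  }, numeric(1))
  median(pct)
}

#' Detrended \eqn{\Delta F/F} from fluorescence components
#'
#' Elementwise `(F - F0) / (B0 + F0)`, where `F` is the background-corrected
#' ROI fluorescence and `F0`, `B0` are the rolling baselines of the ROI and
#' background traces (set at the [rolling_mode_percentile()] of each trace).
#'
#' @param f,f0,b0 Numeric vectors of equal length.
#' @return The \eqn{\Delta F/F} trace.
#' @export
compute_dff <- function(f, f0, b0) {
  stopifnot(length(f) == length(f0), length(f) == length(b0))
  den <- b0 + f0
  bad <- which(den == 0)
  if (length(bad)) {
    stop("zero denominator (B0 + F0) at frame(s) ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  (f - f0) / den
}

#' Velocity-filtered spatial binning of a session
#'
#' Bins each neuron's \eqn{\Delta F/F} by corridor position (5-cm bins by
#' default), excluding frames outside trials and frames with running
#' velocity below `velocity_threshold` (strictly below; frames at the
#' threshold are kept). Produces per-trial maps, the across-trial mean map,
#' and per-bin occupancy. Bins a trial never visits at running speed are
#' missing (`NA`), not zero.
#'
#' @param session A [session_data()].
#' @param config A [corridor_config()].
#' @param velocity_threshold Minimum running velocity (cm/s).
#' @return An object of class `spatial_activity_map`: a list with `lambda`
#'   (neurons x bins trial-mean map), `per_trial` (trials x neurons x bins
#'   array), `occupancy` (trials x bins kept-frame counts), `kept_frames`,
#'   `kept_bins`, `kept_trials` (aligned vectors describing the retained
#'   frames), and the `config`.
#' @export
bin_activity <- function(session, config = corridor_config(),
                         velocity_threshold = 5) {
  frames <- trial_frames(session)
  trial <- attr(frames, "trial")
  keep <- session$velocity_cm_s[frames] >= velocity_threshold
  if (!any(keep)) stop("no frames at or above the velocity threshold")
  frames <- frames[keep]; trial <- trial[keep]
  bin <- position_to_bin(session$position_cm[frames], config)
  nb <- config$n_bins
  n_trials <- nrow(session$trial_bounds)
  n_neurons <- nrow(session$dff)
  grp <- (trial - 1L) * nb + bin # trial x bin cell index
  counts <- tabulate(grp, nbins = n_trials * nb)
  # sums per (trial, bin) for every neuron at once
  sums <- rowsum(t(session$dff[, frames, drop = FALSE]), group = grp,
                 reorder = TRUE)
  cell_ids <- as.integer(rownames(sums))
  per_trial <- array(NA_real_, c(n_trials, n_neurons, nb))
  tr_of <- (cell_ids - 1L) %/% nb + 1L
  bin_of <- (cell_ids - 1L) %% nb + 1L
  for (j in seq_along(cell_ids)) {
    per_trial[tr_of[j], , bin_of[j]] <- sums[j, ] / counts[cell_ids[j]]
  }
  lambda <- apply(per_trial, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  structure(list(
    lambda = lambda,
    per_trial = per_trial,
    occupancy = matrix(counts, n_trials, nb, byrow = TRUE),
    kept_frames = frames, kept_bins = bin, kept_trials = trial,
    velocity_threshold = velocity_threshold,
    config = config
  ), class = "spatial_activity_map")
}

#' @export
print.spatial_activity_map <- function(x, ...) {
  cat("<spatial_activity_map> ", nrow(x$lambda), " neurons x ",
      ncol(x$lambda), " bins, ", dim(x$per_trial)[1], " trials, ",
      length(x$kept_frames), " kept frames\n", sep = "")
  invisible(x)
}

# Gaussian-smooth one map row. Missing bins are linearly interpolated from
# their neighbors before smoothing; with reflag = TRUE they are set back to
# NA afterwards. Reflective (mirror) boundaries conserve total mass.
smooth_vec <- function(v, sigma_bins, reflag = TRUE) {
  nb <- length(v)
  miss <- is.na(v)
  if (all(miss)) return(v)
  if (any(miss)) {
    idx <- which(!miss)
    v <- approx(idx, v[idx], xout = seq_len(nb), rule = 2)$y
  }
  if (sigma_bins > 0) {
    r <- max(1L, ceiling(4 * sigma_bins))
    k <- dnorm(seq(-r, r), sd = sigma_bins)
    k <- k / sum(k)
    pad <- c(v[pmin(r:1, nb)], v, v[pmax(nb - 1:r + 1L, 1L)])
    v <- as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + nb)]
  }
  if (reflag) v[miss] <- NA_real_
  v
}

#' Gaussian smoothing of spatial activity maps
#'
#' Smooths along the position axis with a Gaussian kernel of SD `sigma_cm`
#' using reflective (mirror) boundaries, which conserve total map mass.
#' Missing bins are interpolated from neighbors before smoothing and
#' re-flagged as missing afterwards (`reflag = FALSE` keeps the
#' interpolated values, as the decoder requires). `sigma_cm = 0` is the
#' identity.
#'
#' @param x A numeric vector (one map row), a neurons x bins matrix, or a
#'   `spatial_activity_map`.
#' @param sigma_cm Kernel SD in cm.
#' @param bin_size_cm Bin width (taken from the map's config when `x` is a
#'   `spatial_activity_map`).
#' @param reflag Restore missing bins after smoothing?
#' @return Same shape as the input; for a `spatial_activity_map`, the object
#'   gains `lambda_smooth` and `per_trial_smooth` components.
#' @export
smooth_map <- function(x, sigma_cm = 5, bin_size_cm = 5, reflag = TRUE) {
  if (inherits(x, "spatial_activity_map")) {
    bs <- x$config$bin_size_cm
    x$lambda_smooth <- smooth_map(x$lambda, sigma_cm, bs, reflag)
    pt <- x$per_trial
    for (t in seq_len(dim(pt)[1])) {
      pt[t, , ] <- smooth_map(pt[t, , , drop = FALSE][1, , ],
                              sigma_cm, bs, reflag)
    }
    x$per_trial_smooth <- pt
    return(x)
  }
  sigma_bins <- sigma_cm / bin_size_cm
  if (is.matrix(x)) {
    t(apply(x, 1, smooth_vec, sigma_bins = sigma_bins, reflag = reflag))
  } else {
    smooth_vec(as.numeric(x), sigma_bins, reflag)
  }
}

#' Plot a spatial activity map as a position x neuron heatmap
#' @param object A `spatial_activity_map`.
#' @param smoothed Plot the smoothed maps if present.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spatial_activity_map
#' @export
autoplot.spatial_activity_map <- function(object, smoothed = TRUE, ...) {
  m <- if (smoothed && !is.null(object$lambda_smooth)) {
    object$lambda_smooth
  } else {
    object$lambda
  }
  # order neurons by peak position for the classic sequence plot
  ord <- order(apply(m, 1, function(v) if (all(is.na(v))) NA else which.max(v)))
  df <- tidyr::expand_grid(neuron = seq_len(nrow(m)), bin = seq_len(ncol(m)))
  df$dff <- as.vector(t(m[ord, , drop = FALSE]))
  df$position_cm <- bin_centers(object$config)[df$bin]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_cm, y = .data$neuron,
                                   fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "corridor position (cm)", y = "neuron (sorted by peak)",
                  fill = "mean ΔF/F") +
    ggplot2::theme_minimal()
}
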