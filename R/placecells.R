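#' Noise level of a trace from the FWHM of its value distribution
#'
#' The noise SD sigma is estimated from the full width at half maximum of
#' the central peak of the \eqn{\Delta F/F} value distribution (Gaussian
#' KDE): `sigma = FWHM / (2 sqrt(2 ln 2))`. Sparse positive transients
#' broaden the right tail but barely move the central peak, so the estimate
#' tracks the noise floor rather than the signal.
#'
#' @param trace Numeric vector (>= 100 frames for a stable estimate).
#' @return Noise SD in \eqn{\Delta F/F} units (0 for a constant trace).
#' @export
noise_sigma_fwhm <- function(trace) {
  if (diff(range(trace)) < .Machine$double.eps * 100) {
    warning("constant trace: noise sigma set to 0")
    return(0)
  }
  d <- density(trace, n = 1024)
  i0 <- which.max(d$y)
  half <- d$y[i0] / 2
  # walk out from the peak to the half-maximum crossings, interpolating
  left <- d$x[1]
  for (i in seq(i0, 2)) {
    if (d$y[i - 1] < half) {
      left <- approx(d$y[(i - 1):i], d$x[(i - 1):i], xout = half)$y
      break
    }
  }
  right <- d$x[length(d$x)]
  for (i in seq(i0, length(d$y) - 1)) {
    if (d$y[i + 1] < half) {
      right <- approx(d$y[i:(i + 1)], d$x[i:(i + 1)], xout = half)$y
      break
    }
  }
  (right - left) / (2 * sqrt(2 * log(2)))
}

#' Significant calcium transients of a trace
#'
#' Maximal runs of frames with \eqn{\Delta F/F} above `3 * sigma` lasting at
#' least 0.5 s.
#'
#' @param dff Numeric trace.
#' @param sigma Noise SD (see [noise_sigma_fwhm()]).
#' @param frame_rate_hz Sampling rate.
#' @param min_duration_s Minimum duration (s).
#' @param n_sigma Threshold in units of sigma.
#' @return Integer matrix with columns `start`, `end` (inclusive, 1-based);
#'   zero rows when no transient qualifies.
#' @export
significant_transients <- function(dff, sigma, frame_rate_hz = 30,
                                   min_duration_s = 0.5, n_sigma = 3) {
  stopifnot(sigma >= 0)
  min_len <- ceiling(min_duration_s * frame_rate_hz)
  runs <- true_runs(dff > n_sigma * sigma)
  runs[runs[, "end"] - runs[, "start"] + 1L >= min_len, , drop = FALSE]
}

#' Candidate place fields of a smoothed spatial map row
#'
#' The baseline is the mean of the lowest quartile of bin values; candidate
#' fields are maximal runs of bins strictly above
#' `baseline + 0.25 * (max - baseline)`. A flat map yields no candidates.
#'
#' @param map_row Numeric vector of bin values with no missing entries
#'   (smooth with `reflag = FALSE` first).
#' @return Integer matrix with columns `start`, `end` (inclusive bin
#'   indices).
#' @export
candidate_fields <- function(map_row) {
  stopifnot(!anyNA(map_row))
  nb <- length(map_row)
  q <- sort(map_row)[seq_len(max(1L, floor(nb / 4)))]
  baseline <- mean(q)
  mx <- max(map_row)
  if (mx <= baseline + .Machine$double.eps * 100) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  thr <- baseline + 0.25 * (mx - baseline)
  true_runs(map_row > thr)
}

#' Evaluate the three place-field acceptance criteria for one candidate
#'
#' (1) width of at least 15 cm; (2) mean in-field activity at least 6x the
#' mean out-of-field activity (when the out-of-field mean is not positive,
#' the criterion holds whenever the in-field mean is positive); (3)
#' significant transients covering at least 20% of the velocity-filtered
#' frames the animal spent moving inside the field.
#'
#' @param run Length-2 integer vector or 1-row matrix, inclusive bin bounds.
#' @param map_row Smoothed map row used for detection.
#' @param transient_mask Logical per-frame vector: frame lies inside a
#'   significant transient (see [significant_transients()]).
#' @param kept_frames,kept_bins Velocity-filtered frames and their bins, as
#'   produced by [bin_activity()].
#' @param bin_size_cm Bin width.
#' @param min_width_cm,in_out_ratio,min_coverage Criterion thresholds.
#' @return A one-row tibble with the measured quantities, per-criterion
#'   flags and overall `pass`.
#' @export
field_criteria <- function(run, map_row, transient_mask, kept_frames,
                           kept_bins, bin_size_cm = 5, min_width_cm = 15,
                           in_out_ratio = 6, min_coverage = 0.2) {
  run <- as.integer(run)
  bins <- run[1]:run[2]
  width_cm <- length(bins) * bin_size_cm
  mean_in <- mean(map_row[bins])
  mean_out <- mean(map_row[-bins])
  pass_width <- width_cm >= min_width_cm
  pass_ratio <- if (mean_out <= 0) {
    mean_in > 0
  } else {
    mean_in * (1 + 1e-9) >= in_out_ratio * mean_out
  }
  sel <- kept_bins >= run[1] & kept_bins <= run[2]
  coverage <- if (any(sel)) mean(transient_mask[kept_frames[sel]]) else 0
  pass_coverage <- coverage >= min_coverage
  tibble::tibble(bin_start = run[1], bin_end = run[2], width_cm = width_cm,
                 mean_in = mean_in, mean_out = mean_out, coverage = coverage,
                 pass_width = pass_width, pass_ratio = pass_ratio,
                 pass_coverage = pass_coverage,
                 pass = pass_width && pass_ratio && pass_coverage)
}

# ---- internal fast path reused by detection and bootstrap ---------------

# Precompute everything about a session's binning that is independent of
# the trace, so the bootstrap can re-run detection cheaply.
pc_context <- function(session, config, velocity_threshold = 5) {
  sam_frames <- trial_frames(session)
  trial <- attr(sam_frames, "trial")
  keep <- session$velocity_cm_s[sam_frames] >= velocity_threshold
  frames <- sam_frames[keep]; trial <- trial[keep]
  bins <- position_to_bin(session$position_cm[frames], config)
  nb <- config$n_bins
  n_trials <- nrow(session$trial_bounds)
  grp <- (trial - 1L) * nb + bins
  counts <- tabulate(grp, nbins = n_trials * nb)
  occupied <- which(counts > 0)
  list(frames = frames, bins = bins, grp = grp, counts = counts,
       occupied = occupied,
       tr_of = (occupied - 1L) %/% nb + 1L,
       bin_of = (occupied - 1L) %% nb + 1L,
       nb = nb, n_trials = n_trials,
       sigma_bins = 5 / config$bin_size_cm,
       min_tr_len = ceiling(0.5 * session$frame_rate_hz),
       fr = session$frame_rate_hz)
}

# Smoothed (interpolated, not reflagged) trial-mean map of one trace.
trace_mean_map <- function(trace, ctx) {
  sums <- rowsum(trace[ctx$frames], group = ctx$grp, reorder = TRUE)
  m <- matrix(NA_real_, ctx$n_trials, ctx$nb)
  m[cbind(ctx$tr_of, ctx$bin_of)] <- sums[, 1] / ctx$counts[ctx$occupied]
  row <- colMeans(m, na.rm = TRUE)
  row[is.nan(row)] <- NA_real_
  smooth_vec(row, ctx$sigma_bins, reflag = FALSE)
}

# Lean bootstrap path: does any candidate field of this trace pass all
# three criteria? Identical logic to detect_fields_trace without building
# result tables.
any_passing_field <- function(trace, mask, ctx, bin_size_cm,
                              min_width_cm = 15, in_out_ratio = 6,
                              min_coverage = 0.2) {
  row <- trace_mean_map(trace, ctx)
  runs <- candidate_fields(row)
  if (nrow(runs) == 0) return(FALSE)
  min_bins <- ceiling(min_width_cm / bin_size_cm)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_bins, ,
               drop = FALSE]
  if (nrow(runs) == 0) return(FALSE)
  tmask_kept <- NULL
  for (j in seq_len(nrow(runs))) {
    bins <- runs[j, "start"]:runs[j, "end"]
    mean_in <- mean(row[bins])
    mean_out <- mean(row[-bins])
    ok_ratio <- if (mean_out <= 0) {
      mean_in > 0
    } else {
      mean_in * (1 + 1e-9) >= in_out_ratio * mean_out
    }
    if (!ok_ratio) next
    if (is.null(tmask_kept)) {
      tmask_kept <- filter_runs(mask, ctx$min_tr_len)[ctx$frames]
    }
    sel <- ctx$bins >= runs[j, "start"] & ctx$bins <= runs[j, "end"]
    if (any(sel) && mean(tmask_kept[sel]) >= min_coverage) return(TRUE)
  }
  FALSE
}

# Full three-criterion detection for one trace; mask is the per-frame
# above-3-sigma indicator (before the duration filter). Returns the fields
# tibble (possibly 0-row).
detect_fields_trace <- function(trace, mask, ctx, bin_size_cm,
                                min_width_cm = 15, in_out_ratio = 6,
                                min_coverage = 0.2) {
  row <- trace_mean_map(trace, ctx)
  runs <- candidate_fields(row)
  if (nrow(runs) == 0) {
    return(field_criteria(c(1L, 1L), rep(0, ctx$nb), logical(0),
                          integer(0), integer(0))[0, ])
  }
  tmask <- filter_runs(mask, ctx$min_tr_len)
  dplyr::bind_rows(lapply(seq_len(nrow(runs)), function(j) {
    field_criteria(runs[j, ], row, tmask, ctx$frames, ctx$bins,
                   bin_size_cm = bin_size_cm, min_width_cm = min_width_cm,
                   in_out_ratio = in_out_ratio, min_coverage = min_coverage)
  }))
}

#' Bootstrap significance of place-field detection for one cell
#'
#' The \eqn{\Delta F/F} trace is split into 50-frame chunks whose order is
#' randomly permuted against the fixed behavior (position and velocity are
#' unchanged), the full detection (candidate screening plus all three
#' criteria) is re-run on the shuffled trace, and `p_pf` is the fraction of
#' shuffles in which a place field passes all three criteria. The final
#' partial chunk is kept as its own piece.
#'
#' @param trace One neuron's \eqn{\Delta F/F} trace.
#' @param session The [session_data()] the trace belongs to.
#' @param config A [corridor_config()].
#' @param chunk_frames Chunk length (frames).
#' @param n_shuffles Number of shuffles.
#' @param seed Optional seed.
#' @param velocity_threshold Running-velocity filter (cm/s).
#' @return `p_pf` in `[0, 1]`.
#' @export
bootstrap_pvalue <- function(trace, session, config = corridor_config(),
                             chunk_frames = 50, n_shuffles = 1000,
                             seed = NULL, velocity_threshold = 5) {
  stopifnot(length(trace) >= 2 * chunk_frames)
  local_seed(seed)
  ctx <- pc_context(session, config, velocity_threshold)
  sigma <- noise_sigma_fwhm(trace)
  mask <- trace > 3 * sigma
  chunks <- split(seq_along(trace),
                  ceiling(seq_along(trace) / chunk_frames))
  hits <- 0L
  for (s in seq_len(n_shuffles)) {
    perm <- unlist(chunks[sample.int(length(chunks))], use.names = FALSE)
    if (any_passing_field(trace[perm], mask[perm], ctx, config$bin_size_cm)) {
      hits <- hits + 1L
    }
  }
  hits / n_shuffles
}

#' Is a cell a place cell?
#'
#' True when at least one detected field passes all three criteria and the
#' cell's bootstrap significance `p_pf` is at most `alpha`.
#'
#' @param fields Fields tibble (from [detect_place_cells()] internals) with
#'   a `pass` column.
#' @param p_pf Bootstrap p-value of the cell.
#' @param alpha Significance level.
#' @return Logical scalar.
#' @export
classify_place_cell <- function(fields, p_pf, alpha = 0.05) {
  !is.null(fields) && nrow(fields) > 0 && any(fields$pass) &&
    !is.na(p_pf) && p_pf <= alpha
}

#' Detect place cells in a session
#'
#' Runs the complete per-neuron detection: velocity-filtered spatial maps,
#' Gaussian smoothing, candidate screening, the three field criteria, and
#' chunk-shuffle bootstrap significance. The bootstrap is only run for
#' neurons with at least one passing field (others cannot become place
#' cells regardless of `p_pf`).
#'
#' @param session A [session_data()].
#' @param config A [corridor_config()].
#' @param n_shuffles Bootstrap shuffles per cell.
#' @param seed Optional seed.
#' @param alpha Place-cell significance level on `p_pf`.
#' @param velocity_threshold Running-velocity filter (cm/s).
#' @param chunk_frames Bootstrap chunk length.
#' @return A tibble, one row per neuron: `neuron`, `n_fields`,
#'   `n_passing_fields`, `p_pf` (NA when no field passes), `is_pc`, and the
#'   best passing field's bounds/width. All detected fields are in
#'   attribute `"fields"`.
#' @export
detect_place_cells <- function(session, config = corridor_config(),
                               n_shuffles = 1000, seed = NULL, alpha = 0.05,
                               velocity_threshold = 5, chunk_frames = 50) {
  local_seed(seed)
  ctx <- pc_context(session, config, velocity_threshold)
  n <- nrow(session$dff)
  chunks <- split(seq_len(ncol(session$dff)),
                  ceiling(seq_len(ncol(session$dff)) / chunk_frames))
  rows <- vector("list", n)
  all_fields <- vector("list", n)
  for (i in seq_len(n)) {
    trace <- session$dff[i, ]
    sigma <- noise_sigma_fwhm(trace)
    mask <- trace > 3 * sigma
    f <- detect_fields_trace(trace, mask, ctx, config$bin_size_cm)
    p_pf <- NA_real_
    if (nrow(f) && any(f$pass)) {
      hits <- 0L
      for (s in seq_len(n_shuffles)) {
        perm <- unlist(chunks[sample.int(length(chunks))], use.names = FALSE)
        if (any_passing_field(trace[perm], mask[perm], ctx,
                              config$bin_size_cm)) {
          hits <- hits + 1L
        }
      }
      p_pf <- hits / n_shuffles
    }
    is_pc <- classify_place_cell(f, p_pf, alpha)
    best <- if (nrow(f) && any(f$pass)) {
      fp <- f[f$pass, ]
      fp[which.max(fp$mean_in), ]
    } else {
      NULL
    }
    rows[[i]] <- tibble::tibble(
      neuron = i, n_fields = nrow(f),
      n_passing_fields = if (nrow(f)) sum(f$pass) else 0L,
      p_pf = p_pf, is_pc = is_pc,
      field_start = if (is.null(best)) NA_integer_ else best$bin_start,
      field_end = if (is.null(best)) NA_integer_ else best$bin_end,
      field_width_cm = if (is.null(best)) NA_real_ else best$width_cm)
    if (nrow(f)) all_fields[[i]] <- dplyr::mutate(f, neuron = i)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fields") <- dplyr::bind_rows(all_fields)
  class(out) <- c("place_cell_table", class(out))
  out
}

#' Within-session stability of a neuron's spatial map
#'
#' Pearson correlation between the mean maps of the first and second halves
#' of the trials, and between odd and even trials; the two coefficients are
#' Fisher z-transformed, averaged, and transformed back.
#'
#' @param per_trial_maps Trials x bins matrix of one neuron's per-trial
#'   (smoothed) maps; `NA` bins are ignored in trial means.
#' @return The combined correlation, or `NA` with fewer than 4 trials or
#'   degenerate maps.
#' @export
within_session_stability <- function(per_trial_maps) {
  nt <- nrow(per_trial_maps)
  if (is.null(nt) || nt < 4) return(NA_real_)
  half <- floor(nt / 2)
  mean_map <- function(rows) {
    v <- colMeans(per_trial_maps[rows, , drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  r_half <- safe_cor(mean_map(1:half), mean_map((half + 1):nt))
  r_oe <- safe_cor(mean_map(seq(1, nt, 2)), mean_map(seq(2, nt, 2)))
  fisher_mean(c(r_half, r_oe))
}

#' Cross-session stability score of one neuron for one phase
#'
#' Pearson correlations of the neuron's (smoothed) session maps over all
#' session pairs 3 days apart within the phase, Fisher-averaged and
#' back-transformed.
#'
#' @param session_maps Sessions x bins matrix of one neuron's maps.
#' @param days Integer day per session (same order as rows).
#' @param phase Restrict to pairs whose sessions both fall in this phase
#'   (`NULL` uses all 3-day pairs regardless of phase).
#' @param pair_gap_days Required day separation (default 3).
#' @return Fisher-mean correlation, or `NA` without a qualifying pair.
#' @export
cross_session_stability <- function(session_maps, days, phase = NULL,
                                    pair_gap_days = 3) {
  stopifnot(nrow(session_maps) == length(days))
  ph <- session_phase(days)
  rs <- c()
  for (a in seq_along(days)) {
    for (b in seq_along(days)) {
      if (b <= a) next
      if (abs(days[b] - days[a]) != pair_gap_days) next
      if (!is.null(phase) && !(ph[a] == phase && ph[b] == phase)) next
      va <- session_maps[a, ]; vb <- session_maps[b, ]
      ok <- !is.na(va) & !is.na(vb)
      if (sum(ok) < 3 || sd(va[ok]) == 0 || sd(vb[ok]) == 0) next
      rs <- c(rs, cor(va[ok], vb[ok]))
    }
  }
  fisher_mean(rs)
}

#' Per-neuron, per-phase stability scores across an experiment
#'
#' @param maps_by_session Named list (by session) of neurons x bins map
#'   matrices with consistent neuron ordering (tracked cells).
#' @param days Integer day per session.
#' @return Tibble with `neuron`, `phase`, `score`.
#' @export
stability_scores <- function(maps_by_session, days) {
  stopifnot(length(maps_by_session) == length(days))
  n <- nrow(maps_by_session[[1]])
  nb <- ncol(maps_by_session[[1]])
  phases <- unique(session_phase(days))
  out <- list()
  for (ph in phases) {
    scores <- vapply(seq_len(n), function(i) {
      m <- do.call(rbind, lapply(maps_by_session, function(x) x[i, ]))
      cross_session_stability(m, days, phase = ph)
    }, numeric(1))
    out[[ph]] <- tibble::tibble(neuron = seq_len(n), phase = ph,
                                score = scores)
  }
  dplyr::bind_rows(out)
}

#' Classify tracked cells as stable/unstable place cells or non-coding
#'
#' The network baseline is the median pre-injection (healthy) stability
#' score across all neurons. Within each phase, a place cell whose score
#' exceeds the baseline is `stable_pc`; at or below it (ties included) it
#' is `unstable_pc`; cells that are not place cells in that phase are
#' `noncoding`.
#'
#' @param scores Tibble from [stability_scores()].
#' @param is_pc Tibble with `neuron`, `phase`, `is_pc` (a cell's place-cell
#'   status in that phase, e.g. detected in at least one session of it).
#' @param baseline Network baseline; defaults to the median healthy score.
#' @param healthy_persistent Optional logical vector indexed by neuron: did
#'   the cell keep a place field across all healthy sessions? When given,
#'   a healthy-phase cell is `stable_pc` only if also persistent (the
#'   day-by-day persistence reading of healthy stability); post phases are
#'   untouched. `NULL` (default) applies the median split alone.
#' @return Tibble `neuron`, `phase`, `score`, `is_pc`, `class`, plus the
#'   baseline in attribute `"baseline"`.
#' @export
classify_stability <- function(scores, is_pc, baseline = NULL,
                               healthy_persistent = NULL) {
  if (is.null(baseline)) {
    hs <- scores$score[scores$phase == "healthy"]
    if (!length(hs) || all(is.na(hs))) {
      stop("no healthy scores to establish the network baseline")
    }
    baseline <- median(hs, na.rm = TRUE)
  }
  d <- dplyr::left_join(scores, is_pc, by = c("neuron", "phase"))
  d$is_pc[is.na(d$is_pc)] <- FALSE
  d$class <- dplyr::case_when(
    !d$is_pc ~ "noncoding",
    !is.na(d$score) & d$score > baseline ~ "stable_pc",
    TRUE ~ "unstable_pc"
  )
  if (!is.null(healthy_persistent)) {
    demote <- d$phase == "healthy" & d$class == "stable_pc" &
      !healthy_persistent[d$neuron]
    d$class[demote] <- "unstable_pc"
  }
  attr(d, "baseline") <- baseline
  d
}
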