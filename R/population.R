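#' Population vector correlation matrix between two sessions
#'
#' For tracked neurons with spatial maps \eqn{\lambda^1, \lambda^2} in two
#' sessions, the PVC between positions `x` and `y` is the cosine similarity
#' of the across-neuron activity vectors:
#' \deqn{PVC(x,y) = \frac{\sum_j \lambda_j^1(x) \lambda_j^2(y)}
#'   {\sqrt{(\sum_j \lambda_j^1(x)^2)(\sum_j \lambda_j^2(y)^2)}}}
#' It is invariant to global rescaling of either session's maps.
#'
#' @param maps1,maps2 Neurons x bins matrices (same neurons, same order,
#'   same bin count; no missing values — use interpolated smoothed maps).
#' @return Bins x bins matrix; entries where either position's population
#'   vector is all-zero are `NA`.
#' @export
pvc_matrix <- function(maps1, maps2) {
  stopifnot(dim(maps1) == dim(maps2), !anyNA(maps1), !anyNA(maps2))
  num <- crossprod(maps1, maps2) # bins x bins
  n1 <- sqrt(colSums(maps1^2)); n2 <- sqrt(colSums(maps2^2))
  den <- outer(n1, n2)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' PVC curve and its summary metrics
#'
#' Averages the PVC matrix over all position pairs at each location offset
#' `|x - y|` from 0 up to `max_offset_cm`. The y-intercept (offset 0) is
#' the same-position cross-session correlation of the population; the
#' maximum absolute initial slope over offsets 0-100 cm (discrete
#' differences, reported per 100 cm) measures spatial precision.
#'
#' @param matrix Bins x bins PVC matrix (missing entries are skipped).
#' @param config A [corridor_config()].
#' @param max_offset_cm Largest offset included in the curve.
#' @param slope_range_cm Offset range scanned for the initial slope.
#' @return Object of class `pvc_result`: tibble-backed `curve`
#'   (`offset_cm`, `pvc`), `y_intercept`, `initial_slope` (per 100 cm), and
#'   `rpp` (relative peak prominences of the curve).
#' @export
pvc_curve_stats <- function(matrix, config = corridor_config(),
                            max_offset_cm = 275, slope_range_cm = 100) {
  nb <- ncol(matrix)
  bs <- config$length_cm / nb
  offsets <- seq(0, max_offset_cm, by = bs)
  curve <- vapply(offsets, function(off) {
    k <- as.integer(round(off / bs))
    idx <- which(row(matrix) - col(matrix) == k | col(matrix) - row(matrix) == k)
    mean(matrix[idx], na.rm = TRUE)
  }, numeric(1))
  n_slope <- as.integer(slope_range_cm / bs)
  d <- abs(diff(curve[seq_len(n_slope + 1L)]))
  structure(list(
    curve = tibble::tibble(offset_cm = offsets, pvc = curve),
    y_intercept = curve[1],
    initial_slope = max(d, na.rm = TRUE) * (100 / bs),
    rpp = rpp(curve),
    config = config), class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat("<pvc_result> y-intercept ", sprintf("%.3f", x$y_intercept),
      ", max initial slope ", sprintf("%.3f", x$initial_slope),
      " per 100 cm, ", length(x$rpp), " peak(s)\n", sep = "")
  invisible(x)
}

#' @rdname pvc_curve_stats
#' @param x A `pvc_result`.
#' @param ... Unused.
#' @method tidy pvc_result
#' @export
tidy.pvc_result <- function(x, ...) x$curve

#' @rdname pvc_curve_stats
#' @method glance pvc_result
#' @export
glance.pvc_result <- function(x, ...) {
  tibble::tibble(y_intercept = x$y_intercept,
                 initial_slope = x$initial_slope,
                 n_peaks = length(x$rpp),
                 max_rpp = if (length(x$rpp)) max(x$rpp) else NA_real_)
}

#' Plot a PVC curve
#' @param object A `pvc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pvc_result
#' @export
autoplot.pvc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$offset_cm, y = .data$pvc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "location offset (cm)",
                  y = "population vector correlation") +
    ggplot2::theme_minimal()
}

#' Relative peak prominence of a curve
#'
#' Local maxima of the curve are compared with the mean of their flanking
#' local minima (or the curve ends): `rpp = (peak - mean(valleys)) / peak`.
#' Monotone or flat curves have no peaks and return an empty vector.
#'
#' @param curve Numeric vector (length >= 5), e.g. a PVC curve.
#' @return Numeric vector of relative prominences, one per interior peak.
#' @export
rpp <- function(curve) {
  stopifnot(length(curve) >= 5)
  n <- length(curve)
  peaks <- integer(0); valleys <- c(1L)
  for (i in 2:(n - 1)) {
    left <- curve[i] - curve[i - 1]; right <- curve[i + 1] - curve[i]
    if (left > 0 && right < 0) peaks <- c(peaks, i)
    if (left < 0 && right > 0) valleys <- c(valleys, i)
  }
  valleys <- c(valleys, n)
  out <- vapply(peaks, function(p) {
    lv <- valleys[valleys < p]; rv <- valleys[valleys > p]
    lmin <- curve[lv[length(lv)]]; rmin <- curve[rv[1]]
    (curve[p] - mean(c(lmin, rmin))) / curve[p]
  }, numeric(1))
  out
}

#' Pairwise Pearson correlations between neurons
#'
#' In `trace` mode, correlates \eqn{\Delta F/F} traces over frames
#' ("pairwise firing activity", synchrony in time); in `map` mode,
#' correlates spatial activity maps over bins ("spatial synchronicity").
#'
#' @param x Neurons x (frames or bins) matrix; `NA` entries are dropped
#'   pairwise (map mode).
#' @param mode `"trace"` or `"map"` (labels the result; computation is the
#'   Pearson correlation across columns either way).
#' @return Symmetric neurons x neurons correlation matrix with unit
#'   diagonal; rows of zero-variance neurons are `NA` (diagonal stays 1).
#' @export
pairwise_correlations <- function(x, mode = c("trace", "map")) {
  mode <- match.arg(mode)
  stopifnot(nrow(x) >= 2)
  m <- suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  sds <- apply(x, 1, sd, na.rm = TRUE)
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m) <- 1
  attr(m, "mode") <- mode
  m
}

#' Highly synchronous cell pairs and their class composition
#'
#' Thresholds the off-diagonal upper-triangle correlations at the given
#' percentile (midpoint interpolation); pairs strictly above form the
#' synchronous pool. For every unordered class pair, reports the fraction
#' of that class pair's cells pairs that land in the pool (under
#' class-independent correlations this converges to `1 - percentile/100`)
#' and, as an alternative reading, each class pair's share of the pool.
#'
#' @param corr_matrix Symmetric correlation matrix (e.g.
#'   [pairwise_correlations()]).
#' @param classes Class label per neuron.
#' @param percentile Pool threshold percentile (default 95).
#' @return List of class `sync_pool`: `threshold`, `pool` (tibble of pairs
#'   above threshold), and `composition` (tibble per class pair:
#'   `n_pairs`, `n_in_pool`, `frac_in_pool`, `share_of_pool`).
#' @export
sync_pool_composition <- function(corr_matrix, classes, percentile = 95) {
  n <- nrow(corr_matrix)
  stopifnot(length(classes) == n)
  ut <- upper.tri(corr_matrix)
  i <- row(corr_matrix)[ut]; j <- col(corr_matrix)[ut]
  r <- corr_matrix[ut]
  ok <- !is.na(r)
  i <- i[ok]; j <- j[ok]; r <- r[ok]
  if (length(r) < 20) warning("fewer than 20 pairs: percentile unstable")
  thr <- quantile(r, percentile / 100, type = 2, names = FALSE)
  in_pool <- r > thr
  pair_class <- purrr::map2_chr(classes[i], classes[j],
                                ~ paste(sort(c(.x, .y)), collapse = "-"))
  comp <- tibble::tibble(pair_class = pair_class, in_pool = in_pool) |>
    dplyr::group_by(.data$pair_class) |>
    dplyr::summarise(n_pairs = dplyr::n(), n_in_pool = sum(.data$in_pool),
                     .groups = "drop") |>
    dplyr::mutate(frac_in_pool = .data$n_in_pool / .data$n_pairs,
                  share_of_pool = .data$n_in_pool / sum(.data$n_in_pool))
  structure(list(
    threshold = thr, percentile = percentile,
    pool = tibble::tibble(neuron_a = i[in_pool], neuron_b = j[in_pool],
                          r = r[in_pool],
                          pair_class = pair_class[in_pool]),
    composition = comp), class = "sync_pool")
}

#' @export
print.sync_pool <- function(x, ...) {
  cat("<sync_pool> ", nrow(x$pool), " pairs above the ", x$percentile,
      "th percentile (threshold ", sprintf("%.3f", x$threshold), ")\n",
      sep = "")
  print(x$composition)
  invisible(x)
}

#' Cosine similarity of two correlation structures
#'
#' Flattens the strict upper triangles of two neuron correlation matrices
#' (same neurons, same order) and returns their cosine similarity; entries
#' missing in either matrix are dropped pairwise.
#'
#' @param corr_a,corr_b Square correlation matrices of equal dimension.
#' @return Cosine similarity in `[-1, 1]`, or `NA` for a zero-norm vector.
#' @export
correlation_similarity <- function(corr_a, corr_b) {
  stopifnot(dim(corr_a) == dim(corr_b))
  ut <- upper.tri(corr_a)
  a <- corr_a[ut]; b <- corr_b[ut]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Phase-averaged pairwise correlations matched across phase pairs
#'
#' Computes trace correlations per session, averages each cell pair's
#' coefficient across the sessions of each phase (cells must be present in
#' every session of both phases; with a complete registry this is all
#' cells), then, for each pair of phases, correlates and regresses the
#' matched coefficients. Phase pairs whose correlation p-value exceeds
#' `alpha` are flagged `excluded`.
#'
#' @param sessions Named list of [session_data()] (names are session ids).
#' @param alpha Significance threshold for exclusion (default 0.05).
#' @return List of class `phase_pairwise`: `pair_means` (tibble: pair,
#'   phase, mean r) and `regressions` (tibble per phase pair: `r`, `p`,
#'   `slope`, `n_pairs`, `excluded`).
#' @export
phase_averaged_pairwise <- function(sessions, alpha = 0.05) {
  stopifnot(length(sessions) >= 2)
  days <- vapply(sessions, function(s) s$day, numeric(1))
  phases <- session_phase(days)
  n <- nrow(sessions[[1]]$dff)
  ut <- NULL
  by_phase <- list()
  for (ph in unique(phases)) {
    mats <- lapply(sessions[phases == ph], function(s) {
      pairwise_correlations(s$dff, mode = "trace")
    })
    if (is.null(ut)) ut <- upper.tri(mats[[1]])
    stacked <- vapply(mats, function(m) m[ut], numeric(sum(ut)))
    by_phase[[ph]] <- rowMeans(as.matrix(stacked))
  }
  phase_names <- names(by_phase)
  combos <- utils::combn(phase_names, 2, simplify = FALSE)
  regressions <- purrr::map_dfr(combos, function(pp) {
    a <- by_phase[[pp[1]]]; b <- by_phase[[pp[2]]]
    ok <- !is.na(a) & !is.na(b)
    ct <- cor.test(a[ok], b[ok])
    slope <- coef(lm(b[ok] ~ a[ok]))[2]
    tibble::tibble(phase_a = pp[1], phase_b = pp[2], n_pairs = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value,
                   slope = unname(slope), excluded = ct$p.value > alpha)
  })
  idx <- which(ut, arr.ind = TRUE)
  pair_means <- purrr::imap_dfr(by_phase, function(v, ph) {
    tibble::tibble(neuron_a = idx[, 1], neuron_b = idx[, 2], phase = ph,
                   mean_r = v)
  })
  structure(list(pair_means = pair_means, regressions = regressions),
            class = "phase_pairwise")
}

#' Place-field distances to reward zones
#'
#' For each place field (center = position of maximal smoothed in-field
#' activity), the distance to the nearest reward-zone edge (0 inside a
#' zone) and a `in` / `close` / `far` category, plus the stability
#' contrast: mean distance of unstable minus stable place cells.
#'
#' @param fields Tibble with `neuron` and `center_cm` (field centers), and
#'   optionally a `class` column (`stable_pc` / `unstable_pc`).
#' @param config A [corridor_config()].
#' @param close_threshold_cm Boundary between `close` and `far` (cm).
#' @return List of class `field_geometry`: `fields` (input plus
#'   `rz_distance_cm`, `category`) and `stability_contrast_cm` (`NA`
#'   without class labels).
#' @export
field_rz_geometry <- function(fields, config = corridor_config(),
                              close_threshold_cm = 25) {
  d <- rz_distance(fields$center_cm, config)
  cat_ <- ifelse(d == 0, "in", ifelse(d <= close_threshold_cm, "close", "far"))
  out <- dplyr::mutate(tibble::as_tibble(fields), rz_distance_cm = d,
                       category = cat_)
  contrast <- NA_real_
  if ("class" %in% names(fields)) {
    mu_u <- mean(d[fields$class == "unstable_pc"], na.rm = TRUE)
    mu_s <- mean(d[fields$class == "stable_pc"], na.rm = TRUE)
    contrast <- mu_u - mu_s
  }
  structure(list(fields = out, stability_contrast_cm = contrast),
            class = "field_geometry")
}

#' Pairwise anatomical distance versus synchrony
#'
#' Euclidean distances between ROI centroids for every neuron pair, and
#' the Pearson correlation between distance and pairwise synchrony.
#'
#' @param centroids Neurons x 2 matrix of centroid coordinates (micrometer).
#' @param corr_matrix Pairwise correlation matrix of the same neurons.
#' @return List: `pairs` (tibble neuron_a, neuron_b, distance_um, r) and
#'   `distance_synchrony_r`.
#' @export
pair_euclidean_distance <- function(centroids, corr_matrix) {
  stopifnot(ncol(centroids) == 2, nrow(centroids) == nrow(corr_matrix))
  dm <- as.matrix(dist(centroids))
  ut <- upper.tri(dm)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- tibble::tibble(neuron_a = idx[, 1], neuron_b = idx[, 2],
                          distance_um = dm[ut], r = corr_matrix[ut])
  ok <- !is.na(pairs$r)
  rr <- if (sum(ok) >= 3 && sd(pairs$distance_um[ok]) > 0 &&
            sd(pairs$r[ok]) > 0) {
    cor(pairs$distance_um[ok], pairs$r[ok])
  } else {
    NA_real_
  }
  list(pairs = pairs, distance_synchrony_r = rr)
}
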