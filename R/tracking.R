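# Phase cross-correlation shift between two equally sized images, with
# parabolic sub-pixel refinement. Returns c(dy, dx): b is a translated by
# this amount (rows, cols).
phase_corr_shift <- function(a, b) {
  eps <- .Machine$double.eps
  fa <- fft(a); fb <- fft(b)
  r <- fb * Conj(fa)
  r <- r / (Mod(r) + eps)
  cc <- Re(fft(r, inverse = TRUE)) / length(r)
  peak <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  n <- dim(cc)
  wrap <- function(i, d) ifelse(i > d / 2, i - d, i) # 0-based offset
  refine <- function(p, d, neighbor) {
    # parabolic interpolation over the peak and its two neighbors
    im <- ((p - 2) %% d) + 1L; ip <- (p %% d) + 1L
    ym <- neighbor(im); y0 <- neighbor(p); yp <- neighbor(ip)
    den <- ym - 2 * y0 + yp
    if (abs(den) < eps) 0 else 0.5 * (ym - yp) / den
  }
  dy <- wrap(peak[1] - 1L, n[1]) +
    refine(peak[1], n[1], function(i) cc[i, peak[2]])
  dx <- wrap(peak[2] - 1L, n[2]) +
    refine(peak[2], n[2], function(i) cc[peak[1], i])
  c(dy = dy, dx = dx)
}

#' Patchwise sub-pixel shift field between two fields of view
#'
#' Splits both images into a square grid of patches (2 x 2 by default),
#' estimates each patch's sub-pixel translation by phase cross-correlation,
#' and interpolates the patch shifts to a per-pixel displacement field,
#' accommodating non-rigid tissue deformation between sessions. A
#' featureless (flat) patch inherits the mean shift of the others.
#'
#' @param fov_a,fov_b Numeric matrices of identical dimensions (e.g. mean
#'   intensity images of the two sessions).
#' @param n_patches Number of patches; must be a perfect square.
#' @return Object of class `shift_field`: `dy`, `dx` (per-pixel matrices,
#'   the displacement taking session-A coordinates to session B),
#'   `patch_shifts` (tibble), and the patch grid size.
#' @export
estimate_shift_field <- function(fov_a, fov_b, n_patches = 4) {
  stopifnot(all(dim(fov_a) == dim(fov_b)))
  g <- round(sqrt(n_patches))
  stopifnot(g * g == n_patches)
  nr <- nrow(fov_a); nc <- ncol(fov_a)
  ry <- floor(seq(0, nr, length.out = g + 1))
  rx <- floor(seq(0, nc, length.out = g + 1))
  sy <- matrix(NA_real_, g, g); sx <- matrix(NA_real_, g, g)
  cy <- (head(ry, -1) + tail(ry, -1) + 1) / 2
  cx <- (head(rx, -1) + tail(rx, -1) + 1) / 2
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      pa <- fov_a[(ry[i] + 1):ry[i + 1], (rx[j] + 1):rx[j + 1]]
      pb <- fov_b[(ry[i] + 1):ry[i + 1], (rx[j] + 1):rx[j + 1]]
      if (sd(pa) < 1e-12 || sd(pb) < 1e-12) next # featureless patch
      s <- phase_corr_shift(pa, pb)
      sy[i, j] <- s["dy"]; sx[i, j] <- s["dx"]
    }
  }
  if (anyNA(sy)) {
    if (all(is.na(sy))) stop("all patches featureless; cannot estimate shifts")
    warning("featureless patch(es): shift set to the mean of the others")
    sy[is.na(sy)] <- mean(sy, na.rm = TRUE)
    sx[is.na(sx)] <- mean(sx, na.rm = TRUE)
  }
  interp_grid <- function(s) {
    if (g == 1) return(matrix(s[1, 1], nr, nc))
    rows_interp <- t(vapply(seq_len(g), function(i) {
      approx(cx, s[i, ], xout = seq_len(nc), rule = 2)$y
    }, numeric(nc)))
    vapply(seq_len(nc), function(j) {
      approx(cy, rows_interp[, j], xout = seq_len(nr), rule = 2)$y
    }, numeric(nr))
  }
  structure(list(dy = interp_grid(sy), dx = interp_grid(sx),
                 patch_shifts = tibble::tibble(
                   patch_row = rep(seq_len(g), times = g),
                   patch_col = rep(seq_len(g), each = g),
                   dy = as.vector(sy), dx = as.vector(sx)),
                 grid = g), class = "shift_field")
}

#' @export
print.shift_field <- function(x, ...) {
  cat("<shift_field> ", x$grid, "x", x$grid, " patches, mean shift (",
      sprintf("%.2f", mean(x$dy)), ", ", sprintf("%.2f", mean(x$dx)),
      ") px\n", sep = "")
  invisible(x)
}

#' Match ROIs across sessions by mutual nearest neighbors
#'
#' Displaces session-A centroids by the shift field, then pairs cells that
#' are mutual nearest neighbors; pairs within `max_dist_px` are accepted.
#' The automatic acceptance rule stands in for manual curation of matches.
#'
#' @param centroids_a,centroids_b N x 2 matrices of `(x, y)` centroids in
#'   pixel coordinates of their own session.
#' @param shift_field A [estimate_shift_field()] result (or `NULL` for no
#'   displacement).
#' @param max_dist_px Acceptance radius in pixels (about 20 micrometer at
#'   830 um / 512 px).
#' @return Tibble of class `match_table`: `roi_a`, `roi_b`, `distance_px`,
#'   `accepted` — one row per mutual-nearest-neighbor pair.
#' @export
match_cells <- function(centroids_a, centroids_b, shift_field = NULL,
                        max_dist_px = 12) {
  empty <- tibble::tibble(roi_a = integer(0), roi_b = integer(0),
                          distance_px = numeric(0), accepted = logical(0))
  if (!nrow(centroids_a) || !nrow(centroids_b)) {
    return(structure(empty, class = c("match_table", class(empty))))
  }
  a <- as.matrix(centroids_a)
  if (!is.null(shift_field)) {
    nr <- nrow(shift_field$dy); nc <- ncol(shift_field$dy)
    px <- pmin(pmax(round(a[, 1]), 1), nc)
    py <- pmin(pmax(round(a[, 2]), 1), nr)
    at <- cbind(py, px)
    a <- a + cbind(shift_field$dx[at], shift_field$dy[at])
  }
  b <- as.matrix(centroids_b)
  dm <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  dm <- sqrt(dm)
  nn_ab <- apply(dm, 1, which.min)
  nn_ba <- apply(dm, 2, which.min)
  mutual <- which(nn_ba[nn_ab] == seq_len(nrow(a)))
  out <- tibble::tibble(
    roi_a = mutual, roi_b = nn_ab[mutual],
    distance_px = dm[cbind(mutual, nn_ab[mutual])])
  out$accepted <- out$distance_px <= max_dist_px
  structure(out, class = c("match_table", class(empty)))
}

#' Render a synthetic field of view from ROI centroids
#'
#' Places an isotropic Gaussian blob at every centroid and adds Gaussian
#' pixel noise — a synthetic stand-in for a session's mean intensity image,
#' used to exercise the shift estimation and matching on known ground
#' truth.
#'
#' @param centroids N x 2 matrix of `(x, y)` blob centers in pixels.
#' @param dim Image size `c(rows, cols)`.
#' @param sigma_px Blob SD in pixels.
#' @param amplitude Blob peak intensity.
#' @param noise_sd Additive noise SD.
#' @param seed Optional seed.
#' @return A `dim[1]` x `dim[2]` numeric matrix.
#' @export
simulate_fov <- function(centroids, dim = c(128, 128), sigma_px = 2.5,
                         amplitude = 1, noise_sd = 0.02, seed = NULL) {
  local_seed(seed)
  img <- matrix(0, dim[1], dim[2])
  xs <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]), dim[1], dim[2])
  for (k in seq_len(nrow(centroids))) {
    img <- img + amplitude *
      exp(-((xs - centroids[k, 1])^2 + (ys - centroids[k, 2])^2) /
            (2 * sigma_px^2))
  }
  img + matrix(rnorm(length(img), 0, noise_sd), dim[1], dim[2])
}
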