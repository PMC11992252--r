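CLASS_LEVELS <- c("stable_pc", "unstable_pc", "noncoding")

#' Functional-class transition probabilities between two time points
#'
#' `P(a -> b)` is the fraction of cells labelled `a` at the first time point
#' that are labelled `b` at the second. Rows with an empty from-class are
#' `NA`.
#'
#' @param labels_t1,labels_t2 Class labels of the same tracked cells at the
#'   two time points (same length and order). Cells labelled `"absent"` or
#'   `NA` at either time point are dropped pairwise.
#' @param classes Class universe defining the matrix dimensions.
#' @return A `length(classes)` square matrix of transition probabilities;
#'   rows sum to 1 (or are all `NA`).
#' @export
transition_probabilities <- function(labels_t1, labels_t2,
                                     classes = CLASS_LEVELS) {
  stopifnot(length(labels_t1) == length(labels_t2))
  ok <- !is.na(labels_t1) & !is.na(labels_t2) &
    labels_t1 != "absent" & labels_t2 != "absent"
  f1 <- factor(labels_t1[ok], levels = classes)
  f2 <- factor(labels_t2[ok], levels = classes)
  counts <- table(from = f1, to = f2)
  n_from <- rowSums(counts)
  p <- unclass(counts) / ifelse(n_from > 0, n_from, NA)
  p[n_from == 0, ] <- NA_real_
  p
}

#' Transition excess over a shuffled-class null (Delta P)
#'
#' Compares observed transition probabilities with a chance distribution in
#' which the second time point's class labels are randomly permuted across
#' cells. `delta_p = P_true - mean(P_shuffle)`; positive entries mark
#' transitions that occur more often than expected if classes reshuffled at
#' random, and the per-entry shuffle SD supports z-scoring.
#'
#' @inheritParams transition_probabilities
#' @param n_shuffles Number of label permutations (>= 100).
#' @param seed Optional seed.
#' @return Object of class `transition_stats`: list with `p_true`,
#'   `p_shuffle`, `delta_p`, `shuffle_sd` (matrices), `n_cells`,
#'   `n_shuffles`.
#' @export
shuffled_delta_p <- function(labels_t1, labels_t2, n_shuffles = 1000,
                             seed = NULL, classes = CLASS_LEVELS) {
  stopifnot(n_shuffles >= 100)
  local_seed(seed)
  ok <- !is.na(labels_t1) & !is.na(labels_t2) &
    labels_t1 != "absent" & labels_t2 != "absent"
  l1 <- labels_t1[ok]; l2 <- labels_t2[ok]
  p_true <- transition_probabilities(l1, l2, classes)
  k <- length(classes)
  acc <- matrix(0, k, k); acc2 <- matrix(0, k, k)
  for (s in seq_len(n_shuffles)) {
    ps <- transition_probabilities(l1, sample(l2), classes)
    ps[is.na(ps)] <- 0 # empty from-classes stay empty in every shuffle
    acc <- acc + ps
    acc2 <- acc2 + ps^2
  }
  p_shuffle <- acc / n_shuffles
  shuffle_sd <- sqrt(pmax(acc2 / n_shuffles - p_shuffle^2, 0))
  empty <- is.na(p_true[, 1])
  p_shuffle[empty, ] <- NA_real_
  shuffle_sd[empty, ] <- NA_real_
  dimnames(p_shuffle) <- dimnames(shuffle_sd) <- dimnames(p_true)
  structure(list(p_true = p_true, p_shuffle = p_shuffle,
                 delta_p = p_true - p_shuffle, shuffle_sd = shuffle_sd,
                 n_cells = length(l1), n_shuffles = n_shuffles),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("<transition_stats> ", x$n_cells, " cells, ", x$n_shuffles,
      " shuffles\ndelta_p:\n", sep = "")
  print(round(x$delta_p, 4))
  invisible(x)
}

#' @rdname shuffled_delta_p
#' @param x A `transition_stats`.
#' @param ... Unused.
#' @return For `tidy()`: one row per (from, to) pair with `p_true`,
#'   `p_shuffle`, `delta_p`, `shuffle_sd`, `n`.
#' @method tidy transition_stats
#' @export
tidy.transition_stats <- function(x, ...) {
  k <- nrow(x$p_true)
  cls <- rownames(x$p_true)
  tibble::tibble(
    from_class = rep(cls, times = k),
    to_class = rep(cls, each = k),
    p_true = as.vector(x$p_true),
    p_shuffle = as.vector(x$p_shuffle),
    delta_p = as.vector(x$delta_p),
    shuffle_sd = as.vector(x$shuffle_sd),
    n = x$n_cells)
}

#' Heatmap of transition excess over chance
#' @param object A `transition_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transition_stats
#' @export
autoplot.transition_stats <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to_class, y = .data$from_class,
                                  fill = .data$delta_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%+.2f", .data$delta_p))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "class at t2", y = "class at t1",
                  fill = expression(Delta * P)) +
    ggplot2::theme_minimal()
}
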