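#' Empirical ROC operating points
#'
#' Computes the empirical ROC curve for one reader from two score vectors,
#' using the convention "positive if score >= threshold". One operating
#' point is produced per distinct threshold, and the endpoints (0, 0) and
#' (1, 1) are always present.
#'
#' @param scores_benign Numeric vector of scores for actually negative
#'   (benign) cases.
#' @param scores_malignant Numeric vector of scores for actually positive
#'   (malignant) cases.
#' @return A tibble of class `empirical_roc` with columns `threshold`
#'   (`Inf` for the (0,0) corner, `-Inf` for (1,1)), `fpf` and `tpf`, in
#'   nondecreasing fpf/tpf order.
#' @examples
#' empirical_roc(c(10, 40), c(35, 90))
#' @export
empirical_roc <- function(scores_benign, scores_malignant) {
  check_two_classes(scores_benign, scores_malignant)
  thr <- sort(unique(c(scores_benign, scores_malignant)), decreasing = TRUE)
  fpf <- vapply(thr, function(t) mean(scores_benign >= t), numeric(1))
  tpf <- vapply(thr, function(t) mean(scores_malignant >= t), numeric(1))
  out <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    fpf = c(0, fpf, 1),
    tpf = c(0, tpf, 1)
  )
  out <- dplyr::distinct(out, .data$fpf, .data$tpf, .keep_all = TRUE)
  class(out) <- c("empirical_roc", class(out))
  out
}

#' Wilcoxon (trapezoidal) AUC
#'
#' The Mann-Whitney estimator of the area under the empirical ROC curve:
#' the fraction of (benign, malignant) pairs in which the malignant case
#' outscores the benign one, ties counting one half. Equals the
#' trapezoidal area under [empirical_roc()].
#'
#' @inheritParams empirical_roc
#' @return A number in \[0, 1\].
#' @examples
#' wilcoxon_auc(c(1, 3), c(2, 4))  # 0.75
#' @export
wilcoxon_auc <- function(scores_benign, scores_malignant) {
  check_two_classes(scores_benign, scores_malignant)
  n0 <- length(scores_benign)
  n1 <- length(scores_malignant)
  r <- rank(c(scores_benign, scores_malignant), ties.method = "average")
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Trapezoidal area under a set of ROC points
#'
#' @param roc An `empirical_roc` tibble (or any data frame with `fpf`,
#'   `tpf` in nondecreasing order).
#' @return The trapezoidal area.
#' @export
trapezoid_auc <- function(roc) {
  fpf <- roc$fpf
  tpf <- roc$tpf
  sum(diff(fpf) * (head(tpf, -1) + tpf[-1]) / 2)
}

check_two_classes <- function(scores_benign, scores_malignant) {
  if (length(scores_benign) == 0 || length(scores_malignant) == 0) {
    abort("both score vectors must be nonempty")
  }
  if (anyNA(scores_benign) || anyNA(scores_malignant)) {
    abort("scores contain missing values")
  }
  invisible(TRUE)
}

# internal: Wilcoxon AUC plus all leave-one-case-out values in
# O(n log n) via placement sums. Returns theta, loo_benign (aligned to
# scores_benign order) and loo_malignant.
wilcoxon_loo <- function(scores_benign, scores_malignant) {
  n0 <- length(scores_benign)
  n1 <- length(scores_malignant)
  if (n0 < 2 || n1 < 2) abort("insufficient cases for jackknife")
  sx <- sort(scores_benign)
  sy <- sort(scores_malignant)
  # wins for each malignant: #{benign < y} + 0.5 #{benign == y}
  leq_x <- findInterval(scores_malignant, sx)
  less_x <- findInterval(scores_malignant, sx, left.open = TRUE)
  q <- less_x + 0.5 * (leq_x - less_x)
  w <- sum(q)
  # placement of each benign: #{malignant > x} + 0.5 #{malignant == x}
  leq_y <- findInterval(scores_benign, sy)
  less_y <- findInterval(scores_benign, sy, left.open = TRUE)
  p <- (n1 - leq_y) + 0.5 * (leq_y - less_y)
  list(
    theta = w / (n0 * n1),
    loo_benign = (w - p) / ((n0 - 1) * n1),
    loo_malignant = (w - q) / (n0 * (n1 - 1))
  )
}

#' @method autoplot empirical_roc
#' @export
autoplot.empirical_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpf, y = .data$tpf)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive fraction",
                  y = "True positive fraction") +
    ggplot2::theme_minimal()
}
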