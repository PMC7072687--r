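#' Fit a binormal ROC curve by maximum likelihood
#'
#' Fits the two-parameter binormal ROC model
#' \deqn{TPF = \Phi(a + b\,\Phi^{-1}(FPF))}
#' to rating data by the Dorfman-Alf categorical likelihood: scores are
#' reduced to at most `max_bins` ordered categories (quantile binning of
#' the pooled scores when the number of distinct values exceeds
#' `max_bins`), and `(a, b)` together with the latent category cutpoints
#' maximise the product-multinomial likelihood of the two class-conditional
#' category counts. The latent benign distribution is standard normal and
#' the malignant distribution is N(a/b, 1/b).
#'
#' Optimisation uses multiple starting slopes (b in 0.5, 1, 2) to avoid
#' local optima. On degenerate data (perfect separation or
#' non-convergence) a half-count continuity correction is added to the
#' extreme category cells and the fit retried; if that also fails the
#' returned curve has `b = 1` and `a = sqrt(2) * qnorm(AUC_w)` (the
#' Wilcoxon AUC inverse), flagged `converged = FALSE`.
#'
#' @inheritParams empirical_roc
#' @param max_bins Maximum number of rating categories used in the
#'   likelihood; default 20.
#' @return An object of class `binormal_fit`: a list with elements `a`,
#'   `b`, `loglik`, `n_bins`, `converged`, `cutpoints`, `auc`.
#' @examples
#' set.seed(1)
#' fit <- fit_binormal(rnorm(500), rnorm(500, 1.2))
#' fit$a; fit$b; fit$auc
#' @export
fit_binormal <- function(scores_benign, scores_malignant, max_bins = 20) {
  check_two_classes(scores_benign, scores_malignant)
  pooled <- c(scores_benign, scores_malignant)
  if (length(unique(pooled)) < 2) {
    abort("no discrimination information: a single distinct score value")
  }

  breaks <- binormal_breaks(pooled, max_bins)
  n0k <- bin_counts(scores_benign, breaks)
  n1k <- bin_counts(scores_malignant, breaks)
  keep <- (n0k + n1k) > 0
  n0k <- n0k[keep]
  n1k <- n1k[keep]
  k <- length(n0k)
  auc_w <- wilcoxon_auc(scores_benign, scores_malignant)

  fit <- dorfman_alf_ml(n0k, n1k, auc_w)
  if (!fit$converged) {
    # continuity correction on the extreme category cells, then refit
    n0c <- n0k
    n1c <- n1k
    n0c[c(1, k)] <- n0c[c(1, k)] + 0.5
    n1c[c(1, k)] <- n1c[c(1, k)] + 0.5
    fit2 <- dorfman_alf_ml(n0c, n1c, auc_w)
    if (fit2$converged) {
      fit <- fit2
      fit$converged <- FALSE   # a corrected fit, flagged for the caller
    } else {
      fit <- list(a = sqrt(2) * qnorm(min(max(auc_w, 1e-6), 1 - 1e-6)),
                  b = 1, loglik = NA_real_, cutpoints = numeric(0),
                  converged = FALSE)
    }
  }

  structure(
    list(a = fit$a, b = fit$b, loglik = fit$loglik, n_bins = k,
         converged = fit$converged, cutpoints = fit$cutpoints,
         auc = binormal_auc(fit$a, fit$b)),
    class = "binormal_fit"
  )
}

# category breaks: distinct values if few, else pooled quantiles
binormal_breaks <- function(pooled, max_bins) {
  vals <- sort(unique(pooled))
  if (length(vals) <= max_bins) {
    breaks <- c(-Inf, vals[-1] - diff(vals) / 2, Inf)
  } else {
    qs <- stats::quantile(pooled, probs = seq(0, 1, length.out = max_bins + 1),
                          names = FALSE, type = 7)
    breaks <- c(-Inf, unique(qs[-c(1, max_bins + 1)]), Inf)
  }
  breaks
}

bin_counts <- function(x, breaks) {
  tabulate(findInterval(x, breaks, left.open = FALSE),
           nbins = length(breaks) - 1)
}

# ML for the categorical binormal model; counts may be non-integer
# (continuity-corrected). Returns a, b, cutpoints, loglik, converged.
dorfman_alf_ml <- function(n0k, n1k, auc_w) {
  k <- length(n0k)
  if (k < 2) return(list(converged = FALSE))
  n0 <- sum(n0k)
  n1 <- sum(n1k)

  # initial cutpoints from the pooled empirical distribution
  pool <- n0k + n1k
  cum <- cumsum(pool)[-k] / sum(pool)
  cum <- pmin(pmax(cum, 0.005), 0.995)
  c0 <- qnorm(cum)
  c0 <- cummax(c0 + seq_len(k - 1) * 1e-9)  # strictly increasing

  nll <- function(par) {
    a <- par[1]
    b <- exp(par[2])
    cuts <- cumsum(c(par[3], exp(par[-(1:3)])))
    p0 <- diff(c(0, pnorm(cuts), 1))
    p1 <- diff(c(0, pnorm(b * cuts - a), 1))
    -sum(n0k * log(pmax(p0, 1e-300)) + n1k * log(pmax(p1, 1e-300)))
  }

  auc_c <- min(max(auc_w, 1e-6), 1 - 1e-6)
  best <- NULL
  for (b0 in c(0.5, 1, 2)) {
    a0 <- qnorm(auc_c) * sqrt(1 + b0^2)
    par0 <- c(a0, log(b0), c0[1],
              if (k > 2) log(pmax(diff(c0), 1e-6)) else numeric(0))
    res <- tryCatch(
      optim(par0, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best)) return(list(converged = FALSE))

  a <- best$par[1]
  b <- exp(best$par[2])
  cuts <- cumsum(c(best$par[3], exp(best$par[-(1:3)])))
  ok <- best$convergence == 0 && is.finite(best$value) &&
    abs(a) < 10 && b > 0.02 && b < 50
  list(a = a, b = b, cutpoints = cuts, loglik = -best$value, converged = ok)
}

#' Area under a binormal ROC curve
#'
#' Closed form for the full area: `pnorm(a / sqrt(1 + b^2))`.
#'
#' @param a Binormal intercept.
#' @param b Binormal slope; must be positive.
#' @return The AUC, in (0, 1).
#' @examples
#' binormal_auc(1, 1)  # pnorm(1 / sqrt(2))
#' @export
binormal_auc <- function(a, b) {
  if (b <= 0) abort("binormal slope b must be positive")
  pnorm(a / sqrt(1 + b^2))
}

#' Partial area under a fitted binormal ROC curve
#'
#' Numerically integrates the fitted curve TPF(FPF) over a false positive
#' fraction interval, by default \[0, 0.3\] (specificity 70--100%).
#'
#' @param fit A `binormal_fit`, or a list with elements `a` and `b`.
#' @param fpf_lo,fpf_hi Integration limits, `0 <= fpf_lo < fpf_hi <= 1`.
#' @return The partial area, in \[0, `fpf_hi - fpf_lo`\].
#' @examples
#' pauc(list(a = 0, b = 1))  # chance curve: 0.045
#' @export
pauc <- function(fit, fpf_lo = 0, fpf_hi = 0.3) {
  if (!(fpf_lo >= 0 && fpf_hi <= 1 && fpf_lo < fpf_hi)) {
    abort("need 0 <= fpf_lo < fpf_hi <= 1")
  }
  a <- fit$a
  b <- fit$b
  if (b <= 0) abort("binormal slope b must be positive")
  integrate(function(x) pnorm(a + b * qnorm(x)), fpf_lo, fpf_hi,
            rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Sensitivity at fixed specificity on a binormal curve
#'
#' @param fit A `binormal_fit`, or a list with elements `a` and `b`.
#' @param spec Target specificity, in (0, 1); default 0.95.
#' @return `pnorm(a + b * qnorm(1 - spec))`.
#' @export
sens_at_spec <- function(fit, spec = 0.95) {
  if (!(spec > 0 && spec < 1)) abort("spec must be in (0, 1)")
  pnorm(fit$a + fit$b * qnorm(1 - spec))
}

#' Specificity at fixed sensitivity on a binormal curve
#'
#' @param fit A `binormal_fit`, or a list with elements `a` and `b`.
#' @param sens Target sensitivity, in (0, 1); default 0.95.
#' @return `1 - pnorm((qnorm(sens) - a) / b)`.
#' @export
spec_at_sens <- function(fit, sens = 0.95) {
  if (!(sens > 0 && sens < 1)) abort("sens must be in (0, 1)")
  1 - pnorm((qnorm(sens) - fit$a) / fit$b)
}

#' Sample a fitted binormal curve on an FPF grid
#'
#' @param fit A `binormal_fit`.
#' @param n Number of evenly spaced FPF values; default 1001.
#' @return A tibble with columns `fpf`, `tpf`.
#' @export
binormal_curve <- function(fit, n = 1001) {
  fpf <- seq(0, 1, length.out = n)
  tpf <- c(0, pnorm(fit$a + fit$b * qnorm(fpf[-c(1, n)])), 1)
  tibble::tibble(fpf = fpf, tpf = tpf)
}

#' @export
print.binormal_fit <- function(x, ...) {
  cat("Binormal ROC fit\n")
  cat(sprintf("  a = %.4f, b = %.4f  (AUC = %.4f)\n", x$a, x$b, x$auc))
  cat(sprintf("  categories: %d, log-likelihood: %s, converged: %s\n",
              x$n_bins,
              if (is.na(x$loglik)) "NA" else sprintf("%.2f", x$loglik),
              x$converged))
  invisible(x)
}

#' @method tidy binormal_fit
#' @export
tidy.binormal_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance binormal_fit
#' @export
glance.binormal_fit <- function(x, ...) {
  tibble::tibble(auc = x$auc, loglik = x$loglik, n_bins = x$n_bins,
                 converged = x$converged)
}

#' @method autoplot binormal_fit
#' @export
autoplot.binormal_fit <- function(object, ...) {
  ggplot2::ggplot(binormal_curve(object),
                  ggplot2::aes(x = .data$fpf, y = .data$tpf)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive fraction",
                  y = "True positive fraction") +
    ggplot2::theme_minimal()
}
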