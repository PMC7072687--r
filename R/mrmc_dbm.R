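#' Jackknife pseudovalues of a reader accuracy metric
#'
#' For every (modality, reader) the accuracy metric is computed on the full
#' case set (`theta`) and with each case deleted in turn; the
#' leave-one-case-out values are turned into jackknife pseudovalues
#' \deqn{Y_{ijk} = c\,\hat\theta_{ij} - (c - 1)\,\hat\theta_{ij(k)}}
#' where `c` is the total number of cases. For the Wilcoxon AUC (a
#' U-statistic) the mean of the pseudovalues over cases equals the
#' full-sample estimate exactly.
#'
#' @param ratings A ratings data frame (see [validate_ratings()]).
#' @param metric Either `"wilcoxon"` (the default; computed with an
#'   O(n log n) placement algorithm) or a function
#'   `f(scores_benign, scores_malignant)` returning a scalar accuracy.
#' @return A tibble of class `pseudovalue_cube` with columns `modality`,
#'   `reader_id`, `case_id`, `pseudovalue`, and attributes `theta` (tibble
#'   of full-sample metric values per modality and reader) and
#'   `metric_name`.
#' @export
jackknife_pseudovalues <- function(ratings, metric = "wilcoxon") {
  dat <- ratings_to_array(ratings)
  if (sum(dat$truth == 0) < 2 || sum(dat$truth == 1) < 2) {
    abort("insufficient cases for jackknife: need 2 of each truth class")
  }
  res <- pseudovalues_core(dat$scores, dat$truth, metric)
  dims <- dim(dat$scores)
  cube <- tibble::tibble(
    modality = factor(rep(dat$modalities, times = dims[2] * dims[3]),
                      levels = dat$modalities),
    reader_id = rep(rep(dat$readers, each = dims[1]), times = dims[3]),
    case_id = rep(dat$cases, each = dims[1] * dims[2]),
    pseudovalue = as.vector(res$Y)
  )
  theta <- tibble::tibble(
    modality = factor(rep(dat$modalities, times = dims[2]),
                      levels = dat$modalities),
    reader_id = rep(dat$readers, each = dims[1]),
    theta = as.vector(res$theta)
  )
  attr(cube, "theta") <- theta
  attr(cube, "metric_name") <-
    if (is.character(metric)) metric else "custom"
  attr(cube, "truth") <- dat$truth
  class(cube) <- c("pseudovalue_cube", class(cube))
  cube
}

# internal: scores array [t, r, c], truth vector -> list(Y array, theta
# matrix [t, r])
pseudovalues_core <- function(scores, truth, metric = "wilcoxon") {
  dims <- dim(scores)
  t_ <- dims[1]; r_ <- dims[2]; c_ <- dims[3]
  ben <- which(truth == 0)
  mal <- which(truth == 1)
  Y <- array(NA_real_, dims)
  theta <- matrix(NA_real_, t_, r_)
  fast <- is.character(metric) && identical(metric, "wilcoxon")
  for (i in seq_len(t_)) {
    for (j in seq_len(r_)) {
      x <- scores[i, j, ben]
      y <- scores[i, j, mal]
      if (fast) {
        lo <- wilcoxon_loo(x, y)
        th <- lo$theta
        loo <- numeric(c_)
        loo[ben] <- lo$loo_benign
        loo[mal] <- lo$loo_malignant
      } else {
        f <- if (is.character(metric)) match.fun(metric) else metric
        th <- f(x, y)
        loo <- vapply(seq_len(c_), function(k) {
          if (truth[k] == 0) f(scores[i, j, setdiff(ben, k)], y)
          else f(x, scores[i, j, setdiff(mal, k)])
        }, numeric(1))
      }
      theta[i, j] <- th
      Y[i, j, ] <- c_ * th - (c_ - 1) * loo
    }
  }
  list(Y = Y, theta = theta)
}

#' Three-way mixed ANOVA of jackknife pseudovalues
#'
#' Decomposes the pseudovalue cube (modality x reader x case, one
#' observation per cell) into the seven mean squares of the fully crossed
#' three-factor ANOVA: MS(T), MS(R), MS(C), MS(TR), MS(TC), MS(RC) and
#' MS(TRC).
#'
#' @param pv A `pseudovalue_cube` from [jackknife_pseudovalues()].
#' @return An object of class `dbm_result` with element `ms` (named mean
#'   squares), the design dimensions, per-modality pseudovalue means and
#'   the two-way mean squares of each single-modality table (used for
#'   per-modality confidence intervals). Test fields are filled in by
#'   [dbm_test()].
#' @export
dbm_anova <- function(pv) {
  Y <- cube_to_array(pv)
  d <- dim(Y)
  t_ <- d[1]; r_ <- d[2]; c_ <- d[3]
  if (t_ < 2 || r_ < 2 || c_ < 2) {
    abort("dbm_anova needs at least 2 levels of modality, reader and case")
  }
  g <- mean(Y)
  mt <- apply(Y, 1, mean)
  mr <- apply(Y, 2, mean)
  mc_ <- apply(Y, 3, mean)
  mtr <- apply(Y, c(1, 2), mean)
  mtc <- apply(Y, c(1, 3), mean)
  mrc <- apply(Y, c(2, 3), mean)

  ss_t <- r_ * c_ * sum((mt - g)^2)
  ss_r <- t_ * c_ * sum((mr - g)^2)
  ss_c <- t_ * r_ * sum((mc_ - g)^2)
  ss_tr <- c_ * sum((mtr - outer(mt, rep(1, r_)) -
                       outer(rep(1, t_), mr) + g)^2)
  ss_tc <- r_ * sum((mtc - outer(mt, rep(1, c_)) -
                       outer(rep(1, t_), mc_) + g)^2)
  ss_rc <- t_ * sum((mrc - outer(mr, rep(1, c_)) -
                       outer(rep(1, r_), mc_) + g)^2)
  fitted <- array(0, d)
  for (i in seq_len(t_)) for (j in seq_len(r_)) {
    fitted[i, j, ] <- mtr[i, j] + mtc[i, ] + mrc[j, ] -
      mt[i] - mr[j] - mc_ + g
  }
  ss_trc <- sum((Y - fitted)^2)

  ms <- c(
    T = ss_t / (t_ - 1),
    R = ss_r / (r_ - 1),
    C = ss_c / (c_ - 1),
    TR = ss_tr / ((t_ - 1) * (r_ - 1)),
    TC = ss_tc / ((t_ - 1) * (c_ - 1)),
    RC = ss_rc / ((r_ - 1) * (c_ - 1)),
    TRC = ss_trc / ((t_ - 1) * (r_ - 1) * (c_ - 1))
  )

  # per-modality two-way mean squares, for single-modality CIs
  per_mod <- lapply(seq_len(t_), function(i) two_way_ms(Y[i, , ]))

  structure(
    list(
      ms = ms,
      dims = c(t = t_, r = r_, c = c_),
      modalities = dimnames(Y)[[1]] %||% as.character(seq_len(t_)),
      modality_means = unname(mt),
      per_modality_ms = per_mod,
      metric_name = attr(pv, "metric_name") %||% "wilcoxon"
    ),
    class = "dbm_result"
  )
}

cube_to_array <- function(pv) {
  mods <- levels(pv$modality)
  readers <- sort(unique(pv$reader_id))
  cases <- sort(unique(pv$case_id))
  Y <- array(NA_real_, c(length(mods), length(readers), length(cases)),
             dimnames = list(mods, readers, cases))
  Y[cbind(match(as.character(pv$modality), mods),
          match(pv$reader_id, readers),
          match(pv$case_id, cases))] <- pv$pseudovalue
  if (anyNA(Y)) abort("pseudovalue cube is not fully crossed")
  Y
}

# two-way (reader x case) mean squares of a single-modality slice
two_way_ms <- function(M) {
  r_ <- nrow(M); c_ <- ncol(M)
  g <- mean(M)
  mr <- rowMeans(M)
  mc_ <- colMeans(M)
  ss_r <- c_ * sum((mr - g)^2)
  ss_c <- r_ * sum((mc_ - g)^2)
  resid <- M - outer(mr, rep(1, c_)) - outer(rep(1, r_), mc_) + g
  c(R = ss_r / (r_ - 1), C = ss_c / (c_ - 1),
    RC = sum(resid^2) / ((r_ - 1) * (c_ - 1)))
}

#' Dorfman-Berbaum-Metz modality test
#'
#' Tests the null of equal modality accuracy from the pseudovalue ANOVA.
#' The default uses the Hillis form: denominator
#' `D = MS(TR) + max(MS(TC) - MS(TRC), 0)`, `F = MS(T) / D` on `t - 1`
#' numerator df and Hillis denominator df
#' `ddf = D^2 / (MS(TR)^2 / ((t-1)(r-1)))`. With `hillis = FALSE` the
#' original untruncated denominator `MS(TR) + MS(TC) - MS(TRC)` with
#' `(t-1)(r-1)(c-1)` denominator df is used instead (for comparison; the
#' two give different p-values).
#'
#' For two modalities the modality difference (first level minus second
#' level of the modality factor) is reported with a two-sided
#' `100(1 - alpha)%` confidence interval using the same denominator and
#' df as the F test. Per-modality means get t intervals from their
#' single-modality two-way ANOVAs.
#'
#' @param result A `dbm_result` from [dbm_anova()].
#' @param alpha Two-sided significance level; default 0.05.
#' @param hillis Use the Hillis-corrected denominator and df (default
#'   `TRUE`).
#' @return The `dbm_result` with fields `F`, `ndf`, `ddf`, `p`, `diff`
#'   (tibble, for t = 2), `per_modality` (tibble) and `no_variability`
#'   filled in.
#' @export
dbm_test <- function(result, alpha = 0.05, hillis = TRUE) {
  if (!inherits(result, "dbm_result")) abort("result must be a dbm_result")
  ms <- result$ms
  t_ <- result$dims[["t"]]; r_ <- result$dims[["r"]]; c_ <- result$dims[["c"]]

  if (hillis) {
    D <- ms[["TR"]] + max(ms[["TC"]] - ms[["TRC"]], 0)
    ddf <- if (D > 0 && ms[["TR"]] > 0) {
      D^2 / (ms[["TR"]]^2 / ((t_ - 1) * (r_ - 1)))
    } else {
      (t_ - 1) * (r_ - 1)
    }
  } else {
    D <- ms[["TR"]] + ms[["TC"]] - ms[["TRC"]]
    ddf <- (t_ - 1) * (r_ - 1) * (c_ - 1)
  }
  ndf <- t_ - 1

  no_var <- !(D > 0)
  if (no_var) {
    Fstat <- NA_real_
    p <- 1
  } else {
    Fstat <- ms[["T"]] / D
    p <- pf(Fstat, ndf, ddf, lower.tail = FALSE)
  }

  result$F <- Fstat
  result$ndf <- ndf
  result$ddf <- ddf
  result$p <- p
  result$alpha <- alpha
  result$hillis <- hillis
  result$no_variability <- no_var

  # per-modality means with single-modality t intervals
  pm <- purrr::map2_dfr(
    seq_len(t_), result$per_modality_ms,
    function(i, m2) {
      V <- m2[["R"]] + max(m2[["C"]] - m2[["RC"]], 0)
      df_i <- if (V > 0 && m2[["R"]] > 0) V^2 / (m2[["R"]]^2 / (r_ - 1))
              else r_ - 1
      se <- sqrt(V / (r_ * c_))
      est <- result$modality_means[i]
      tq <- qt(1 - alpha / 2, df_i)
      tibble::tibble(modality = result$modalities[i], estimate = est,
                     ci_lo = est - tq * se, ci_hi = est + tq * se)
    }
  )
  result$per_modality <- pm

  if (t_ == 2) {
    est <- result$modality_means[1] - result$modality_means[2]
    se <- sqrt(2 * max(D, 0) / (r_ * c_))
    tq <- qt(1 - alpha / 2, ddf)
    result$diff <- tibble::tibble(
      contrast = paste(result$modalities[1], "-", result$modalities[2]),
      estimate = est, ci_lo = est - tq * se, ci_hi = est + tq * se,
      p = p
    )
  }
  result
}

#' Run the full DBM pipeline on a rating table
#'
#' Convenience wrapper: [jackknife_pseudovalues()] then [dbm_anova()] then
#' [dbm_test()].
#'
#' @inheritParams jackknife_pseudovalues
#' @inheritParams dbm_test
#' @return A complete `dbm_result`.
#' @export
dbm_compare <- function(ratings, metric = "wilcoxon", alpha = 0.05,
                        hillis = TRUE) {
  pv <- jackknife_pseudovalues(ratings, metric)
  dbm_test(dbm_anova(pv), alpha = alpha, hillis = hillis)
}

# internal fast path used in simulation loops: scores array + truth ->
# list(p, diff, theta) without tibble construction
dbm_core <- function(scores, truth, alpha = 0.05, hillis = TRUE) {
  res <- pseudovalues_core(scores, truth, "wilcoxon")
  Y <- res$Y
  d <- dim(Y)
  t_ <- d[1]; r_ <- d[2]; c_ <- d[3]
  g <- mean(Y)
  mt <- apply(Y, 1, mean)
  mr <- apply(Y, 2, mean)
  mc_ <- apply(Y, 3, mean)
  mtr <- apply(Y, c(1, 2), mean)
  mtc <- apply(Y, c(1, 3), mean)
  ms_t <- r_ * c_ * sum((mt - g)^2) / (t_ - 1)
  ms_tr <- c_ * sum((mtr - outer(mt, rep(1, r_)) -
                       outer(rep(1, t_), mr) + g)^2) /
    ((t_ - 1) * (r_ - 1))
  ms_tc <- r_ * sum((mtc - outer(mt, rep(1, c_)) -
                       outer(rep(1, t_), mc_) + g)^2) /
    ((t_ - 1) * (c_ - 1))
  mrc <- apply(Y, c(2, 3), mean)
  fitted <- array(0, d)
  for (i in seq_len(t_)) for (j in seq_len(r_)) {
    fitted[i, j, ] <- mtr[i, j] + mtc[i, ] + mrc[j, ] -
      mt[i] - mr[j] - mc_ + g
  }
  ms_trc <- sum((Y - fitted)^2) / ((t_ - 1) * (r_ - 1) * (c_ - 1))

  if (hillis) {
    D <- ms_tr + max(ms_tc - ms_trc, 0)
    ddf <- if (D > 0 && ms_tr > 0) D^2 / (ms_tr^2 / ((t_ - 1) * (r_ - 1)))
           else (t_ - 1) * (r_ - 1)
  } else {
    D <- ms_tr + ms_tc - ms_trc
    ddf <- (t_ - 1) * (r_ - 1) * (c_ - 1)
  }
  p <- if (D > 0) pf(ms_t / D, t_ - 1, ddf, lower.tail = FALSE) else 1
  list(p = p, diff = mt[1] - mt[2], theta = res$theta)
}

#' Single-reader paired modality test
#'
#' For one reader under two modalities: jackknife pseudovalues are
#' computed per modality, and the per-case pseudovalue differences are
#' tested against zero mean with a two-sided one-sample t test on
#' `c - 1` degrees of freedom. This is DBM with a single reader, the
#' cases being the only random factor.
#'
#' @param ratings A ratings data frame with exactly two modalities.
#' @param reader The reader identifier.
#' @param metric As in [jackknife_pseudovalues()].
#' @return A one-row tibble: `reader_id`, `theta_1`, `theta_2` (metric per
#'   modality in modality level order), `diff` (theta_1 - theta_2), `p`,
#'   `zero_variance` flag.
#' @export
per_reader_test <- function(ratings, reader, metric = "wilcoxon") {
  ratings <- validate_ratings(ratings)
  if (nlevels(ratings$modality) != 2) {
    abort("per_reader_test needs exactly two modalities")
  }
  sub <- ratings[ratings$reader_id == as.character(reader), ]
  if (nrow(sub) == 0) abort(sprintf("unknown reader: %s", reader))
  dat <- ratings_to_array(sub)
  res <- pseudovalues_core(dat$scores, dat$truth, metric)
  d <- res$Y[1, 1, ] - res$Y[2, 1, ]
  zero_var <- isTRUE(all.equal(var(d), 0)) || var(d) == 0
  p <- if (zero_var) 1 else t.test(d)$p.value
  tibble::tibble(
    reader_id = as.character(reader),
    theta_1 = res$theta[1, 1],
    theta_2 = res$theta[2, 1],
    diff = res$theta[1, 1] - res$theta[2, 1],
    p = p,
    zero_variance = zero_var
  )
}

#' Reader-subgroup DBM analysis with a between-group improvement test
#'
#' Runs the full DBM pipeline separately within each reader group, and
#' compares groups on their per-reader modality improvements
#' (second modality level minus first, per reader) with a two-sample
#' Welch t test.
#'
#' @param ratings A ratings data frame with two modalities.
#' @param groups A named list of character vectors of reader ids forming a
#'   partition of the readers; each group needs at least 2 readers.
#' @param metric,alpha,hillis As in [dbm_compare()].
#' @return A list with `per_group` (named list of `dbm_result`),
#'   `improvements` (tibble of per-reader improvements with group labels)
#'   and `between` (one-row tibble with the Welch test estimate and p;
#'   only for exactly two groups, otherwise `NULL`).
#' @export
subgroup_analysis <- function(ratings, groups, metric = "wilcoxon",
                              alpha = 0.05, hillis = TRUE) {
  ratings <- validate_ratings(ratings)
  readers <- unique(ratings$reader_id)
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids) || !setequal(all_ids, readers)) {
    abort("groups must partition the readers of the rating table")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("each group needs at least 2 readers")
  }
  per_group <- lapply(groups, function(ids) {
    dbm_compare(ratings[ratings$reader_id %in% ids, ],
                metric = metric, alpha = alpha, hillis = hillis)
  })
  pv <- jackknife_pseudovalues(ratings, metric)
  th <- attr(pv, "theta")
  th_w <- tidyr::pivot_wider(th, names_from = "modality",
                             values_from = "theta")
  mods <- levels(th$modality)
  improvement <- th_w[[mods[2]]] - th_w[[mods[1]]]
  grp <- rep(NA_character_, nrow(th_w))
  for (g in names(groups)) grp[th_w$reader_id %in% groups[[g]]] <- g
  improvements <- tibble::tibble(reader_id = th_w$reader_id, group = grp,
                                 improvement = improvement)
  between <- NULL
  if (length(groups) == 2) {
    g1 <- improvements$improvement[improvements$group == names(groups)[1]]
    g2 <- improvements$improvement[improvements$group == names(groups)[2]]
    if (var(g1) + var(g2) == 0) {
      between <- tibble::tibble(estimate = mean(g1) - mean(g2), p = 1,
                                zero_variance = TRUE)
    } else {
      tt <- t.test(g1, g2)
      between <- tibble::tibble(estimate = mean(g1) - mean(g2),
                                p = tt$p.value, zero_variance = FALSE)
    }
  }
  list(per_group = per_group, improvements = improvements, between = between)
}

#' Monte-Carlo power of the DBM test under a simulation configuration
#'
#' Simulates `nsim` studies from a [roe_metz_config()], applies the DBM
#' test to each, and returns the rejection fraction with its binomial
#' standard error. With equal modality separations this estimates the
#' type-I error rate instead of power.
#'
#' @param cfg A `roe_metz_config`.
#' @param alpha Significance level; default 0.05.
#' @param nsim Number of simulated studies (at least 100).
#' @param seed Integer seed controlling all replicates.
#' @return A one-row tibble: `power`, `mc_se`, `nsim`, `alpha`.
#' @export
estimate_power <- function(cfg, alpha = 0.05, nsim = 500, seed = 1) {
  if (nsim < 100) abort("nsim must be at least 100")
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1, nsim))
  reject <- vapply(seeds, function(s) {
    sim <- withr::with_seed(s, simulate_scores_core(cfg))
    dbm_core(sim$scores, sim$truth, alpha = alpha)$p < alpha
  }, logical(1))
  pw <- mean(reject)
  tibble::tibble(power = pw, mc_se = sqrt(pw * (1 - pw) / nsim),
                 nsim = nsim, alpha = alpha)
}

#' @export
print.dbm_result <- function(x, ...) {
  cat("Dorfman-Berbaum-Metz pseudovalue ANOVA",
      sprintf("(metric: %s)\n", x$metric_name))
  cat(sprintf("  design: %d modalities x %d readers x %d cases\n",
              x$dims[["t"]], x$dims[["r"]], x$dims[["c"]]))
  cat("  mean squares:\n")
  print(round(x$ms, 6))
  if (!is.null(x$p)) {
    cat(sprintf("  F = %s on (%g, %.2f) df, p = %.4g%s\n",
                if (is.na(x$F)) "NA" else sprintf("%.4f", x$F),
                x$ndf, x$ddf, x$p,
                if (isTRUE(x$no_variability)) " [no variability]" else ""))
    if (!is.null(x$diff)) {
      cat(sprintf("  difference %s = %.4f (%.4f, %.4f)\n",
                  x$diff$contrast, x$diff$estimate, x$diff$ci_lo,
                  x$diff$ci_hi))
    }
  }
  invisible(x)
}

#' @method tidy dbm_result
#' @export
tidy.dbm_result <- function(x, ...) {
  out <- tibble::tibble(term = names(x$ms), mean_square = unname(x$ms))
  out
}

#' @method glance dbm_result
#' @export
glance.dbm_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$F %||% NA_real_,
    ndf = x$ndf %||% NA_real_,
    ddf = x$ddf %||% NA_real_,
    p.value = x$p %||% NA_real_,
    n_modalities = x$dims[["t"]],
    n_readers = x$dims[["r"]],
    n_cases = x$dims[["c"]]
  )
}
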