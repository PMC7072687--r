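#' Per-case interobserver score spread
#'
#' Sample standard deviation (divisor r - 1) of the reader scores for
#' each case, per modality. This is the interobserver variability of the
#' 0-100 malignancy-potential score.
#'
#' @param ratings A ratings data frame with at least 2 readers.
#' @param modality Optional modality label to restrict to; default all.
#' @return A tibble with columns `case_id`, `truth`, `modality`, `sd`.
#' @export
per_case_sd <- function(ratings, modality = NULL) {
  ratings <- validate_ratings(ratings)
  if (dplyr::n_distinct(ratings$reader_id) < 2) {
    abort("per_case_sd needs at least 2 readers")
  }
  if (!is.null(modality)) {
    if (!modality %in% levels(ratings$modality)) {
      abort(sprintf("unknown modality: %s", modality))
    }
    ratings <- ratings[as.character(ratings$modality) == modality, ]
  }
  ratings |>
    dplyr::group_by(.data$case_id, .data$truth, .data$modality) |>
    dplyr::summarise(sd = sd(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$case_id, .data$modality)
}

#' Paired modality comparison of interobserver spread
#'
#' For a two-modality study, compares the per-case across-reader SD
#' between the first and second modality with a paired two-sided test
#' over cases (difference = first modality minus second). Also returns
#' the average SD per modality with t confidence intervals over cases.
#'
#' @param ratings A ratings data frame with exactly two modalities.
#' @param subset One of `"all"`, `"benign"`, `"malignant"`: which cases
#'   enter the comparison.
#' @param test `"t"` (paired t, the default) or `"wilcoxon"` (signed
#'   rank).
#' @param conf_level Confidence level for intervals; default 0.95.
#' @return A one-row tibble: `subset`, `n_cases`, `mean_sd_1`, `ci_lo_1`,
#'   `ci_hi_1`, `mean_sd_2`, `ci_lo_2`, `ci_hi_2`, `difference`, `ci_lo`,
#'   `ci_hi`, `p`, `zero_variance`.
#' @export
compare_modalities_sd <- function(ratings, subset = c("all", "benign",
                                                      "malignant"),
                                  test = c("t", "wilcoxon"),
                                  conf_level = 0.95) {
  subset <- match.arg(subset)
  test <- match.arg(test)
  ratings <- validate_ratings(ratings)
  if (nlevels(ratings$modality) != 2) {
    abort("compare_modalities_sd needs exactly two modalities")
  }
  sds <- per_case_sd(ratings)
  keep <- switch(subset, all = TRUE, benign = sds$truth == 0,
                 malignant = sds$truth == 1)
  sds <- sds[keep, , drop = FALSE]
  mods <- levels(ratings$modality)
  wide <- tidyr::pivot_wider(sds, names_from = "modality",
                             values_from = "sd")
  d <- wide[[mods[1]]] - wide[[mods[2]]]
  paired_modality_comparison(wide[[mods[1]]], wide[[mods[2]]], d,
                             subset, test, conf_level)
}

paired_modality_comparison <- function(v1, v2, d, subset, test,
                                       conf_level) {
  n <- length(d)
  alpha <- 1 - conf_level
  ci_t <- function(v) {
    m <- mean(v)
    se <- sd(v) / sqrt(length(v))
    tq <- qt(1 - alpha / 2, length(v) - 1)
    c(m, m - tq * se, m + tq * se)
  }
  s1 <- ci_t(v1)
  s2 <- ci_t(v2)
  zero_var <- var(d) == 0
  if (zero_var) {
    p <- 1
    dci <- c(mean(d), mean(d), mean(d))
  } else if (test == "t") {
    tt <- t.test(d, conf.level = conf_level)
    p <- tt$p.value
    dci <- c(mean(d), tt$conf.int[1], tt$conf.int[2])
  } else {
    wt <- stats::wilcox.test(d, exact = FALSE)
    p <- wt$p.value
    dci <- ci_t(d)  # interval still t-based on the mean difference
  }
  tibble::tibble(
    subset = subset, n_cases = n,
    mean_sd_1 = s1[1], ci_lo_1 = s1[2], ci_hi_1 = s1[3],
    mean_sd_2 = s2[1], ci_lo_2 = s2[2], ci_hi_2 = s2[3],
    difference = dci[1], ci_lo = dci[2], ci_hi = dci[3],
    p = p, zero_variance = zero_var
  )
}

#' Mean malignancy-potential score by truth class and modality
#'
#' Averages the scores over readers and cases within each truth class and
#' modality, and tests the paired modality difference per class: for each
#' case the reader-mean score is formed, and the per-case differences
#' (first modality minus second) are tested with a paired two-sided t
#' test over the cases of that class.
#'
#' @param ratings A ratings data frame with exactly two modalities.
#' @param conf_level Confidence level; default 0.95.
#' @return A tibble with one row per truth class: `class`, `n_cases`,
#'   `mean_1`, `mean_2` (per modality in level order), `difference`,
#'   `ci_lo`, `ci_hi`, `p`, `zero_variance`.
#' @export
mean_score_by_class <- function(ratings, conf_level = 0.95) {
  ratings <- validate_ratings(ratings)
  if (nlevels(ratings$modality) != 2) {
    abort("mean_score_by_class needs exactly two modalities")
  }
  mods <- levels(ratings$modality)
  case_means <- ratings |>
    dplyr::group_by(.data$case_id, .data$truth, .data$modality) |>
    dplyr::summarise(m = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "m")
  purrr::map_dfr(c(benign = 0, malignant = 1), function(tv) {
    sub <- case_means[case_means$truth == tv, ]
    d <- sub[[mods[1]]] - sub[[mods[2]]]
    zero_var <- var(d) == 0
    if (zero_var) {
      p <- 1
      lo <- hi <- mean(d)
    } else {
      tt <- t.test(d, conf.level = conf_level)
      p <- tt$p.value
      lo <- tt$conf.int[1]
      hi <- tt$conf.int[2]
    }
    tibble::tibble(
      class = if (tv == 0) "benign" else "malignant",
      n_cases = nrow(sub),
      mean_1 = mean(sub[[mods[1]]]), mean_2 = mean(sub[[mods[2]]]),
      difference = mean(d), ci_lo = lo, ci_hi = hi, p = p,
      zero_variance = zero_var
    )
  })
}
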