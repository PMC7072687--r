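#' Full MRMC reader-study analysis
#'
#' Runs the complete modality comparison on a two-modality rating table:
#'
#' * per-reader Wilcoxon AUCs with single-reader jackknife paired tests;
#' * the overall DBM pseudovalue ANOVA modality test with Hillis degrees
#'   of freedom, modality means and the modality difference with CI;
#' * junior/senior subgroup DBM analyses plus a Welch test on per-reader
#'   improvements (when `reader_info` is supplied);
#' * interobserver score-SD comparisons for all / benign / malignant
#'   cases and class-conditional mean scores;
#' * binormal-curve operating metrics per reader (partial AUC over
#'   `pauc_range`, sensitivity at `fixed_spec`, specificity at
#'   `fixed_sens`), averaged over readers with t confidence intervals and
#'   paired t tests for the modality difference.
#'
#' The headline AUC comparison uses the trapezoidal Wilcoxon AUC inside
#' the DBM jackknife; the curve-shape metrics come from per-reader
#' maximum-likelihood binormal fits.
#'
#' @param ratings A ratings data frame with exactly two modalities.
#' @param reader_info Optional reader experience table (columns
#'   `reader_id`, `experience_years`); enables the subgroup analysis.
#' @param pauc_range False-positive-fraction interval for the partial
#'   AUC; default `c(0, 0.3)`.
#' @param fixed_spec Specificity at which sensitivity is read off;
#'   default 0.95.
#' @param fixed_sens Sensitivity at which specificity is read off;
#'   default 0.95.
#' @param alpha Two-sided significance level; default 0.05.
#' @param experience_threshold Years separating junior from senior;
#'   default 10.
#' @param max_bins Rating categories for the binormal fits; default 20.
#' @param hillis Use Hillis-corrected DBM; default `TRUE`.
#' @return An object of class `reader_study_analysis`; see the elements
#'   `reader_auc`, `dbm`, `modality_summary`, `difference`, `subgroup`,
#'   `sd_summary`, `mean_scores`, `curve_metrics`, `settings`.
#' @export
analyze_reader_study <- function(ratings, reader_info = NULL,
                                 pauc_range = c(0, 0.3),
                                 fixed_spec = 0.95, fixed_sens = 0.95,
                                 alpha = 0.05, experience_threshold = 10,
                                 max_bins = 20, hillis = TRUE) {
  ratings <- validate_ratings(ratings)
  if (nlevels(ratings$modality) != 2) {
    abort("analyze_reader_study needs exactly two modalities")
  }
  if (!(pauc_range[1] >= 0 && pauc_range[2] <= 1 &&
          pauc_range[1] < pauc_range[2])) {
    abort("pauc_range must satisfy 0 <= lo < hi <= 1")
  }
  if (!(fixed_spec > 0 && fixed_spec < 1)) abort("fixed_spec not in (0, 1)")
  if (!(fixed_sens > 0 && fixed_sens < 1)) abort("fixed_sens not in (0, 1)")
  mods <- levels(ratings$modality)
  readers <- sort(unique(ratings$reader_id))

  # per-reader AUC table with paired single-reader tests
  reader_auc <- purrr::map_dfr(readers, function(rd) {
    per_reader_test(ratings, rd)
  })
  names(reader_auc)[names(reader_auc) == "theta_1"] <- paste0("auc_", mods[1])
  names(reader_auc)[names(reader_auc) == "theta_2"] <- paste0("auc_", mods[2])
  reader_auc$improvement <- -reader_auc$diff
  reader_auc$diff <- NULL

  # overall DBM
  dbm <- dbm_compare(ratings, metric = "wilcoxon", alpha = alpha,
                     hillis = hillis)
  difference <- tibble::tibble(
    contrast = paste(mods[2], "-", mods[1]),
    estimate = -dbm$diff$estimate,
    ci_lo = -dbm$diff$ci_hi, ci_hi = -dbm$diff$ci_lo,
    p = dbm$diff$p
  )

  # subgroups
  subgroup <- NULL
  if (!is.null(reader_info)) {
    info <- tibble::as_tibble(reader_info)
    info$reader_id <- as.character(info$reader_id)
    jr <- info$reader_id[info$experience_years < experience_threshold]
    sr <- info$reader_id[info$experience_years >= experience_threshold]
    jr <- intersect(readers, jr)
    sr <- intersect(readers, sr)
    if (length(jr) >= 2 && length(sr) >= 2) {
      subgroup <- subgroup_analysis(
        ratings, groups = list(junior = jr, senior = sr),
        alpha = alpha, hillis = hillis)
    } else {
      warn("subgroup analysis skipped: a group has fewer than 2 readers")
    }
  }

  # interobserver variability
  sd_summary <- dplyr::bind_rows(
    compare_modalities_sd(ratings, "all", conf_level = 1 - alpha),
    compare_modalities_sd(ratings, "benign", conf_level = 1 - alpha),
    compare_modalities_sd(ratings, "malignant", conf_level = 1 - alpha)
  )
  mean_scores <- mean_score_by_class(ratings, conf_level = 1 - alpha)

  # binormal curve metrics per reader
  fits <- tidyr::expand_grid(reader_id = readers, modality = mods)
  fits$fit <- purrr::map2(fits$reader_id, fits$modality, function(rd, md) {
    sub <- ratings[ratings$reader_id == rd &
                     as.character(ratings$modality) == md, ]
    fit_binormal(sub$score[sub$truth == 0], sub$score[sub$truth == 1],
                 max_bins = max_bins)
  })
  fits$pauc <- purrr::map_dbl(fits$fit, pauc, fpf_lo = pauc_range[1],
                              fpf_hi = pauc_range[2])
  fits$sens_at_spec <- purrr::map_dbl(fits$fit, sens_at_spec,
                                      spec = fixed_spec)
  fits$spec_at_sens <- purrr::map_dbl(fits$fit, spec_at_sens,
                                      sens = fixed_sens)
  fits$converged <- purrr::map_lgl(fits$fit, "converged")

  curve_metrics <- purrr::map_dfr(
    c("pauc", "sens_at_spec", "spec_at_sens"),
    function(mn) summarize_reader_metric(fits, mn, mods, alpha)
  )

  structure(
    list(
      dims = rating_dims(ratings),
      reader_auc = reader_auc,
      dbm = dbm,
      modality_summary = dbm$per_modality,
      difference = difference,
      subgroup = subgroup,
      sd_summary = sd_summary,
      mean_scores = mean_scores,
      reader_fits = fits[, setdiff(names(fits), "fit")],
      curve_metrics = curve_metrics,
      settings = list(
        metric = "wilcoxon (DBM); binormal ML (curve metrics)",
        pauc_range = pauc_range, fixed_spec = fixed_spec,
        fixed_sens = fixed_sens, alpha = alpha,
        experience_threshold = experience_threshold,
        max_bins = max_bins, hillis = hillis
      )
    ),
    class = "reader_study_analysis"
  )
}

# average a per-reader curve metric over readers, with paired t contrast
summarize_reader_metric <- function(fits, metric_name, mods, alpha) {
  wide <- tidyr::pivot_wider(
    fits[, c("reader_id", "modality", metric_name)],
    names_from = "modality", values_from = dplyr::all_of(metric_name)
  )
  v1 <- wide[[mods[1]]]
  v2 <- wide[[mods[2]]]
  d <- v2 - v1
  ci_t <- function(v) {
    m <- mean(v)
    se <- sd(v) / sqrt(length(v))
    tq <- qt(1 - alpha / 2, length(v) - 1)
    c(m, m - tq * se, m + tq * se)
  }
  s1 <- ci_t(v1)
  s2 <- ci_t(v2)
  if (var(d) == 0) {
    p <- 1
    dlo <- dhi <- mean(d)
  } else {
    tt <- t.test(d, conf.level = 1 - alpha)
    p <- tt$p.value
    dlo <- tt$conf.int[1]
    dhi <- tt$conf.int[2]
  }
  tibble::tibble(
    metric = metric_name, contrast = paste(mods[2], "-", mods[1]),
    mean_1 = s1[1], ci_lo_1 = s1[2], ci_hi_1 = s1[3],
    mean_2 = s2[1], ci_lo_2 = s2[2], ci_hi_2 = s2[3],
    difference = mean(d), ci_lo = dlo, ci_hi = dhi, p = p
  )
}

#' @export
print.reader_study_analysis <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "MRMC reader-study analysis: %d readers, %d cases (%d benign / %d malignant)\n",
    d$n_readers, d$n_cases, d$n_benign, d$n_malignant))
  ms <- x$modality_summary
  for (i in seq_len(nrow(ms))) {
    cat(sprintf("  %-14s AUC %.3f (%.3f, %.3f)\n", ms$modality[i],
                ms$estimate[i], ms$ci_lo[i], ms$ci_hi[i]))
  }
  cat(sprintf("  difference %s = %.3f (%.3f, %.3f), DBM p = %.4g\n",
              x$difference$contrast, x$difference$estimate,
              x$difference$ci_lo, x$difference$ci_hi, x$difference$p))
  cat(sprintf("  mean interobserver SD: %.2f vs %.2f (p = %.4g)\n",
              x$sd_summary$mean_sd_1[1], x$sd_summary$mean_sd_2[1],
              x$sd_summary$p[1]))
  invisible(x)
}

#' @method tidy reader_study_analysis
#' @export
tidy.reader_study_analysis <- function(x, ...) {
  x$reader_auc
}

#' @method glance reader_study_analysis
#' @export
glance.reader_study_analysis <- function(x, ...) {
  ms <- x$modality_summary
  tibble::tibble(
    auc_1 = ms$estimate[1], auc_2 = ms$estimate[2],
    auc_difference = x$difference$estimate,
    ci_lo = x$difference$ci_lo, ci_hi = x$difference$ci_hi,
    p.value = x$difference$p,
    n_readers = x$dims$n_readers, n_cases = x$dims$n_cases
  )
}

#' @method autoplot reader_study_analysis
#' @export
autoplot.reader_study_analysis <- function(object, ...) {
  ra <- object$reader_auc
  mods <- sub("^auc_", "", grep("^auc_", names(ra), value = TRUE))
  long <- tidyr::pivot_longer(
    ra[, c("reader_id", paste0("auc_", mods))],
    cols = -"reader_id", names_to = "modality", values_to = "auc",
    names_prefix = "auc_")
  long$modality <- factor(long$modality, levels = mods)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$modality, y = .data$auc,
                                     group = .data$reader_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Wilcoxon AUC",
                  title = "Per-reader AUC by modality") +
    ggplot2::theme_minimal()
}
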