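#' Read an analysis configuration from JSON or YAML
#'
#' Configuration files use the same field names as the corresponding
#' constructors; unknown fields raise a usage error naming the field.
#'
#' @param config A file path (`.json`, `.yaml`/`.yml`) or a list.
#' @return The configuration list.
#' @export
read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
  ext <- tolower(tools::file_ext(config))
  if (ext == "json") {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(config)
  } else {
    abort("config must be .json, .yaml or .yml")
  }
}

config_take <- function(cfg, allowed, context) {
  extra <- setdiff(names(cfg), allowed)
  if (length(extra) > 0) {
    abort(sprintf("unknown %s config field(s): %s", context,
                  paste(extra, collapse = ", ")))
  }
  cfg
}

provenance <- function(cfg, seed) {
  list(
    package = "mrmcad",
    version = as.character(utils::packageVersion("mrmcad")),
    seed = seed,
    config = cfg,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Simulate a study and write its files
#'
#' Generates a rating table, a reader-experience table and a battery of
#' contour pairs from a configuration, and writes them as CSV together
#' with a provenance JSON (configuration, seed, package version).
#' Re-running with the same configuration reproduces the files
#' byte-for-byte.
#'
#' Config fields (all optional): `seed`, `output_dir`, `ratings` (a list
#' with `n_readers`, `n_benign`, `n_malignant`, `auc_targets`),
#' `contours` (a list with `n_pairs`, `base_radius_mm`,
#' `radial_noise_sd_mm`, `systematic_offset_mm`, `n_vertices`).
#'
#' @param config A config list or JSON/YAML path; see Details.
#' @param output_dir Output directory (created if missing); overrides the
#'   config field.
#' @return Invisibly, a named list of the written file paths.
#' @export
cmd_simulate <- function(config = list(), output_dir = NULL) {
  cfg <- read_config(config)
  cfg <- config_take(cfg, c("seed", "output_dir", "ratings", "contours"),
                     "simulate")
  seed <- cfg$seed %||% 20200206
  out_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rcfg <- config_take(cfg$ratings %||% list(),
                      c("n_readers", "n_benign", "n_malignant",
                        "auc_targets"), "simulate ratings")
  rm_cfg <- default_study_config(
    auc_targets = rcfg$auc_targets %||% c(0.728, 0.792), seed = seed)
  if (!is.null(rcfg$n_readers)) rm_cfg$n_readers <- as.integer(rcfg$n_readers)
  if (!is.null(rcfg$n_benign)) rm_cfg$n_benign <- as.integer(rcfg$n_benign)
  if (!is.null(rcfg$n_malignant)) {
    rm_cfg$n_malignant <- as.integer(rcfg$n_malignant)
  }
  validate_roe_metz_config(rm_cfg)
  ratings <- simulate_ratings(rm_cfg)

  ccfg <- config_take(cfg$contours %||% list(),
                      c("n_pairs", "base_radius_mm", "radial_noise_sd_mm",
                        "systematic_offset_mm", "n_vertices"),
                      "simulate contours")
  # a mixed-offset battery so that all three match categories occur
  offsets <- ccfg$systematic_offset_mm %||% c(0.2, 0.8, 1.3)
  n_total <- ccfg$n_pairs %||% 265
  n_sub <- diff(round(seq(0, n_total, length.out = length(offsets) + 1)))
  pairs <- purrr::imap_dfr(offsets, function(off, b) {
    cs_cfg <- contour_sim_config(
      n_pairs = n_sub[b],
      base_radius_mm = ccfg$base_radius_mm %||% 10,
      radial_noise_sd_mm = ccfg$radial_noise_sd_mm %||% 0.45,
      systematic_offset_mm = off,
      n_vertices = ccfg$n_vertices %||% 128,
      seed = seed + b
    )
    simulate_contour_pairs(cs_cfg)
  })
  pairs$case_id <- sprintf("pair_%03d", seq_len(nrow(pairs)))

  paths <- list(
    ratings = file.path(out_dir, "ratings.csv"),
    readers = file.path(out_dir, "readers.csv"),
    contours = file.path(out_dir, "contours.csv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_ratings(ratings, paths$ratings)
  readr::write_csv(default_reader_info(rm_cfg$n_readers), paths$readers)
  write_contours(pairs, paths$contours)
  write_json_report(provenance(cfg, seed), paths$provenance)
  invisible(paths)
}

#' Analyse a rating table and write report files
#'
#' Reads the ratings (and optional reader experience table) named in the
#' configuration, runs [analyze_reader_study()], and writes the report
#' tables as CSV plus a single JSON bundle: the per-reader AUC table, the
#' overall and subgroup modality comparisons, the interobserver SD and
#' mean-score summaries, and the binormal curve metrics (partial AUC,
#' sensitivity/specificity at fixed operating points).
#'
#' Config fields: `ratings_path` (required), `readers_path`,
#' `pauc_interval` (length-2), `fixed_spec`, `fixed_sens`, `alpha`,
#' `experience_threshold`, `output_dir`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the `reader_study_analysis` object.
#' @export
cmd_analyze <- function(config, output_dir = NULL) {
  cfg <- read_config(config)
  cfg <- config_take(cfg, c("ratings_path", "readers_path",
                            "pauc_interval", "fixed_spec", "fixed_sens",
                            "alpha", "experience_threshold",
                            "output_dir"), "analyze")
  if (is.null(cfg$ratings_path)) abort("analyze config needs ratings_path")
  out_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ratings <- read_ratings(cfg$ratings_path)
  reader_info <- if (!is.null(cfg$readers_path)) {
    readr::read_csv(cfg$readers_path, col_types = readr::cols(
      reader_id = readr::col_character(),
      experience_years = readr::col_double()))
  }
  res <- analyze_reader_study(
    ratings, reader_info = reader_info,
    pauc_range = as.numeric(cfg$pauc_interval %||% c(0, 0.3)),
    fixed_spec = cfg$fixed_spec %||% 0.95,
    fixed_sens = cfg$fixed_sens %||% 0.95,
    alpha = cfg$alpha %||% 0.05,
    experience_threshold = cfg$experience_threshold %||% 10
  )

  readr::write_csv(res$reader_auc, file.path(out_dir, "reader_auc.csv"))
  overall <- dplyr::bind_rows(
    dplyr::mutate(res$modality_summary, term = .data$modality,
                  .keep = "unused", .before = 1),
    tibble::tibble(term = res$difference$contrast,
                   estimate = res$difference$estimate,
                   ci_lo = res$difference$ci_lo,
                   ci_hi = res$difference$ci_hi,
                   p = res$difference$p)
  )
  readr::write_csv(overall, file.path(out_dir, "overall_auc.csv"))
  if (!is.null(res$subgroup)) {
    sg <- purrr::imap_dfr(res$subgroup$per_group, function(g, nm) {
      dplyr::mutate(g$per_modality, group = nm, .before = 1)
    })
    readr::write_csv(sg, file.path(out_dir, "subgroup_auc.csv"))
  }
  readr::write_csv(res$sd_summary, file.path(out_dir, "score_sd.csv"))
  readr::write_csv(res$mean_scores, file.path(out_dir, "mean_scores.csv"))
  readr::write_csv(res$curve_metrics,
                   file.path(out_dir, "curve_metrics.csv"))

  bundle <- list(
    dims = res$dims,
    mean_squares = as.list(res$dbm$ms),
    F = res$dbm$F, ndf = res$dbm$ndf, ddf = res$dbm$ddf, p = res$dbm$p,
    modality_summary = res$modality_summary,
    difference = res$difference,
    sd_summary = res$sd_summary,
    mean_scores = res$mean_scores,
    curve_metrics = res$curve_metrics,
    settings = res$settings
  )
  if (!is.null(res$subgroup)) {
    bundle$subgroup_between <- res$subgroup$between
    bundle$subgroup_improvements <- res$subgroup$improvements
  }
  write_json_report(bundle, file.path(out_dir, "analysis.json"))
  write_json_report(provenance(cfg, NA), file.path(out_dir,
                                                   "provenance.json"))
  invisible(res)
}

#' Evaluate contour pairs and write segmentation reports
#'
#' Reads contour pairs, computes each pair's directional match ratio and
#' category, and writes the per-pair results plus the
#' quality-by-truth-class cross-tabulation with its two-proportion test.
#'
#' Config fields: `contours_path` (required), `tolerance_mm` (default 1),
#' `mode` (`segment`/`vertex`), `output_dir`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the `match_summary`.
#' @export
cmd_segmatch <- function(config, output_dir = NULL) {
  cfg <- read_config(config)
  cfg <- config_take(cfg, c("contours_path", "tolerance_mm", "mode",
                            "output_dir"), "segmatch")
  if (is.null(cfg$contours_path)) abort("segmatch config needs contours_path")
  out_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pairs <- read_contours(cfg$contours_path)
  tol <- cfg$tolerance_mm %||% 1
  mode <- cfg$mode %||% "segment"
  results <- purrr::pmap_dfr(
    pairs[, c("case_id", "truth", "physician", "software")],
    function(case_id, truth, physician, software) {
      mr <- match_ratio(physician, software, tolerance_mm = tol,
                        mode = mode)
      dplyr::bind_cols(tibble::tibble(case_id = case_id, truth = truth),
                       tidy(mr))
    }
  )
  readr::write_csv(results, file.path(out_dir, "match_results.csv"))
  summary <- summarize_matches(results[, c("category", "truth")])
  readr::write_csv(summary$table,
                   file.path(out_dir, "segmentation_crosstab.csv"))
  write_json_report(list(table = summary$table, test = summary$test,
                         tolerance_mm = tol, mode = mode),
                    file.path(out_dir, "segmentation.json"))
  write_json_report(provenance(cfg, NA),
                    file.path(out_dir, "provenance.json"))
  invisible(summary)
}

#' Estimate DBM power for a configuration and write it as JSON
#'
#' Config fields: `n_readers`, `n_benign`, `n_malignant`, `auc_targets`,
#' `alpha`, `nsim`, `seed`, `output_dir`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the power tibble from [estimate_power()].
#' @export
cmd_power <- function(config = list(), output_dir = NULL) {
  cfg <- read_config(config)
  cfg <- config_take(cfg, c("n_readers", "n_benign", "n_malignant",
                            "auc_targets", "alpha", "nsim", "seed",
                            "output_dir"), "power")
  out_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1
  rm_cfg <- default_study_config(
    auc_targets = cfg$auc_targets %||% c(0.728, 0.792), seed = seed)
  if (!is.null(cfg$n_readers)) rm_cfg$n_readers <- as.integer(cfg$n_readers)
  if (!is.null(cfg$n_benign)) rm_cfg$n_benign <- as.integer(cfg$n_benign)
  if (!is.null(cfg$n_malignant)) {
    rm_cfg$n_malignant <- as.integer(cfg$n_malignant)
  }
  validate_roe_metz_config(rm_cfg)
  pw <- estimate_power(rm_cfg, alpha = cfg$alpha %||% 0.05,
                       nsim = cfg$nsim %||% 500, seed = seed)
  write_json_report(c(as.list(pw), list(config = cfg)),
                    file.path(out_dir, "power.json"))
  invisible(pw)
}
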