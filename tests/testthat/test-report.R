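small_sim_config <- function(dir, seed = 13) {
  list(seed = seed, output_dir = dir,
       ratings = list(n_readers = 5, n_benign = 20, n_malignant = 15),
       contours = list(n_pairs = 12, n_vertices = 48))
}

test_that("simulate writes deterministic files with the configured shape", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- cmd_simulate(small_sim_config(dir1))
  p2 <- cmd_simulate(small_sim_config(dir2))
  expect_true(all(file.exists(unlist(p1))))
  expect_equal(length(readLines(p1$ratings)) - 1L, 5L * 35L * 2L)
  for (f in c("ratings", "readers", "contours")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  prov <- jsonlite::read_json(p1$provenance)
  expect_equal(prov$seed, 13)
  expect_equal(prov$package, "mrmcad")
  # a missing output directory is created
  nested <- file.path(dir1, "a", "b")
  expect_false(dir.exists(nested))
  cmd_simulate(small_sim_config(nested))
  expect_true(dir.exists(nested))
  expect_error(cmd_simulate(list(bogus_field = 1)), "bogus_field")
})

test_that("analyze produces the full report bundle and is reproducible", {
  dir <- withr::local_tempdir()
  cmd_simulate(small_sim_config(dir))
  acfg <- list(ratings_path = file.path(dir, "ratings.csv"),
               readers_path = file.path(dir, "readers.csv"),
               output_dir = file.path(dir, "rep1"))
  res <- cmd_analyze(acfg)
  expect_s3_class(res, "reader_study_analysis")
  out <- file.path(dir, "rep1")
  for (f in c("reader_auc.csv", "overall_auc.csv", "subgroup_auc.csv",
              "score_sd.csv", "mean_scores.csv", "curve_metrics.csv",
              "analysis.json", "provenance.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  ra <- readr::read_csv(file.path(out, "reader_auc.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(ra), 5)
  expect_true(all(c("p", "improvement") %in% names(ra)))
  # rerun on the same inputs gives identical outputs
  cmd_analyze(modifyList(acfg, list(output_dir = file.path(dir, "rep2"))))
  for (f in c("reader_auc.csv", "overall_auc.csv", "curve_metrics.csv")) {
    expect_identical(readLines(file.path(dir, "rep1", f)),
                     readLines(file.path(dir, "rep2", f)))
  }
  expect_error(cmd_analyze(list(output_dir = dir)), "ratings_path")
})

test_that("analysis results carry tidy, glance and plot methods", {
  cfg <- roe_metz_config(4, 20, 15, separations = c(0.7, 1.3), seed = 3)
  res <- analyze_reader_study(simulate_ratings(cfg))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("auc_difference", "p.value") %in% names(gl)))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(empirical_roc(c(1, 3), c(2, 4))), "ggplot")
  fit <- fit_binormal(round(runif(40, 0, 100)), round(runif(40, 20, 100)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(tidy(fit)$term, c("a", "b"))
})

test_that("the analysis difference direction favours the better modality", {
  cfg <- roe_metz_config(5, 40, 30, separations = c(0.6, 1.4), seed = 21)
  res <- analyze_reader_study(simulate_ratings(cfg))
  expect_gt(res$difference$estimate, 0)   # second modality is stronger
  expect_equal(res$difference$contrast, "with_cad - without_cad")
  # null configuration: difference straddles zero far more often than not;
  # check a single draw stays small
  cfg0 <- roe_metz_config(5, 40, 30, separations = c(1, 1), seed = 22)
  res0 <- analyze_reader_study(simulate_ratings(cfg0))
  expect_lt(abs(res0$difference$estimate), 0.1)
})

test_that("segmatch reports the cross-tab for simulated pairs", {
  dir <- withr::local_tempdir()
  cmd_simulate(small_sim_config(dir))
  summ <- cmd_segmatch(list(contours_path = file.path(dir, "contours.csv"),
                            output_dir = file.path(dir, "seg")))
  expect_s3_class(summ, "match_summary")
  expect_true(file.exists(file.path(dir, "seg", "match_results.csv")))
  tab <- readr::read_csv(file.path(dir, "seg", "segmentation_crosstab.csv"),
                         show_col_types = FALSE)
  expect_equal(tab$subset, c("all", "benign", "malignant"))
  expect_equal(tab$n[1], 12)
  # the mixed-offset default battery populates every category on a
  # larger draw
  dir2 <- withr::local_tempdir()
  cmd_simulate(list(seed = 99, output_dir = dir2,
                    ratings = list(n_readers = 2, n_benign = 5,
                                   n_malignant = 5),
                    contours = list(n_pairs = 60)))
  summ2 <- cmd_segmatch(list(contours_path = file.path(dir2,
                                                       "contours.csv"),
                             output_dir = file.path(dir2, "seg")))
  counts <- summ2$table[summ2$table$subset == "all",
                        c("excellent", "satisfactory", "poor")]
  expect_true(all(counts > 0))
})

test_that("power reporting writes a JSON estimate", {
  dir <- withr::local_tempdir()
  pw <- cmd_power(list(n_readers = 4, n_benign = 20, n_malignant = 15,
                       nsim = 100, seed = 2, output_dir = dir))
  expect_true(file.exists(file.path(dir, "power.json")))
  js <- jsonlite::read_json(file.path(dir, "power.json"))
  expect_equal(js$power, pw$power)
  expect_true(pw$power >= 0 && pw$power <= 1)
})

test_that("yaml and json configs are parsed alike", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(file.path(dir, "j"))
  jpath <- file.path(dir, "cfg.json")
  ypath <- file.path(dir, "cfg.yaml")
  jsonlite::write_json(cfg, jpath, auto_unbox = TRUE)
  yaml::write_yaml(cfg, ypath)
  cmd_simulate(jpath)
  cfg$output_dir <- file.path(dir, "y")
  yaml::write_yaml(cfg, ypath)
  cmd_simulate(ypath)
  expect_identical(readLines(file.path(dir, "j", "ratings.csv")),
                   readLines(file.path(dir, "y", "ratings.csv")))
  expect_error(read_config(file.path(dir, "nope.json")), "not found")
})
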