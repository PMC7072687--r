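test_that("pseudovalues match hand enumeration on the 4-case toy", {
  rs <- toy_ratings(array(c(1, 3, 2, 4), c(1, 1, 4)),
                    truth = c(0, 0, 1, 1), modalities = "m")
  pv <- jackknife_pseudovalues(rs)
  # theta = 0.75; deleting the benign case scored 1 leaves AUC 0.5,
  # so its pseudovalue is 4 * 0.75 - 3 * 0.5 = 1.5
  expect_equal(attr(pv, "theta")$theta, 0.75)
  expect_equal(pv$pseudovalue[pv$case_id == "c01"], 1.5)
  # cube rows are in case order; the oracle returns benign cases then
  # malignant, which is the same order in this toy
  expect_equal(pv$pseudovalue, brute_pseudovalues(c(1, 3), c(2, 4)))
})

test_that("pseudovalues equal brute-force leave-one-out on random instances", {
  withr::with_seed(21, {
    for (i in 1:100) {
      c0 <- sample(2:5, 1)
      c1 <- sample(2:5, 1)
      x <- sample(0:30, c0, replace = TRUE)
      y <- sample(0:30, c1, replace = TRUE)
      rs <- toy_ratings(array(c(x, y), c(1, 1, c0 + c1)),
                        truth = c(rep(0, c0), rep(1, c1)),
                        modalities = "m")
      pv <- jackknife_pseudovalues(rs)
      pv <- pv[order(pv$case_id), ]
      expect_equal(pv$pseudovalue, brute_pseudovalues(x, y),
                   tolerance = 1e-10)
      # U-statistic identity: pseudovalue mean equals the full AUC
      expect_equal(mean(pv$pseudovalue), wilcoxon_auc(x, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("constant discrimination gives constant pseudovalues", {
  # both classes constant within class: every leave-one-out AUC equals theta
  rs <- toy_ratings(array(rep(c(10, 10, 80, 80), each = 2), c(2, 1, 4)),
                    truth = c(0, 0, 1, 1))
  pv <- jackknife_pseudovalues(rs)
  expect_true(all(pv$pseudovalue == 1))
})

test_that("a custom metric function goes through the naive jackknife", {
  rs <- random_toy_ratings(t_ = 1, r_ = 1, c0 = 4, c1 = 4)
  pv_fast <- jackknife_pseudovalues(rs, "wilcoxon")
  pv_fn <- jackknife_pseudovalues(rs, function(b, m) wilcoxon_auc(b, m))
  expect_equal(pv_fast$pseudovalue, pv_fn$pseudovalue, tolerance = 1e-12)
})

test_that("ANOVA mean squares obey closed forms and the SS identity", {
  # pure modality effect: Y[i,j,k] = alpha_i
  a1 <- 0.9; a2 <- 0.3; r_ <- 4; c_ <- 6
  Y <- array(rep(c(a1, a2), times = r_ * c_), c(2, r_, c_))
  rs <- toy_ratings(Y, truth = c(rep(0, 3), rep(1, 3)))
  pv <- jackknife_pseudovalues(rs)
  pv$pseudovalue <- as.vector(Y)   # inject the closed-form cube
  an <- dbm_anova(pv)
  expect_equal(unname(an$ms[["T"]]), r_ * c_ * (a1 - a2)^2 / 2,
               tolerance = 1e-10)
  expect_equal(unname(an$ms[c("R", "C", "TR", "TC", "RC", "TRC")]),
               rep(0, 6), tolerance = 1e-10, ignore_attr = TRUE)

  # identical pseudovalues: every mean square vanishes
  pv$pseudovalue <- rep(0.7, nrow(pv))
  expect_true(all(dbm_anova(pv)$ms < 1e-20))

  # decomposition identity on random cubes
  withr::with_seed(31, {
    for (i in 1:100) {
      t_ <- sample(2:3, 1); r_ <- sample(2:4, 1); c_ <- sample(4:6, 1)
      Y <- array(rnorm(t_ * r_ * c_), c(t_, r_, c_))
      rs <- toy_ratings(array(50, c(t_, r_, c_)),
                        truth = c(rep(0, 2), rep(1, c_ - 2)))
      pv <- jackknife_pseudovalues(rs)
      pv$pseudovalue <- as.vector(Y)
      ms <- dbm_anova(pv)$ms
      ss_total <- sum((Y - mean(Y))^2)
      ss_parts <- sum(ms * c((t_ - 1), (r_ - 1), (c_ - 1),
                             (t_ - 1) * (r_ - 1), (t_ - 1) * (c_ - 1),
                             (r_ - 1) * (c_ - 1),
                             (t_ - 1) * (r_ - 1) * (c_ - 1)))
      expect_equal(ss_parts, ss_total, tolerance = 1e-10)
    }
  })
})

test_that("dbm_test uses the Hillis denominator and df", {
  rs <- random_toy_ratings(t_ = 2, r_ = 5, c0 = 4, c1 = 4)
  an <- dbm_anova(jackknife_pseudovalues(rs))
  an$ms[c("TR", "TC", "TRC")] <- c(1, 0.5, 0.5)
  an$ms[["T"]] <- 2
  res <- dbm_test(an)
  # D = 1 + max(0.5 - 0.5, 0) = 1, ddf = 1 / (1 / ((2-1)(5-1))) = 4
  expect_equal(res$F, 2)
  expect_equal(res$ddf, 4)
  expect_equal(res$ndf, 1)
  expect_equal(res$p, pf(2, 1, 4, lower.tail = FALSE))
  # truncation active when MS(TC) < MS(TRC)
  an$ms[c("TR", "TC", "TRC")] <- c(1, 0.2, 0.5)
  expect_equal(dbm_test(an)$ddf, 4)
})

test_that("no-variability designs return p = 1 with a flag", {
  rs <- toy_ratings(array(50, c(2, 3, 6)),
                    truth = c(rep(0, 3), rep(1, 3)))
  res <- dbm_compare(rs)
  expect_true(res$no_variability)
  expect_equal(res$p, 1)
})

test_that("modality relabelling flips the difference but not F or p", {
  rs <- random_toy_ratings(t_ = 2, r_ = 4, c0 = 5, c1 = 5)
  res1 <- dbm_compare(rs)
  swapped <- rs
  swapped$modality <- factor(as.character(swapped$modality),
                             levels = rev(levels(rs$modality)))
  res2 <- dbm_compare(swapped)
  expect_equal(res2$F, res1$F, tolerance = 1e-10)
  expect_equal(res2$p, res1$p, tolerance = 1e-10)
  expect_equal(res2$diff$estimate, -res1$diff$estimate, tolerance = 1e-10)
})

test_that("adding a constant to one modality leaves the AUC-based F unchanged", {
  rs <- random_toy_ratings(t_ = 2, r_ = 3, c0 = 5, c1 = 5)
  rs$score <- pmin(rs$score, 90)
  shifted <- rs
  m1 <- levels(rs$modality)[1]
  sel <- as.character(shifted$modality) == m1
  shifted$score[sel] <- shifted$score[sel] + 5
  res1 <- dbm_compare(rs)
  res2 <- dbm_compare(shifted)
  expect_equal(res2$F, res1$F, tolerance = 1e-10)
  expect_equal(res2$p, res1$p, tolerance = 1e-10)
})

test_that("per-reader test matches a brute-force paired t on pseudovalues", {
  rs <- random_toy_ratings(t_ = 2, r_ = 2, c0 = 3, c1 = 3)
  rd <- unique(rs$reader_id)[1]
  res <- per_reader_test(rs, rd)
  sub <- rs[rs$reader_id == rd, ]
  mods <- levels(rs$modality)
  pvs <- lapply(mods, function(m) {
    s <- sub[as.character(sub$modality) == m, ]
    s <- s[order(s$case_id), ]
    brute_pseudovalues(s$score[s$truth == 0], s$score[s$truth == 1])
  })
  # brute_pseudovalues orders benign cases then malignant; case ids sort
  # the same way in these toys
  d <- pvs[[1]] - pvs[[2]]
  expect_equal(res$p, t.test(d)$p.value, tolerance = 1e-10)
  expect_equal(res$diff, mean(d), tolerance = 1e-10)
})

test_that("per-reader test is null on identical modalities and responds to shifts", {
  x <- array(rep(c(10, 30, 50, 25, 40, 60), each = 2), c(2, 1, 6))
  rs <- toy_ratings(x, truth = c(0, 0, 0, 1, 1, 1))
  res <- per_reader_test(rs, "r01")
  expect_equal(res$p, 1)
  expect_equal(res$diff, 0)
  expect_true(res$zero_variance)
  # inflating malignant scores of the second modality increases theta_2
  rs2 <- rs
  sel <- rs2$truth == 1 & as.character(rs2$modality) == "mod2"
  rs2$score[sel] <- rs2$score[sel] + 15
  res2 <- per_reader_test(rs2, "r01")
  expect_gt(res2$theta_2, res2$theta_1)
})

test_that("subgroup analysis reduces to the ungrouped result and is symmetric", {
  rs <- random_toy_ratings(t_ = 2, r_ = 4, c0 = 5, c1 = 5)
  ids <- unique(rs$reader_id)
  whole <- subgroup_analysis(rs, list(all = ids))
  expect_equal(whole$per_group$all$p, dbm_compare(rs)$p, tolerance = 1e-12)
  expect_null(whole$between)

  # duplicate the reader set as two identical groups: improvements match
  rs2 <- dplyr::bind_rows(
    rs, dplyr::mutate(rs, reader_id = paste0(.data$reader_id, "_b")))
  groups <- list(g1 = ids, g2 = paste0(ids, "_b"))
  res <- subgroup_analysis(rs2, groups)
  expect_equal(res$between$p, 1)
  expect_equal(res$between$estimate, 0)
  expect_error(subgroup_analysis(rs, list(g1 = ids[1], g2 = ids[-1])),
               "at least 2 readers")
  expect_error(subgroup_analysis(rs, list(g1 = ids[-1])), "partition")
})

test_that("power estimation is deterministic and monotone in study size", {
  cfg_small <- roe_metz_config(n_readers = 4, n_benign = 30,
                               n_malignant = 20,
                               separations = c(0.6, 1.3), seed = 1)
  p1 <- estimate_power(cfg_small, nsim = 100, seed = 5)
  p2 <- estimate_power(cfg_small, nsim = 100, seed = 5)
  expect_identical(p1, p2)
  expect_true(p1$power >= 0 && p1$power <= 1)
  cfg_large <- cfg_small
  cfg_large$n_readers <- 10L
  cfg_large$n_benign <- 90L
  cfg_large$n_malignant <- 60L
  p3 <- estimate_power(cfg_large, nsim = 100, seed = 5)
  expect_gte(p3$power, p1$power - 2 * (p1$mc_se + p3$mc_se))
  expect_error(estimate_power(cfg_small, nsim = 10), "at least 100")
})
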