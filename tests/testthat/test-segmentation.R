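square <- function(half = 10) {
  contour_mm(cbind(c(-half, half, half, -half),
                   c(-half, -half, half, half)))
}

test_that("contour construction enforces the invariants", {
  expect_s3_class(square(), "contour")
  expect_error(contour_mm(cbind(0:1, 0:1)), "at least 3")
  expect_error(contour_mm(cbind(c(0, 0, 1), c(0, 0, 1))), "identical")
  expect_error(contour_mm(cbind(c(0, 1, 0), c(0, 1, 0))), "identical")
  expect_error(contour_mm(cbind(c(0, 1, Inf), c(0, 1, 2))), "finite")
  expect_error(contour_mm(cbind(c(0, 1, 2), c(0, 1, 0)), closed = FALSE),
               "open contours")
})

test_that("nearest distance is exact on hand geometry", {
  sq <- square(10)
  expect_equal(nearest_distance(c(0, 0), sq), 10)
  expect_equal(nearest_distance(c(10, 10), sq), 0)
  expect_equal(nearest_distance(c(0, -10), sq), 0)   # on an edge interior
  expect_equal(nearest_distance(c(13, 0), sq), 3)
  expect_equal(nearest_distance(c(13, 14), sq), 5)   # corner 3-4-5
  # vertex mode never undercuts segment mode
  withr::with_seed(41, {
    for (i in 1:100) {
      p <- runif(2, -30, 30)
      expect_gte(nearest_distance(p, sq, mode = "vertex"),
                 nearest_distance(p, sq, mode = "segment") - 1e-12)
    }
  })
})

test_that("point-to-segment distances agree with dense brute force", {
  withr::with_seed(43, {
    for (i in 1:100) {
      n <- sample(3:7, 1)
      ang <- sort(runif(n, 0, 2 * pi))
      rad <- runif(n, 2, 6)
      v <- cbind(rad * cos(ang), rad * sin(ang))
      ct <- contour_mm(v)
      p <- runif(2, -8, 8)
      expect_lt(abs(nearest_distance(p, ct) -
                      brute_point_contour_dist(p, v)), 1e-4)
    }
  })
})

test_that("match ratio follows the radial geometry of circles", {
  c10 <- circle_contour(10, 360)
  expect_equal(match_ratio(c10, c10)$ratio, 1)
  expect_equal(match_ratio(c10, circle_contour(10.5, 360))$ratio, 1)
  m <- match_ratio(c10, circle_contour(11.5, 360))
  expect_equal(m$ratio, 0)
  expect_equal(m$category, "poor")
  expect_true(all(abs(m$distances - 1.5) < 0.01))
  expect_error(match_ratio(c10, c10, tolerance_mm = 0), "positive")
})

test_that("ratio shrinks with tolerance and is translation invariant", {
  withr::with_seed(47, {
    base <- circle_contour(10, 90)
    noisy <- contour_mm(cbind((10 + rnorm(90, 0, 0.8)) *
                                cos(seq(0, 2 * pi, length.out = 91)[-91]),
                              (10 + rnorm(90, 0, 0.8)) *
                                sin(seq(0, 2 * pi, length.out = 91)[-91])))
  })
  tols <- c(2, 1, 0.5, 0.25)
  ratios <- vapply(tols, function(tl) {
    match_ratio(base, noisy, tolerance_mm = tl)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) <= 0))
  # rigid translation of both contours changes nothing
  shift <- function(ct, dx, dy) {
    contour_mm(cbind(ct$x_mm + dx, ct$y_mm + dy))
  }
  m0 <- match_ratio(base, noisy)
  m1 <- match_ratio(shift(base, 3.2, -7.7), shift(noisy, 3.2, -7.7))
  expect_equal(m1$distances, m0$distances, tolerance = 1e-9)
  expect_equal(m1$ratio, m0$ratio)
})

test_that("the measure is directional and each direction matches brute force", {
  # a small arc-like triangle inside a large square: every triangle vertex
  # is far from the square, but some square vertices are near nothing
  inner <- contour_mm(cbind(c(0, 1, 0.5), c(0, 0, 0.8)))
  outer <- square(1.2)
  r_io <- match_ratio(inner, outer)$ratio
  r_oi <- match_ratio(outer, inner)$ratio
  expect_false(isTRUE(all.equal(r_io, r_oi)))
  brute_ratio <- function(a, b) {
    va <- cbind(a$x_mm, a$y_mm)
    mean(vapply(seq_len(nrow(va)), function(i) {
      brute_point_contour_dist(va[i, ], cbind(b$x_mm, b$y_mm)) <= 1
    }, logical(1)))
  }
  expect_equal(r_io, brute_ratio(inner, outer))
  expect_equal(r_oi, brute_ratio(outer, inner))
})

test_that("classification applies the category rule at its boundaries", {
  expect_equal(classify_match(1), "excellent")
  expect_equal(classify_match(1 - 1e-13), "excellent")
  expect_equal(classify_match(0.999), "satisfactory")
  expect_equal(classify_match(0.85), "satisfactory")
  expect_equal(classify_match(0.7), "satisfactory")
  expect_equal(classify_match(0.699), "poor")
  expect_equal(classify_match(0.5), "poor")
  expect_equal(classify_match(0), "poor")
  expect_error(classify_match(1.2), "\\[0, 1\\]")
  expect_error(classify_match(-0.1), "\\[0, 1\\]")
})

test_that("cross-tab counts, percentages and the symmetric null behave", {
  records <- tibble::tibble(
    category = c(rep("excellent", 4), rep("satisfactory", 2),
                 rep("poor", 2)),
    truth = c(0, 0, 1, 1, 0, 1, 0, 1)
  )
  sm <- summarize_matches(records)
  tab <- sm$table
  expect_equal(tab$n, c(8L, 4L, 4L))
  expect_equal(tab$excellent, c(4L, 2L, 2L))
  expect_equal(tab$pct_successful, c(75, 75, 75))
  expect_equal(sm$test$p, 1)   # identical class proportions
  expect_error(summarize_matches(
    tibble::tibble(category = "great", truth = 0)), "unknown category")
  expect_error(summarize_matches(records[0, ]), "empty")
})

test_that("contour CSV io round-trips pairs", {
  cfg <- contour_sim_config(n_pairs = 4, radial_noise_sd_mm = 0.3,
                            n_vertices = 32, seed = 9)
  pairs <- simulate_contour_pairs(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(pairs, path)
  back <- read_contours(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$truth, as.numeric(pairs$truth))
  for (i in 1:4) {
    expect_equal(back$physician[[i]]$x_mm, pairs$physician[[i]]$x_mm)
    expect_equal(back$software[[i]]$y_mm, pairs$software[[i]]$y_mm)
  }
})
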