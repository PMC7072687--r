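#' Configuration for the latent-variable rating simulator
#'
#' Defines a Roe-Metz-style two-class latent model for fully crossed
#' MRMC rating data. For reader j, case k and modality i the latent
#' decision variable is
#' \deqn{Z_{ijk} = (\delta_i + \tau_{ij})\,s_k + C_k + RC_{jk} +
#'   \varepsilon_{ijk}}
#' with truth indicator `s_k` (1 for malignant), case effect
#' `C_k ~ N(0, var_case)` and reader-by-case effect
#' `RC_jk ~ N(0, var_reader_case)` shared across modalities (the paired
#' design), modality-specific noise `eps ~ N(0, var_error)`, and a
#' reader-by-modality skill perturbation `tau_ij ~ N(0, var_reader_skill)`
#' of the class separation `delta_i`. The within-class latent variance
#' `var_case + var_reader_case + var_error` is normalised to 1, so the
#' expected reader-averaged AUC of modality i is
#' `pnorm(delta_i / sqrt(2 + var_reader_skill))`.
#'
#' Scores are mapped to the 0-100 rating scale by
#' `clamp(round(50 + score_slope * Z), 0, 100)`.
#'
#' @param n_readers,n_benign,n_malignant Design dimensions.
#' @param separations Per-modality latent class separations
#'   (nonnegative), one per modality.
#' @param var_reader_skill Variance of the reader-by-modality separation
#'   perturbation; default 0.04.
#' @param var_case,var_reader_case,var_error Latent variance components;
#'   must be nonnegative and sum to 1 (defaults 0.6, 0.2, 0.2).
#' @param score_slope Points of score per latent unit; default 20.
#' @param modalities Modality labels, same length as `separations`.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `roe_metz_config`.
#' @export
roe_metz_config <- function(n_readers, n_benign, n_malignant,
                            separations = c(1, 1),
                            var_reader_skill = 0.04,
                            var_case = 0.6, var_reader_case = 0.2,
                            var_error = 0.2, score_slope = 20,
                            modalities = NULL, seed = 1) {
  if (is.null(modalities)) {
    modalities <- if (length(separations) == 2) {
      c("without_cad", "with_cad")
    } else {
      paste0("modality_", seq_along(separations))
    }
  }
  cfg <- structure(
    list(n_readers = as.integer(n_readers),
         n_benign = as.integer(n_benign),
         n_malignant = as.integer(n_malignant),
         separations = as.numeric(separations),
         var_reader_skill = var_reader_skill,
         var_case = var_case, var_reader_case = var_reader_case,
         var_error = var_error, score_slope = score_slope,
         modalities = as.character(modalities),
         seed = as.integer(seed)),
    class = "roe_metz_config"
  )
  validate_roe_metz_config(cfg)
  cfg
}

validate_roe_metz_config <- function(cfg) {
  with(cfg, {
    if (n_readers < 1 || n_benign < 2 || n_malignant < 2) {
      abort("need n_readers >= 1 and at least 2 cases per class")
    }
    if (length(separations) < 1 || any(separations < 0)) {
      abort("separations must be nonnegative, one per modality")
    }
    if (length(modalities) != length(separations)) {
      abort("modalities and separations must have the same length")
    }
    vars <- c(var_reader_skill, var_case, var_reader_case, var_error)
    if (any(vars < 0)) abort("variance components must be nonnegative")
    if (abs(var_case + var_reader_case + var_error - 1) > 1e-8) {
      abort("var_case + var_reader_case + var_error must equal 1")
    }
    if (score_slope <= 0) abort("score_slope must be positive")
  })
  invisible(cfg)
}

#' Default study-shaped simulator configuration
#'
#' The configuration mirroring the thyroid-nodule reader study design:
#' 19 readers, 165 benign and 100 malignant cases, two paired modalities
#' (without / with CAD) with latent separations calibrated so the
#' expected reader-averaged Wilcoxon AUCs are 0.728 and 0.792 via
#' `delta_i = qnorm(AUC_i) * sqrt(2 + var_reader_skill)`.
#'
#' @param auc_targets Expected reader-averaged AUC per modality; default
#'   `c(0.728, 0.792)`.
#' @param seed Seed; default 20200206.
#' @return A `roe_metz_config`.
#' @export
default_study_config <- function(auc_targets = c(0.728, 0.792),
                                 seed = 20200206) {
  var_reader_skill <- 0.04
  roe_metz_config(
    n_readers = 19, n_benign = 165, n_malignant = 100,
    separations = qnorm(auc_targets) * sqrt(2 + var_reader_skill),
    var_reader_skill = var_reader_skill,
    var_case = 0.6, var_reader_case = 0.2, var_error = 0.2,
    score_slope = 20, seed = seed
  )
}

#' Expected reader-averaged AUC of a simulator configuration
#'
#' Closed form ignoring score rounding and clamping:
#' `pnorm(delta / sqrt(2 + var_reader_skill))`.
#'
#' @param cfg A `roe_metz_config`.
#' @return A numeric vector, one expected AUC per modality.
#' @export
expected_auc <- function(cfg) {
  pnorm(cfg$separations / sqrt(2 + cfg$var_reader_skill))
}

# internal: draw one study using the CURRENT RNG state.
# Returns list(scores = array [t, r, c], truth).
simulate_scores_core <- function(cfg) {
  t_ <- length(cfg$separations)
  r_ <- cfg$n_readers
  c_ <- cfg$n_benign + cfg$n_malignant
  s <- c(rep(0, cfg$n_benign), rep(1, cfg$n_malignant))
  tau <- matrix(rnorm(t_ * r_, 0, sqrt(cfg$var_reader_skill)), t_, r_)
  Ck <- rnorm(c_, 0, sqrt(cfg$var_case))
  RC <- matrix(rnorm(r_ * c_, 0, sqrt(cfg$var_reader_case)), r_, c_)
  eps <- array(rnorm(t_ * r_ * c_, 0, sqrt(cfg$var_error)), c(t_, r_, c_))
  scores <- array(NA_real_, c(t_, r_, c_))
  for (i in seq_len(t_)) {
    sep <- outer(cfg$separations[i] + tau[i, ], s)    # r x c
    z <- sep + matrix(Ck, r_, c_, byrow = TRUE) + RC + eps[i, , ]
    scores[i, , ] <- pmin(pmax(round(50 + cfg$score_slope * z), 0), 100)
  }
  list(scores = scores, truth = s)
}

#' Simulate a fully crossed MRMC rating table
#'
#' Draws one study from a [roe_metz_config()]. Deterministic given the
#' config seed; the global RNG state is left untouched.
#'
#' @param cfg A `roe_metz_config`.
#' @return A validated ratings tibble with `n_readers * n_cases *
#'   n_modalities` rows. Case ids are ordered benign first; reader and
#'   case ids are zero-padded so lexicographic and numeric order agree.
#' @export
simulate_ratings <- function(cfg) {
  validate_roe_metz_config(cfg)
  sim <- withr::with_seed(cfg$seed, simulate_scores_core(cfg))
  t_ <- length(cfg$modalities)
  r_ <- cfg$n_readers
  c_ <- cfg$n_benign + cfg$n_malignant
  readers <- sprintf("reader_%02d", seq_len(r_))
  cases <- sprintf("case_%03d", seq_len(c_))
  out <- tibble::tibble(
    reader_id = rep(rep(readers, each = t_), times = c_),
    case_id = rep(cases, each = t_ * r_),
    modality = factor(rep(cfg$modalities, times = r_ * c_),
                      levels = cfg$modalities),
    score = as.vector(sim$scores),
    truth = rep(as.integer(sim$truth), each = t_ * r_)
  )
  validate_ratings(out)
}

#' Study-shaped reader experience profile
#'
#' A deterministic experience table matching the study's reader mix:
#' 12 junior readers with 2-9 years of experience and 7 senior readers
#' with 14-31 years.
#'
#' @param n_readers Total readers; default 19. For other counts the same
#'   12:7 junior:senior proportion is kept (rounded).
#' @return A tibble with `reader_id`, `experience_years`.
#' @export
default_reader_info <- function(n_readers = 19) {
  n_junior <- round(n_readers * 12 / 19)
  n_senior <- n_readers - n_junior
  years <- c(
    round(seq(2, 9, length.out = max(n_junior, 1)))[seq_len(n_junior)],
    round(seq(14, 31, length.out = max(n_senior, 1)))[seq_len(n_senior)]
  )
  tibble::tibble(
    reader_id = sprintf("reader_%02d", seq_len(n_readers)),
    experience_years = as.numeric(years)
  )
}

#' Configuration for the contour-pair simulator
#'
#' @param n_pairs Number of contour pairs.
#' @param base_radius_mm Radius of the physician (reference) circle;
#'   must be positive.
#' @param radial_noise_sd_mm SD of the per-vertex radial perturbation of
#'   the software contour.
#' @param systematic_offset_mm Constant radial offset of the software
#'   contour (positive = software contour larger).
#' @param n_vertices Vertices per contour; at least 16.
#' @param prop_malignant Probability a pair is labelled malignant;
#'   default 100/265, the study's class mix.
#' @param seed Integer seed.
#' @return A validated list of class `contour_sim_config`.
#' @export
contour_sim_config <- function(n_pairs = 100, base_radius_mm = 10,
                               radial_noise_sd_mm = 0.3,
                               systematic_offset_mm = 0,
                               n_vertices = 128,
                               prop_malignant = 100 / 265, seed = 1) {
  cfg <- structure(
    list(n_pairs = as.integer(n_pairs),
         base_radius_mm = base_radius_mm,
         radial_noise_sd_mm = radial_noise_sd_mm,
         systematic_offset_mm = systematic_offset_mm,
         n_vertices = as.integer(n_vertices),
         prop_malignant = prop_malignant,
         seed = as.integer(seed)),
    class = "contour_sim_config"
  )
  if (cfg$base_radius_mm <= 0) abort("base_radius_mm must be positive")
  if (cfg$n_vertices < 16) abort("n_vertices must be at least 16")
  if (cfg$radial_noise_sd_mm < 0) abort("radial_noise_sd_mm must be >= 0")
  if (cfg$n_pairs < 1) abort("n_pairs must be at least 1")
  if (cfg$prop_malignant < 0 || cfg$prop_malignant > 1) {
    abort("prop_malignant must be in [0, 1]")
  }
  cfg
}

#' Circle sampled as a contour
#'
#' @param radius_mm Circle radius in millimetres.
#' @param n_vertices Number of evenly spaced vertices.
#' @param center Length-2 centre coordinates; default the origin.
#' @return A `contour`.
#' @export
circle_contour <- function(radius_mm, n_vertices = 128, center = c(0, 0)) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  contour_mm(cbind(center[1] + radius_mm * cos(ang),
                   center[2] + radius_mm * sin(ang)))
}

#' Simulate physician/software contour pairs
#'
#' The physician contour is a circle of `base_radius_mm` sampled at
#' `n_vertices` points. The software contour uses the same angles with
#' radius perturbed by smoothed Gaussian noise (circular moving average,
#' window 3) plus the constant systematic offset. Radial (star-shaped)
#' perturbation of positive radii cannot self-intersect; draws producing
#' a nonpositive radius are resampled (up to 100 retries), then rejected.
#'
#' @param cfg A `contour_sim_config`.
#' @return A tibble with columns `case_id`, `truth` and list-columns
#'   `physician`, `software` holding `contour` objects.
#' @export
simulate_contour_pairs <- function(cfg) {
  if (!inherits(cfg, "contour_sim_config")) {
    abort("cfg must be a contour_sim_config")
  }
  withr::with_seed(cfg$seed, {
    truth <- as.integer(runif(cfg$n_pairs) < cfg$prop_malignant)
    ang <- seq(0, 2 * pi,
               length.out = cfg$n_vertices + 1)[-(cfg$n_vertices + 1)]
    pairs <- purrr::map(seq_len(cfg$n_pairs), function(idx) {
      phys <- contour_mm(cbind(cfg$base_radius_mm * cos(ang),
                               cfg$base_radius_mm * sin(ang)))
      for (try in 1:100) {
        noise <- rnorm(cfg$n_vertices, 0, cfg$radial_noise_sd_mm)
        noise <- circular_ma3(noise)
        radius <- cfg$base_radius_mm + cfg$systematic_offset_mm + noise
        if (all(radius > 0)) {
          soft <- contour_mm(cbind(radius * cos(ang), radius * sin(ang)))
          return(list(physician = phys, software = soft))
        }
      }
      abort("could not draw a valid software contour (radius <= 0)")
    })
    tibble::tibble(
      case_id = sprintf("pair_%03d", seq_len(cfg$n_pairs)),
      truth = truth,
      physician = purrr::map(pairs, "physician"),
      software = purrr::map(pairs, "software")
    )
  })
}

# circular moving average with window 3 (keeps the mean, smooths kinks)
circular_ma3 <- function(x) {
  n <- length(x)
  (x + x[c(n, 1:(n - 1))] + x[c(2:n, 1)]) / 3
}
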