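#' Validate a reader-rating table
#'
#' A rating table holds one malignancy-potential score per
#' (reader, case, modality) cell of a fully crossed MRMC design, together
#' with the per-case pathology truth. It is an ordinary tibble with columns
#' `reader_id`, `case_id`, `modality`, `score` and `truth`; `validate_ratings()`
#' checks the design invariants and returns the table in canonical order.
#'
#' Invariants enforced:
#' * every (reader, case, modality) cell present exactly once (fully crossed);
#' * all scores within \[0, 100\] (real-valued; decimals are allowed);
#' * `truth` constant per case, coded 0 = benign, 1 = malignant, with at
#'   least two cases of each class.
#'
#' @param ratings A data frame with columns `reader_id`, `case_id`,
#'   `modality`, `score`, `truth`.
#' @return A tibble sorted by (reader, case, modality), with `modality`
#'   kept as a factor whose level order is the order of first appearance
#'   (or the existing level order if already a factor).
#' @examples
#' rs <- simulate_ratings(roe_metz_config(n_readers = 3, n_benign = 5,
#'                                        n_malignant = 5, seed = 1))
#' validate_ratings(rs)
#' @export
validate_ratings <- function(ratings) {
  required <- c("reader_id", "case_id", "modality", "score", "truth")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols) > 0) {
    abort(paste0("ratings is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ratings <- tibble::as_tibble(ratings)
  if (!is.factor(ratings$modality)) {
    ratings$modality <- factor(ratings$modality,
                               levels = unique(as.character(ratings$modality)))
  }
  ratings$reader_id <- as.character(ratings$reader_id)
  ratings$case_id <- as.character(ratings$case_id)

  if (nrow(ratings) == 0) abort("ratings table is empty")
  if (anyNA(ratings[required])) abort("ratings contains missing values")
  if (any(ratings$score < 0 | ratings$score > 100)) {
    bad <- ratings[ratings$score < 0 | ratings$score > 100, ][1, ]
    abort(sprintf(
      "score out of range [0, 100]: reader %s, case %s, modality %s has %g",
      bad$reader_id, bad$case_id, as.character(bad$modality), bad$score))
  }
  if (!all(ratings$truth %in% c(0, 1))) {
    abort("truth must be coded 0 (benign) or 1 (malignant)")
  }

  # truth constant per case
  tr <- dplyr::distinct(ratings, .data$case_id, .data$truth)
  dup <- tr$case_id[duplicated(tr$case_id)]
  if (length(dup) > 0) {
    abort(sprintf("inconsistent truth: case %s has more than one truth value",
                  dup[[1]]))
  }
  if (sum(tr$truth == 0) < 2 || sum(tr$truth == 1) < 2) {
    abort("need at least 2 cases of each truth class")
  }

  readers <- unique(ratings$reader_id)
  cases <- unique(ratings$case_id)
  mods <- levels(ratings$modality)

  # fully crossed, no duplicates
  key <- paste(ratings$reader_id, ratings$case_id,
               as.character(ratings$modality), sep = "\r")
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    abort(sprintf("duplicate cell: reader %s, case %s, modality %s",
                  k[1], k[2], k[3]))
  }
  n_expect <- length(readers) * length(cases) * length(mods)
  if (nrow(ratings) != n_expect) {
    full <- expand.grid(reader_id = readers, case_id = cases,
                        modality = mods, stringsAsFactors = FALSE)
    fkey <- paste(full$reader_id, full$case_id, full$modality, sep = "\r")
    miss <- full[match(setdiff(fkey, key)[1], fkey), ]
    abort(sprintf(
      "incomplete design: missing cell reader %s, case %s, modality %s",
      miss$reader_id, miss$case_id, miss$modality))
  }

  dplyr::arrange(ratings, .data$reader_id, .data$case_id, .data$modality)
}

#' Read a reader-rating table from long CSV
#'
#' Expects a UTF-8 CSV with header `reader_id,case_id,modality,score,truth`.
#' The result is validated with [validate_ratings()]; row order of the file
#' does not affect any downstream statistic.
#'
#' @param path Path to the CSV file.
#' @return A validated ratings tibble.
#' @export
read_ratings <- function(path) {
  ratings <- readr::read_csv(
    path,
    col_types = readr::cols(
      reader_id = readr::col_character(),
      case_id = readr::col_character(),
      modality = readr::col_character(),
      score = readr::col_double(),
      truth = readr::col_integer()
    )
  )
  validate_ratings(ratings)
}

#' Write a reader-rating table to long CSV
#'
#' Rows are written in deterministic (reader, case, modality) lexicographic
#' order with fixed column order, so the same table always produces the
#' same bytes and `read_ratings(write_ratings(x))` round-trips exactly.
#'
#' @param ratings A ratings data frame (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  # modality sorts in level order (not alphabetically) so that the
  # first-appearance order in the file reproduces the level order on read
  out <- dplyr::arrange(ratings, .data$reader_id, .data$case_id,
                        .data$modality)
  out <- dplyr::mutate(out, modality = as.character(.data$modality))
  out <- out[, c("reader_id", "case_id", "modality", "score", "truth")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Split a rating table into junior and senior reader groups
#'
#' Readers with fewer than `threshold_years` years of experience form the
#' junior group; readers at or above the threshold form the senior group.
#' Cases and modalities are unchanged, so the two halves partition the
#' readers of the input.
#'
#' @param ratings A ratings data frame.
#' @param reader_info A data frame with columns `reader_id` and
#'   `experience_years` (nonnegative), one row per reader.
#' @param threshold_years Experience cut point in years; default 10.
#' @return A named list with validated ratings tibbles `junior` and
#'   `senior`. A group can be empty (zero readers), in which case the
#'   element is `NULL`.
#' @export
split_by_experience <- function(ratings, reader_info, threshold_years = 10) {
  ratings <- validate_ratings(ratings)
  if (!all(c("reader_id", "experience_years") %in% names(reader_info))) {
    abort("reader_info needs columns reader_id and experience_years")
  }
  reader_info <- tibble::as_tibble(reader_info)
  reader_info$reader_id <- as.character(reader_info$reader_id)
  if (anyDuplicated(reader_info$reader_id)) {
    abort("reader_info has duplicated reader_id")
  }
  if (any(reader_info$experience_years < 0)) {
    abort("experience_years must be nonnegative")
  }
  readers <- unique(ratings$reader_id)
  missing <- setdiff(readers, reader_info$reader_id)
  if (length(missing) > 0) {
    abort(paste0("no experience record for reader(s): ",
                 paste(missing, collapse = ", ")))
  }
  info <- reader_info[reader_info$reader_id %in% readers, ]
  junior_ids <- info$reader_id[info$experience_years < threshold_years]
  senior_ids <- info$reader_id[info$experience_years >= threshold_years]
  take <- function(ids) {
    if (length(ids) == 0) return(NULL)
    if (length(ids) < 2) {
      warn("group has fewer than 2 readers; reader-variance estimates are weak")
    }
    validate_ratings(ratings[ratings$reader_id %in% ids, ])
  }
  list(junior = take(junior_ids), senior = take(senior_ids))
}

#' Study dimensions of a rating table
#'
#' @param ratings A validated ratings data frame.
#' @return A one-row tibble with `n_readers`, `n_cases`, `n_modalities`,
#'   `n_benign`, `n_malignant`.
#' @export
rating_dims <- function(ratings) {
  ratings <- validate_ratings(ratings)
  tr <- dplyr::distinct(ratings, .data$case_id, .data$truth)
  tibble::tibble(
    n_readers = dplyr::n_distinct(ratings$reader_id),
    n_cases = nrow(tr),
    n_modalities = nlevels(ratings$modality),
    n_benign = sum(tr$truth == 0),
    n_malignant = sum(tr$truth == 1)
  )
}

# internal: ratings tibble -> list(scores = array[t, r, c], truth,
# readers, cases, modalities). Used by the DBM pipeline and simulator loops.
ratings_to_array <- function(ratings) {
  ratings <- validate_ratings(ratings)
  readers <- sort(unique(ratings$reader_id))
  cases <- sort(unique(ratings$case_id))
  mods <- levels(ratings$modality)
  arr <- array(NA_real_,
               dim = c(length(mods), length(readers), length(cases)),
               dimnames = list(mods, readers, cases))
  idx <- cbind(match(as.character(ratings$modality), mods),
               match(ratings$reader_id, readers),
               match(ratings$case_id, cases))
  arr[idx] <- ratings$score
  tr <- dplyr::distinct(ratings, .data$case_id, .data$truth)
  truth <- tr$truth[match(cases, tr$case_id)]
  list(scores = arr, truth = truth, readers = readers, cases = cases,
       modalities = mods)
}
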