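#' Construct a closed nodule contour
#'
#' A contour is an ordered list of 2D vertices in millimetres describing a
#' closed polyline (the last vertex connects back to the first). Open
#' contours are rejected rather than silently closed.
#'
#' @param vertices A two-column matrix or data frame of x/y coordinates in
#'   millimetres, at least 3 rows, finite, with no two consecutive
#'   vertices identical (including the wrap-around pair).
#' @param closed Must be `TRUE`; present so that accidentally open
#'   contours fail loudly.
#' @return A tibble of class `contour` with columns `x_mm`, `y_mm`.
#' @examples
#' sq <- contour_mm(cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10)))
#' @export
contour_mm <- function(vertices, closed = TRUE) {
  if (!isTRUE(closed)) abort("open contours are not supported")
  v <- as.matrix(as.data.frame(vertices)[, 1:2])
  storage.mode(v) <- "double"
  if (nrow(v) < 3) abort("a contour needs at least 3 vertices")
  if (!all(is.finite(v))) abort("contour coordinates must be finite")
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  if (any(rowSums((v - nxt)^2) == 0)) {
    abort("contour has two identical consecutive vertices")
  }
  out <- tibble::tibble(x_mm = v[, 1], y_mm = v[, 2])
  class(out) <- c("contour", class(out))
  out
}

as_contour <- function(x) {
  if (inherits(x, "contour")) x else contour_mm(x)
}

#' Distance from a point to the nearest point of a contour
#'
#' In `"segment"` mode (the default) the contour is treated as a
#' continuous closed polyline and the minimum Euclidean distance from the
#' point to any edge is returned; in `"vertex"` mode only the sampled
#' vertices are candidates, so the result is never smaller than in
#' segment mode.
#'
#' @param p A length-2 numeric vector (x, y) in millimetres.
#' @param target A `contour` (or coercible vertex matrix).
#' @param mode `"segment"` or `"vertex"`.
#' @return The distance in millimetres.
#' @export
nearest_distance <- function(p, target, mode = c("segment", "vertex")) {
  mode <- match.arg(mode)
  target <- as_contour(target)
  min(point_contour_distances(matrix(p, nrow = 1), target, mode))
}

# vectorised: distances from each row of pts (n x 2) to the contour
point_contour_distances <- function(pts, target, mode) {
  vx <- target$x_mm
  vy <- target$y_mm
  if (mode == "vertex") {
    d2 <- outer(pts[, 1], vx, "-")^2 + outer(pts[, 2], vy, "-")^2
    return(sqrt(apply(d2, 1, min)))
  }
  ax <- vx; ay <- vy
  bx <- c(vx[-1], vx[1]); by <- c(vy[-1], vy[1])
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    tpar <- ((px - ax) * ex + (py - ay) * ey) / len2
    tpar <- pmin(pmax(tpar, 0), 1)
    dx <- px - (ax + tpar * ex)
    dy <- py - (ay + tpar * ey)
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

#' Directional contour match ratio
#'
#' Evaluates every vertex of the physician-adjusted contour against the
#' software-defined contour: a vertex is matched when its distance to the
#' nearest point of the software locus is at most `tolerance_mm`
#' (default 1 mm). The match ratio is the matched fraction of physician
#' vertices. The measure is directional: swapping the two contours
#' generally changes the result.
#'
#' @param physician The physician-adjusted `contour` (evaluated vertices).
#' @param software The software-defined `contour` (distance target).
#' @param tolerance_mm Match tolerance in millimetres; must be positive.
#' @param mode Distance mode, see [nearest_distance()].
#' @return An object of class `match_result`: a list with `distances`
#'   (per physician vertex, mm), `ratio`, `category` (see
#'   [classify_match()]), `tolerance_mm`, `n_vertices`.
#' @examples
#' a <- circle_contour(10, 90)
#' match_ratio(a, a)$ratio  # 1
#' @export
match_ratio <- function(physician, software, tolerance_mm = 1,
                        mode = c("segment", "vertex")) {
  mode <- match.arg(mode)
  if (tolerance_mm <= 0) abort("tolerance_mm must be positive")
  physician <- as_contour(physician)
  software <- as_contour(software)
  d <- point_contour_distances(cbind(physician$x_mm, physician$y_mm),
                               software, mode)
  ratio <- mean(d <= tolerance_mm)
  structure(
    list(distances = d, ratio = ratio, category = classify_match(ratio),
         tolerance_mm = tolerance_mm, n_vertices = length(d)),
    class = "match_result"
  )
}

#' Classify a match ratio
#'
#' Three ordered quality categories: `excellent` for a ratio of exactly
#' 100% (within 1e-12), `satisfactory` for a ratio of at least 70% but
#' below 100%, `poor` below 70%. Excellent and satisfactory together
#' constitute successful segmentation.
#'
#' @param ratio A match ratio in \[0, 1\].
#' @return A character scalar: `"excellent"`, `"satisfactory"` or
#'   `"poor"`.
#' @export
classify_match <- function(ratio) {
  if (is.na(ratio) || ratio < 0 || ratio > 1) {
    abort("ratio must be in [0, 1]")
  }
  if (ratio >= 1 - 1e-12) "excellent"
  else if (ratio >= 0.7) "satisfactory"
  else "poor"
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "Contour match: ratio %.3f (%s), %d vertices, tolerance %g mm\n",
    x$ratio, x$category, x$n_vertices, x$tolerance_mm))
  invisible(x)
}

#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, category = x$category,
                 n_vertices = x$n_vertices, tolerance_mm = x$tolerance_mm,
                 mean_distance_mm = mean(x$distances),
                 max_distance_mm = max(x$distances))
}

#' Cross-tabulate segmentation quality by truth class
#'
#' Builds the counts and row percentages of match categories for all
#' cases and within the benign and malignant classes, and compares the
#' successful (excellent + satisfactory) fraction between the two classes
#' with a Pearson chi-square two-proportion test (no continuity
#' correction by default).
#'
#' @param records A data frame with columns `category` (values
#'   `excellent` / `satisfactory` / `poor`) and `truth` (0 benign, 1
#'   malignant), one row per case.
#' @param correct Apply the Yates continuity correction; default `FALSE`.
#' @return An object of class `match_summary`: a list with `table` (a
#'   tibble with rows all / benign / malignant, counts and percentages
#'   per category and the successful fraction) and `test` (one-row tibble
#'   with the chi-square statistic and p comparing successful proportions
#'   between classes).
#' @export
summarize_matches <- function(records, correct = FALSE) {
  records <- tibble::as_tibble(records)
  if (!all(c("category", "truth") %in% names(records))) {
    abort("records needs columns category and truth")
  }
  if (nrow(records) == 0) abort("records is empty")
  cats <- c("excellent", "satisfactory", "poor")
  bad <- setdiff(unique(records$category), cats)
  if (length(bad) > 0) {
    abort(paste0("unknown category label(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(records$truth %in% c(0, 1))) {
    abort("truth must be coded 0 (benign) or 1 (malignant)")
  }
  row_for <- function(sub, label) {
    n <- nrow(sub)
    counts <- unname(vapply(cats, function(cc) sum(sub$category == cc),
                            integer(1)))
    tibble::tibble(
      subset = label, n = n,
      excellent = counts[1], satisfactory = counts[2], poor = counts[3],
      pct_excellent = 100 * counts[1] / n,
      pct_satisfactory = 100 * counts[2] / n,
      pct_poor = 100 * counts[3] / n,
      successful = counts[1] + counts[2],
      pct_successful = 100 * (counts[1] + counts[2]) / n
    )
  }
  tab <- dplyr::bind_rows(
    row_for(records, "all"),
    row_for(records[records$truth == 0, ], "benign"),
    row_for(records[records$truth == 1, ], "malignant")
  )
  ben <- tab[tab$subset == "benign", ]
  mal <- tab[tab$subset == "malignant", ]
  test <- if (ben$n > 0 && mal$n > 0) {
    if (ben$successful / ben$n == mal$successful / mal$n) {
      # equal proportions (including the all-successful degenerate case,
      # where the chi-square statistic is 0/0): no evidence of a difference
      tibble::tibble(method = "two-proportion chi-square",
                     statistic = 0, p = 1, correct = correct)
    } else {
      pt <- suppressWarnings(
        prop.test(c(ben$successful, mal$successful), c(ben$n, mal$n),
                  correct = correct)
      )
      tibble::tibble(method = "two-proportion chi-square",
                     statistic = unname(pt$statistic), p = pt$p.value,
                     correct = correct)
    }
  } else {
    tibble::tibble(method = "two-proportion chi-square",
                   statistic = NA_real_, p = NA_real_, correct = correct)
  }
  structure(list(table = tab, test = test), class = "match_summary")
}

#' @export
print.match_summary <- function(x, ...) {
  cat("Segmentation quality cross-tabulation\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat(sprintf("Successful fraction, benign vs malignant: p = %.4g (%s)\n",
              x$test$p, x$test$method))
  invisible(x)
}

#' @method tidy match_summary
#' @export
tidy.match_summary <- function(x, ...) x$table

#' @method glance match_summary
#' @export
glance.match_summary <- function(x, ...) x$test

#' Read contour pairs from long CSV
#'
#' Expects columns `case_id`, `role` (`software` or `physician`),
#' `vertex_index`, `x_mm`, `y_mm`, and optionally `truth`.
#'
#' @param path CSV file path.
#' @return A tibble with one row per case: `case_id`, `truth` (`NA` when
#'   absent), and list-columns `physician`, `software` holding `contour`
#'   objects.
#' @export
read_contours <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    case_id = readr::col_character(),
    role = readr::col_character(),
    vertex_index = readr::col_integer(),
    x_mm = readr::col_double(),
    y_mm = readr::col_double(),
    .default = readr::col_double()
  ))
  if (!all(df$role %in% c("software", "physician"))) {
    abort("role must be 'software' or 'physician'")
  }
  df |>
    dplyr::arrange(.data$case_id, .data$role, .data$vertex_index) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::group_modify(function(g, key) {
      tibble::tibble(
        truth = if ("truth" %in% names(g)) g$truth[1] else NA_real_,
        physician = list(contour_mm(
          g[g$role == "physician", c("x_mm", "y_mm")])),
        software = list(contour_mm(
          g[g$role == "software", c("x_mm", "y_mm")]))
      )
    }) |>
    dplyr::ungroup()
}

#' Write contour pairs to long CSV
#'
#' @param pairs A tibble as returned by [read_contours()] or
#'   [simulate_contour_pairs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(pairs, path) {
  rows <- purrr::pmap_dfr(
    pairs[, c("case_id", "truth", "physician", "software")],
    function(case_id, truth, physician, software) {
      dplyr::bind_rows(
        tibble::tibble(case_id = case_id, role = "physician",
                       vertex_index = seq_len(nrow(physician)),
                       x_mm = physician$x_mm, y_mm = physician$y_mm,
                       truth = truth),
        tibble::tibble(case_id = case_id, role = "software",
                       vertex_index = seq_len(nrow(software)),
                       x_mm = software$x_mm, y_mm = software$y_mm,
                       truth = truth)
      )
    }
  )
  readr::write_csv(rows, path)
  invisible(path)
}
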