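# Independent brute-force oracles used across the suite. These stay
# deliberately naive: direct enumeration, never the package's own path.

# Mann-Whitney by full pair enumeration, ties counting one half
brute_auc <- function(benign, malignant) {
  s <- 0
  for (x in benign) for (y in malignant) {
    s <- s + (y > x) + 0.5 * (y == x)
  }
  s / (length(benign) * length(malignant))
}

# jackknife pseudovalues by literal leave-one-out recomputation
brute_pseudovalues <- function(benign, malignant, metric = brute_auc) {
  nb <- length(benign)
  nm <- length(malignant)
  cc <- nb + nm
  th <- metric(benign, malignant)
  loo <- numeric(cc)
  for (k in seq_len(nb)) loo[k] <- metric(benign[-k], malignant)
  for (k in seq_len(nm)) loo[nb + k] <- metric(benign, malignant[-k])
  cc * th - (cc - 1) * loo
}

# distance from a point to a closed polyline by dense sampling of edges
brute_point_contour_dist <- function(p, vertices, n_per_edge = 20000) {
  v <- rbind(vertices, vertices[1, ])
  best <- Inf
  for (e in seq_len(nrow(vertices))) {
    tt <- seq(0, 1, length.out = n_per_edge)
    px <- v[e, 1] + tt * (v[e + 1, 1] - v[e, 1])
    py <- v[e, 2] + tt * (v[e + 1, 2] - v[e, 2])
    best <- min(best, sqrt(min((p[1] - px)^2 + (p[2] - py)^2)))
  }
  best
}

# small fully crossed rating table from a score array [t, r, c]
toy_ratings <- function(scores, truth,
                        modalities = paste0("mod", seq_len(dim(scores)[1]))) {
  d <- dim(scores)
  tibble::tibble(
    reader_id = rep(rep(sprintf("r%02d", seq_len(d[2])), each = d[1]),
                    times = d[3]),
    case_id = rep(sprintf("c%02d", seq_len(d[3])), each = d[1] * d[2]),
    modality = factor(rep(modalities, times = d[2] * d[3]),
                      levels = modalities),
    score = as.vector(scores),
    truth = rep(truth, each = d[1] * d[2])
  )
}

# random small study: scores integer 0..100, >= 2 cases per class
random_toy_ratings <- function(t_ = 2, r_ = 2, c0 = 3, c1 = 3) {
  cc <- c0 + c1
  scores <- array(sample(0:100, t_ * r_ * cc, replace = TRUE),
                  c(t_, r_, cc))
  toy_ratings(scores, c(rep(0, c0), rep(1, c1)))
}
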