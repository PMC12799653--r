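# Reference implementations used as ground truth: the brute-force (linear)
# k-nearest-neighbour search, and a Monte-Carlo containment estimator that
# arbitrates the geometry kernel.

#' Brute-force k-nearest-neighbour search
#'
#' The exact linear-scan baseline: for each query, compute all `n` distances
#' with the package's shared kernel, sort ascending with ties broken by lower
#' training row index, and keep the first `k`. Deliberately simple and fully
#' vectorised per query; used as the ground truth in every equivalence test.
#'
#' @param training Numeric training matrix (`n x p`).
#' @param queries Numeric query matrix (`m x p`).
#' @param k Number of neighbours, `1 <= k <= n`.
#' @return An `"stnn_knn"` object with `iterations` fixed at 1 and
#'   `k_prime = n` for every query.
#' @export
brute_force_knn <- function(training, queries, k) {
  x <- check_matrix(training, "training")
  q <- check_matrix(queries, "queries")
  if (ncol(q) != ncol(x)) {
    stop("`queries` dimension does not match `training`", call. = FALSE)
  }
  n <- nrow(x)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  if (k > n) stop("`k` cannot exceed the training-set size", call. = FALSE)
  k <- as.integer(k)
  m <- nrow(q)
  out_idx <- matrix(NA_integer_, m, k)
  out_dist <- matrix(NA_real_, m, k)
  all_idx <- seq_len(n)
  for (i in seq_len(m)) {
    d <- row_distances(x, q[i, ])
    sel <- top_k_select(all_idx, d, k)
    out_idx[i, ] <- sel$idx
    out_dist[i, ] <- sel$dist
  }
  new_stnn_knn(out_idx, out_dist, rep(n, m), rep(1L, m), k, "brute_force")
}

#' Monte-Carlo estimate of the containment probability
#'
#' Samples points uniformly in the radius-`r` ball (direction times
#' `U^{1/p}`-scaled radius, exact in any dimension) and reports the fraction
#' within `r_i` of a point at distance `d` from the centre, with its binomial
#' standard error. Independent of the closed-form geometry path; this is the
#' validation oracle for [containment_probability()].
#'
#' @inheritParams containment_probability
#' @param n_samples Number of Monte-Carlo draws (at least 1000).
#' @param seed Optional integer seed; the estimate is deterministic given it.
#' @return A list with `estimate` and `se`.
#' @export
mc_containment_estimate <- function(p, r, r_i, d, n_samples = 1e5,
                                    seed = NULL) {
  p <- check_dimension(p)
  if (n_samples < 1000) stop("`n_samples` must be at least 1000", call. = FALSE)
  with_preserved_seed(seed, {
    hits <- 0
    left <- as.integer(n_samples)
    block <- as.integer(min(left, max(1000L, floor(2e7 / p))))
    ri2 <- r_i^2
    while (left > 0L) {
      b <- min(block, left)
      z <- matrix(stats::rnorm(b * p), b, p)
      u <- stats::runif(b)^(1 / p)
      scale <- r * u / sqrt(rowSums(z^2))
      # query centre at (d, 0, ..., 0)
      d2 <- (z[, 1] * scale - d)^2
      if (p > 1) d2 <- d2 + rowSums((z[, -1, drop = FALSE] * scale)^2)
      hits <- hits + sum(d2 <= ri2)
      left <- left - b
    }
    est <- hits / n_samples
    list(estimate = est, se = sqrt(est * (1 - est) / n_samples))
  })
}
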