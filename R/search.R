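# The search itself: escalating-tau sweep of fixed-radius KD-tree queries,
# returning exact k-nearest neighbours identical to brute force.

#' Select the k nearest candidates
#'
#' Stable selection of the `k` smallest candidates by `(distance, training
#' index)`; ties in distance are broken by the lower training row index. The
#' same rule is applied by the brute-force reference, which is what makes the
#' exact-agreement property (same indices, same order) testable.
#'
#' @param idx Candidate training row indices (1-based).
#' @param dist Their distances.
#' @param k Number of neighbours to keep, `k <= length(idx)`.
#' @return A list with ordered `idx` and `dist` of length `k`.
#' @export
top_k_select <- function(idx, dist, k) {
  if (length(idx) < k) {
    stop("contract violation: fewer candidates than k", call. = FALSE)
  }
  ord <- order(dist, idx)[seq_len(k)]
  list(idx = idx[ord], dist = dist[ord])
}

new_stnn_knn <- function(indices, distances, k_prime, iterations, k, method,
                         ...) {
  structure(list(indices = indices, distances = distances, k_prime = k_prime,
                 iterations = iterations, k = k, method = method, ...),
            class = "stnn_knn")
}

#' Stochastic fixed-radius k-nearest-neighbour search
#'
#' For each query: assign its ring group, then sweep the threshold schedule.
#' At threshold `tau` the query sphere radius solving `P(S_i) = tau` (shared
#' across the ring, solved at the ring's outer boundary) is submitted as a
#' fixed-radius KD-tree query; if fewer than `k` candidates are captured the
#' next threshold is tried. The final threshold is 1, whose radius `d + r`
#' covers the whole training sphere by the triangle inequality, so the sweep
#' always terminates with at least `k` candidates. Candidates are re-scored
#' with the shared distance kernel and the `k` nearest kept, so the result is
#' identical — same indices, same order — to [brute_force_knn()].
#'
#' Queries outside the bounding sphere (group `G + 1`) solve the radius
#' equation at their own centroid distance. A degenerate training set with
#' bounding radius 0 (all rows identical) bypasses the geometry and returns
#' the first `k` rows.
#'
#' @param index An [stnn_index()], or a training matrix (indexed on the fly).
#' @param queries Numeric matrix of query points, `p` columns.
#' @param k Number of neighbours, `1 <= k <= n`.
#' @param G Number of ring groups (default 1, the fastest setting; `G` has no
#'   effect on the result, only on how many radius equations are shared).
#' @param t Length of the default threshold schedule.
#' @param schedule Optional explicit threshold schedule (ascending, ending at
#'   1); overrides `t`.
#' @return An object of class `"stnn_knn"`: `indices` and `distances` are
#'   `m x k` matrices ordered by ascending `(distance, index)`; `k_prime` is
#'   the candidate count at termination; `iterations` the number of thresholds
#'   tried per query; `n_equations` the number of shared group equations
#'   solved (at most `G * t`); `n_query_equations` the per-query solves for
#'   group `G + 1`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' q <- matrix(rnorm(10), 5, 2)
#' res <- stnn_search(stnn_index(x), q, k = 3)
#' identical(res$indices, brute_force_knn(x, q, k = 3)$indices)
#' @export
stnn_search <- function(index, queries, k, G = 1L, t = 10L, schedule = NULL) {
  if (!inherits(index, "stnn_index")) index <- stnn_index(index)
  q <- check_matrix(queries, "queries")
  if (ncol(q) != index$p) {
    stop("`queries` dimension does not match the training index", call. = FALSE)
  }
  n <- index$n
  p <- index$p
  r <- index$bounding_radius
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  if (k > n) stop("`k` cannot exceed the training-set size", call. = FALSE)
  k <- as.integer(k)
  m <- nrow(q)
  if (is.null(schedule)) schedule <- tau_schedule(k, n, t)
  schedule <- check_schedule(schedule)
  t_len <- length(schedule)

  out_idx <- matrix(NA_integer_, m, k)
  out_dist <- matrix(NA_real_, m, k)
  k_prime <- integer(m)
  iters <- integer(m)

  if (r == 0) {
    # all training rows coincide: every row is equidistant from any query
    for (i in seq_len(m)) {
      d <- row_distances(index$data, q[i, ], idx = seq_len(k))
      out_idx[i, ] <- seq_len(k)
      out_dist[i, ] <- d
      k_prime[i] <- n
      iters[i] <- 1L
    }
    return(new_stnn_knn(out_idx, out_dist, k_prime, iters, k, "stnnfr",
                        G = as.integer(G), schedule = schedule,
                        n_equations = 0L, n_query_equations = 0L))
  }

  G <- as.integer(G)
  boundaries <- ring_radii(r, p, G)
  asg <- assign_groups(index, q, boundaries)
  radius_cache <- matrix(NA_real_, G, t_len)
  n_eq <- 0L
  n_query_eq <- 0L

  for (i in seq_len(m)) {
    qi <- q[i, ]
    g <- asg$group_id[i]
    dq <- asg$centroid_distance[i]
    cand <- NULL
    it <- 0L
    for (s in seq_len(t_len)) {
      it <- s
      tau <- schedule[s]
      if (g <= G) {
        if (is.na(radius_cache[g, s])) {
          radius_cache[g, s] <- solve_radius(p, r, boundaries[g], tau)
          n_eq <- n_eq + 1L
        }
        rad <- radius_cache[g, s]
      } else if (tau >= 1) {
        rad <- dq + r
      } else {
        rad <- solve_radius(p, r, dq, tau)
        n_query_eq <- n_query_eq + 1L
      }
      # tiny inflation at the covering radius guards the triangle-inequality
      # bound against floating-point rounding
      if (s == t_len) rad <- rad * (1 + 1e-9)
      fr <- fixed_radius_candidates(index, qi, rad)
      if (length(fr$idx) >= k) {
        cand <- fr
        break
      }
    }
    if (is.null(cand)) {
      stop(sprintf(
        "internal error: threshold sweep exhausted with fewer than k candidates (query %d)",
        i), call. = FALSE)
    }
    sel <- top_k_select(cand$idx, cand$dist, k)
    out_idx[i, ] <- sel$idx
    out_dist[i, ] <- sel$dist
    k_prime[i] <- length(cand$idx)
    iters[i] <- it
  }

  new_stnn_knn(out_idx, out_dist, k_prime, iters, k, "stnnfr", G = G,
               schedule = schedule, n_equations = n_eq,
               n_query_equations = n_query_eq)
}

#' @export
print.stnn_knn <- function(x, ...) {
  cat(sprintf("%s k-nearest-neighbour result: %d queries, k = %d\n",
              x$method, nrow(x$indices), x$k))
  cat(sprintf("  mean iterations = %.3f, mean candidates k' = %.1f\n",
              mean(x$iterations), mean(x$k_prime)))
  invisible(x)
}

#' Tidy a neighbour result
#'
#' @param x An `"stnn_knn"` result.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with `query_id`, `rank`, `train_index` (1-based), and
#'   `distance`, one row per (query, rank).
#' @export
as.data.frame.stnn_knn <- function(x, row.names = NULL, optional = FALSE, ...) {
  m <- nrow(x$indices)
  data.frame(query_id = rep(seq_len(m), each = x$k),
             rank = rep(seq_len(x$k), times = m),
             train_index = as.integer(t(x$indices)),
             distance = as.numeric(t(x$distances)))
}
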