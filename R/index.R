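# Training-set index: centroid, centroid distances, bounding radius, KD-tree.

check_matrix <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop(sprintf("`%s` must be a numeric matrix", name),
                          call. = FALSE)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", name),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite values", name),
         call. = FALSE)
  }
  x
}

# Shared Euclidean distance kernel (C++, fixed accumulation order). `idx`
# selects training rows (1-based); NULL means all rows.
row_distances <- function(x, q, idx = NULL) {
  if (is.null(idx)) {
    row_dists_cpp(x, q)
  } else {
    row_dists_idx_cpp(x, q, as.integer(idx) - 1L)
  }
}

#' Build a training-set index for stochastic fixed-radius search
#'
#' Computes the training centroid \eqn{\bar{x}}, the Euclidean distances of
#' every training row to it, the bounding radius `r` (their maximum, so the
#' hypersphere `S` of radius `r` around the centroid contains every training
#' point by construction), and a KD-tree over the rows supporting fixed-radius
#' queries. The tree is built once and reused across queries.
#'
#' @param training Numeric matrix, one observation per row, no missing values.
#' @param leaf_size KD-tree leaf size (number of points per leaf bucket).
#' @return An object of class `"stnn_index"`: a list with `data`, `n`, `p`,
#'   `centroid`, `centroid_distances`, `bounding_radius`, and the opaque `tree`.
#' @examples
#' idx <- stnn_index(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
#' idx$centroid        # (1, 1)
#' idx$bounding_radius # sqrt(2)
#' @export
stnn_index <- function(training, leaf_size = 16L) {
  x <- check_matrix(training, "training")
  centroid <- colMeans(x)
  cd <- row_distances(x, centroid)
  structure(list(data = x, n = nrow(x), p = ncol(x), centroid = centroid,
                 centroid_distances = cd, bounding_radius = max(cd),
                 tree = kd_build_cpp(x, as.integer(leaf_size))),
            class = "stnn_index")
}

#' @export
print.stnn_index <- function(x, ...) {
  cat(sprintf("Training index: n = %d, p = %d, bounding radius r = %g\n",
              x$n, x$p, x$bounding_radius))
  invisible(x)
}

#' Fixed-radius candidate retrieval
#'
#' All training rows within Euclidean distance `radius` of `query_point`,
#' retrieved through the KD-tree and re-scored with the package's shared
#' distance kernel, so membership is exactly the linear-scan filter
#' `distance <= radius`.
#'
#' @param index An [stnn_index()].
#' @param query_point Length-`p` numeric vector.
#' @param radius Search radius, strictly positive.
#' @return A list with `idx` (1-based training row indices, ascending) and
#'   `dist` (their distances, in the same order).
#' @export
fixed_radius_candidates <- function(index, query_point, radius) {
  stopifnot(inherits(index, "stnn_index"))
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  q <- as.numeric(query_point)
  if (length(q) != index$p) {
    stop("`query_point` has the wrong dimension", call. = FALSE)
  }
  # tree query slightly inflated; the kernel re-filter is authoritative
  cand0 <- kd_query_cpp(index$tree, index$data, q, radius * (1 + 1e-9))
  d <- row_dists_idx_cpp(index$data, q, cand0)
  keep <- d <= radius
  list(idx = cand0[keep] + 1L, dist = d[keep])
}
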