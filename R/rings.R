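# Ring groups and the escalating threshold schedule. Queries are grouped by
# their distance to the training centroid into G concentric rings of equal
# probability mass (under the spherical uniform assumption); each ring shares
# one solved radius per threshold, so at most G x t radius equations are
# solved per run.

#' Ring boundary radii
#'
#' Boundaries \eqn{\delta_g = r (g/G)^{1/p}}, `g = 1..G`, chosen so each
#' sub-sphere of radius \eqn{\delta_g} holds probability mass `g/G` under the
#' spherical uniform assumption. The last boundary is exactly `r`.
#'
#' @param r Bounding radius of the training sphere, positive.
#' @param p Dimension.
#' @param G Number of ring groups, a positive integer.
#' @return Strictly ascending numeric vector of length `G` ending at `r`.
#' @examples
#' ring_radii(1, 2, 3) # sqrt(1/3), sqrt(2/3), 1
#' @export
ring_radii <- function(r, p, G) {
  p <- check_dimension(p)
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G < 1 ||
      G != round(G)) {
    stop("`G` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be strictly positive", call. = FALSE)
  }
  G <- as.integer(G)
  delta <- r * (seq_len(G) / G)^(1 / p)
  delta[G] <- r
  delta
}

#' Assign query points to ring groups
#'
#' Each query falls in the ring whose boundaries bracket its centroid distance,
#' with boundaries closed on the right (`d = delta_g` maps to group `g`, and
#' `d = 0` to group 1). Queries beyond the bounding radius get group `G + 1`.
#'
#' @param index An [stnn_index()].
#' @param queries Numeric matrix of query points, `p` columns.
#' @param boundaries Ring boundaries from [ring_radii()].
#' @return A data frame with `centroid_distance` and `group_id` per query.
#' @export
assign_groups <- function(index, queries, boundaries) {
  stopifnot(inherits(index, "stnn_index"))
  q <- check_matrix(queries, "queries")
  if (ncol(q) != index$p) {
    stop("`queries` dimension does not match the index", call. = FALSE)
  }
  dq <- row_distances(q, index$centroid)
  grp <- findInterval(dq, boundaries, left.open = TRUE) + 1L
  data.frame(centroid_distance = dq, group_id = grp)
}

#' Evenly spaced threshold schedule
#'
#' The escalating thresholds \eqn{T = (\tau^{(1)}, ..., \tau^{(t)})}: `t`
#' evenly spaced values from `k/n` (the expected neighbour fraction) to 1
#' inclusive. The final value is exactly 1, which forces a covering radius and
#' guarantees termination. `k = n` degenerates to the single value 1.
#'
#' @param k Number of neighbours sought.
#' @param n Training-set size.
#' @param t Schedule length.
#' @return Strictly ascending numeric vector ending at 1.
#' @examples
#' tau_schedule(10, 100, 10) # 0.1, 0.2, ..., 1
#' @export
tau_schedule <- function(k, n, t = 10L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != round(t)) {
    stop("`t` must be a single positive integer", call. = FALSE)
  }
  if (k == n) return(1)
  v <- seq(k / n, 1, length.out = as.integer(t))
  v[length(v)] <- 1
  v
}

check_schedule <- function(schedule) {
  if (!is.numeric(schedule) || length(schedule) < 1L ||
      any(!is.finite(schedule)) || any(schedule <= 0) ||
      schedule[length(schedule)] != 1 ||
      (length(schedule) > 1L && any(diff(schedule) <= 0))) {
    stop("`schedule` must be strictly ascending, in (0, 1], and end at exactly 1",
         call. = FALSE)
  }
  schedule
}

#' Shared search radius for a ring group
#'
#' Solves the radius equation at the ring's outer boundary
#' (`d = delta_g`), which is conservative for every query in the ring because
#' the containment probability is non-increasing in the centroid distance.
#'
#' @param index An [stnn_index()].
#' @param boundaries Ring boundaries from [ring_radii()].
#' @param g Group id in `1..G`. Group `G + 1` (queries outside the bounding
#'   sphere) has no shared radius; its equation is solved per query at the
#'   query's own centroid distance.
#' @param tau Target probability mass in `(0, 1]`.
#' @return The solved group radius.
#' @export
group_radius <- function(index, boundaries, g, tau) {
  stopifnot(inherits(index, "stnn_index"))
  G <- length(boundaries)
  if (!is.numeric(g) || length(g) != 1L || g < 1 || g > G || g != round(g)) {
    stop("`g` must be a group id in 1..G; group G + 1 is solved per query",
         call. = FALSE)
  }
  solve_radius(index$p, index$bounding_radius, boundaries[g], tau)
}
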