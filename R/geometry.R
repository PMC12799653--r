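# Hypersphere geometry on the log scale: ball volumes, hyperspherical caps,
# two-sphere intersections, containment probabilities, and the radius solving
# P(S_i) = tau. Everything funnels through log-gamma and the regularized
# incomplete beta function so that dimensions in the hundreds stay finite.

check_dimension <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1 ||
      p != round(p)) {
    stop("`p` must be a single positive integer dimension", call. = FALSE)
  }
  as.integer(p)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single finite non-negative number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

log_ball_volume <- function(p, radius) {
  if (radius <= 0) return(-Inf)
  (p / 2) * log(pi) + p * log(radius) - lgamma(p / 2 + 1)
}

#' Volume of a p-dimensional ball
#'
#' Lebesgue volume \eqn{\pi^{p/2} \rho^p / \Gamma(p/2 + 1)} of the ball of
#' radius \eqn{\rho} in \eqn{R^p}, evaluated in log space so that dimensions of
#' several hundred do not overflow double precision.
#'
#' @param p Dimension, a positive integer.
#' @param radius Ball radius, a non-negative number.
#' @return The volume, a non-negative number; zero iff `radius` is zero.
#' @examples
#' ball_volume(2, 1) # pi
#' ball_volume(3, 1) # 4 * pi / 3
#' @export
ball_volume <- function(p, radius) {
  p <- check_dimension(p)
  radius <- check_nonneg(radius, "radius")
  if (radius == 0) return(0)
  exp(log_ball_volume(p, radius))
}

# log of Vcap(r', a) / V_p(r'), the cap fraction of its own ball.
# a >= 0 cuts off the minority side: fraction = I_{1 - a^2/r'^2}((p+1)/2, 1/2)/2.
log_cap_fraction <- function(p, r_prime, a) {
  x <- 1 - (a / r_prime)^2
  x <- min(max(x, 0), 1)
  if (a >= 0) {
    log(0.5) + stats::pbeta(x, (p + 1) / 2, 0.5, log.p = TRUE)
  } else {
    log1p(-0.5 * stats::pbeta(x, (p + 1) / 2, 0.5))
  }
}

#' Volume of a hyperspherical cap
#'
#' Volume of the cap cut from a p-ball of radius `r_prime` by a hyperplane at
#' signed offset `a` from its centre. For `a >= 0` the cap is the minority side
#' and its volume is
#' \deqn{\frac{\pi^{p/2}}{2}\frac{r'^p}{\Gamma(p/2+1)}
#'       I_{1 - a^2/r'^2}\!\left(\frac{p+1}{2}, \frac{1}{2}\right),}
#' with \eqn{I} the regularized incomplete beta function; for `a < 0` it is the
#' complement of the cap at `-a`.
#'
#' @param p Dimension.
#' @param r_prime Sphere radius, strictly positive.
#' @param a Signed offset of the cutting hyperplane, with `abs(a) <= r_prime`.
#' @return Cap volume in `[0, ball_volume(p, r_prime)]`.
#' @examples
#' cap_volume(2, 1, 0) # half disc, pi / 2
#' cap_volume(3, 1, 1) # tangent plane, 0
#' @export
cap_volume <- function(p, r_prime, a) {
  p <- check_dimension(p)
  if (!is.numeric(r_prime) || length(r_prime) != 1L || !is.finite(r_prime) ||
      r_prime <= 0) {
    stop("`r_prime` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) ||
      abs(a) > r_prime) {
    stop("`a` must satisfy abs(a) <= r_prime", call. = FALSE)
  }
  exp(log_ball_volume(p, r_prime) + log_cap_fraction(p, r_prime, a))
}

# Relative guard below which a centre separation is treated as exactly zero;
# the cap offsets c1, c2 divide by d.
.d_zero_guard <- 1e-12

#' Intersection volume of two hyperspheres
#'
#' Volume of the intersection of the sphere of radius `r` (the training bound)
#' and the sphere of radius `r_i` (the query sphere) whose centres are `d`
#' apart, via the piecewise rule: disjoint when `d >= r_i + r`; full containment
#' of the smaller ball when `d <= abs(r_i - r)`; otherwise the sum of two caps
#' \eqn{V^{cap}_p(r, c_1) + V^{cap}_p(r_i, c_2)} with
#' \eqn{c_1 = (d^2 + r^2 - r_i^2)/(2d)} and \eqn{c_2 = (d^2 - r^2 + r_i^2)/(2d)}.
#'
#' @param p Dimension.
#' @param r Radius of the first (training) sphere.
#' @param r_i Radius of the second (query) sphere.
#' @param d Distance between the centres.
#' @return An object of class `"sphere_intersection"`: a list with elements
#'   `p`, `r`, `r_i`, `d`, `c1`, `c2` (`NA` in the disjoint and containment
#'   cases, where they are never evaluated), `volume`, and `probability`
#'   (`volume / ball_volume(p, r)` when `r > 0`, computed in log space).
#' @examples
#' intersection_volume(5, 1, 0.3, 2)$volume   # disjoint: 0
#' intersection_volume(4, 1, 0.2, 0.1)$volume # small ball inside: ball_volume(4, 0.2)
#' @export
intersection_volume <- function(p, r, r_i, d) {
  p <- check_dimension(p)
  r <- check_nonneg(r, "r")
  r_i <- check_nonneg(r_i, "r_i")
  d <- check_nonneg(d, "d")
  if (d < .d_zero_guard * max(r, r_i)) d <- 0
  c1 <- c2 <- NA_real_
  if (d >= r_i + r) {
    vol <- 0
  } else if (d <= abs(r_i - r)) {
    vol <- ball_volume(p, min(r_i, r))
  } else {
    c1 <- (d^2 + r^2 - r_i^2) / (2 * d)
    c2 <- (d^2 - r^2 + r_i^2) / (2 * d)
    vol <- cap_volume(p, r, c1) + cap_volume(p, r_i, c2)
  }
  prob <- if (r > 0) containment_probability(p, r, r_i, d) else NA_real_
  structure(list(p = p, r = r, r_i = r_i, d = d, c1 = c1, c2 = c2,
                 volume = vol, probability = prob),
            class = "sphere_intersection")
}

#' @export
print.sphere_intersection <- function(x, ...) {
  cat(sprintf(
    "Hypersphere intersection (p = %d): r = %g, r_i = %g, d = %g\n", x$p, x$r,
    x$r_i, x$d))
  cat(sprintf("  volume = %g, containment probability = %g\n", x$volume,
              x$probability))
  invisible(x)
}

#' Containment probability of the query sphere
#'
#' Probability mass of the training sphere `S` (radius `r`) captured by a query
#' sphere of radius `r_i` centred `d` away, under the spherical uniform
#' assumption: `P = volume(S_i ∩ S) / volume(S)`. Computed as a ratio of cap
#' fractions in log space so that `p` in the hundreds neither overflows nor
#' underflows prematurely.
#'
#' @inheritParams intersection_volume
#' @return A probability in `[0, 1]`.
#' @examples
#' containment_probability(2, 1, 0.5, 0) # (0.5)^2 = 0.25
#' @export
containment_probability <- function(p, r, r_i, d) {
  p <- check_dimension(p)
  r_i <- check_nonneg(r_i, "r_i")
  d <- check_nonneg(d, "d")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be strictly positive (degenerate training spheres are handled upstream)",
         call. = FALSE)
  }
  if (d < .d_zero_guard * max(r, r_i)) d <- 0
  if (d >= r_i + r) return(0)
  if (d <= abs(r_i - r)) {
    if (r_i >= r) return(1)
    return(exp(p * (log(r_i) - log(r))))
  }
  c1 <- (d^2 + r^2 - r_i^2) / (2 * d)
  c2 <- (d^2 - r^2 + r_i^2) / (2 * d)
  term1 <- exp(log_cap_fraction(p, r, c1))
  term2 <- exp(p * (log(r_i) - log(r)) + log_cap_fraction(p, r_i, c2))
  min(max(term1 + term2, 0), 1)
}

#' Solve for the query radius achieving a target containment probability
#'
#' Finds the radius `r_i` of the query sphere such that the containment
#' probability equals `tau`, i.e. the root of
#' \eqn{f(r_i \mid r, p, d, \tau) = P(S_i) - \tau = 0}. `P` is continuous and
#' non-decreasing in `r_i` with `P(0) = 0` and `P(d + r) = 1`, so the root is
#' bracketed on `[0, d + r]`; Brent's method is used, with a bisection fallback
#' polishing to the requested probability tolerance. `tau = 1` short-circuits
#' to `d + r`, the minimal radius covering the whole training sphere.
#'
#' @inheritParams containment_probability
#' @param tau Target probability mass in `(0, 1]`.
#' @param tol Absolute tolerance on the probability scale.
#' @return The solved radius, in `(0, d + r]`.
#' @examples
#' solve_radius(2, 1, 0, 0.1) # sqrt(0.1), the d = 0 closed form r * tau^(1/p)
#' @export
solve_radius <- function(p, r, d, tau, tol = 1e-10) {
  p <- check_dimension(p)
  d <- check_nonneg(d, "d")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0 ||
      tau > 1) {
    stop("`tau` must lie in (0, 1]", call. = FALSE)
  }
  if (tau == 1) return(d + r)
  hi <- d + r
  f <- function(x) containment_probability(p, r, x, d) - tau
  root <- tryCatch(
    stats::uniroot(f, lower = 0, upper = hi, tol = max(1e-14 * hi, 1e-300),
                   maxiter = 2000L)$root,
    error = function(e) NA_real_)
  if (!is.na(root) && abs(f(root)) <= tol) return(root)
  # Bisection fallback: guaranteed by monotonicity. In very high dimension P
  # can jump through tau within one representable step of r_i, in which case
  # the interval collapses to machine precision instead.
  lo <- 0
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
    if (hi - lo <= .Machine$double.eps * hi) break
  }
  (lo + hi) / 2
}
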