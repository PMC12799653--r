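# Seeded synthetic-data generators matching the simulation conditions under
# which the search is studied: spherical uniform (radius 1), multivariate
# standard normal, and multivariate t with 10 degrees of freedom and identity
# scale matrix.

#' Sample uniformly from a p-ball
#'
#' Rows i.i.d. uniform on the ball of the given radius: an isotropic Gaussian
#' direction scaled by `radius * U^{1/p}`, which is exact in any dimension
#' (the radial CDF of the uniform ball is `(s/radius)^p`).
#'
#' @param n Number of rows.
#' @param p Dimension.
#' @param radius Ball radius (default 1).
#' @param seed Optional integer seed.
#' @return An `n x p` numeric matrix.
#' @export
sample_spherical_uniform <- function(n, p, radius = 1, seed = NULL) {
  p <- check_dimension(p)
  with_preserved_seed(seed, {
    z <- matrix(stats::rnorm(n * p), n, p)
    u <- stats::runif(n)^(1 / p)
    z * (radius * u / sqrt(rowSums(z^2)))
  })
}

#' Sample a multivariate standard normal matrix
#'
#' @inheritParams sample_spherical_uniform
#' @return An `n x p` matrix of i.i.d. standard normal entries.
#' @export
sample_mv_normal <- function(n, p, seed = NULL) {
  p <- check_dimension(p)
  with_preserved_seed(seed, matrix(stats::rnorm(n * p), n, p))
}

#' Sample a multivariate t matrix with identity scale
#'
#' Rows i.i.d. multivariate t: a standard normal vector divided by
#' `sqrt(chi^2_df / df)`. The scale matrix is the identity, so for `df > 2`
#' the covariance is `df / (df - 2)` times the identity. Heavier tails than
#' the normal place more mass toward the outer shell of the bounding sphere.
#'
#' @inheritParams sample_spherical_uniform
#' @param df Degrees of freedom, positive (default 10).
#' @return An `n x p` numeric matrix.
#' @export
sample_mv_t <- function(n, p, df = 10, seed = NULL) {
  p <- check_dimension(p)
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0) {
    stop("`df` must be a single positive number", call. = FALSE)
  }
  with_preserved_seed(seed, {
    z <- matrix(stats::rnorm(n * p), n, p)
    z / sqrt(stats::rchisq(n, df) / df)
  })
}

# k_spec < 1 is a fraction of n (round half up); k_spec >= 1 is absolute.
resolve_k <- function(k_spec, n) {
  if (!is.numeric(k_spec) || length(k_spec) != 1L || !is.finite(k_spec) ||
      k_spec <= 0) {
    stop("`k_spec` must be a single positive number", call. = FALSE)
  }
  k <- if (k_spec < 1) max(1L, as.integer(floor(k_spec * n + 0.5)))
       else as.integer(floor(k_spec + 0.5))
  if (k > n) stop("resolved k exceeds n", call. = FALSE)
  k
}

#' Generate a complete simulation scenario
#'
#' Draws training and query matrices from one of the three study
#' distributions (both sets from the same distribution), resolves `k` from an
#' absolute count or a fraction of `n`, and builds the default threshold
#' schedule.
#'
#' @param distribution One of `"spherical_uniform"`, `"mv_normal"`, `"mv_t"`.
#' @param n Training-set size.
#' @param m Query-set size, `m <= n`.
#' @param p Dimension.
#' @param k_spec Absolute `k` (values `>= 1`) or fraction of `n` (values
#'   `< 1`, rounded half up).
#' @param t Threshold-schedule length (default 10).
#' @param radius Ball radius for the spherical uniform (default 1).
#' @param df Degrees of freedom for the multivariate t (default 10).
#' @param seed Optional integer seed; the same seed reproduces the scenario
#'   exactly.
#' @return A list with `training`, `query`, `k`, and `schedule`.
#' @examples
#' sc <- make_scenario("spherical_uniform", n = 100, m = 20, p = 5,
#'                     k_spec = 0.16, seed = 1)
#' sc$k # 16
#' @export
make_scenario <- function(distribution = c("spherical_uniform", "mv_normal",
                                           "mv_t"),
                          n, m, p, k_spec, t = 10L, radius = 1, df = 10,
                          seed = NULL) {
  distribution <- match.arg(distribution)
  if (m > n) stop("`m` cannot exceed `n`", call. = FALSE)
  k <- resolve_k(k_spec, n)
  draw <- switch(distribution,
    spherical_uniform = function(nn) sample_spherical_uniform(nn, p, radius),
    mv_normal = function(nn) sample_mv_normal(nn, p),
    mv_t = function(nn) sample_mv_t(nn, p, df))
  with_preserved_seed(seed, {
    training <- draw(n)
    query <- draw(m)
    list(training = training, query = query, k = k,
         schedule = tau_schedule(k, n, t))
  })
}

#' Write a matrix as delimited text
#'
#' Convenience writer for round-tripping generated matrices through the
#' command-line interface. No row names; a header row of `V1..Vp`.
#'
#' @param x Numeric matrix.
#' @param path Output file.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @export
write_matrix <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
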