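# Benchmark harness: per-replicate records of agreement with the brute-force
# reference, sweep iterations, and (informational) timing and memory deltas.
# Correctness is a gate, not a metric: any disagreement aborts with a
# diagnostic dump.

mem_used_mb <- function() sum(gc(verbose = FALSE)[, 2L])

#' Run one benchmark scenario
#'
#' For each replicate: generate the scenario from a deterministically derived
#' seed, run both the stochastic fixed-radius search and the brute-force
#' reference, verify exact index-and-order agreement, and record iterations,
#' elapsed times, and memory deltas. Disagreement aborts with the offending
#' query's group, radius schedule position, and candidate sets.
#'
#' @param distribution,n,m,p,k_spec,t,radius,df Passed to [make_scenario()].
#' @param G Number of ring groups.
#' @param replicates Number of seeded replicates.
#' @param seed Base seed; replicate seeds are derived from it.
#' @return A data frame, one row per replicate, with scenario parameters,
#'   `agreement` (all `TRUE` on return), `mean_iterations`, `max_iterations`,
#'   `mean_k_prime`, `elapsed_stnnfr`, `elapsed_brute` (seconds), and
#'   `mem_delta_mb` (indicative only).
#' @export
run_scenario <- function(distribution, n, m, p, k_spec, G = 1L, t = 10L,
                         replicates = 5L, seed = 1L, radius = 1, df = 10) {
  records <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    rep_seed <- derive_seed(seed, rep_i)
    sc <- make_scenario(distribution, n = n, m = m, p = p, k_spec = k_spec,
                        t = t, radius = radius, df = df, seed = rep_seed)
    mem0 <- mem_used_mb()
    t_fit <- system.time(index <- stnn_index(sc$training))["elapsed"]
    t_stnn <- system.time(
      res <- stnn_search(index, sc$query, sc$k, G = G,
                         schedule = sc$schedule))["elapsed"]
    mem1 <- mem_used_mb()
    t_brute <- system.time(
      ref <- brute_force_knn(sc$training, sc$query, sc$k))["elapsed"]
    agree <- identical(res$indices, ref$indices)
    if (!agree) {
      bad <- which(apply(res$indices != ref$indices, 1L, any))[1L]
      stop(sprintf(
        paste0("agreement failure at replicate %d, query %d:\n",
               "  stnnfr:  %s\n  brute:   %s\n",
               "  iterations = %d, k' = %d, schedule = %s"),
        rep_i, bad,
        paste(res$indices[bad, ], collapse = " "),
        paste(ref$indices[bad, ], collapse = " "),
        res$iterations[bad], res$k_prime[bad],
        paste(signif(res$schedule, 4), collapse = " ")), call. = FALSE)
    }
    records[[rep_i]] <- data.frame(
      distribution = distribution, n = n, m = m, p = p, k = sc$k, G = G,
      t = length(sc$schedule), replicate = rep_i, seed = rep_seed,
      agreement = agree, mean_iterations = mean(res$iterations),
      max_iterations = max(res$iterations), mean_k_prime = mean(res$k_prime),
      elapsed_fit = as.numeric(t_fit), elapsed_stnnfr = as.numeric(t_stnn),
      elapsed_brute = as.numeric(t_brute), mem_delta_mb = mem1 - mem0)
  }
  do.call(rbind, records)
}

#' Expand a benchmark configuration into a scenario grid
#'
#' List-valued keys are grid axes and expand Cartesian-style; scalar keys are
#' held fixed. Recognised keys: `distribution`, `n`, `m`, `p`, `k_spec`, `G`,
#' `t`, `replicates`, `seed`.
#'
#' @param config Named list (e.g. parsed from a YAML file).
#' @return A data frame with one row per scenario.
#' @export
bench_grid <- function(config) {
  keys <- c("distribution", "n", "m", "p", "k_spec", "G", "t", "replicates",
            "seed")
  defaults <- list(distribution = "spherical_uniform", n = 1000, m = 50,
                   p = 10, k_spec = 5, G = 1, t = 10, replicates = 5,
                   seed = 1)
  unknown <- setdiff(names(config), keys)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key: %s", unknown[1L]), call. = FALSE)
  }
  vals <- lapply(keys, function(k) {
    v <- config[[k]]
    if (is.null(v)) defaults[[k]] else unlist(v)
  })
  names(vals) <- keys
  grid <- expand.grid(vals, stringsAsFactors = FALSE)
  grid[grid$m <= grid$n, , drop = FALSE]
}

#' Run a whole benchmark grid
#'
#' @param config Named list as for [bench_grid()].
#' @param verbose Print a progress line per scenario.
#' @return A data frame of per-replicate records across the grid.
#' @export
run_bench <- function(config, verbose = FALSE) {
  grid <- bench_grid(config)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (verbose) {
      message(sprintf("[%s] scenario %d/%d: %s n=%d m=%d p=%d k_spec=%g G=%d",
                      format(Sys.time(), "%H:%M:%S"), i, nrow(grid),
                      g$distribution, g$n, g$m, g$p, g$k_spec, g$G))
    }
    out[[i]] <- run_scenario(g$distribution, n = g$n, m = g$m, p = g$p,
                             k_spec = g$k_spec, G = g$G, t = g$t,
                             replicates = g$replicates, seed = g$seed)
  }
  do.call(rbind, out)
}

#' Summarise benchmark records per scenario
#'
#' @param records Data frame from [run_bench()] or [run_scenario()].
#' @return One row per scenario with replicate means.
#' @export
summarize_bench <- function(records) {
  key <- c("distribution", "n", "m", "p", "k", "G", "t")
  agg <- stats::aggregate(
    records[c("mean_iterations", "mean_k_prime", "elapsed_stnnfr",
              "elapsed_brute", "mem_delta_mb")],
    by = records[key], FUN = mean)
  agg$all_agree <- stats::aggregate(records$agreement, by = records[key],
                                    FUN = all)$x
  agg
}
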