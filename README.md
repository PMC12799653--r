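# stnnfr

Exact k-nearest-neighbour (kNN) search by stochastic fixed-radius queries.

The brute-force kNN search computes all `n × m` distances between a training
set and a query set — exact, but wasteful when only `k ≪ n` neighbours matter.
`stnnfr` keeps the exactness while searching only a fraction of the training
set, a need that arises routinely in biostatistics and machine learning at
scale (health-records cohorts, high-dimensional omics and imaging features).

## The method

All training points lie, by construction, inside the bounding hypersphere `S`
centred at the training centroid `x̄` with radius
`r = max_j ‖x_j − x̄‖`. Assume the training points are dispersed as a
spherical uniform distribution on `S` (the worst-case, evenly spread model),
with density `g(x) = 1 / volume(S)` on `{x : ‖x − x̄‖ ≤ r}`.

For a query `x_i` at centroid distance `d = ‖x_i − x̄‖`, a search sphere `S_i`
of radius `r_i` captures the training mass

    P(S_i) = volume(S_i ∩ S) / volume(S),

where the intersection volume follows the piecewise hypersphere-overlap rule:
0 when `d ≥ r_i + r`; the smaller ball's volume when `d ≤ |r_i − r|`;
otherwise the sum of two hyperspherical caps
`V_p^cap(r, c₁) + V_p^cap(r_i, c₂)` with cap offsets
`c₁ = (d² + r² − r_i²)/(2d)`, `c₂ = (d² − r² + r_i²)/(2d)` and cap volumes
expressed through the regularized incomplete beta function
`I_{1−a²/r′²}((p+1)/2, 1/2)`.

The search radius is the root of `P(S_i) − τ = 0` for a target mass
`τ ∈ (0, 1]` — e.g. `τ = k/n` expects exactly `k` training points inside
`S_i`. The radius is submitted as a fixed-radius KD-tree query; if fewer than
`k` candidates come back, `τ` escalates through an evenly spaced schedule from
`k/n` to 1. The final value `τ = 1` solves to radius `d + r`, which covers
all of `S` by the triangle inequality, so the sweep always terminates and the
`k` nearest of the captured candidates are exactly the global `k` nearest —
same indices, same order, as brute force.

Since `P(S_i)` depends on the query only through `d`, queries are binned into
`G` concentric rings of equal mass (boundaries `δ_g = r·(g/G)^{1/p}`) and each
ring shares one radius per threshold, solved conservatively at the ring's
outer edge — at most `G × t` radius equations per run instead of `m × t`.

## Worked example

```r
library(stnnfr)
train <- sample_spherical_uniform(2000, 25, seed = 42)
query <- sample_spherical_uniform(10, 25, seed = 43)

index <- stnn_index(train)
index
#> Training index: n = 2000, p = 25, bounding radius r = 1.00988

res <- stnn_search(index, query, k = 5)
res
#> stnnfr k-nearest-neighbour result: 10 queries, k = 5
#>   mean iterations = 1.100, mean candidates k' = 36.0

head(as.data.frame(res), 5)
#>   query_id rank train_index  distance
#> 1        1    1        1595 0.8582432
#> 2        1    2        1108 0.8886530
#> 3        1    3         292 0.8913071
#> 4        1    4         510 0.9211005
#> 5        1    5         288 0.9222164

ref <- brute_force_knn(train, query, k = 5)
identical(res$indices, ref$indices) && identical(res$distances, ref$distances)
#> [1] TRUE
```

The bounding radius is just over 1 (the sampling ball's radius), most queries
resolve in a single sweep iteration, and on average only 36 of the 2000
training points — the candidates inside the solved radius — were ever scored
per query, yet the result is bit-identical to the brute-force search.

A command-line wrapper lives at `inst/cli/stnnfr.R`
(`stnnfr.R query --train train.csv --query query.csv -k 5 --oracle`;
`stnnfr.R bench --config grid.yaml --out results`).

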