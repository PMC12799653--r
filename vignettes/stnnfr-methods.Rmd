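---
title: "Stochastic fixed-radius kNN search: model, geometry, and design choices"
author: "stnnfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic fixed-radius kNN search: model, geometry, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnnfr)
```

## The problem and the model

A k-nearest-neighbour search must return, for each of `m` query points, the
`k` training points (out of `n`) at smallest Euclidean distance. The linear
baseline scores all `n` distances per query. `stnnfr` avoids most of that
work without giving up exactness, by answering a different question first:
*how large a sphere around the query do we expect to need before it holds k
training points?*

The training set is bounded by the hypersphere `S` centred at the sample
centroid with radius `r`, the maximum centroid distance — so no neighbour can
ever lie outside `S`. Treating the training points as spherical-uniform on
`S` (density `1/volume(S)`), the expected fraction of training points inside
a query sphere `S_i` of radius `r_i` at centroid distance `d` is the volume
ratio `P(S_i) = volume(S_i ∩ S)/volume(S)`. Setting `P(S_i) = τ = k/n` and
solving for `r_i` gives a radius that holds `k` points *in expectation*; a
fixed-radius KD-tree query retrieves the actual candidates, and whenever at
least `k` arrive, the `k` closest of them are provably the global `k` nearest
(if ≥ k points lie within `r_i`, the k-th order statistic is ≤ `r_i`, so
every true neighbour is in the candidate set). If fewer arrive, `τ` escalates
through a schedule ending at 1, whose solved radius `d + r` covers all of `S`
by the triangle inequality — the sweep cannot fail, it can only take more
iterations.

The spherical uniform assumption is therefore *not* a correctness assumption.
It only calibrates how fast the radius grows; on mis-specified data (e.g.
Gaussian or heavy-tailed t) the method stays exact and merely iterates more.

## Geometry on the log scale

The containment probability uses the piecewise two-sphere intersection rule
(disjoint / contained / lens), the lens case being a sum of two
hyperspherical caps whose volumes reduce to the regularized incomplete beta
function `I_{1−a²/r′²}((p+1)/2, 1/2)` (evaluated with `stats::pbeta`). The
raw volume formulas overflow double precision around `p ≈ 340` (and the unit
ball's volume underflows long before), so every probability is computed as a
ratio in log space: cap fractions via `pbeta(..., log.p = TRUE)` plus
`p·log(r_i/r)` terms, exponentiated only at the end. This keeps the solver
usable at `p` in the hundreds, the regime where high-dimensional feature sets
(e.g. 450 handwriting kinematics features) live.

Numerical guards, chosen once:

* **`d ≈ 0`.** The cap offsets `c₁, c₂` divide by `d`. Centre separations
  below `1e-12 · max(r, r_i)` are treated as exactly zero, which routes
  through the containment branch where no division occurs. Case boundaries
  resolve by the written `≥`/`≤` comparisons, first match wins.
* **Root finding.** `P` is continuous and non-decreasing in `r_i` with
  `P(0) = 0` and `P(d + r) = 1`, so the root of `P − τ` is bracketed on
  `[0, d + r]`. Brent's method (`stats::uniroot`) runs first; if the
  probability residual exceeds the tolerance (default `1e-10`), a plain
  bisection polishes it. In very high dimension `P` can pass through `τ`
  within one representable step of `r_i`; the interval then collapses to
  machine precision, which is the best attainable answer.
* **`τ = 1`** short-circuits to `d + r` exactly — no solver, and the
  guarantee that the final sweep iteration captures all `n` points.
* **Covering-radius rounding.** At the final threshold the radius is
  inflated by a relative `1e-9` before the tree query, so the triangle
  inequality bound cannot be lost to floating-point rounding.

## Exactness as a testable property

"Same neighbours, in the same order" is only meaningful under a declared
tie-break. Both search paths order candidates by ascending
`(distance, training row index)`, and every distance in the package — index
build, brute force, candidate re-scoring, KD-tree leaf scans — goes through
one C++ kernel with a fixed per-row accumulation order. Identical arithmetic
in, identical ordering out; the equivalence tests can therefore use
`identical()` rather than a tolerance. The fixed-radius primitive likewise
re-filters the tree's (slightly inflated) candidate set with the shared
kernel, making its membership exactly the linear-scan filter.

## Tunable parameters

* **`k`** — neighbours per query, `1 ≤ k ≤ n`.
* **`G`** (default 1) — number of equal-mass ring groups with boundaries
  `δ_g = r·(g/G)^{1/p}`. Queries in ring `g` share the radius solved at the
  outer edge `d = δ_g`, which is conservative for the whole ring because `P`
  is non-increasing in `d`. `G` trades the number of solved equations
  (at most `G × t`) against radius tightness; it never changes the result,
  only the running time, and `G = 1` is the fastest default at these problem
  sizes. In high dimension the rings collapse toward the shell
  (`δ₁ = r·(1/G)^{1/p} → r`), so large `G` buys little.
* **`t`** (default 10) — schedule length. The schedule runs evenly spaced
  from `k/n` (the neighbour fraction, so the first radius already expects `k`
  points) to exactly 1. `t` bounds the worst-case iteration count.
* **Group `G+1`** — queries outside the bounding sphere. The ring
  construction only tiles `[0, r]`, so these solve the radius equation at
  their own centroid distance, per query and per threshold. Under the model
  such queries are rare (a same-distribution query falls beyond the training
  maximum with probability ≈ 1/(n+1)), so the extra solves are negligible.
* **`leaf_size`** (default 16) — KD-tree bucket size; a pure time/space
  knob with no effect on results.

## What the synthetic generators emulate

The three seeded generators reproduce the dispersion regimes the method is
studied under: `sample_spherical_uniform` (radius 1; the assumption exactly
met, and the worst case for evenly spread neighbours),
`sample_mv_normal` (standard normal; mass concentrated well inside the
bounding sphere, mis-specifying the model toward over-large radii), and
`sample_mv_t` (df = 10, identity **scale** matrix, hence covariance
`df/(df−2)·I = 1.25·I` — the standard sampler parameterisation, stated here
because "identity covariance" is ambiguous; heavy tails push the bounding
radius out). Query sets are drawn from the same distribution as the training
set. Fractional `k` specifications (`0.16n`, `0.33n`, `0.5n`) round half up.

What they deliberately do **not** emulate: correlated features, cluster
structure, group-specific covariances, or any real measured data set.
Passing tests on these generators show exactness and calibration under
controlled dispersion models — exactness is distribution-free (see above),
but the *efficiency* figures (iterations near 1, small candidate sets) are
statements about these models, not about arbitrary real data.

## Problem sizes in the shipped tests

The equivalence suite runs a reduced grid — three distributions ×
`n ∈ {100, 1000, 10000}` × `m ∈ {50, 100}` × `p ∈ {5, 20, 50}` ×
`k ∈ {1, 0.16n}` × `G ∈ {1, 5}`, five seeded replicates each — sized so the
whole suite completes in minutes on a single core while still crossing the
regimes (tiny and large `n`, `k` from 1 to 1600, queries inside and outside
the bounding sphere). The benchmark harness accepts larger grids from a YAML
configuration; its timing and memory columns are informational only —
correctness is enforced as a gate (any disagreement with brute force aborts
the run with a diagnostic dump), never summarised away.

## Known limitations

* Euclidean metric only: the volume argument linking `τ` to a radius is
  metric-specific.
* The index is static; no incremental insertion, no out-of-core data.
* KD-tree range queries degrade toward a linear scan as `p` grows; the
  method still wins by scoring only the candidate ball, but the tree's
  pruning contributes little beyond `p` of a few tens.
* Degenerate training sets (all rows identical, `r = 0`) bypass the
  geometry — the radius equation is undefined there — and return the first
  `k` rows, all equidistant.
* Timing and memory are hardware- and implementation-dependent and are never
  asserted by the test suite.
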