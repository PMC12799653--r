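# Independent low-dimensional oracles and small fixture builders.

# 1-D: overlap length of [-r, r] and [d - ri, d + ri].
interval_overlap <- function(r, ri, d) {
  max(0, min(r, d + ri) - max(-r, d - ri))
}

# 2-D: classical lens (circle-circle intersection) area.
lens_area <- function(r, ri, d) {
  if (d >= r + ri) return(0)
  if (d <= abs(r - ri)) return(pi * min(r, ri)^2)
  r^2 * acos((d^2 + r^2 - ri^2) / (2 * d * r)) +
    ri^2 * acos((d^2 + ri^2 - r^2) / (2 * d * ri)) -
    0.5 * sqrt((-d + r + ri) * (d + r - ri) * (d - r + ri) * (d + r + ri))
}

# 3-D: sphere-sphere intersection volume via the cap-height formula.
sphere_overlap_3d <- function(r, ri, d) {
  if (d >= r + ri) return(0)
  if (d <= abs(r - ri)) return(4 / 3 * pi * min(r, ri)^3)
  pi * (r + ri - d)^2 *
    (d^2 + 2 * d * ri - 3 * ri^2 + 2 * d * r + 6 * r * ri - 3 * r^2) /
    (12 * d)
}

# Plain-R linear-scan distances (independent of the package's C++ kernel).
scan_distances <- function(x, q) {
  sqrt(colSums((t(x) - q)^2))
}

# Random lens-case geometry triple: radii in (0.2, 2), d strictly between
# |r - ri| and r + ri.
random_lens_triple <- function() {
  r <- runif(1, 0.2, 2)
  ri <- runif(1, 0.2, 2)
  lo <- abs(r - ri)
  d <- runif(1, lo + 0.05 * (r + ri - lo), r + ri - 0.01)
  list(r = r, ri = ri, d = d)
}
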