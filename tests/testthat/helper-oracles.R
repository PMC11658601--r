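# Independent brute-force oracles used across the suite.

# mean distance to k nearest neighbours, computed from the full distance
# matrix (independent of the package's C++ path)
brute_knn_avg_dist <- function(pts, k) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
}

# greedy max-min farthest point sampling by exhaustive search
brute_fps <- function(pts, m, start = 1L) {
  D <- as.matrix(stats::dist(pts))
  sel <- start
  for (s in seq_len(m - 1L)) {
    mind <- apply(D[, sel, drop = FALSE], 1, min)
    mind[sel] <- -Inf
    sel <- c(sel, which.max(mind))
  }
  unname(sel)
}

# all indices within radius of a center, nearest first
brute_ball <- function(pts, center, radius) {
  d <- sqrt(colSums((t(pts) - center)^2))
  ord <- order(d)
  ord[d[ord] <= radius]
}

# fine-grid roots of x * exp(-x^2/2) = theta * exp(-1/2) on both sides of 1
grid_rapid_roots <- function(theta, step = 1e-6) {
  target <- theta * exp(-0.5)
  g <- function(x) x * exp(-x^2 / 2) - target
  refine <- function(lo, hi) {
    xs <- seq(lo, hi, by = step)
    v <- g(xs)
    i <- which(v[-1] * v[-length(v)] <= 0)[1]
    # linear interpolation across the sign change
    x1 <- xs[i]; x2 <- xs[i + 1]
    x1 - v[i] * (x2 - x1) / (v[i + 1] - v[i])
  }
  c(x1 = refine(1e-6, 1), x2 = refine(1, 4))
}

# a tiny field used by many tests: n_var varieties x 3 N levels x 2 reps
small_layout <- function(n_var = 2) {
  generate_layout(trial_design(n_varieties = n_var))
}

make_cloud <- function(points, ...) point_cloud(as.matrix(points), ...)
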