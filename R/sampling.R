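#' Farthest point sampling
#'
#' Greedy max-min subsampling: starting from `start_index`, repeatedly
#' pick the point farthest from the already-selected set. This is the
#' subsampling step of the hierarchical point-set encoder; it covers the
#' cloud far more evenly than random sampling. Deterministic.
#'
#' @param points N x 3 coordinate matrix.
#' @param m number of samples, 1 <= m <= N.
#' @param start_index index of the first sample (default 1).
#' @return Integer vector of `m` selected point indices.
#' @export
farthest_point_sample <- function(points, m, start_index = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (m < 1 || m > n) stop("m must satisfy 1 <= m <= N", call. = FALSE)
  if (start_index < 1 || start_index > n) stop("invalid start_index", call. = FALSE)
  fps_cpp(points, as.integer(m), as.integer(start_index))
}

#' Fixed-radius neighborhood grouping (ball query)
#'
#' For every center, collects up to `k_max` point indices within
#' `radius`, nearest first. Centers with no point in radius are padded
#' with their single nearest point and flagged; groups with fewer than
#' `k_max` members repeat their nearest member to fill the group (so the
#' result is a dense m x k_max index matrix suitable for batched
#' feature encoding).
#'
#' @param points N x 3 coordinate matrix.
#' @param centers M x 3 coordinate matrix.
#' @param radius grouping radius (> 0).
#' @param k_max maximum group size (>= 1).
#' @return List with `idx` (M x k_max index matrix), `n_in` (points
#'   within radius per center) and `padded` (logical, center had no
#'   point in radius).
#' @export
ball_query <- function(points, centers, radius, k_max) {
  points <- as.matrix(points); centers <- as.matrix(centers)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  ball_query_cpp(points, centers, radius, as.integer(k_max))
}
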