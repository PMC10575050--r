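# Shared fixtures and independent oracles used across the suite.

# straight-line trajectory x = t, length n
line_traj <- function(n = 10, dt = 0.1) {
  tt <- (seq_len(n) - 1) * dt
  trajectory(tt, 2 * tt, -tt, dt = dt)
}

random_traj <- function(n, dt = 0.1) {
  trajectory(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n), dt = dt)
}

# Exhaustive DTW oracle: enumerate every monotone path on the n1 x n2
# grid (steps down/right/diagonal), take the lexicographic minimum of
# (total cost, path length), and normalise by that length.
dtw_brute <- function(t1, t2) {
  m1 <- as.matrix(as.data.frame(t1)[c("x", "y", "z")])
  m2 <- as.matrix(as.data.frame(t2)[c("x", "y", "z")])
  n1 <- nrow(m1); n2 <- nrow(m2)
  d <- outer(seq_len(n1), seq_len(n2),
             Vectorize(function(i, j) sqrt(sum((m1[i, ] - m2[j, ])^2))))
  best <- c(Inf, Inf)  # (cost, K)
  walk <- function(i, j, cost, k) {
    cost <- cost + d[i, j]; k <- k + 1L
    if (i == n1 && j == n2) {
      if (cost < best[1] || (cost == best[1] && k < best[2]))
        best <<- c(cost, k)
      return(invisible())
    }
    if (i < n1 && j < n2) walk(i + 1L, j + 1L, cost, k)
    if (i < n1) walk(i + 1L, j, cost, k)
    if (j < n2) walk(i, j + 1L, cost, k)
  }
  walk(1L, 1L, 0, 0L)
  list(distance = best[1] / best[2], cost = best[1], K = best[2])
}

# Brute-force enumeration of the window start rule.
window_count_brute <- function(n, q, s) {
  if (n < q) return(0L)
  starts <- integer(0)
  st <- 0L
  while (st + q <= n) { starts <- c(starts, st); st <- st + s }
  if (starts[length(starts)] + q < n) starts <- c(starts, n - q)
  length(starts)
}

# two-link planar arm fixture
two_link_skeleton <- function(l1 = 0.3, l2 = 0.25) {
  skeleton_model(
    data.frame(name = c("upper", "fore"), parent = c(NA, "upper"),
               length = c(l1, l2), dx = c(1, 1), dy = c(0, 0), dz = c(0, 0)),
    data.frame(point = "wrist", segment = "fore", ox = 0, oy = 0, oz = 0))
}

# random world-to-camera rigid pose keeping the unit box at positive depth
random_camera <- function() {
  M <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  camera_model(stats::runif(1, 400, 1200), stats::runif(1, 400, 1200),
               stats::runif(1, -200, 200), stats::runif(1, -200, 200),
               rotation = R,
               translation = c(stats::runif(2, -0.5, 0.5), 3))
}

quiet_noise <- function() {
  noise_spec(accel_sigma = 0, accel_bias_walk = 0, pixel_sigma = 0,
             angle_sigma = 0, dropout_prob = 0, position_sigma = 0)
}
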