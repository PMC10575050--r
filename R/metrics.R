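#' Dynamic time warping distance between two trajectories
#'
#' Aligns two trajectories of possibly different lengths with a monotone
#' warping path (steps down, right, diagonal), minimising the total
#' Euclidean point distance along the path, and reports the minimum total
#' cost divided by the alignment length `K`. Among minimal-cost paths the
#' shortest alignment is used, which makes the result deterministic.
#'
#' @param t1,t2 Trajectories (or data frames coercible to one).
#' @return A `dtw_result` list: `distance` (mean per-alignment-step cost),
#'   `path` (K x 2 matrix of 1-based index pairs), and `K`.
#' @export
dtw <- function(t1, t2) {
  m1 <- traj_matrix(as_trajectory(t1))
  m2 <- traj_matrix(as_trajectory(t2))
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 == 0L || n2 == 0L) stop("trajectories must be non-empty", call. = FALSE)
  # local cost matrix
  d <- matrix(0, n1, n2)
  for (j in seq_len(n2))
    d[, j] <- sqrt((m1[, 1] - m2[j, 1])^2 + (m1[, 2] - m2[j, 2])^2 +
                   (m1[, 3] - m2[j, 3])^2)
  C <- matrix(Inf, n1, n2)  # minimal cumulative cost
  L <- matrix(0L, n1, n2)   # path length of that (lexicographically) best path
  C[1, 1] <- d[1, 1]; L[1, 1] <- 1L
  for (j in seq_len(n2)) {
    for (i in seq_len(n1)) {
      if (i == 1L && j == 1L) next
      best_c <- Inf; best_l <- 0L
      consider <- function(ci, li) {
        if (ci < best_c || (ci == best_c && li < best_l)) {
          best_c <<- ci; best_l <<- li
        }
      }
      if (i > 1L && j > 1L) consider(C[i - 1, j - 1], L[i - 1, j - 1])
      if (i > 1L) consider(C[i - 1, j], L[i - 1, j])
      if (j > 1L) consider(C[i, j - 1], L[i, j - 1])
      C[i, j] <- d[i, j] + best_c
      L[i, j] <- best_l + 1L
    }
  }
  # backtrack with the same preference (diagonal first on exact ties)
  path <- matrix(0L, L[n1, n2], 2)
  i <- n1; j <- n2; k <- L[n1, n2]
  while (k >= 1L) {
    path[k, ] <- c(i, j)
    k <- k - 1L
    if (i == 1L && j == 1L) break
    cand <- list()
    if (i > 1L && j > 1L) cand <- c(cand, list(c(i - 1L, j - 1L)))
    if (i > 1L) cand <- c(cand, list(c(i - 1L, j)))
    if (j > 1L) cand <- c(cand, list(c(i, j - 1L)))
    keys <- vapply(cand, function(p) C[p[1], p[2]], numeric(1))
    lens <- vapply(cand, function(p) L[p[1], p[2]], integer(1))
    ok <- which(d[i, j] + keys == C[i, j] & lens == L[i, j] - 1L)
    if (length(ok) == 0L) ok <- which.min(keys)
    i <- cand[[ok[1]]][1]; j <- cand[[ok[1]]][2]
  }
  structure(list(distance = C[n1, n2] / L[n1, n2],
                 path = path, K = L[n1, n2]),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("# DTW: distance %.6g over an alignment of length %d\n",
              x$distance, x$K))
  invisible(x)
}

#' Mean squared point deviation between paired trajectories
#'
#' Mean over samples of the squared Euclidean distance between points at
#' the same index; trajectories must be equally long (resample first if
#' rates differ).
#'
#' @param tc,te Trajectories of equal length.
#' @return Mean squared deviation, m^2.
#' @export
mse <- function(tc, te) {
  mc <- traj_matrix(as_trajectory(tc)); me <- traj_matrix(as_trajectory(te))
  if (nrow(mc) != nrow(me)) stop("trajectories must have equal length", call. = FALSE)
  mean(rowSums((mc - me)^2))
}

#' Euclidean deviation family between paired trajectories
#'
#' Per-sample Euclidean distances aggregated three ways: the mean, the
#' maximum, and the total.
#'
#' @param tc,te Trajectories of equal length.
#' @return A one-row tibble with columns `d_mean`, `d_max`, `d_sum`
#'   (meters).
#' @export
euclid_stats <- function(tc, te) {
  mc <- traj_matrix(as_trajectory(tc)); me <- traj_matrix(as_trajectory(te))
  if (nrow(mc) != nrow(me)) stop("trajectories must have equal length", call. = FALSE)
  d <- sqrt(rowSums((mc - me)^2))
  tibble::tibble(d_mean = mean(d), d_max = max(d), d_sum = sum(d))
}

#' Metrics on cumulative traveled distance
#'
#' Applies [mse()] and the Euclidean family to cumulative per-step
#' displacement magnitudes instead of positions, so recordings whose
#' calibration left a coordinate offset or flipped direction can still be
#' compared by how far the point has traveled.
#'
#' @param tc,te Trajectories of equal length.
#' @return A one-row tibble with `mse_path`, `d_mean_path`, `d_max_path`,
#'   `d_sum_path`.
#' @export
path_metrics <- function(tc, te) {
  cum_path <- function(tr) {
    m <- traj_matrix(as_trajectory(tr))
    c(0, cumsum(sqrt(rowSums(diff(m)^2))))
  }
  pc <- cum_path(tc); pe <- cum_path(te)
  if (length(pc) != length(pe))
    stop("trajectories must have equal length", call. = FALSE)
  d <- abs(pc - pe)
  tibble::tibble(mse_path = mean(d^2), d_mean_path = mean(d),
                 d_max_path = max(d), d_sum_path = sum(d))
}
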