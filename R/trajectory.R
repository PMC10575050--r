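#' Construct a target-point trajectory
#'
#' A trajectory is the ordered sequence of metric 3-D positions of one
#' anatomical target point (wrist, foot, lumbar region, neck) sampled on a
#' regular time grid. It is stored as a tibble with columns `t`, `x`, `y`,
#' `z` (seconds and meters) plus a `dt` attribute; the i-th sample sits at
#' `t0 + (i-1) * dt`. Coordinates are right-handed with Y pointing up.
#'
#' @param x,y,z Numeric coordinate vectors of equal length, meters.
#' @param dt Sampling interval, seconds (> 0).
#' @param t0 Start time, seconds.
#' @return A `trajectory` tibble with columns `t`, `x`, `y`, `z`.
#' @examples
#' trajectory(x = 0:4 / 10, y = rep(0, 5), z = rep(0, 5), dt = 1 / 30)
#' @export
trajectory <- function(x, y, z, dt, t0 = 0) {
  x <- as.double(x); y <- as.double(y); z <- as.double(z)
  n <- length(x)
  if (n == 0L) stop("trajectory must contain at least one sample", call. = FALSE)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("trajectory coordinates must be finite", call. = FALSE)
  out <- tibble::tibble(t = t0 + (seq_len(n) - 1) * dt, x = x, y = y, z = z)
  attr(out, "dt") <- as.double(dt)
  class(out) <- c("trajectory", class(out))
  out
}

#' Coerce a data frame to a trajectory
#'
#' Accepts any data frame with columns `x`, `y`, `z` and optionally `t`.
#' When `t` is present and `dt` is not given, the sampling interval is
#' inferred as the median inter-sample gap; timestamps must be strictly
#' increasing.
#'
#' @param df A data frame with columns `x`, `y`, `z` and optionally `t`.
#' @param dt Sampling interval in seconds; required when `df` has no `t`.
#' @return A `trajectory` tibble.
#' @export
as_trajectory <- function(df, dt = NULL) {
  if (inherits(df, "trajectory") && is.null(dt)) return(df)
  stopifnot(is.data.frame(df))
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("data frame must have columns x, y, z", call. = FALSE)
  t0 <- 0
  if ("t" %in% names(df) && nrow(df) >= 2L) {
    tt <- as.double(df$t)
    if (any(diff(tt) <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
    if (is.null(dt)) dt <- stats::median(diff(tt))
    t0 <- tt[1]
  }
  if (is.null(dt))
    stop("`dt` must be supplied when no timestamps are present", call. = FALSE)
  trajectory(df$x, df$y, df$z, dt = dt, t0 = t0)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("# Trajectory: %d samples at %.6g Hz (dt = %.6g s)\n",
              nrow(x), 1 / attr(x, "dt"), attr(x, "dt")))
  NextMethod()
}

#' Sampling interval of a trajectory
#' @param traj A `trajectory`.
#' @return The sampling interval `dt` in seconds.
#' @export
trajectory_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) stop("object carries no `dt` attribute", call. = FALSE)
  dt
}

# N x 3 coordinate matrix view
traj_matrix <- function(traj) {
  cbind(x = traj$x, y = traj$y, z = traj$z)
}

#' Read a trajectory from delimited text
#'
#' Reads comma-separated rows `t,x,y,z` or `x,y,z` ('.' decimal mark, an
#' optional header line is auto-detected). Row order is preserved; with
#' timestamps present, `dt` is inferred as the median inter-sample gap.
#'
#' @param source File path or connection.
#' @param dt Sampling interval in seconds; required for headerless `x,y,z`
#'   input without timestamps.
#' @return A `trajectory` tibble.
#' @export
read_trajectory <- function(source, dt = NULL) {
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trajectory stream", call. = FALSE)
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  header <- if (has_header) tolower(trimws(first)) else NULL
  data_lines <- if (has_header) lines[-1] else lines
  if (length(data_lines) == 0L) stop("empty trajectory stream", call. = FALSE)
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  ncol <- length(fields[[1]])
  if (!ncol %in% c(3L, 4L))
    stop("trajectory rows must have 3 (x,y,z) or 4 (t,x,y,z) fields", call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(fields), ncol = ncol)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != ncol)
      stop(sprintf("malformed trajectory row at line %d", i + has_header), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("malformed trajectory row at line %d", i + has_header), call. = FALSE)
    vals[i, ] <- v
  }
  has_t <- if (!is.null(header)) "t" %in% header else ncol == 4L
  df <- if (has_t) {
    tibble::tibble(t = vals[, 1], x = vals[, 2], y = vals[, 3], z = vals[, 4])
  } else {
    tibble::tibble(x = vals[, 1], y = vals[, 2], z = vals[, 3])
  }
  if (has_t && nrow(df) >= 2L && any(diff(df$t) <= 0))
    stop("non-monotone timestamps in trajectory stream", call. = FALSE)
  if (has_t && nrow(df) == 1L && is.null(dt)) dt <- 1
  as_trajectory(df, dt = dt)
}

#' Write a trajectory to CSV
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[c("t", "x", "y", "z")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a trajectory to a target rate
#'
#' Linearly interpolates each axis onto the grid `t0 + k / target_hz`
#' covering the original time span, so recordings from heterogeneous
#' hardware (30-500 Hz) can be aligned to a common rate before comparison
#' or classification.
#'
#' @param traj A `trajectory` with at least two samples.
#' @param target_hz Target sampling rate, Hz (> 0).
#' @return A `trajectory` with `dt = 1 / target_hz`.
#' @export
resample_trajectory <- function(traj, target_hz) {
  traj <- as_trajectory(traj)
  if (nrow(traj) < 2L) stop("resampling needs at least two samples", call. = FALSE)
  if (!is.numeric(target_hz) || target_hz <= 0)
    stop("`target_hz` must be positive", call. = FALSE)
  new_dt <- 1 / target_hz
  t0 <- traj$t[1]
  span <- traj$t[nrow(traj)] - t0
  new_t <- t0 + seq(0, floor(span / new_dt + 1e-9)) * new_dt
  interp <- function(v) stats::approx(traj$t, v, xout = new_t, rule = 2)$y
  trajectory(interp(traj$x), interp(traj$y), interp(traj$z),
             dt = new_dt, t0 = t0)
}

#' Spatial and speed limits of a trajectory
#'
#' Computes the boundary values describing an exercise movement: per-axis
#' minimum and maximum position, and the mean absolute per-step speed per
#' axis (`mean(|diff(coord)|) / dt`). The absolute-value convention makes
#' oscillating repetitions register a nonzero speed, so slow and fast
#' executions of the same movement are distinguishable.
#'
#' @param traj A `trajectory` with at least two samples.
#' @return A `limits` tibble with one row per axis and columns
#'   `axis`, `min`, `max`, `mean_speed`.
#' @export
compute_limits <- function(traj) {
  traj <- as_trajectory(traj)
  if (nrow(traj) < 2L) stop("limits need at least two samples", call. = FALSE)
  m <- traj_matrix(traj)
  dt <- trajectory_dt(traj)
  out <- tibble::tibble(
    axis = c("x", "y", "z"),
    min = unname(apply(m, 2, min)),
    max = unname(apply(m, 2, max)),
    mean_speed = unname(apply(m, 2, function(v) mean(abs(diff(v))) / dt))
  )
  class(out) <- c("limits", class(out))
  out
}

#' Forward-difference velocity of a trajectory
#'
#' @param traj A `trajectory` with at least two samples.
#' @return A tibble with columns `t`, `vx`, `vy`, `vz` of length `N - 1`
#'   (velocity over `[t_i, t_{i+1})`, meters/second).
#' @export
differentiate <- function(traj) {
  traj <- as_trajectory(traj)
  if (nrow(traj) < 2L) stop("differentiation needs at least two samples", call. = FALSE)
  dt <- trajectory_dt(traj)
  n <- nrow(traj)
  tibble::tibble(
    t = traj$t[-n],
    vx = diff(traj$x) / dt,
    vy = diff(traj$y) / dt,
    vz = diff(traj$z) / dt
  )
}

#' Total path length of a trajectory
#' @param traj A `trajectory`.
#' @return Total traveled distance in meters.
#' @export
path_length <- function(traj) {
  traj <- as_trajectory(traj)
  if (nrow(traj) < 2L) return(0)
  d <- diff(traj_matrix(traj))
  sum(sqrt(rowSums(d^2)))
}

#' Bundle trajectories of several target points
#'
#' An exercise record tracks `m >= 1` target points simultaneously (one for
#' arm raises and step-ups, two - lumbar region and neck - for
#' sit-to-stand). All member trajectories must share `dt` and length.
#'
#' @param trajectories Named list of `trajectory` objects.
#' @param label Optional exercise-category label.
#' @return A `trajectory_set`: long tibble with columns `point`, `t`, `x`,
#'   `y`, `z` and attributes `dt` and `label`.
#' @export
trajectory_set <- function(trajectories, label = NULL) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  if (is.null(names(trajectories)) || any(!nzchar(names(trajectories))))
    stop("trajectories must be a named list", call. = FALSE)
  trajectories <- lapply(trajectories, as_trajectory)
  dts <- vapply(trajectories, trajectory_dt, numeric(1))
  ns <- vapply(trajectories, nrow, integer(1))
  if (length(unique(round(dts, 12))) != 1L || length(unique(ns)) != 1L)
    stop("all member trajectories must share dt and length", call. = FALSE)
  out <- dplyr::bind_rows(lapply(trajectories, tibble::as_tibble), .id = "point")
  attr(out, "dt") <- dts[[1]]
  attr(out, "label") <- label
  class(out) <- c("trajectory_set", class(out))
  out
}

#' Split a trajectory set back into per-point trajectories
#' @param ts A `trajectory_set`.
#' @return Named list of `trajectory` objects.
#' @export
set_points <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  dt <- attr(ts, "dt")
  pts <- split(tibble::as_tibble(ts)[c("t", "x", "y", "z")], ts$point)
  lapply(pts[unique(ts$point)], as_trajectory, dt = dt)
}

#' Label of a trajectory set
#' @param ts A `trajectory_set`.
#' @return The category label, or `NULL`.
#' @export
set_label <- function(ts) attr(ts, "label")

#' Collect labeled records into a tidy collection
#'
#' @param sets List of `trajectory_set` objects.
#' @return A tibble with one row per record: columns `record` (integer id),
#'   `label`, and `data` (list column of trajectory sets).
#' @export
record_collection <- function(sets) {
  stopifnot(is.list(sets))
  labels <- vapply(sets, function(s) {
    l <- set_label(s); if (is.null(l)) NA_character_ else as.character(l)
  }, character(1))
  tibble::tibble(record = seq_along(sets), label = labels, data = sets)
}

#' Reject records with an implausible traveled distance
#'
#' Tracking dropouts, electromagnetic interference and inertial error
#' accumulation produce runaway trajectories. A record is rejected when any
#' of its target-point trajectories travels more than `max_path_m` meters
#' in total (default 3 m).
#'
#' @param records A record collection (see [record_collection()]) or a list
#'   of `trajectory_set`s.
#' @param max_path_m Rejection threshold on total path length, meters.
#' @return A list with elements `kept` and `rejected` (record collections)
#'   and counts `n_kept`, `n_rejected`.
#' @export
filter_faulty_records <- function(records, max_path_m = 3) {
  if (!is.data.frame(records)) records <- record_collection(records)
  if (nrow(records) == 0L) {
    empty <- records
    return(list(kept = empty, rejected = empty, n_kept = 0L, n_rejected = 0L))
  }
  bad <- vapply(records$data, function(ts) {
    any(vapply(set_points(ts), path_length, numeric(1)) > max_path_m)
  }, logical(1))
  list(
    kept = records[!bad, , drop = FALSE],
    rejected = records[bad, , drop = FALSE],
    n_kept = sum(!bad),
    n_rejected = sum(bad)
  )
}

#' Mean Euclidean deviation between two equally sampled trajectories
#'
#' The average point-wise Euclidean distance, the objective a processing
#' chain for noisy inertial data tries to minimise against ground truth.
#'
#' @param processed,truth Trajectories with equal sample counts.
#' @return Mean deviation in meters.
#' @export
deviation_mean <- function(processed, truth) {
  p <- as_trajectory(processed); s <- as_trajectory(truth)
  if (nrow(p) != nrow(s))
    stop("trajectories must have equal length", call. = FALSE)
  mean(sqrt(rowSums((traj_matrix(p) - traj_matrix(s))^2)))
}
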