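# Elementary rotation matrices (right-handed, angles in radians).
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

# Device-to-world rotation for a Y-up world: intrinsic yaw (about vertical
# Y), then pitch (about X), then roll (about Z).
rot_ypr <- function(yaw, pitch, roll) rot_y(yaw) %*% rot_x(pitch) %*% rot_z(roll)

#' Construct an inertial record
#'
#' Raw output of an inertial navigation system (accelerometer + gyroscope):
#' per-sample 3-axis acceleration in the device frame and the device
#' orientation as yaw/pitch/roll angles, on a regular time grid.
#'
#' @param accel N x 3 matrix or data frame of accelerations, m/s^2
#'   (device frame).
#' @param orient N x 3 matrix or data frame of orientation angles
#'   (roll, pitch, yaw), radians. Defaults to all zero.
#' @param dt Sampling interval, seconds.
#' @param gravity Gravity vector to subtract after rotation to the world
#'   frame, m/s^2. Zero (the default) for sensors that already report
#'   non-gravitational acceleration.
#' @return An `inertial_record` tibble with columns `t`, `ax`, `ay`, `az`,
#'   `roll`, `pitch`, `yaw` and attributes `dt`, `gravity`.
#' @export
inertial_record <- function(accel, orient = NULL, dt, gravity = c(0, 0, 0)) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L || nrow(accel) == 0L)
    stop("`accel` must be a non-empty N x 3 matrix", call. = FALSE)
  if (is.null(orient)) orient <- matrix(0, nrow(accel), 3)
  orient <- as.matrix(orient)
  if (!all(dim(orient) == dim(accel)))
    stop("`orient` must match `accel` in shape", call. = FALSE)
  if (!all(is.finite(accel)) || !all(is.finite(orient)))
    stop("inertial samples must be finite", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  stopifnot(length(gravity) == 3L, all(is.finite(gravity)))
  out <- tibble::tibble(
    t = seq_len(nrow(accel)) * dt,
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    roll = orient[, 1], pitch = orient[, 2], yaw = orient[, 3]
  )
  attr(out, "dt") <- as.double(dt)
  attr(out, "gravity") <- as.double(gravity)
  class(out) <- c("inertial_record", class(out))
  out
}

#' Read an inertial record from CSV
#'
#' Expects columns `t,ax,ay,az,roll,pitch,yaw` (header required; angles in
#' radians). `dt` is inferred as the median timestamp gap.
#'
#' @param path File path or connection.
#' @param gravity Gravity vector passed to [inertial_record()].
#' @return An `inertial_record`.
#' @export
read_inertial <- function(path, gravity = c(0, 0, 0)) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az", "roll", "pitch", "yaw")
  if (!all(need %in% names(df)))
    stop("inertial CSV must have columns t,ax,ay,az,roll,pitch,yaw", call. = FALSE)
  dt <- if (nrow(df) >= 2) stats::median(diff(df$t)) else 1
  inertial_record(df[c("ax", "ay", "az")], df[c("roll", "pitch", "yaw")],
                  dt = dt, gravity = gravity)
}

#' Rotate device-frame accelerations into the world frame
#'
#' Applies, per sample, the rotation given by the recorded orientation
#' angles (intrinsic yaw about the vertical Y axis, then pitch about X,
#' then roll about Z) and subtracts the record's gravity vector.
#'
#' @param record An `inertial_record`.
#' @return A tibble with columns `ax`, `ay`, `az`: world-frame,
#'   gravity-compensated accelerations, m/s^2.
#' @export
rotate_to_world <- function(record) {
  stopifnot(inherits(record, "inertial_record"))
  g <- attr(record, "gravity")
  acc <- cbind(record$ax, record$ay, record$az)
  out <- matrix(0, nrow(acc), 3)
  for (i in seq_len(nrow(acc))) {
    R <- rot_ypr(record$yaw[i], record$pitch[i], record$roll[i])
    out[i, ] <- drop(R %*% acc[i, ]) - g
  }
  tibble::tibble(ax = out[, 1], ay = out[, 2], az = out[, 3])
}

# Dead-reckoning recurrence, one axis. Velocity is updated first and the
# position step uses the updated velocity plus a*dt^2/2, i.e.
#   s_i = s_{i-1} + a_i dt ;  x_i = x_{i-1} + s_i dt + a_i dt^2 / 2 .
# This overcounts relative to trapezoidal integration (the per-step
# increment is s_{i-1} dt + 1.5 a_i dt^2); it is kept as the reference
# dead-reckoning scheme of the package and its exact inverse is used by
# the inertial simulator.
integrate_axis <- function(a, dt) {
  s <- cumsum(a) * dt
  x <- cumsum(s * dt + a * dt^2 / 2)
  list(s = s, x = x)
}

#' Dead-reckon a trajectory from world-frame accelerations
#'
#' Double-integrates an acceleration stream with zero initial velocity and
#' position. The caller is responsible for rotating samples into the world
#' frame first (see [rotate_to_world()] and [process_ins()]).
#'
#' @param record An `inertial_record` whose `ax`, `ay`, `az` columns are
#'   taken as world-frame accelerations.
#' @return A list with `trajectory` (N+1 samples: the origin plus one
#'   position per measurement) and `velocity` (tibble of N per-step
#'   velocities, m/s).
#' @export
integrate_acceleration <- function(record) {
  stopifnot(inherits(record, "inertial_record"))
  dt <- attr(record, "dt")
  ix <- integrate_axis(record$ax, dt)
  iy <- integrate_axis(record$ay, dt)
  iz <- integrate_axis(record$az, dt)
  traj <- trajectory(c(0, ix$x), c(0, iy$x), c(0, iz$x), dt = dt, t0 = 0)
  vel <- tibble::tibble(t = record$t, vx = ix$s, vy = iy$s, vz = iz$s)
  list(trajectory = traj, velocity = vel)
}

#' Kalman-filter configuration
#'
#' Parameters of the per-axis linear Kalman filter used to denoise
#' acceleration before dead reckoning.
#'
#' @param process_noise_scale Spectral density of the white-jerk process
#'   noise; scales how fast the filter lets the acceleration state move.
#'   The default corresponds to jerk magnitudes of order 1 m/s^3, typical
#'   of slow rehabilitation movements.
#' @param measurement_noise_var Variance of the acceleration measurement
#'   noise, (m/s^2)^2. Default (0.05)^2.
#' @param initial_state_var Initial diagonal state variance.
#' @return A `kalman_config` list.
#' @export
kalman_config <- function(process_noise_scale = 1,
                          measurement_noise_var = 0.05^2,
                          initial_state_var = 1) {
  stopifnot(process_noise_scale >= 0, measurement_noise_var >= 0,
            initial_state_var >= 0)
  structure(list(process_noise_scale = process_noise_scale,
                 measurement_noise_var = measurement_noise_var,
                 initial_state_var = initial_state_var),
            class = "kalman_config")
}

# One-axis linear Kalman filter with state (position, velocity,
# acceleration). The transition uses the same discretisation as the
# dead-reckoning recurrence (x += v dt + 1.5 a dt^2 with the updated
# velocity), so in the zero-measurement-noise limit the filter reproduces
# integrate_acceleration. The measurement observes acceleration only.
# With `smooth = TRUE` a Rauch-Tung-Striebel backward pass turns the
# causal filter into a zero-phase smoother (records are processed
# offline, so non-causality costs nothing).
kalman_axis <- function(a, dt, cfg, smooth = TRUE) {
  FF <- matrix(c(1, 0, 0,
                 dt, 1, 0,
                 1.5 * dt^2, dt, 1), 3)  # column-major: F[1,] = (1, dt, 1.5dt^2)
  H <- matrix(c(0, 0, 1), 1)
  g <- c(dt^3 / 6, dt^2 / 2, dt)
  Q <- cfg$process_noise_scale * tcrossprod(g)
  R <- cfg$measurement_noise_var
  xhat <- matrix(0, 3, 1)
  P <- diag(cfg$initial_state_var, 3)
  n <- length(a)
  xf <- matrix(0, 3, n); xp <- matrix(0, 3, n)
  Pf <- array(0, c(3, 3, n)); Pp <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    xpred <- FF %*% xhat
    Ppred <- FF %*% P %*% t(FF) + Q
    xp[, i] <- xpred; Pp[, , i] <- Ppred
    S <- drop(H %*% Ppred %*% t(H)) + R
    K <- (Ppred %*% t(H)) / S
    xhat <- xpred + K %*% (a[i] - drop(H %*% xpred))
    P <- (diag(3) - K %*% H) %*% Ppred
    xf[, i] <- xhat; Pf[, , i] <- P
  }
  if (!smooth || n < 2L) return(xf[1, ])
  xs <- xf
  for (i in (n - 1):1) {
    C <- Pf[, , i] %*% t(FF) %*% solve(Pp[, , i + 1])
    xs[, i] <- xf[, i] + C %*% (xs[, i + 1] - xp[, i + 1])
  }
  xs[1, ]
}

#' Kalman-smoothed dead reckoning
#'
#' Runs a per-axis linear Kalman filter with a constant-acceleration
#' kinematic state (position, velocity, acceleration) over the world-frame
#' acceleration measurements and returns the position track; by default a
#' Rauch-Tung-Striebel backward pass is added so the estimate is
#' zero-phase (exercise records are processed offline). The process-noise
#' scale should match the motion regime: of order 1 for active movement
#' (jerk ~ 1 m/s^3), much smaller (~1e-3) for rest-phase data, where the
#' filter's benefit over raw double integration is largest.
#'
#' @param record An `inertial_record` with world-frame accelerations.
#' @param cfg A [kalman_config()].
#' @param smooth Add the backward (RTS) smoothing pass. `FALSE` gives the
#'   causal filter.
#' @return A `trajectory` (N+1 samples, starting at the origin).
#' @export
kalman_smooth <- function(record, cfg = kalman_config(), smooth = TRUE) {
  stopifnot(inherits(record, "inertial_record"), inherits(cfg, "kalman_config"))
  if (!all(is.finite(c(record$ax, record$ay, record$az))))
    stop("non-finite accelerations", call. = FALSE)
  dt <- attr(record, "dt")
  trajectory(c(0, kalman_axis(record$ax, dt, cfg, smooth)),
             c(0, kalman_axis(record$ay, dt, cfg, smooth)),
             c(0, kalman_axis(record$az, dt, cfg, smooth)),
             dt = dt, t0 = 0)
}

#' Full inertial processing chain
#'
#' Rotates samples to the world frame, subtracts gravity, and either
#' dead-reckons directly or runs the Kalman-filtered variant.
#'
#' @param record An `inertial_record`.
#' @param cfg `NULL` for raw double integration, or a [kalman_config()].
#' @return A `trajectory`.
#' @export
process_ins <- function(record, cfg = NULL) {
  world <- rotate_to_world(record)
  rec <- inertial_record(as.matrix(world), dt = attr(record, "dt"))
  if (is.null(cfg)) integrate_acceleration(rec)$trajectory
  else kalman_smooth(rec, cfg)
}
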