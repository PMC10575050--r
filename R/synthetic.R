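#' Noise specification for sensor simulators
#'
#' Magnitudes of the error sources the simulators add on top of
#' ground-truth movement.
#'
#' @param accel_sigma White accelerometer noise, m/s^2. Default 0.05, a
#'   consumer-IMU grade level.
#' @param accel_bias_walk Accelerometer bias random-walk intensity,
#'   m/s^2 per sqrt(s).
#' @param pixel_sigma Keypoint detection jitter, pixels.
#' @param angle_sigma Mocap segment-angle jitter, radians.
#' @param dropout_prob Per-frame probability that a camera loses the
#'   keypoint.
#' @param position_sigma Positional jitter for trajectory-level (tracker
#'   class) records, meters.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(accel_sigma = 0.05, accel_bias_walk = 0.005,
                       pixel_sigma = 1, angle_sigma = 0.01,
                       dropout_prob = 0, position_sigma = 0.005) {
  vals <- c(accel_sigma, accel_bias_walk, pixel_sigma, angle_sigma,
            dropout_prob, position_sigma)
  if (any(vals < 0) || dropout_prob >= 1)
    stop("noise magnitudes must be >= 0 and dropout_prob < 1", call. = FALSE)
  structure(list(accel_sigma = accel_sigma, accel_bias_walk = accel_bias_walk,
                 pixel_sigma = pixel_sigma, angle_sigma = angle_sigma,
                 dropout_prob = dropout_prob, position_sigma = position_sigma),
            class = "noise_spec")
}

#' Exercise templates for the three study tasks
#'
#' Templates describe one repetition's displacement per target point and
#' the repetition-duration law: arm raise to horizontal (wrist, 10 reps,
#' 7.1 +/- 1.7 s), step-up onto a box (foot, 10 reps, 6.3 +/- 1.9 s), and
#' sit-to-stand (lumbar region + neck moving together, 10 reps,
#' 6.1 +/- 1.3 s). Amplitudes are package fixture choices (0.6 m arm
#' raise, 0.2 m step height, 0.45 m rise), not measured values.
#'
#' @param category One of `"arm-raise"`, `"step-up"`, `"sit-stand"`.
#' @param reps Repetition count.
#' @param rep_duration_s `c(mean, sd)` of one repetition's duration,
#'   seconds; defaults per category.
#' @param amplitude Named list: per target point a 3-vector displacement
#'   (m) reached mid-repetition.
#' @param origin Named list of per-point start positions (m).
#' @return An `exercise_template` list.
#' @export
exercise_template <- function(category = c("arm-raise", "step-up", "sit-stand"),
                              reps = 10L, rep_duration_s = NULL,
                              amplitude = NULL, origin = NULL) {
  category <- match.arg(category)
  defaults <- switch(category,
    "arm-raise" = list(dur = c(7.1, 1.7),
                       amp = list(wrist = c(0.30, 0.60, 0)),
                       ori = list(wrist = c(0, 0, 0))),
    "step-up" = list(dur = c(6.3, 1.9),
                     amp = list(foot = c(0.25, 0.20, 0)),
                     ori = list(foot = c(0, 0, 0))),
    "sit-stand" = list(dur = c(6.1, 1.3),
                       amp = list(lumbar = c(0.05, 0.45, 0),
                                  neck = c(0.05, 0.45, 0)),
                       ori = list(lumbar = c(0, 0, 0),
                                  neck = c(0, 0.45, 0)))
  )
  rep_duration_s <- rep_duration_s %||% defaults$dur
  amplitude <- amplitude %||% defaults$amp
  origin <- origin %||% defaults$ori
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  if (any(rep_duration_s <= 0) && rep_duration_s[1] <= 0)
    stop("durations must be positive", call. = FALSE)
  if (!setequal(names(amplitude), names(origin)))
    stop("amplitude and origin must name the same points", call. = FALSE)
  m_expect <- if (category == "sit-stand") 2L else 1L
  if (length(amplitude) != m_expect)
    stop(sprintf("category '%s' tracks %d target point(s)", category, m_expect),
         call. = FALSE)
  structure(list(category = category, reps = as.integer(reps),
                 rep_duration_s = rep_duration_s,
                 amplitude = amplitude, origin = origin),
            class = "exercise_template")
}

# minimum-jerk position profile on [0, 1]
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate a ground-truth exercise recording
#'
#' Builds, per repetition, a smooth minimum-jerk out-and-back profile
#' from the start position to the amplitude endpoint and back, with
#' repetition durations drawn from the template's normal law (truncated
#' below at half the mean). Repetitions are concatenated; for
#' sit-to-stand the two target points move with identical excursion
#' (rigid torso), the neck offset above the lumbar start.
#'
#' @param tmpl An [exercise_template()].
#' @param dt Sampling interval, seconds (default 1/30).
#' @param seed Optional integer seed.
#' @return A labeled `trajectory_set`.
#' @export
generate_exercise <- function(tmpl, dt = 1 / 30, seed = NULL) {
  stopifnot(inherits(tmpl, "exercise_template"))
  if (!is.null(seed)) set.seed(seed)
  mu <- tmpl$rep_duration_s[1]; sdv <- tmpl$rep_duration_s[2]
  durs <- pmax(stats::rnorm(tmpl$reps, mu, sdv), 0.5 * mu)
  # per-rep out-and-back fraction profile; even sample count so the
  # mid-repetition peak is sampled exactly
  prof <- unlist(lapply(durs, function(d) {
    n <- max(4L, 2L * round(d / (2 * dt)))
    tau <- (seq_len(n) - 1) / n
    ifelse(tau < 0.5, min_jerk(2 * tau), min_jerk(2 * (1 - tau)))
  }))
  trajs <- lapply(names(tmpl$amplitude), function(p) {
    a <- tmpl$amplitude[[p]]; o <- tmpl$origin[[p]]
    trajectory(o[1] + a[1] * prof, o[2] + a[2] * prof, o[3] + a[3] * prof,
               dt = dt)
  })
  names(trajs) <- names(tmpl$amplitude)
  trajectory_set(trajs, label = tmpl$category)
}

#' Simulate an inertial record from a ground-truth trajectory
#'
#' Accelerations are the exact algebraic inverse of the dead-reckoning
#' recurrence (velocity update first, position update with the updated
#' velocity plus a dt^2/2), so with zero noise [integrate_acceleration()]
#' reproduces the source trajectory, relative to its start, to machine
#' precision. White noise and a bias random walk are then added;
#' orientation angles are zero (world-aligned device).
#'
#' @param truth A `trajectory` with at least 3 samples.
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed.
#' @param mode `"recurrence"` (exact inverse, default) or `"physical"`
#'   (central-difference accelerations, for robustness experiments).
#' @return An `inertial_record` with `N - 1` samples.
#' @export
simulate_ins <- function(truth, noise = noise_spec(), seed = NULL,
                         mode = c("recurrence", "physical")) {
  mode <- match.arg(mode)
  truth <- as_trajectory(truth)
  if (nrow(truth) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- trajectory_dt(truth)
  p <- sweep(traj_matrix(truth), 2, as.numeric(traj_matrix(truth)[1, ]))
  n <- nrow(p)
  acc <- matrix(0, n - 1, 3)
  if (mode == "recurrence") {
    s <- c(0, 0, 0)
    for (i in 2:n) {
      a <- (p[i, ] - p[i - 1, ] - s * dt) / (1.5 * dt^2)
      s <- s + a * dt
      acc[i - 1, ] <- a
    }
  } else {
    # second central differences, padded at the end
    dd <- diff(p, differences = 2) / dt^2
    acc <- rbind(dd, dd[nrow(dd), ])
  }
  if (noise$accel_sigma > 0)
    acc <- acc + matrix(stats::rnorm(length(acc), 0, noise$accel_sigma),
                        nrow(acc))
  if (noise$accel_bias_walk > 0) {
    bw <- apply(matrix(stats::rnorm(length(acc), 0,
                                    noise$accel_bias_walk * sqrt(dt)),
                       nrow(acc)), 2, cumsum)
    acc <- acc + bw
  }
  inertial_record(acc, dt = dt)
}

#' Simulate mocap frames from a joint-angle program
#'
#' Builds a frame sequence from given per-segment angle trajectories plus
#' white angle noise, and returns the noise-free forward-kinematics
#' trajectory of one attachment as ground truth.
#'
#' @param angles `N x (3 Nb)` matrix (or `N x Nb x 3` array) of absolute
#'   segment angles, radians, in skeleton order.
#' @param skeleton A `skeleton_model`.
#' @param point_name Attachment whose trajectory is the ground truth.
#' @param dt Frame interval, seconds.
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed.
#' @param base N x 6 base-pose matrix; defaults to a static base at the
#'   origin.
#' @return List with `frames` (noisy `mocap_frames`) and `truth`
#'   (noise-free `trajectory`).
#' @export
simulate_mocap <- function(angles, skeleton, point_name, dt,
                           noise = noise_spec(), seed = NULL, base = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(dim(angles)) != 3L) angles <- as.matrix(angles)
  n <- if (is.matrix(angles)) nrow(angles) else dim(angles)[1]
  if (is.null(base)) base <- matrix(0, n, 6)
  clean <- mocap_frames(base, angles, skeleton$segments$name)
  truth <- extract_target_point(clean, skeleton, point_name, dt)
  noisy_rot <- clean$rotations +
    array(stats::rnorm(length(clean$rotations), 0, noise$angle_sigma),
          dim(clean$rotations))
  noisy <- mocap_frames(base, noisy_rot, skeleton$segments$name)
  list(frames = noisy, truth = truth)
}

#' A default orthogonal two-camera rig
#'
#' Front camera on the world Z axis and side camera on the world X axis,
#' both 2.5 m from the origin and looking at it; 1920 x 1080 frames with
#' 1000 px focal length.
#'
#' @return List with `cam1`, `cam2` (`camera_model`s) and `frame_size`.
#' @export
default_rig <- function() {
  list(
    cam1 = camera_model(1000, 1000, 960, 540,
                        rotation = diag(3), translation = c(0, 0, 2.5)),
    cam2 = camera_model(1000, 1000, 960, 540,
                        rotation = rot_y(pi / 2), translation = c(0, 0, 2.5)),
    frame_size = c(1920, 1080)
  )
}

#' Simulate per-camera keypoint streams from ground-truth trajectories
#'
#' Projects every target point through both cameras, adds pixel jitter,
#' and drops frames independently with the dropout probability. Pixels
#' are clamped to the image frame.
#'
#' @param truth A `trajectory_set`.
#' @param cam1,cam2 `camera_model`s.
#' @param frame_size `c(cxmax, cymax)`, pixels.
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed.
#' @return List of two `keypoint_frames` (`cam1`, `cam2`).
#' @export
simulate_vision <- function(truth, cam1, cam2, frame_size = c(1920, 1080),
                            noise = noise_spec(), seed = NULL) {
  stopifnot(inherits(truth, "trajectory_set"))
  if (!is.null(seed)) set.seed(seed)
  pts <- set_points(truth)
  MP1 <- projection_matrix(cam1); MP2 <- projection_matrix(cam2)
  one_cam <- function(MP) {
    rows <- lapply(names(pts), function(p) {
      m <- traj_matrix(pts[[p]])
      uv <- t(apply(m, 1, function(X) {
        h <- drop(MP %*% c(X, 1))
        if (h[3] <= 0) stop("non-positive depth in simulated camera", call. = FALSE)
        h[1:2] / h[3]
      }))
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noise$pixel_sigma), nrow(uv))
      uv[, 1] <- pmin(pmax(uv[, 1], 0), frame_size[1])
      uv[, 2] <- pmin(pmax(uv[, 2], 0), frame_size[2])
      drop_mask <- stats::runif(nrow(uv)) < noise$dropout_prob
      uv[drop_mask, ] <- NA_real_
      tibble::tibble(frame = seq_len(nrow(uv)), point = p,
                     u = uv[, 1], v = uv[, 2])
    })
    keypoint_frames(dplyr::bind_rows(rows), frame_size)
  }
  list(cam1 = one_cam(MP1), cam2 = one_cam(MP2))
}

#' Generate a balanced labeled benchmark collection
#'
#' Emits `n_per_class` single-point records for each of the three
#' exercise categories, with per-record amplitude jitter (+/- 15%),
#' repetition durations drawn from each task's duration law, and
#' tracker-grade positional noise. For sit-to-stand the lumbar and neck
#' points alternate across records, mirroring their separate treatment in
#' classification. Deterministic given `seed`.
#'
#' @param n_per_class Records per category (>= 1).
#' @param dt Sampling interval, seconds.
#' @param noise A [noise_spec()]; `position_sigma` is applied to the
#'   coordinates.
#' @param seed Integer seed.
#' @param reps Repetitions per record.
#' @return A record collection tibble (see [record_collection()]).
#' @export
generate_benchmark <- function(n_per_class, dt = 1 / 30,
                               noise = noise_spec(), seed = 1L, reps = 10L) {
  stopifnot(n_per_class >= 1L)
  set.seed(seed)
  sets <- list()
  for (cat in c("arm-raise", "step-up", "sit-stand")) {
    base_tmpl <- exercise_template(cat, reps = reps)
    for (i in seq_len(n_per_class)) {
      scale <- stats::runif(1, 0.85, 1.15)
      amp <- lapply(base_tmpl$amplitude, function(a) a * scale)
      tmpl <- exercise_template(cat, reps = reps, amplitude = amp,
                                origin = base_tmpl$origin)
      ts <- generate_exercise(tmpl, dt = dt)
      pts <- set_points(ts)
      keep <- if (cat == "sit-stand") {
        if (i %% 2L == 1L) "lumbar" else "neck"
      } else names(pts)[1]
      tr <- pts[[keep]]
      m <- traj_matrix(tr)
      if (noise$position_sigma > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, noise$position_sigma),
                        nrow(m))
      sets[[length(sets) + 1L]] <-
        trajectory_set(stats::setNames(
          list(trajectory(m[, 1], m[, 2], m[, 3], dt = dt)), "target"),
          label = cat)
    }
  }
  record_collection(sets)
}
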