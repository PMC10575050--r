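#' Pinhole camera model
#'
#' Intrinsics (focal lengths and principal point, pixels) plus the
#' world-to-camera rigid transform (rotation, translation).
#'
#' @param fx,fy Focal lengths, pixels (> 0).
#' @param cx,cy Principal point, pixels.
#' @param rotation 3 x 3 orthonormal world-to-camera rotation.
#' @param translation Length-3 translation vector.
#' @return A `camera_model` list.
#' @export
camera_model <- function(fx, fy, cx, cy, rotation = diag(3),
                         translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(fx > 0, fy > 0, all(dim(rotation) == c(3, 3)),
            length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 rotation = rotation, translation = as.double(translation)),
            class = "camera_model")
}

#' Read a camera model from JSON
#'
#' Format: `{fx,fy,cx,cy,R:[[..],[..],[..]],T:[..]}` (R in row-major order).
#' @param path File path.
#' @return A `camera_model`.
#' @export
read_camera <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(j$fx, j$fy, j$cx, j$cy,
               rotation = matrix(unlist(j$R), 3, 3, byrow = TRUE),
               translation = unlist(j$T))
}

#' Pixels-per-meter scale from a body segment of known length
#'
#' Single- and dual-camera metric conversion hinges on relating an
#' observed segment length in pixels to its measured real length.
#'
#' @param pixel_len Observed segment length, pixels (> 0). For keypoints
#'   in normalised coordinates, denormalise with the frame size first.
#' @param real_len Measured segment length, meters (> 0).
#' @return Scale in pixels per meter.
#' @export
scale_from_segment <- function(pixel_len, real_len) {
  if (!is.numeric(pixel_len) || !is.numeric(real_len) ||
      pixel_len <= 0 || real_len <= 0)
    stop("segment lengths must be positive", call. = FALSE)
  pixel_len / real_len
}

#' Keypoint frames container
#'
#' Per-camera 2-D keypoints over time in tidy form. Normalised
#' coordinates (0-1) are converted to pixels using the frame size.
#'
#' @param df Data frame with columns `frame`, `point`, `u`, `v`.
#' @param frame_size `c(cxmax, cymax)` in pixels.
#' @param normalized Whether `u`, `v` are normalised to 0-1.
#' @return A `keypoint_frames` tibble with pixel coordinates and a
#'   `frame_size` attribute.
#' @export
keypoint_frames <- function(df, frame_size, normalized = FALSE) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("frame", "point", "u", "v") %in% names(df)),
            length(frame_size) == 2L, all(frame_size > 0))
  if (normalized) {
    df$u <- df$u * frame_size[1]
    df$v <- df$v * frame_size[2]
  }
  ok <- is.na(df$u) | (df$u >= 0 & df$u <= frame_size[1] &
                       df$v >= 0 & df$v <= frame_size[2])
  if (!all(ok))
    stop("keypoints outside the image frame", call. = FALSE)
  attr(df, "frame_size") <- as.double(frame_size)
  class(df) <- c("keypoint_frames", class(df))
  df
}

# pixel track for one point over n_frames; NA where missing; linear
# interpolation across gaps of at most max_gap frames.
keypoint_track <- function(kf, point_name, max_gap = 5L) {
  sub <- kf[kf$point == point_name & !is.na(kf$u), ]
  if (nrow(sub) == 0L) stop("point never detected", call. = FALSE)
  frames <- sort(unique(kf$frame))
  u <- v <- rep(NA_real_, length(frames))
  m <- match(sub$frame, frames)
  u[m] <- sub$u; v[m] <- sub$v
  gap_runs <- rle(is.na(u))
  if (any(gap_runs$lengths[gap_runs$values] > max_gap))
    stop(sprintf("keypoint gap exceeds %d frames; record invalid", max_gap),
         call. = FALSE)
  if (anyNA(u)) {
    idx <- seq_along(u)
    u <- stats::approx(idx[!is.na(u)], u[!is.na(u)], xout = idx, rule = 2)$y
    v <- stats::approx(idx[!is.na(v)], v[!is.na(v)], xout = idx, rule = 2)$y
  }
  list(u = u, v = v)
}

#' Metric 3-D point from two orthogonal cameras
#'
#' For a front camera (1) and a side camera (2) mounted orthogonally and
#' axis-aligned, converts pixel observations of one point into meters:
#' `px = cx1/kx`, `py = (cymax - (cy1 + cy2)/2)/ky`,
#' `pz = (cxmax - cx2)/kx`. Image rows grow downward, so the
#' `cymax - v` flip makes world Y grow upward; depth comes from the side
#' camera's horizontal coordinate.
#'
#' @param uv1,uv2 Length-2 pixel coordinates `(u, v)` of the point in the
#'   front and side cameras.
#' @param frame_size `c(cxmax, cymax)`, pixels.
#' @param kx,ky Pixels-per-meter scales (see [scale_from_segment()]).
#' @return Numeric length-3 vector `(px, py, pz)` in meters.
#' @export
dual_camera_point <- function(uv1, uv2, frame_size, kx, ky) {
  stopifnot(length(uv1) == 2L, length(uv2) == 2L, kx > 0, ky > 0)
  if (anyNA(uv1) || anyNA(uv2))
    stop("point missing in one of the frames", call. = FALSE)
  c(uv1[1] / kx,
    (frame_size[2] - 0.5 * (uv1[2] + uv2[2])) / ky,
    (frame_size[1] - uv2[1]) / kx)
}

#' Metric trajectory from two orthogonal cameras
#'
#' Applies [dual_camera_point()] frame by frame, interpolating detection
#' gaps of at most `max_gap` frames per camera.
#'
#' @param kf1,kf2 `keypoint_frames` for the front and side cameras, with
#'   identical frame grids.
#' @param point_name Keypoint to reconstruct.
#' @param kx,ky Pixels-per-meter scales.
#' @param dt Sampling interval, seconds.
#' @param max_gap Longest interpolatable detection gap, frames.
#' @return A `trajectory`.
#' @export
dual_camera_metric <- function(kf1, kf2, point_name, kx, ky, dt,
                               max_gap = 5L) {
  fs <- attr(kf1, "frame_size")
  t1 <- keypoint_track(kf1, point_name, max_gap)
  t2 <- keypoint_track(kf2, point_name, max_gap)
  if (length(t1$u) != length(t2$u))
    stop("cameras must share the frame grid", call. = FALSE)
  pts <- t(vapply(seq_along(t1$u), function(i) {
    dual_camera_point(c(t1$u[i], t1$v[i]), c(t2$u[i], t2$v[i]), fs, kx, ky)
  }, numeric(3)))
  trajectory(pts[, 1], pts[, 2], pts[, 3], dt = dt)
}

#' Planar (single-camera) trajectory
#'
#' Tracks a point in the image plane only: `x = u/kx`,
#' `y = (cymax - v)/ky`, `z = 0`.
#'
#' @inheritParams dual_camera_metric
#' @param kf A `keypoint_frames`.
#' @return A `trajectory` with `z` identically zero.
#' @export
single_camera_2d <- function(kf, point_name, kx, ky, dt, max_gap = 5L) {
  fs <- attr(kf, "frame_size")
  tr <- keypoint_track(kf, point_name, max_gap)
  trajectory(tr$u / kx, (fs[2] - tr$v) / ky, rep(0, length(tr$u)), dt = dt)
}

#' 3 x 4 projection matrix of a camera
#'
#' `MP = MA [R | T]` with `MA` the intrinsic matrix.
#'
#' @param cam A `camera_model`.
#' @return A 3 x 4 matrix of rank 3.
#' @export
projection_matrix <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  MA <- matrix(c(cam$fx, 0, 0,
                 0, cam$fy, 0,
                 cam$cx, cam$cy, 1), 3)
  MA %*% cbind(cam$rotation, cam$translation)
}

#' Project a 3-D point to pixel coordinates
#'
#' Homogeneous projection `w (u, v, 1)^T = MP (X, 1)^T`.
#'
#' @param MP A 3 x 4 projection matrix.
#' @param X Length-3 world point.
#' @return Length-2 pixel coordinates `(u, v)`.
#' @export
project_point <- function(MP, X) {
  stopifnot(all(dim(MP) == c(3, 4)), length(X) == 3L)
  h <- drop(MP %*% c(X, 1))
  if (abs(h[3]) < 1e-12)
    stop("degenerate depth: point on the camera's principal plane", call. = FALSE)
  h[1:2] / h[3]
}

#' Triangulate a 3-D point from two or more views (DLT)
#'
#' Stacks, per camera, the homogeneous constraints
#' `u mp3^T X - mp1^T X = 0` and `v mp3^T X - mp2^T X = 0` and solves the
#' homogeneous least-squares system with the singular value decomposition,
#' returning the dehomogenised minimiser of the algebraic error.
#'
#' @param observations List of `list(uv = c(u, v), MP = 3x4 matrix)`, one
#'   per camera (at least two, in general position).
#' @return Length-3 world point, meters.
#' @export
triangulate <- function(observations) {
  stopifnot(is.list(observations), length(observations) >= 2L)
  A <- do.call(rbind, lapply(observations, function(ob) {
    MP <- ob$MP; uv <- ob$uv
    rbind(uv[1] * MP[3, ] - MP[1, ],
          uv[2] * MP[3, ] - MP[2, ])
  }))
  sv <- svd(A)
  if (sv$d[3] / sv$d[1] < 1e-10)
    stop("degenerate geometry: rays nearly parallel", call. = FALSE)
  X <- sv$v[, 4]
  if (abs(X[4]) < 1e-12)
    stop("degenerate geometry: point at infinity", call. = FALSE)
  X[1:3] / X[4]
}

# camera center (null space of the projection matrix), inhomogeneous
camera_center <- function(MP) {
  sv <- svd(MP, nu = 3, nv = 4)
  C <- sv$v[, 4]
  if (abs(C[4]) < 1e-12) stop("camera center at infinity", call. = FALSE)
  C[1:3] / C[4]
}

#' Fundamental matrix of a two-camera rig
#'
#' Builds the rank-2 matrix `MF` with `x2^T MF x1 = 0` for all
#' corresponding homogeneous image points, from the two projection
#' matrices: `MF = [e2]_x MP2 MP1^+`, where `e2` is the epipole (the image
#' of camera 1's center in camera 2) and `MP1^+` the pseudo-inverse.
#'
#' @param cam1,cam2 `camera_model`s with distinct centers.
#' @return A 3 x 3 matrix of rank 2.
#' @export
fundamental_matrix <- function(cam1, cam2) {
  MP1 <- projection_matrix(cam1)
  MP2 <- projection_matrix(cam2)
  C1 <- camera_center(MP1)
  C2 <- camera_center(MP2)
  if (sqrt(sum((C1 - C2)^2)) < 1e-12)
    stop("degenerate geometry: coincident camera centers", call. = FALSE)
  e2 <- drop(MP2 %*% c(C1, 1))
  ex <- matrix(c(0, e2[3], -e2[2],
                 -e2[3], 0, e2[1],
                 e2[2], -e2[1], 0), 3)
  # Moore-Penrose pseudo-inverse of MP1 via SVD
  sv <- svd(MP1)
  dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
  MP1p <- sv$v %*% diag(dinv) %*% t(sv$u)
  MF <- ex %*% MP2 %*% MP1p
  MF / sqrt(sum(MF^2))  # canonical scale (defined up to a constant)
}
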