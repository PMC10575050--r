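# Per-segment / base rotation from an (ax, ay, az) angle triple,
# composed Rz(az) %*% Ry(ay) %*% Rx(ax).
rot_zyx <- function(ax, ay, az) rot_z(az) %*% rot_y(ay) %*% rot_x(ax)

#' Define a sized skeleton model
#'
#' A motion-capture suit reports one base point (on the back) plus per
#' segment rotation angles; converting those into metric target-point
#' positions requires a sized body model: a tree of rigid segments, each
#' with a length and a rest direction, and attachment points that pin a
#' target point to a segment at a fixed offset.
#'
#' @param segments Data frame with columns `name`, `parent` (`NA` for
#'   segments hanging off the base), `length` (m, > 0), and `dx`, `dy`,
#'   `dz` (rest direction; normalised internally).
#' @param attachments Data frame with columns `point`, `segment`, and
#'   `ox`, `oy`, `oz` (offset from the segment start, m).
#' @return A `skeleton_model` list with tibbles `segments` and
#'   `attachments`.
#' @export
skeleton_model <- function(segments, attachments) {
  segments <- tibble::as_tibble(segments)
  attachments <- tibble::as_tibble(attachments)
  stopifnot(all(c("name", "parent", "length", "dx", "dy", "dz") %in% names(segments)),
            all(c("point", "segment", "ox", "oy", "oz") %in% names(attachments)))
  if (any(segments$length <= 0)) stop("segment lengths must be positive", call. = FALSE)
  if (anyDuplicated(segments$name)) stop("duplicate segment names", call. = FALSE)
  bad_parent <- !is.na(segments$parent) & !segments$parent %in% segments$name
  if (any(bad_parent)) stop("unknown parent segment", call. = FALSE)
  # normalise rest directions; reject cycles by walking every chain to base
  nrm <- sqrt(segments$dx^2 + segments$dy^2 + segments$dz^2)
  if (any(nrm == 0)) stop("rest directions must be nonzero", call. = FALSE)
  segments$dx <- segments$dx / nrm; segments$dy <- segments$dy / nrm
  segments$dz <- segments$dz / nrm
  idx <- stats::setNames(seq_len(nrow(segments)), segments$name)
  for (s in segments$name) {
    seen <- character(0); cur <- s
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cyclic segment hierarchy", call. = FALSE)
      seen <- c(seen, cur)
      cur <- segments$parent[idx[[cur]]]
    }
  }
  if (any(!attachments$segment %in% segments$name))
    stop("attachment references unknown segment", call. = FALSE)
  structure(list(segments = segments, attachments = attachments),
            class = "skeleton_model")
}

#' Read / write a skeleton model as JSON
#'
#' Format: `{segments:[{name,parent,length,dir:[dx,dy,dz]}],
#' attachments:{point:{segment,offset:[ox,oy,oz]}}}`.
#'
#' @param path File path.
#' @return A `skeleton_model` (for the reader); `path` invisibly (writer).
#' @export
read_skeleton <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- dplyr::bind_rows(lapply(j$segments, function(s) {
    p <- s$parent
    tibble::tibble(name = s$name,
                   parent = if (is.null(p) || length(p) == 0L || is.na(p[[1]]))
                     NA_character_ else as.character(p),
                   length = s$length,
                   dx = s$dir[[1]], dy = s$dir[[2]], dz = s$dir[[3]])
  }))
  atts <- dplyr::bind_rows(lapply(names(j$attachments), function(p) {
    a <- j$attachments[[p]]
    tibble::tibble(point = p, segment = a$segment,
                   ox = a$offset[[1]], oy = a$offset[[2]], oz = a$offset[[3]])
  }))
  skeleton_model(segs, atts)
}

#' @rdname read_skeleton
#' @param skeleton A `skeleton_model`.
#' @export
write_skeleton <- function(skeleton, path) {
  segs <- lapply(seq_len(nrow(skeleton$segments)), function(i) {
    s <- skeleton$segments[i, ]
    list(name = s$name,
         parent = if (is.na(s$parent)) NA else s$parent,
         length = s$length, dir = c(s$dx, s$dy, s$dz))
  })
  atts <- stats::setNames(lapply(seq_len(nrow(skeleton$attachments)), function(i) {
    a <- skeleton$attachments[i, ]
    list(segment = a$segment, offset = c(a$ox, a$oy, a$oz))
  }), skeleton$attachments$point)
  jsonlite::write_json(list(segments = segs, attachments = atts), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle a motion-capture frame sequence
#'
#' @param base N x 6 matrix / data frame: base position (m) and base
#'   rotation angles (rad) per frame, columns `bx,by,bz,bax,bay,baz`.
#' @param rotations N x (3 Nb) matrix of per-segment angle triples in
#'   skeleton segment order, or an N x Nb x 3 array.
#' @param segment_names Character vector of segment names (length Nb).
#' @param mode `"absolute"`: angles are absolute per-frame rotations;
#'   `"incremental"`: angles are deltas relative to the previous frame and
#'   are accumulated before use.
#' @return A `mocap_frames` object.
#' @export
mocap_frames <- function(base, rotations, segment_names,
                         mode = c("absolute", "incremental")) {
  mode <- match.arg(mode)
  base <- as.matrix(base)
  stopifnot(ncol(base) == 6L)
  if (length(dim(rotations)) == 3L) {
    arr <- rotations
  } else {
    rotations <- as.matrix(rotations)
    stopifnot(ncol(rotations) == 3L * length(segment_names))
    arr <- array(0, c(nrow(rotations), length(segment_names), 3))
    for (k in seq_along(segment_names))
      arr[, k, ] <- rotations[, (3 * k - 2):(3 * k), drop = FALSE]
  }
  stopifnot(dim(arr)[1] == nrow(base), dim(arr)[2] == length(segment_names))
  if (!all(is.finite(base)) || !all(is.finite(arr)))
    stop("mocap frames must be finite", call. = FALSE)
  if (mode == "incremental") arr <- array(apply(arr, c(2, 3), cumsum), dim(arr))
  structure(list(base = base, rotations = arr,
                 segment_names = as.character(segment_names)),
            class = "mocap_frames")
}

#' @export
print.mocap_frames <- function(x, ...) {
  cat(sprintf("# Mocap frames: %d frames, %d segments (%s)\n",
              nrow(x$base), length(x$segment_names),
              paste(x$segment_names, collapse = ", ")))
  invisible(x)
}

# chain rotations and start/end positions for one frame
fk_frame <- function(base_pose, angles, skeleton) {
  segs <- skeleton$segments
  idx <- stats::setNames(seq_len(nrow(segs)), segs$name)
  base_pos <- base_pose[1:3]
  R_base <- rot_zyx(base_pose[4], base_pose[5], base_pose[6])
  R_chain <- vector("list", nrow(segs))
  start <- matrix(NA_real_, nrow(segs), 3)
  end <- matrix(NA_real_, nrow(segs), 3)
  done <- rep(FALSE, nrow(segs))
  solve_seg <- function(i) {
    if (done[i]) return(invisible())
    p <- segs$parent[i]
    if (is.na(p)) {
      R_par <- R_base
      s <- base_pos
    } else {
      j <- idx[[p]]
      solve_seg(j)
      R_par <- R_chain[[j]]
      s <- end[j, ]
    }
    R_own <- rot_zyx(angles[i, 1], angles[i, 2], angles[i, 3])
    R <- R_par %*% R_own
    R_chain[[i]] <<- R
    start[i, ] <<- s
    end[i, ] <<- s + drop(R %*% (segs$length[i] * c(segs$dx[i], segs$dy[i], segs$dz[i])))
    done[i] <<- TRUE
  }
  for (i in seq_len(nrow(segs))) solve_seg(i)
  list(start = start, end = end, R_chain = R_chain, idx = idx)
}

#' Forward kinematics for one frame
#'
#' Propagates the base pose through the segment tree: each segment starts
#' where its parent ends (or at the base point), and its end is the start
#' plus the chain-rotated, length-scaled rest direction. Chain rotation
#' composes the base rotation with every ancestor's own rotation,
#' parent-to-child.
#'
#' @param frames A `mocap_frames` object.
#' @param skeleton A `skeleton_model` whose segment order matches
#'   `frames$segment_names`.
#' @param frame_index Which frame to solve (1-based).
#' @return A tibble with one row per segment: `segment`, start (`sx,sy,sz`)
#'   and end (`ex,ey,ez`) positions in meters.
#' @export
forward_kinematics <- function(frames, skeleton, frame_index = 1L) {
  stopifnot(inherits(frames, "mocap_frames"), inherits(skeleton, "skeleton_model"))
  if (!identical(frames$segment_names, skeleton$segments$name))
    stop("frame segment order must match the skeleton", call. = FALSE)
  ang <- array(frames$rotations[frame_index, , , drop = FALSE],
               dim = dim(frames$rotations)[2:3])
  fk <- fk_frame(frames$base[frame_index, ], ang, skeleton)
  tibble::tibble(
    segment = skeleton$segments$name,
    sx = fk$start[, 1], sy = fk$start[, 2], sz = fk$start[, 3],
    ex = fk$end[, 1], ey = fk$end[, 2], ez = fk$end[, 3]
  )
}

#' Extract a target-point trajectory from mocap frames
#'
#' For every frame the target point is the attached segment's start
#' position plus the attachment offset. With `rotate_offsets = TRUE`
#' (default) the offset co-rotates with the segment (rigid attachment);
#' with `FALSE` it is added as a world-frame constant.
#'
#' @param frames A `mocap_frames` object.
#' @param skeleton A `skeleton_model`.
#' @param point_name Name of the attachment to extract.
#' @param dt Sampling interval of the frame sequence, seconds.
#' @param rotate_offsets Whether attachment offsets co-rotate with their
#'   segment.
#' @return A `trajectory`.
#' @export
extract_target_point <- function(frames, skeleton, point_name, dt,
                                 rotate_offsets = TRUE) {
  stopifnot(inherits(frames, "mocap_frames"), inherits(skeleton, "skeleton_model"))
  att <- skeleton$attachments[skeleton$attachments$point == point_name, ]
  if (nrow(att) == 0L)
    stop(sprintf("unknown target point '%s'", point_name), call. = FALSE)
  off <- c(att$ox, att$oy, att$oz)
  n <- nrow(frames$base)
  out <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    ang <- array(frames$rotations[f, , , drop = FALSE],
                 dim = dim(frames$rotations)[2:3])
    fk <- fk_frame(frames$base[f, ], ang, skeleton)
    i <- fk$idx[[att$segment]]
    delta <- if (rotate_offsets) drop(fk$R_chain[[i]] %*% off) else off
    out[f, ] <- fk$start[i, ] + delta
  }
  trajectory(out[, 1], out[, 2], out[, 3], dt = dt)
}
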