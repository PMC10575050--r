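test_that("forward kinematics matches closed-form geometry", {
  one <- skeleton_model(
    data.frame(name = "arm", parent = NA, length = 1, dx = 1, dy = 0, dz = 0),
    data.frame(point = "tip", segment = "arm", ox = 0, oy = 0, oz = 0))
  rest <- mocap_frames(matrix(0, 1, 6), matrix(0, 1, 3), "arm")
  fk <- forward_kinematics(rest, one)
  expect_equal(c(fk$ex, fk$ey, fk$ez), c(1, 0, 0))

  quarter <- mocap_frames(matrix(0, 1, 6), matrix(c(0, 0, pi / 2), 1), "arm")
  fkq <- forward_kinematics(quarter, one)
  expect_equal(c(fkq$ex, fkq$ey, fkq$ez), c(0, 1, 0), tolerance = 1e-12)

  two <- two_link_skeleton()
  fr <- mocap_frames(matrix(0, 1, 6),
                     matrix(c(0, 0, pi / 6, 0, 0, pi / 4), 1),
                     c("upper", "fore"))
  fk2 <- forward_kinematics(fr, two)
  expect_equal(fk2$ex[2], 0.3 * cos(pi / 6) + 0.25 * cos(pi / 6 + pi / 4),
               tolerance = 1e-9)
  expect_equal(fk2$ey[2], 0.3 * sin(pi / 6) + 0.25 * sin(pi / 6 + pi / 4),
               tolerance = 1e-9)
  expect_equal(fk2$ez[2], 0, tolerance = 1e-12)
})

test_that("segments are rigid and the rest pose is reproduced under random motion", {
  sk <- skeleton_model(
    data.frame(name = c("torso", "upper", "fore"),
               parent = c(NA, "torso", "upper"),
               length = c(0.5, 0.3, 0.25),
               dx = c(0, 1, 1), dy = c(1, 0, 0), dz = c(0, 0, 0)),
    data.frame(point = "wrist", segment = "fore", ox = 0.02, oy = -0.01, oz = 0))
  set.seed(31)
  n <- 200
  base <- cbind(matrix(rnorm(n * 3, 0, 0.2), n), matrix(rnorm(n * 3, 0, 1), n))
  ang <- matrix(rnorm(n * 9, 0, 1.5), n)
  frames <- mocap_frames(base, ang, sk$segments$name)
  worst <- 0
  for (f in seq_len(n)) {
    fk <- forward_kinematics(frames, sk, f)
    len <- sqrt((fk$ex - fk$sx)^2 + (fk$ey - fk$sy)^2 + (fk$ez - fk$sz)^2)
    worst <- max(worst, max(abs(len - sk$segments$length)))
  }
  expect_lt(worst, 1e-9)

  # rest pose: zero angles give the chained rest directions exactly
  rest <- mocap_frames(matrix(0, 1, 6), matrix(0, 1, 9), sk$segments$name)
  fr <- forward_kinematics(rest, sk)
  expect_equal(fr$ey[1], 0.5)
  expect_equal(fr$ex[2], 0.3)
  expect_equal(c(fr$sx[2], fr$sy[2]), c(0, 0.5))
})

test_that("doubling lengths and offsets doubles coordinates relative to the base", {
  mk <- function(scale) skeleton_model(
    data.frame(name = c("a", "b"), parent = c(NA, "a"),
               length = scale * c(0.4, 0.3),
               dx = c(1, 0), dy = c(0, 1), dz = c(0, 0)),
    data.frame(point = "p", segment = "b",
               ox = scale * 0.05, oy = 0, oz = scale * 0.02))
  set.seed(8)
  ang <- matrix(rnorm(30 * 6, 0, 1), 30)
  base <- matrix(0, 30, 6)
  f1 <- mocap_frames(base, ang, c("a", "b"))
  t1 <- extract_target_point(f1, mk(1), "p", dt = 0.1)
  t2 <- extract_target_point(f1, mk(2), "p", dt = 0.1)
  expect_equal(2 * as.matrix(t1[c("x", "y", "z")]),
               as.matrix(t2[c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("target-point extraction handles rotating and constant offsets", {
  one <- skeleton_model(
    data.frame(name = "arm", parent = NA, length = 0.3, dx = 1, dy = 0, dz = 0),
    data.frame(point = "mark", segment = "arm", ox = 0, oy = 0.1, oz = 0))
  n <- 10
  sweep_z <- seq(0, pi / 2, length.out = n)
  frames <- mocap_frames(matrix(0, n, 6),
                         cbind(0, 0, sweep_z), "arm")
  tr <- extract_target_point(frames, one, "mark", dt = 0.1)
  # co-rotating offset: (0, 0.1, 0) rotated by Rz(theta)
  expect_equal(tr$x, -0.1 * sin(sweep_z), tolerance = 1e-9)
  expect_equal(tr$y, 0.1 * cos(sweep_z), tolerance = 1e-9)

  trc <- extract_target_point(frames, one, "mark", dt = 0.1,
                              rotate_offsets = FALSE)
  expect_equal(trc$x, rep(0, n), tolerance = 1e-12)
  expect_equal(trc$y, rep(0.1, n), tolerance = 1e-12)

  # zero offset equals the segment start; static frames give a constant
  zero_off <- skeleton_model(one$segments,
                             data.frame(point = "mark", segment = "arm",
                                        ox = 0, oy = 0, oz = 0))
  static <- mocap_frames(matrix(c(1, 2, 3, 0, 0, 0), 5, 6, byrow = TRUE),
                         matrix(0.3, 5, 3), "arm")
  trs <- extract_target_point(static, zero_off, "mark", dt = 0.1)
  expect_equal(unique(round(trs$x, 12)), 1)
  expect_equal(unique(round(trs$y, 12)), 2)

  expect_error(extract_target_point(frames, one, "nope", dt = 0.1), "unknown")
})

test_that("incremental rotation mode accumulates angle deltas", {
  # tip = segment start + co-rotated offset of one arm length
  one <- skeleton_model(
    data.frame(name = "arm", parent = NA, length = 1, dx = 1, dy = 0, dz = 0),
    data.frame(point = "tip", segment = "arm", ox = 1, oy = 0, oz = 0))
  inc <- mocap_frames(matrix(0, 3, 6),
                      matrix(c(0, 0, pi / 6), 3, 3, byrow = TRUE), "arm",
                      mode = "incremental")
  tr <- extract_target_point(inc, one, "tip", dt = 1)
  expect_equal(tr$x, cos(pi / 6 * (1:3)), tolerance = 1e-12)
  expect_equal(tr$y, sin(pi / 6 * (1:3)), tolerance = 1e-12)
  # absolute mode, same angles, no accumulation
  ab <- mocap_frames(matrix(0, 3, 6),
                     matrix(c(0, 0, pi / 6), 3, 3, byrow = TRUE), "arm")
  tra <- extract_target_point(ab, one, "tip", dt = 1)
  expect_equal(tra$x, rep(cos(pi / 6), 3), tolerance = 1e-12)
})

test_that("skeletons validate their tree and round-trip through JSON", {
  expect_error(skeleton_model(
    data.frame(name = c("a", "b"), parent = c("b", "a"), length = c(1, 1),
               dx = c(1, 1), dy = c(0, 0), dz = c(0, 0)),
    data.frame(point = "p", segment = "a", ox = 0, oy = 0, oz = 0)),
    "cyclic")
  sk <- two_link_skeleton()
  tf <- withr::local_tempfile(fileext = ".json")
  write_skeleton(sk, tf)
  back <- read_skeleton(tf)
  expect_equal(back$segments$length, sk$segments$length)
  expect_equal(back$attachments$segment, sk$attachments$segment)
})
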