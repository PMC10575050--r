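test_that("generated exercises reach their amplitude and repeat cleanly", {
  tmpl <- exercise_template("arm-raise", reps = 1,
                            rep_duration_s = c(4, 0),
                            amplitude = list(wrist = c(0, 0.6, 0)),
                            origin = list(wrist = c(0, 0, 0)))
  ts <- generate_exercise(tmpl, dt = 1 / 30, seed = 1)
  tr <- set_points(ts)$wrist
  expect_lt(abs(max(tr$y) - 0.6), 1e-9)
  expect_lt(abs(tr$y[1]), 1e-12)
  expect_lt(abs(tr$y[nrow(tr)]), 0.05)  # profile returns to rest
  expect_equal(set_label(ts), "arm-raise")

  # ten repetitions -> exactly ten excursions above 90% of the amplitude
  ts10 <- generate_exercise(exercise_template("arm-raise"), seed = 2)
  y <- set_points(ts10)$wrist$y
  high <- rle(y > 0.9 * 0.6)
  expect_equal(sum(high$values), 10)

  flat <- generate_exercise(exercise_template(
    "arm-raise", amplitude = list(wrist = c(0, 0, 0)),
    origin = list(wrist = c(0, 0, 0))), seed = 3)
  expect_true(all(as.matrix(set_points(flat)$wrist[c("x", "y", "z")]) == 0))

  # sit-to-stand: both points share the excursion, neck offset upward
  ss <- generate_exercise(exercise_template("sit-stand"), seed = 4)
  pts <- set_points(ss)
  expect_equal(max(pts$lumbar$y) - min(pts$lumbar$y),
               max(pts$neck$y) - min(pts$neck$y), tolerance = 1e-9)
  expect_gt(min(pts$neck$y), max(pts$lumbar$y) - 0.46)
})

test_that("generation is bitwise reproducible per seed", {
  a <- generate_exercise(exercise_template("step-up"), seed = 9)
  b <- generate_exercise(exercise_template("step-up"), seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  bench1 <- generate_benchmark(2, seed = 5)
  bench2 <- generate_benchmark(2, seed = 5)
  expect_identical(lapply(bench1$data, as.data.frame),
                   lapply(bench2$data, as.data.frame))
})

test_that("the inertial simulator is the exact inverse of dead reckoning", {
  set.seed(20)
  ts <- generate_exercise(exercise_template("sit-stand", reps = 2), dt = 1 / 50)
  truth <- set_points(ts)$lumbar
  rec <- simulate_ins(truth, quiet_noise())
  back <- integrate_acceleration(rec)$trajectory
  shifted <- sweep(as.matrix(truth[c("x", "y", "z")]), 2,
                   as.numeric(as.matrix(truth[c("x", "y", "z")])[1, ]))
  expect_lt(max(abs(as.matrix(back[c("x", "y", "z")]) - shifted)), 1e-9)

  const <- trajectory(rep(1, 20), rep(-2, 20), rep(0.5, 20), dt = 0.1)
  rc <- simulate_ins(const, quiet_noise())
  expect_true(all(abs(as.matrix(rc[c("ax", "ay", "az")])) < 1e-12))

  # physical mode exists but is not the exact inverse
  rp <- simulate_ins(truth, quiet_noise(), mode = "physical")
  expect_equal(nrow(rp), nrow(truth) - 1)
})

test_that("the mocap simulator round-trips noise-free and scales with angle noise", {
  sk <- two_link_skeleton()
  n <- 50
  ang <- cbind(0, 0, seq(0, pi / 2, length.out = n), 0, 0, 0)
  sim <- simulate_mocap(ang, sk, "wrist", dt = 1 / 30, quiet_noise())
  rebuilt <- extract_target_point(sim$frames, sk, "wrist", dt = 1 / 30)
  expect_lt(max(abs(as.matrix(rebuilt[c("x", "y", "z")]) -
                    as.matrix(sim$truth[c("x", "y", "z")]))), 1e-9)

  static <- simulate_mocap(matrix(0, 10, 6), sk, "wrist", dt = 1 / 30,
                           quiet_noise())
  expect_equal(nrow(unique(round(as.data.frame(
    static$truth[c("x", "y", "z")]), 12))), 1)

  # small-angle linearisation: sigma_angle * effective arm length
  set.seed(30)
  sigma <- 0.01
  noisy <- simulate_mocap(ang, sk, "wrist", dt = 1 / 30,
                          noise_spec(angle_sigma = sigma), seed = 44)
  rebuilt_n <- extract_target_point(noisy$frames, sk, "wrist", dt = 1 / 30)
  dmean <- deviation_mean(rebuilt_n, noisy$truth)
  # two joints moving a ~0.55 m chain: expected deviation of order
  # sigma * L, checked within a factor of two
  pred <- sigma * 0.55
  expect_gt(dmean, pred / 2)
  expect_lt(dmean, pred * 2)
})

test_that("the vision simulator round-trips through triangulation and drops frames", {
  set.seed(40)
  ts <- generate_exercise(exercise_template("arm-raise", reps = 1), dt = 1 / 30)
  rig <- default_rig()
  kps <- simulate_vision(ts, rig$cam1, rig$cam2, rig$frame_size, quiet_noise())
  MP1 <- projection_matrix(rig$cam1); MP2 <- projection_matrix(rig$cam2)
  truth <- as.matrix(set_points(ts)$wrist[c("x", "y", "z")])
  worst <- 0
  for (i in seq(1, nrow(truth), by = 7)) {
    uv1 <- c(kps$cam1$u[i], kps$cam1$v[i])
    uv2 <- c(kps$cam2$u[i], kps$cam2$v[i])
    X <- triangulate(list(list(uv = uv1, MP = MP1), list(uv = uv2, MP = MP2)))
    worst <- max(worst, max(abs(X - truth[i, ])))
  }
  expect_lt(worst, 1e-6)

  kpd <- simulate_vision(ts, rig$cam1, rig$cam2, rig$frame_size,
                         noise_spec(dropout_prob = 0.2), seed = 8)
  frac <- mean(is.na(kpd$cam1$u))
  n <- nrow(kpd$cam1)
  expect_lt(abs(frac - 0.2), 5 * sqrt(0.2 * 0.8 / n))

  # pixel noise propagates to metric error at the depth/focal scale
  cam_a <- camera_model(500, 500, 500, 500, translation = c(0, 0, 2))
  Ry90 <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3)  # +90 deg about Y
  cam_b <- camera_model(500, 500, 500, 500, rotation = Ry90,
                        translation = c(0, 0, 2))
  small <- trajectory_set(list(p = trajectory(rep(0.05, 40), rep(-0.02, 40),
                                              rep(0.01, 40), dt = 1 / 30)),
                          label = "s")
  kpn <- simulate_vision(small, cam_a, cam_b, c(4000, 4000),
                         noise_spec(pixel_sigma = 1), seed = 13)
  MPa <- projection_matrix(cam_a); MPb <- projection_matrix(cam_b)
  errs <- vapply(1:40, function(i) {
    X <- triangulate(list(list(uv = c(kpn$cam1$u[i], kpn$cam1$v[i]), MP = MPa),
                          list(uv = c(kpn$cam2$u[i], kpn$cam2$v[i]), MP = MPb)))
    sqrt(sum((X - c(0.05, -0.02, 0.01))^2))
  }, numeric(1))
  bound <- 2 / 500 * sqrt(2)  # first-order: depth / focal * sigma_px * sqrt(2)
  expect_gt(median(errs), bound / 3)
  expect_lt(median(errs), bound * 3)
})

test_that("benchmarks are balanced and single-pointed", {
  bench <- generate_benchmark(1, seed = 3)
  expect_equal(nrow(bench), 3)
  expect_setequal(bench$label, c("arm-raise", "step-up", "sit-stand"))
  bench4 <- generate_benchmark(4, seed = 3)
  expect_equal(as.integer(table(bench4$label)), rep(4L, 3))
  expect_true(all(vapply(bench4$data,
                         function(ts) length(set_points(ts)), 1L) == 1L))
})
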