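test_that("spline references reproduce polynomials and beat constant fits", {
  lin <- line_traj(50, dt = 0.05)
  ref <- fit_reference(lin, "line")
  expect_lt(ref$rss, 1e-18)
  pred <- predict_reference(ref, c(0, 0.5, 1))
  expect_equal(pred$x, c(0, 0.5, 1), tolerance = 1e-9)

  set.seed(21)
  noisy <- trajectory(rnorm(40), rnorm(40), rnorm(40), dt = 0.1)
  ref_n <- fit_reference(noisy, "noise")
  const_rss <- sum(scale(as.matrix(noisy[c("x", "y", "z")]), scale = FALSE)^2)
  expect_lte(ref_n$rss, const_rss + 1e-12)

  expect_error(fit_reference(trajectory(1:3, 1:3, 1:3, dt = 1), "x", degree = 3),
               "too few")
})

test_that("spline fits agree with a normal-equations least-squares oracle", {
  set.seed(33)
  n <- 120; dt <- 1 / 30
  tt <- (seq_len(n) - 1) * dt
  y <- sin(2 * pi * tt / 2) + rnorm(n, 0, 0.05)
  tr <- trajectory(y, rep(0, n), rep(0, n), dt = dt)
  ref <- fit_reference(tr, "sine")
  # oracle: same basis, coefficients from the normal equations
  B <- splines::bs(tt, knots = ref$knots, degree = ref$degree,
                   intercept = TRUE, Boundary.knots = ref$boundary)
  beta <- solve(crossprod(B), crossprod(B, y))
  oracle_rss <- sum((y - B %*% beta)^2)
  rss_x <- sum((y - predict_reference(ref, tt)$x)^2)
  expect_lt(abs(rss_x - oracle_rss) / oracle_rss, 0.1)
})

test_that("references survive a JSON round trip", {
  set.seed(2)
  ts <- generate_exercise(exercise_template("step-up", reps = 2))
  ref <- fit_reference(set_points(ts)$foot, "step-up")
  tf <- withr::local_tempfile(fileext = ".json")
  write_reference(ref, tf)
  back <- read_reference(tf)
  grid <- seq(0, ref$duration - 0.2, by = 0.1)
  expect_equal(predict_reference(back, grid), predict_reference(ref, grid),
               tolerance = 1e-9)
  expect_equal(back$limits$max, ref$limits$max)
  sc <- evaluate_exercise(back, ref)
  expect_equal(unlist(sc[1, ]), c(F = 0, P = 1, LD = 0, LS = 1))
})

test_that("a reference scored against itself is ideal on all four components", {
  set.seed(14)
  for (cat in c("arm-raise", "step-up")) {
    ts <- generate_exercise(exercise_template(cat, reps = 2))
    ref <- fit_reference(set_points(ts)[[1]], cat)
    sc <- evaluate_exercise(ref, ref)
    expect_identical(sc$F, 0)
    expect_identical(sc$P, 1)
    expect_identical(sc$LD, 0)
    expect_identical(sc$LS, 1)
  }
})

test_that("the duration score applies its branches worst-first", {
  mk <- function(p_target) {
    n <- round(p_target / 0.05)
    tt <- (seq_len(n) - 1) * 0.05
    fit_reference(trajectory(sin(tt), cos(tt), tt / 10, dt = 0.05), "c")
  }
  ref10 <- mk(10)
  expect_equal(evaluate_exercise(mk(9), ref10)$P, 1)          # faster -> 1
  expect_equal(evaluate_exercise(ref10, ref10)$P, 1)          # equal -> 1
  expect_equal(evaluate_exercise(mk(12), ref10,
                                 eval_config(lambda = 0.1))$P, 0)   # 12 > 11
  expect_equal(evaluate_exercise(mk(10.5), ref10,
                                 eval_config(lambda = 0.25))$P, 0.5) # within tolerance
  expect_error(evaluate_exercise(fit_reference(line_traj(20), "other"), ref10),
               "category")
})

test_that("uniform offsets cannot improve shape or limit deviation", {
  set.seed(6)
  ts <- generate_exercise(exercise_template("arm-raise", reps = 2))
  base <- set_points(ts)$wrist
  ref <- fit_reference(base, "arm-raise")
  s0 <- evaluate_exercise(ref, ref)
  for (delta in c(0.05, 0.2)) {
    shifted <- trajectory(base$x + delta, base$y + delta, base$z,
                          dt = trajectory_dt(base))
    sc <- evaluate_exercise(fit_reference(shifted, "arm-raise"), ref)
    expect_gte(sc$F, s0$F)
    expect_gte(sc$LD, s0$LD)
    expect_equal(sc$LS, 1, tolerance = 1e-9)
  }
})

test_that("half-speed playback halves the speed ratio and zeroes the duration score", {
  set.seed(26)
  n <- 200; dt <- 1 / 30
  tt <- (seq_len(n) - 1) * dt
  ref_tr <- trajectory(sin(pi * tt / max(tt)), 0.5 * tt / max(tt), rep(0, n),
                       dt = dt)
  slow_tr <- trajectory(ref_tr$x[ceiling(seq_len(2 * n) / 2)],
                        ref_tr$y[ceiling(seq_len(2 * n) / 2)],
                        ref_tr$z[ceiling(seq_len(2 * n) / 2)], dt = dt)
  ref <- fit_reference(ref_tr, "c")
  slow <- fit_reference(slow_tr, "c")
  sc <- evaluate_exercise(slow, ref, eval_config(lambda = 0.5))
  expect_equal(sc$P, 0)
  expect_equal(sc$LS, 0.5, tolerance = 0.05)  # execution at half speed
  sc_rev <- evaluate_exercise(ref, slow, eval_config(lambda = 0.5))
  expect_equal(sc_rev$LS, 2, tolerance = 0.2)
})

test_that("group comparison wraps the Kruskal-Wallis rank test", {
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_gt(same$p.value, 0.9)
  apart <- compare_groups(list(a = 1:3, b = 100:102, c = 200:202))
  expect_lt(apart$p.value, 0.05)
  # cross-check against the base routine directly
  direct <- stats::kruskal.test(list(1:3, 100:102, 200:202))
  expect_equal(apart$statistic, unname(direct$statistic))
  expect_error(compare_groups(list(a = 1:3)), "two groups")
  expect_error(compare_groups(list(a = 1:3, b = numeric(0))), "at least one")
})

test_that("tidy and glance summarise fitted objects", {
  ref <- fit_reference(line_traj(30), "line")
  td <- tidy(ref)
  expect_true(all(c("axis", "term", "estimate") %in% names(td)))
  expect_equal(sort(unique(td$axis)), c("x", "y", "z"))
  gl <- glance(ref)
  expect_equal(gl$category, "line")
  expect_equal(gl$n, 30L)
  sc <- evaluate_exercise(ref, ref)
  expect_equal(tidy(sc)$ideal, c(0, 1, 0, 1))
  expect_equal(names(glance(sc)), c("F", "P", "LD", "LS"))
})
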