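#' Evaluation configuration for the quality score
#'
#' @param lambda Duration tolerance, dimensionless, in (0, 0.5]: an
#'   execution slower than the reference by more than `lambda * p_k`
#'   seconds scores 0 on the duration component.
#' @param grid_dt Comparison grid step in seconds for the trajectory
#'   deviation; `NULL` (default) uses the mean of the two recordings'
#'   sampling intervals.
#' @param normalize_F Report the trajectory deviation as a mean over grid
#'   nodes instead of the plain sum.
#' @return An `eval_config` list.
#' @export
eval_config <- function(lambda = 0.25, grid_dt = NULL, normalize_F = FALSE) {
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 0.5)
    stop("`lambda` must lie in (0, 0.5]", call. = FALSE)
  if (!is.null(grid_dt) && grid_dt <= 0)
    stop("`grid_dt` must be positive", call. = FALSE)
  structure(list(lambda = lambda, grid_dt = grid_dt,
                 normalize_F = isTRUE(normalize_F)),
            class = "eval_config")
}

# choose interior knots every ~spacing seconds, keeping the fit
# overdetermined (df = n_knots + degree + 1 <= N)
spline_knots <- function(span, n, degree, spacing = 0.25) {
  if (span <= spacing) return(numeric(0))
  k <- seq(spacing, span - spacing / 2, by = spacing)
  max_k <- max(0L, n - degree - 1L)
  if (length(k) > max_k) k <- if (max_k == 0L) numeric(0) else
    stats::quantile(k, probs = seq_len(max_k) / (max_k + 1), names = FALSE)
  k
}

#' Fit per-axis reference curves to a trajectory
#'
#' Represents an exercise execution as smooth per-axis curves
#' `f_x(t), f_y(t), f_z(t)` obtained by least-squares B-spline regression
#' (cubic by default, interior knots every ~0.25 s), together with the
#' recording's duration and its spatial/speed limits. A fitted object of
#' this kind is both the stored reference for a category and the summary
#' of a new execution to be scored against it.
#'
#' @param traj A `trajectory`.
#' @param category Exercise-category identifier.
#' @param degree Spline degree (default cubic).
#' @param knot_spacing Interior-knot spacing, seconds.
#' @return An `exercise_reference` object.
#' @export
fit_reference <- function(traj, category, degree = 3L, knot_spacing = 0.25) {
  traj <- as_trajectory(traj)
  n <- nrow(traj)
  if (n < degree + 1L)
    stop("too few samples for the requested spline degree", call. = FALSE)
  dt <- trajectory_dt(traj)
  tt <- traj$t - traj$t[1]
  span <- tt[n]
  knots <- spline_knots(span, n, degree, knot_spacing)
  B <- splines::bs(tt, knots = knots, degree = degree, intercept = TRUE,
                   Boundary.knots = c(0, span))
  qrB <- qr(B)
  coefs <- lapply(list(x = traj$x, y = traj$y, z = traj$z),
                  function(v) qr.coef(qrB, v))
  fitted <- vapply(coefs, function(cf) drop(B %*% ifelse(is.na(cf), 0, cf)),
                   numeric(n))
  rss <- sum((traj_matrix(traj) - fitted)^2)
  structure(list(
    category = category,
    duration = n * dt,      # p = N * dt
    dt = dt,
    degree = as.integer(degree),
    knots = as.double(knots),
    boundary = c(0, span),
    coefficients = lapply(coefs, function(cf) ifelse(is.na(cf), 0, cf)),
    limits = compute_limits(traj),
    n = n,
    rss = rss
  ), class = "exercise_reference")
}

#' Evaluate fitted reference curves on a time grid
#'
#' Times beyond the fitted span are clamped to the last sample (constant
#' extrapolation), which at most affects one grid step when durations are
#' compared.
#'
#' @param ref An `exercise_reference`.
#' @param t Numeric vector of times, seconds.
#' @return A tibble with columns `t`, `x`, `y`, `z`.
#' @export
predict_reference <- function(ref, t) {
  stopifnot(inherits(ref, "exercise_reference"))
  tc <- pmin(pmax(t, ref$boundary[1]), ref$boundary[2])
  B <- splines::bs(tc, knots = ref$knots, degree = ref$degree,
                   intercept = TRUE, Boundary.knots = ref$boundary)
  tibble::tibble(
    t = t,
    x = drop(B %*% ref$coefficients$x),
    y = drop(B %*% ref$coefficients$y),
    z = drop(B %*% ref$coefficients$z)
  )
}

#' @export
print.exercise_reference <- function(x, ...) {
  cat(sprintf(
    "# Exercise reference '%s': %.3g s (%d samples), %d-degree spline, %d interior knots\n",
    x$category, x$duration, x$n, x$degree, length(x$knots)))
  invisible(x)
}

#' Four-component exercise-quality score
#'
#' Compares a fitted execution `current` (index m) against a fitted
#' reference `reference` (index k) of the same category:
#'
#' * `F` - trajectory-shape deviation: the sum over a common time grid
#'   (step `grid_dt`, span `min(p_k, p_m)`) of squared per-axis curve
#'   differences. Ideal 0.
#' * `P` - duration score: 1 when the execution is no slower than the
#'   reference (`p_m <= p_k`), 0.5 when slower within the tolerance
#'   (`p_k < p_m <= p_k (1 + lambda)`), 0 beyond it. Branches are applied
#'   worst-first; equal durations score 1.
#' * `LD` - limit deviation: Euclidean distance between the two per-axis
#'   maximum-position vectors plus the same for the minima. Ideal 0.
#' * `LS` - speed ratio: summed mean per-axis speeds of the execution over
#'   the reference. Ideal 1.
#'
#' @param current,reference `exercise_reference` objects of one category.
#' @param cfg An [eval_config()].
#' @return A `quality_score`: one-row tibble with columns `F`, `P`, `LD`,
#'   `LS`.
#' @export
evaluate_exercise <- function(current, reference, cfg = eval_config()) {
  stopifnot(inherits(current, "exercise_reference"),
            inherits(reference, "exercise_reference"),
            inherits(cfg, "eval_config"))
  if (!identical(current$category, reference$category))
    stop("category mismatch between execution and reference", call. = FALSE)
  pm <- current$duration; pk <- reference$duration
  grid_dt <- if (is.null(cfg$grid_dt)) mean(c(current$dt, reference$dt)) else cfg$grid_dt
  grid <- seq(0, min(pk, pm), by = grid_dt)
  fm <- predict_reference(current, grid)
  fk <- predict_reference(reference, grid)
  Fdev <- sum((fm$x - fk$x)^2) + sum((fm$y - fk$y)^2) + sum((fm$z - fk$z)^2)
  if (cfg$normalize_F) Fdev <- Fdev / length(grid)
  # durations compared with a relative epsilon so serialisation round-offs
  # cannot flip a branch; ties count as equal (score 1)
  eps <- 1e-9 * max(pk, pm)
  P <- if (pm > pk * (1 + cfg$lambda) + eps) 0 else if (pm > pk + eps) 0.5 else 1
  lm_ <- current$limits; lk <- reference$limits
  LD <- sqrt(sum((lm_$max - lk$max)^2)) + sqrt(sum((lm_$min - lk$min)^2))
  denom <- sum(lk$mean_speed)
  if (denom == 0) stop("reference has zero total mean speed; LS undefined", call. = FALSE)
  LS <- sum(lm_$mean_speed) / denom
  out <- tibble::tibble(F = Fdev, P = P, LD = LD, LS = LS)
  class(out) <- c("quality_score", class(out))
  out
}

#' Score every target point of an execution and average
#'
#' Multi-point exercises (sit-to-stand tracks the lumbar region and neck)
#' are scored per target point and the component scores are averaged
#' arithmetically.
#'
#' @param current,reference `trajectory_set`s sharing point names and
#'   label.
#' @param cfg An [eval_config()].
#' @param ... Passed to [fit_reference()].
#' @return A `quality_score` one-row tibble.
#' @export
evaluate_exercise_set <- function(current, reference, cfg = eval_config(), ...) {
  cur <- set_points(current); ref <- set_points(reference)
  if (!setequal(names(cur), names(ref)))
    stop("point names differ between execution and reference", call. = FALSE)
  lab <- set_label(reference) %||% "unlabeled"
  scores <- lapply(names(ref), function(p) {
    evaluate_exercise(fit_reference(cur[[p]], lab, ...),
                      fit_reference(ref[[p]], lab, ...), cfg)
  })
  out <- tibble::as_tibble(as.list(colMeans(do.call(rbind, lapply(scores, as.data.frame)))))
  class(out) <- c("quality_score", class(out))
  out
}

#' Kruskal-Wallis comparison of tracking systems or groups
#'
#' Thin wrapper over [stats::kruskal.test()] for comparing metric samples
#' (for example per-system deviation values) across three or more
#' independent groups without a normality assumption.
#'
#' @param samples Named list of numeric vectors, one per group (at least
#'   two non-empty groups).
#' @return A one-row tibble with `statistic` (H), `df`, and `p.value`.
#' @export
compare_groups <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(samples, length, integer(1)) < 1L))
    stop("every group needs at least one value", call. = FALSE)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), vapply(samples, length, integer(1))))
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p.value = kt$p.value)
}

#' Store / load an exercise reference as JSON
#'
#' Persists the category, duration, spline specification (degree, knots,
#' boundary, per-axis coefficients) and limits.
#'
#' @param ref An `exercise_reference`.
#' @param path File path.
#' @return `path` invisibly (writer); an `exercise_reference` (reader).
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "exercise_reference"))
  jsonlite::write_json(list(
    category = ref$category, duration = ref$duration, dt = ref$dt,
    degree = ref$degree, knots = ref$knots, boundary = ref$boundary,
    coefficients = ref$coefficients,
    limits = as.data.frame(ref$limits), n = ref$n, rss = ref$rss
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lim <- tibble::as_tibble(j$limits)
  class(lim) <- c("limits", class(lim))
  structure(list(
    category = j$category, duration = j$duration, dt = j$dt,
    degree = as.integer(j$degree), knots = as.double(j$knots),
    boundary = as.double(j$boundary),
    coefficients = lapply(j$coefficients, as.double),
    limits = lim, n = as.integer(j$n), rss = j$rss
  ), class = "exercise_reference")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.exercise_reference <- function(x, ...) {
  dplyr::bind_rows(lapply(c("x", "y", "z"), function(ax) {
    tibble::tibble(axis = ax,
                   term = sprintf("b%02d", seq_along(x$coefficients[[ax]])),
                   estimate = x$coefficients[[ax]])
  }))
}

#' @export
glance.exercise_reference <- function(x, ...) {
  tibble::tibble(category = x$category, duration = x$duration, n = x$n,
                 dt = x$dt, degree = x$degree, n_knots = length(x$knots),
                 rss = x$rss)
}

#' @export
tidy.quality_score <- function(x, ...) {
  tibble::tibble(component = c("F", "P", "LD", "LS"),
                 value = c(x$F, x$P, x$LD, x$LS),
                 ideal = c(0, 1, 0, 1))
}

#' @export
glance.quality_score <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "quality_score")
  out
}
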