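# Local minimization: parabolic-step gradient descent at a fixed relaxation
# scale, chained coarse-to-fine.  The objective is any closure
# f(b, grad = FALSE) -> list(value, [grad]), so the same machinery runs on
# toy test objectives and on the full functional (with or without the
# repulsion term).

#' One parabolic descent step
#'
#' Starting from `b` with descent direction `D`, fits a 1-D parabola along
#' the normalized direction `-D` and jumps to its vertex if the parabola
#' is convex, the vertex lies inside the step bracket and the cost
#' decreases there (near a minimum the functional is close to quadratic,
#' so this usually lands almost on the line minimum in one evaluation).
#' The parabola is built either from the value and directional slope at
#' the start plus one trial value (when `slope` is supplied -- one
#' objective evaluation cheaper) or from the values at two trial points.
#' On failure it falls back to backtracking halving.  The returned cost
#' never exceeds the starting cost.
#'
#' @param objective function `f(b, grad = FALSE)` returning
#'   `list(value, grad)`.
#' @param b current iterate (numeric array).
#' @param D gradient at `b`.
#' @param f0 objective value at `b` (recomputed if `NULL`).
#' @param step initial trial step length along the unit direction.
#' @param slope optional directional derivative of the objective along
#'   `-D/|D|` at `b` (must be negative for a descent direction).
#' @param settings a [descent_settings()].
#' @return List with `b`, `value`, `step` (the accepted step length, a good
#'   starting value for the next iteration) and `failed` (TRUE when no
#'   decrease could be found).
#' @export
parabolic_step <- function(objective, b, D, f0 = NULL, step = NULL,
                           slope = NULL, settings = descent_settings()) {
  if (is.null(f0)) f0 <- objective(b)$value
  gnorm <- sqrt(sum(D^2))
  if (gnorm <= settings$grad_floor)
    return(list(b = b, value = f0, step = step, failed = FALSE))
  if (is.null(step)) step <- settings$step0
  dir <- -D / gnorm
  t1 <- step
  f1 <- objective(b + t1 * dir)$value
  if (!is.null(slope) && is.finite(slope) && slope < 0) {
    # parabola from the value and slope at 0 plus one trial value
    a <- (f1 - f0 - slope * t1) / t1^2
    if (is.finite(a) && a > 0) {
      tv <- -slope / (2 * a)
      if (is.finite(tv) && tv > 0 && tv <= 8 * t1) {
        fv <- objective(b + tv * dir)$value
        best <- which.min(c(fv, f1))
        tb <- c(tv, t1)[best]; fb <- c(fv, f1)[best]
        if (is.finite(fb) && fb < f0)
          return(list(b = b + tb * dir, value = fb, step = tb,
                      failed = FALSE))
      }
    }
    if (is.finite(f1) && f1 < f0)
      return(list(b = b + t1 * dir, value = f1, step = t1, failed = FALSE))
  } else {
    t2 <- 2 * step
    f2 <- objective(b + t2 * dir)$value
    # vertex of the parabola through (0, f0), (t1, f1), (t2, f2)
    denom <- 2 * (f0 - 2 * f1 + f2)
    if (is.finite(denom) && denom > 0) {
      tv <- t1 * (3 * f0 - 4 * f1 + f2) / denom
      if (is.finite(tv) && tv > 0 && tv <= 4 * t2) {
        fv <- objective(b + tv * dir)$value
        best <- which.min(c(fv, f1, f2))
        tb <- c(tv, t1, t2)[best]; fb <- c(fv, f1, f2)[best]
        if (is.finite(fb) && fb < f0)
          return(list(b = b + tb * dir, value = fb, step = tb,
                      failed = FALSE))
      }
    }
    if (is.finite(f1) && f1 < f0)
      return(list(b = b + t1 * dir, value = f1, step = t1, failed = FALSE))
    if (is.finite(f2) && f2 < f0)
      return(list(b = b + t2 * dir, value = f2, step = t2, failed = FALSE))
  }
  # backtracking halving
  t <- step / 2
  for (i in seq_len(settings$max_backtrack)) {
    ft <- objective(b + t * dir)$value
    if (is.finite(ft) && ft < f0)
      return(list(b = b + t * dir, value = ft, step = t, failed = FALSE))
    t <- t / 2
  }
  list(b = b, value = f0, step = step, failed = TRUE)
}

#' Minimize the objective at one relaxation scale
#'
#' Repeats [parabolic_step()] until the relative cost decrease stays below
#' `settings$tol` for `settings$tol_streak` consecutive iterations, the
#' gradient norm drops below the floor, a step fails, or `max_iter` is
#' reached.  The search direction is the Polak-Ribiere conjugate-gradient
#' combination of successive gradients (restarted to plain steepest descent
#' whenever it stops being a descent direction), which takes far fewer
#' iterations than raw gradient steps through the long curved valleys this
#' functional develops; each step still uses the parabolic line search.
#' The cost sequence is non-increasing by construction.
#'
#' @inheritParams parabolic_step
#' @param b0 starting map.
#' @return List with `b`, `value`, `iterations`, `converged`, `warning`
#'   (TRUE when the line search failed before convergence).
#' @export
minimize_at_scale <- function(objective, b0, settings = descent_settings()) {
  b <- b0
  res <- objective(b, grad = TRUE)
  f <- res$value
  g <- res$grad
  d <- g
  step <- NULL
  streak <- 0L
  warned <- FALSE
  it <- 0L
  while (it < settings$max_iter) {
    it <- it + 1L
    if (sqrt(sum(g^2)) <= settings$grad_floor) break
    st <- parabolic_step(objective, b, d, f0 = f, step = step,
                         slope = -sum(g * d) / sqrt(sum(d^2)),
                         settings = settings)
    if (st$failed && !identical(d, g)) {
      # stale conjugate direction; retry with the raw gradient
      d <- g
      st <- parabolic_step(objective, b, d, f0 = f, step = step,
                           slope = -sqrt(sum(g^2)),
                           settings = settings)
    }
    if (st$failed) { warned <- TRUE; break }
    rel <- (f - st$value) / max(abs(f), .Machine$double.eps)
    b <- st$b; f <- st$value; step <- st$step
    streak <- if (rel < settings$tol) streak + 1L else 0L
    if (streak >= settings$tol_streak) break
    res <- objective(b, grad = TRUE)
    beta <- max(0, sum(res$grad * (res$grad - g)) / sum(g^2))
    g <- res$grad
    d <- g + beta * d
    if (sum(d * g) <= 0) d <- g  # restart: keep a descent direction
  }
  list(b = b, value = f, iterations = it,
       converged = it < settings$max_iter, warning = warned)
}

# The relaxation ladder: s0, s0*sR, ... down to the first value <= sM.
scale_ladder <- function(schedule) {
  s <- schedule$s0
  out <- s
  while (s > schedule$sM) {
    s <- s * schedule$sR
    out <- c(out, s)
  }
  out
}

#' Graduated (coarse-to-fine) relaxation
#'
#' Minimizes the functional at the initial scale `s0`, then repeatedly
#' shrinks the scale by `sR` and re-minimizes from the previous minimizer,
#' until the final scale `sM` is passed.  Heavy early smoothing leaves only
#' the stable minima; the fine scales then sharpen the survivor.  The
#' reported cost is the pure functional (scale multipliers at `s = 0`, no
#' repulsion), so interpretations found with different repulsion histories
#' are comparable.
#'
#' @param I image matrix.
#' @param b0 starting border-ownership map (usually [random_init()]).
#' @param params a [model_params()].
#' @param schedule a [relaxation_schedule()].
#' @param settings a [descent_settings()].
#' @param particles optional list of repulsive-particle maps; when given,
#'   the repulsion term (see [repulsion_term()]) is added to the objective
#'   at every scale of this search.
#' @param repulsion a [repulsion_settings()]; required when `particles` is
#'   non-empty.
#' @param factor repulsion escalation factor (`>= 1`).
#' @return List with `b` (final map), `value` (pure cost), `per_scale`
#'   (data frame of scale, iterations, cost), `warning`.
#' @export
gradual_relaxation <- function(I, b0, params = model_params(),
                               schedule = relaxation_schedule(),
                               settings = descent_settings(),
                               particles = NULL,
                               repulsion = repulsion_settings(),
                               factor = 1) {
  # ladder of smoothed scales, then a final polish pass on the plain
  # functional (s = 0, all multipliers at their offsets) so the returned
  # map is a stationary point of the cost that ranks interpretations
  ladder <- c(scale_ladder(schedule), 0)
  b <- b0
  warned <- FALSE
  pure <- NA_real_
  log_rows <- list()
  for (s in ladder) {
    ctx <- bo_cost_context(I, params, scale_multipliers(schedule, s))
    objective <- make_objective(ctx, particles, repulsion, factor)
    pass_settings <- settings
    if (s == 0) pass_settings$max_iter <- settings$final_max_iter
    res <- minimize_at_scale(objective, b, pass_settings)
    b <- res$b
    warned <- warned || res$warning
    log_rows[[length(log_rows) + 1]] <-
      data.frame(s = s, iterations = res$iterations, cost = res$value)
    if (s == 0)
      pure <- if (is.null(particles) || length(particles) == 0) res$value
        else bo_cost_eval(b, ctx)$value
  }
  list(b = b, value = pure, per_scale = do.call(rbind, log_rows),
       warning = warned)
}

make_objective <- function(ctx, particles = NULL, repulsion = NULL,
                           factor = 1) {
  if (is.null(particles) || length(particles) == 0)
    return(function(b, grad = FALSE) bo_cost_eval(b, ctx, grad = grad))
  function(b, grad = FALSE) {
    res <- bo_cost_eval(b, ctx, grad = grad)
    rep_val <- 0
    if (grad) rep_grad <- array(0, dim(b))
    for (pcl in particles) {
      d <- bo_distance(b, pcl) + repulsion$eps_rep
      rep_val <- rep_val + 1 / d
      if (grad) {
        # d(dist)/db = sign(b^2 - p^2) * 2b / T
        sgn <- sign(b^2 - pcl^2)
        rep_grad <- rep_grad - (1 / d^2) * sgn * 2 * b / length(b)
      }
    }
    res$value <- res$value + factor * repulsion$rho * rep_val
    if (grad) res$grad <- res$grad + factor * repulsion$rho * rep_grad
    res
  }
}
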