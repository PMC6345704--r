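# Toy objectives exercise the descent machinery independently of the
# functional; analytic optima provide the oracles.

quad_obj <- function(center, scale = 1) {
  function(b, grad = FALSE) {
    out <- list(value = scale * sum((b - center)^2))
    if (grad) out$grad <- 2 * scale * (b - center)
    out
  }
}

test_that("a single parabolic step solves an exactly quadratic line search", {
  center <- array(c(1, -2, 0.5, 3), c(2, 2, 1))
  obj <- quad_obj(center)
  b0 <- array(0, c(2, 2, 1))
  D <- obj(b0, grad = TRUE)$grad
  st <- parabolic_step(obj, b0, D, settings = descent_settings(step0 = 0.5))
  # the line minimum along -D of a quadratic
  dirn <- -D / sqrt(sum(D^2))
  tstar <- -sum(2 * (b0 - center) * dirn) / 2
  expect_equal(st$b, b0 + tstar * dirn, tolerance = 1e-10)
  expect_false(st$failed)
})

test_that("a zero gradient leaves the iterate unchanged", {
  obj <- quad_obj(array(0, c(2, 2, 1)))
  b0 <- array(0, c(2, 2, 1))
  st <- parabolic_step(obj, b0, obj(b0, grad = TRUE)$grad)
  expect_equal(st$b, b0)
})

test_that("quartic descent decreases monotonically toward the origin", {
  obj <- function(b, grad = FALSE) {
    out <- list(value = sum(b^4))
    if (grad) out$grad <- 4 * b^3
    out
  }
  b <- array(1, c(1, 1, 1))
  f <- obj(b)$value
  step <- NULL
  vals <- f
  for (i in 1:10) {
    st <- parabolic_step(obj, b, obj(b, grad = TRUE)$grad, f0 = f,
                         step = step)
    expect_lte(st$value, f)
    b <- st$b; f <- st$value; step <- st$step
    vals <- c(vals, f)
  }
  expect_lt(f, 0.05)
  expect_true(all(diff(vals) <= 0))
})

test_that("minimize_at_scale reaches the unique minimum of a convex quadratic", {
  set.seed(31)
  center <- array(rnorm(24), c(2, 4, 3))
  res <- minimize_at_scale(quad_obj(center), array(0, c(2, 4, 3)),
                           descent_settings(tol = 1e-12))
  expect_lt(max(abs(res$b - center)), 1e-6)
  expect_true(res$converged)
})

test_that("double-well descent stays in the starting-side well", {
  obj <- function(b, grad = FALSE) {
    out <- list(value = sum((b^2 - 1)^2))
    if (grad) out$grad <- 4 * b * (b^2 - 1)
    out
  }
  res_pos <- minimize_at_scale(obj, array(0.3, c(2, 2, 1)))
  expect_equal(as.vector(res_pos$b), rep(1, 4), tolerance = 1e-4)
  res_neg <- minimize_at_scale(obj, array(-0.3, c(2, 2, 1)))
  expect_equal(as.vector(res_neg$b), rep(-1, 4), tolerance = 1e-4)
})

test_that("the relaxation ladder has the prescribed number of scales", {
  sch <- relaxation_schedule(s0 = 1, sR = 0.5, sM = 0.1)
  ladder <- bomap:::scale_ladder(sch)
  expect_equal(length(ladder), 1 + ceiling(log(0.1 / 1) / log(0.5)))
  expect_true(all(diff(ladder) < 0))
  expect_lte(ladder[length(ladder)], 0.1)
  # degenerate schedule: one smoothed pass (plus the final plain polish)
  sch1 <- relaxation_schedule(s0 = 0.2, sM = 0.2)
  expect_equal(length(bomap:::scale_ladder(sch1)), 1)
})

test_that("relaxation on the step edge finds one-sided perpendicular ownership", {
  I <- make_edge_image(20, 20)
  res <- gradual_relaxation(I, random_init(c(20, 20, 12), 1))
  expect_lt(res$value, 0)
  p <- model_params()
  bS <- smooth_bo(res$b, p$sigma_SA, p$sigma_SX)
  en <- apply(bS^2, 3, sum)
  major <- which.max(en)            # dominant direction slice
  expect_true(major %in% c(1, 7))   # perpendicular to the vertical edge
  opposite <- (major - 1 + 6) %% 12 + 1
  expect_lt(en[opposite], 0.02 * en[major])   # one-sided
  # dominant mass sits on the boundary columns
  E <- apply(bS^2, c(1, 2), sum)
  strong <- which(E >= 0.5 * max(E), arr.ind = TRUE)
  expect_true(all(strong[, 2] %in% 9:12))
  # the per-scale cost trace is recorded and ends with the plain pass
  expect_equal(res$per_scale$s[nrow(res$per_scale)], 0)
})
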