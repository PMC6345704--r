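test_that("edge filter bank: sign threshold, null response, oracle match", {
  # the thresholded sign function built into the kernel
  k <- bomap:::edge_kernel(1, 0, 1)            # 7 x 7, center column 4
  expect_equal(k[, 4], rep(0, 7))              # zero column under threshold
  expect_true(all(k[, 5:7] > 0) && all(k[, 1:3] < 0))
  # constant image: odd filter gives exactly zero
  A <- edge_responses(matrix(0.7, 8, 8), 1.0)
  expect_equal(max(abs(A)), 0)
  # vertical step edge: maximal |A| across the edge, matches direct sum
  I <- make_edge_image(16, 16)
  A <- edge_responses(I, 1.0)
  resp <- abs(A[8, 8, ])
  expect_true(which.max(resp) %in% c(1, 7))    # l = 0 or l = L/2
  for (l0 in c(0, 1, 3, 6)) {
    expect_equal(A[8, 8, l0 + 1],
                 edge_response_direct(I, 8, 8, l0, 1.0),
                 tolerance = 1e-12)
  }
  # odd symmetry between opposite directions
  expect_equal(A[, , 1], -A[, , 7], tolerance = 1e-12)
})

test_that("pointwise components match hand evaluations", {
  dims <- c(2, 2, 4)
  bS <- array(0, dims); A <- array(0, dims)
  expect_equal(cost_FA(bS, A), 0)
  expect_equal(cost_FR(bS), 0)
  expect_equal(cost_FV(bS, A, 0.01), 0)
  bS[1, 1, 1] <- 1; A[1, 1, 1] <- 2
  expect_equal(cost_FA(bS, A), -4 / 16)
  bS2 <- array(0, dims); bS2[1, 2, 3] <- 2
  expect_equal(cost_FR(bS2), 16 / 16)
  expect_equal(cost_FR(3 * bS2), 3^4 * cost_FR(bS2))
  # FV weight: 1 where A = 0; 0.01 where A^2 = 99 eps
  eps <- 0.01
  bS3 <- array(0, dims); bS3[2, 2, 2] <- 1
  expect_equal(cost_FV(bS3, array(0, dims), eps), 1 / 16)
  A3 <- array(0, dims); A3[2, 2, 2] <- sqrt(99 * eps)
  expect_equal(cost_FV(bS3, A3, eps), 0.01 / 16)
})

test_that("one-sidedness component: zeros, pairings, and summation oracle", {
  dims <- c(9, 9, 12)
  expect_equal(cost_FN(array(0, dims), 1), 0)
  # a single nonzero site pairs only with empty opposite-range entries
  b1 <- array(0, dims); b1[5, 5, 3] <- 1.4
  expect_equal(cost_FN(b1, 1), 0)
  # two opposite vectors at the same site: direct brute-force oracle
  b2 <- b1; b2[5, 5, 9] <- 0.8
  expect_gt(cost_FN(b2, 1), 0)
  expect_equal(cost_FN(b2, 1), cost_FN_direct(b2, 1), tolerance = 1e-12)
  # near-opposite (deviation m = 2) also penalized, weight cos^2
  b3 <- b1; b3[5, 5, 11] <- 0.8
  expect_gt(cost_FN(b3, 1), 0)
  expect_lt(cost_FN(b3, 1), cost_FN(b2, 1))
  expect_equal(cost_FN(b3, 1), cost_FN_direct(b3, 1), tolerance = 1e-12)
})

test_that("smoothed ramp matches its integral definition and limits", {
  sig <- 0.3
  # independent oracle: numerical convolution of the ramp with the Gaussian
  conv_ramp <- function(x) {
    integrate(function(t) pmax(x - t, 0) * dnorm(t, sd = sig),
              -Inf, Inf, rel.tol = 1e-12)$value
  }
  for (x in c(-0.7, -0.1, 0, 0.05, 0.4, 1.2))
    expect_equal(smoothed_ramp(x, sig), conv_ramp(x), tolerance = 1e-10)
  expect_equal(smoothed_ramp(0, sig), sig / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(smoothed_ramp(10 * sig, sig), 10 * sig, tolerance = 1e-12)
  expect_lt(smoothed_ramp(-10 * sig, sig), 1e-15)
})

test_that("continuity component: quiet on continuation, loud on endings", {
  p <- model_params()
  expect_equal(cost_FC(array(0, c(15, 15, 12)), p), 0)
  sm <- function(b) smooth_bo(b, p$sigma_SA, p$sigma_SX)
  full <- cost_FC(sm(line_map(rows = 1:15)), p)          # spans the canvas
  dangling <- cost_FC(sm(line_map(rows = 1:8)), p)       # ends mid-canvas
  occluded_map <- line_map(rows = 1:8)
  occluded_map[8, , 4] <- 1                              # perpendicular edge
  occluded <- cost_FC(sm(occluded_map), p)
  occ_alone <- cost_FC(sm(line_map(rows = 8, cols = 1:15, l0 = 3)), p)
  expect_gt(dangling, full)
  # the occluder relieves the ending: the joint configuration costs less
  # than the dangling end and the occluder taken separately
  expect_lt(occluded, dangling + occ_alone)
  # an unbroken edge is near-silent per site compared to the dangling end
  expect_lt(full, 0.7 * dangling)
  expect_gte(full, 0)
})

test_that("bending component: straight is free, convex beats concave", {
  p <- model_params()
  sm <- function(b) smooth_bo(b, p$sigma_SA, p$sigma_SX)
  expect_equal(cost_FE(array(0, c(16, 16, 12)), p), 0)
  # straight line: no turn pairs fire beyond numerical dust
  straight <- cost_FE(sm(line_map(H = 16, W = 16, rows = 1:16)), p)
  # L-corner with consistent ownership: convex vs concave versions
  # object in the north-east quadrant: vertical arm owns +x (east), the
  # horizontal arm owns +y (up) -- a convex corner at (8, 8); the
  # complementary ownership gives the concave corner of the L-shaped
  # complement
  corner <- function(convex) {
    b <- array(0, c(16, 16, 12))
    if (convex) {
      b[2:8, 8, 1] <- 1      # ownership +x
      b[8, 8:15, 4] <- 1     # ownership +y: l = 3
    } else {
      b[2:8, 8, 7] <- 1      # ownership -x
      b[8, 8:15, 10] <- 1    # ownership -y: l = 9
    }
    sm(b)
  }
  convex <- cost_FE(corner(TRUE), p)
  concave <- cost_FE(corner(FALSE), p)
  expect_lt(straight, 0.2 * convex)
  expect_gt(concave, convex)
  # closed square: inward ownership (4 convex corners) is cheaper than
  # outward (4 concave corners)
  sq_in <- cost_FE(sm(square_ring_map(inward = TRUE)), p)
  sq_out <- cost_FE(sm(square_ring_map(inward = FALSE)), p)
  expect_gt(sq_out, sq_in)
  expect_gt(sq_in, 0)
})

test_that("multi-scale averaging reduces to the plain component and to means", {
  f <- function(scale) scale^2 + 1
  expect_equal(multiscale(f, 1, 2), f(1))
  expect_equal(multiscale(function(s) 0, 3, 2), 0)
  expect_equal(multiscale(f, 2, 2), mean(c(f(1), f(2))), tolerance = 1e-12)
  # on the real functional: N = 2 equals the mean of the two single-scale
  # one-sidedness costs computed directly
  set.seed(8)
  b <- array(rnorm(6 * 6 * 12, 0, 0.3), c(6, 6, 12))
  p <- model_params()
  direct <- multiscale(function(sc) cost_FN(b, p$sigma_N * sc),
                       2, p$mu)
  expect_equal(direct,
               mean(c(cost_FN(b, p$sigma_N), cost_FN(b, p$sigma_N * p$mu))),
               tolerance = 1e-12)
})

test_that("total cost: zero map, weight linearity, component assembly", {
  I <- make_edge_image(8, 8)
  p <- model_params()
  expect_equal(total_cost(array(0, c(8, 8, 12)), I, p), 0)
  set.seed(11)
  b <- array(rnorm(8 * 8 * 12, 0, 0.3), c(8, 8, 12))
  # only one nonzero weight: total equals that weighted component
  pA <- model_params(alpha_A = 2, alpha_R = 0, alpha_V = 0, alpha_N = 0,
                     alpha_C = 0, alpha_E = 0)
  cmp <- total_cost_components(b, I, pA)
  expect_equal(total_cost(b, I, pA), 2 * cmp$components[["FA"]],
               tolerance = 1e-12)
  # independent assembly through the exported single-scale components
  cmp_all <- total_cost_components(b, I, p)
  bS <- smooth_bo(b, p$sigma_SA, p$sigma_SX)
  manual <- function(fn) multiscale(fn, p$n_scales, p$mu)
  FA <- manual(function(sc) cost_FA(bS, edge_responses(I, p$sigma_A * sc, p$L)))
  FR <- manual(function(sc) cost_FR(bS))
  FV <- manual(function(sc) cost_FV(bS, edge_responses(I, p$sigma_A * sc, p$L),
                                    p$eps_V))
  FN <- manual(function(sc) cost_FN(bS, p$sigma_N * sc))
  FC <- manual(function(sc) cost_FC(bS, modifyList(p, list(lambda_C = p$lambda_C * sc))))
  FE <- manual(function(sc) cost_FE(bS, modifyList(p, list(lambda_C = p$lambda_C * sc))))
  for (pair in list(c("FA", FA), c("FR", FR), c("FV", FV), c("FN", FN),
                    c("FC", FC), c("FE", FE))) {
    expect_equal(cmp_all$components[[pair[[1]]]], as.numeric(pair[[2]]),
                 tolerance = 1e-10, label = pair[[1]])
  }
  total_manual <- p$alpha_A * FA + p$alpha_R * FR + p$alpha_V * FV +
    p$alpha_N * FN + p$alpha_C * FC + p$alpha_E * FE
  expect_equal(total_cost(b, I, p), total_manual, tolerance = 1e-10)
})

test_that("the functional is sign-blind and rotation-equivariant", {
  I <- make_square_image(12, 6)
  p <- model_params()
  set.seed(13)
  b <- array(rnorm(12 * 12 * 12, 0, 0.3), c(12, 12, 12))
  expect_equal(total_cost(b, I, p), total_cost(-b, I, p), tolerance = 1e-12)
  # rotate image and map together by 90 degrees: every component unchanged
  rotm <- function(m) { out <- t(m)[ncol(m):1, ]; out }
  rotb <- function(b) {
    L <- dim(b)[3]
    out <- array(0, c(dim(b)[2], dim(b)[1], L))
    for (l1 in seq_len(L))
      out[, , l1] <- rotm(b[, , (l1 - 1 - L / 4) %% L + 1])
    out
  }
  c1 <- total_cost_components(b, I, p)
  c2 <- total_cost_components(rotb(b), rotm(I), p)
  expect_equal(c1$components, c2$components, tolerance = 1e-9)
  # mirror: flip columns, reflect direction indices (l -> L/2 - l)
  mirm <- function(m) m[, ncol(m):1]
  mirb <- function(b) {
    L <- dim(b)[3]
    out <- array(0, dim(b))
    for (l1 in seq_len(L))
      out[, , (L / 2 - (l1 - 1)) %% L + 1] <- mirm(b[, , l1])
    out
  }
  c3 <- total_cost_components(mirb(b), mirm(I), p)
  expect_equal(c1$components, c3$components, tolerance = 1e-9)
})

test_that("component signs honor their roles on generic maps", {
  I <- make_square_image(12, 6)
  p <- model_params()
  set.seed(17)
  b <- array(rnorm(12 * 12 * 12, 0, 0.4), c(12, 12, 12))
  cmp <- total_cost_components(b, I, p)$components
  expect_lte(cmp[["FA"]], 0)
  expect_gte(cmp[["FR"]], 0)
  expect_gte(cmp[["FV"]], 0)
  expect_gte(cmp[["FN"]], 0)
  expect_gte(cmp[["FC"]], 0)
  expect_gte(cmp[["FE"]], 0)
})
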