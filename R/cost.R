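# The cost functional: six components evaluated on the smoothed
# border-ownership map, averaged over spatial scales, plus the analytic
# gradient.  Everything enters through bS^2, so the functional is invariant
# to flipping the sign of any single entry.
#
# Internally each direction slice is kept as a plain matrix (rows = y,
# cols = x) and the heavy convolutions are done in C++ (src/conv.cpp).

#' Oriented edge responses
#'
#' Cross-correlates the image with a bank of `L` oriented odd filters: a
#' Gaussian multiplied by the sign of the projection onto the direction
#' `alpha_l` (the sign function returns 0 for projections with magnitude
#' `<= 0.001`).  The Gaussian factor is normalized to unit sum, so the
#' response to a unit step edge is about 0.5 regardless of `sigma_a`.  The
#' image is replicate-padded to avoid a spurious frame edge.  The response
#' is maximal (in magnitude) for `l` perpendicular to the edge, and
#' `A[, , l] == -A[, , l + L/2]`.
#'
#' @param I image matrix in `[0, 1]`.
#' @param sigma_a filter width in pixels.
#' @param L number of directions.
#' @return `nrow(I) x ncol(I) x L` array.
#' @export
edge_responses <- function(I, sigma_a, L = 12L) {
  if (sigma_a <= 0) stop("sigma_a must be positive", call. = FALSE)
  dirs <- direction_set(L)
  out <- array(0, c(nrow(I), ncol(I), L))
  for (l1 in seq_len(L))
    out[, , l1] <- conv2_same(I, edge_kernel(dirs$ux[l1], dirs$uy[l1], sigma_a),
                              pad = 1L)
  out
}

# Oriented odd edge filter: sign(p . u) * normalized Gaussian, where p is the
# tap offset in math coordinates (x = column offset, y = -row offset).
edge_kernel <- function(ux, uy, sigma) {
  m <- max(1L, ceiling(3 * sigma))
  di <- matrix(-m:m, 2 * m + 1, 2 * m + 1)        # row offset
  dj <- t(di)                                     # col offset
  g <- exp(-(di^2 + dj^2) / (2 * sigma^2))
  g <- g / sum(g)
  proj <- dj * ux + (-di) * uy
  sgn <- ifelse(abs(proj) <= 0.001, 0, sign(proj))
  sgn * g
}

#' Gaussian-smoothed ramp function
#'
#' The ramp `r(x) = max(x, 0)` convolved with a Gaussian of width
#' `sigma_rp`; closed form `x * pnorm(x / sigma_rp) + sigma_rp *
#' dnorm(x / sigma_rp)`.  Its derivative is `pnorm(x / sigma_rp)`, so the
#' continuity and bending components stay continuously differentiable.
#'
#' @param x numeric vector.
#' @param sigma_rp smoothing width (> 0).
#' @return Numeric vector, `>= 0`, approaching `x` for large positive `x`
#'   and 0 for large negative `x`; equals `sigma_rp / sqrt(2 * pi)` at 0.
#' @export
smoothed_ramp <- function(x, sigma_rp) {
  if (sigma_rp <= 0) stop("sigma_rp must be positive", call. = FALSE)
  u <- x / sigma_rp
  x * pnorm(u) + sigma_rp * dnorm(u)
}

# ---------------------------------------------------------------------------
# Geometry tables shared by the continuity (FC) and bending (FE) components.
#
# A "ray" is a channel/sense pair: channel l holds ownership pointing along
# u_l; the boundary tangent is u_l rotated by 90 degrees, and sense
# sigma = +1/-1 picks one of the two travel directions along it.  The travel
# direction of ray (l, sigma) is the grid direction d = (l + sigma * L/4)
# mod L.  Half-lobe groupings of bS^2 along these rays measure incoming
# ("ending") and outgoing ("originating") boundary mass.

ray_dir <- function(l0, sig, L) (l0 + sig * (L / 4)) %% L

# Candidate originating rays for continuity: every ray whose travel
# direction lies within +-90 degrees of the ending ray's direction, i.e.
# straight continuations, shallow turns, and perpendicular occluders.
# Candidates that keep the ownership side relative to travel (sigma' =
# sigma) are continuations of the same boundary and count at full
# strength; candidates with the opposite ownership side can only be a
# different, occluding boundary and are discounted (third column 0/1 flags
# consistency).  Returned as a list over (l0, sigidx) of index matrices
# [l1, sigidx, consistent] into the lobe list.
fc_candidates <- function(L) {
  q <- L / 4
  out <- vector("list", 2 * L)
  for (l0 in 0:(L - 1)) for (si in 1:2) {
    sig <- c(1, -1)[si]
    din <- ray_dir(l0, sig, L)
    cand <- NULL
    for (dd in -q:q) {
      dout <- (din + dd) %% L
      cand <- rbind(cand,
                    c((dout - q) %% L + 1, 1, if (si == 1) 1 else 0),
                    c((dout + q) %% L + 1, 2, if (si == 2) 1 else 0))
    }
    out[[2 * l0 + si]] <- cand
  }
  out
}

# Bending pairs: incoming ray (l, sigma) turning by delta_l direction steps
# (0 < |delta_l| <= L/4) into the outgoing ray (l + delta_l, sigma); the
# ownership side relative to travel is preserved (sigma' = sigma).  The turn
# is concave when it rotates away from the owned side: sign(delta_l) ==
# sigma.  Weight (dtheta / pi)^2, times kappa for concave turns.
fe_pairs <- function(L, kappa) {
  q <- L / 4
  rows <- list()
  for (l0 in 0:(L - 1)) for (si in 1:2) {
    sig <- c(1, -1)[si]
    for (dl in setdiff(-q:q, 0)) {
      dtheta <- 2 * pi * dl / L
      w <- (dtheta / pi)^2 * if (sign(dl) == sig) kappa else 1
      rows[[length(rows) + 1]] <-
        c(gi_l = l0 + 1, gi_s = 3 - si,                 # incoming mass lobe
          go_l = (l0 + dl) %% L + 1, go_s = si, w = w)
    }
  }
  do.call(rbind, rows)
}

# Sparse taps of the oriented half-lobe kernel: a cone of half-angle
# 2.5 * sigma_phi around grid direction d, Gaussian in distance (width
# lambda, truncated at 2 * lambda) and in off-axis angle, normalized to
# unit sum.  Returns list(di, dj, w).
#
# For continuity candidates, the off-canvas fraction of a lobe counts as
# continuation at the ending's own strength (the canvas border cuts the
# view, not the object), so a boundary running into the border is not
# mistaken for a dangling ending.
lobe_taps <- function(d0, L, lambda, sigma_phi) {
  theta <- 2 * pi * d0 / L
  # radius capped at 12 px: only the heavily smoothed coarse relaxation
  # scales would exceed it, and a 12-px grouping reach is already several
  # times the structures on these canvases
  rad <- min(max(2L, ceiling(2 * lambda)), 12L)
  di <- as.vector(matrix(-rad:rad, 2 * rad + 1, 2 * rad + 1))
  dj <- as.vector(t(matrix(-rad:rad, 2 * rad + 1, 2 * rad + 1)))
  dx <- dj; dy <- -di
  dist <- sqrt(dx^2 + dy^2)
  keep <- dist > 0 & dist <= rad
  di <- di[keep]; dj <- dj[keep]; dx <- dx[keep]; dy <- dy[keep]
  dist <- dist[keep]
  cosphi <- pmin(1, pmax(-1, (dx * cos(theta) + dy * sin(theta)) / dist))
  phi <- acos(cosphi)
  keep <- phi <= 2.5 * sigma_phi
  w <- exp(-dist[keep]^2 / (2 * lambda^2)) * exp(-phi[keep]^2 / (2 * sigma_phi^2))
  list(di = as.integer(di[keep]), dj = as.integer(dj[keep]), w = w / sum(w))
}

# ---------------------------------------------------------------------------
# Cost context: everything that depends on the image, the parameters and the
# relaxation scale, but not on the border-ownership map.

# Scale multipliers of the relaxation schedule at scale parameter s.
# s = 0 gives the plain ("pure") functional used to rank interpretations.
scale_multipliers <- function(schedule, s) {
  list(b = schedule$sB0 + schedule$sBS * s,
       x = schedule$sX0 + schedule$sXS * s,
       r = schedule$sR0 + schedule$sRS * s)
}

bo_cost_context <- function(I, params, mult = list(b = 1, x = 1, r = 1)) {
  L <- params$L
  H <- nrow(I); W <- ncol(I)
  N <- params$n_scales
  ctx <- list(
    H = H, W = W, L = L, N = N, Tnorm = H * W * L,
    params = params,
    Wang = angle_smooth_matrix(L, params$sigma_SA),
    ksx = gauss_kernel1d(params$sigma_SX * mult$b),
    sigR = params$sigma_RP * mult$r,
    m_dev = -(L / 4 - 1):(L / 4 - 1)
  )
  # index tables for the C++ continuity/bending kernel; the lobe-map matrix
  # column of channel/sense (l1, si) is 2 * (l1 - 1) + si
  ocol <- function(tab) 2 * (tab[, 1] - 1) + tab[, 2]
  cand <- fc_candidates(L)
  ctx$cand <- t(vapply(cand, ocol, numeric(nrow(cand[[1]]))))
  storage.mode(ctx$cand) <- "integer"
  gam <- t(vapply(cand, function(tab)
    ifelse(tab[, 3] == 1, 1, params$gamma_occ), numeric(nrow(cand[[1]]))))
  ctx$cgam <- gam
  rays <- expand.grid(si = 1:2, l0 = 0:(L - 1))  # ray r = 2 * l0 + si
  ctx$ee_idx <- as.integer(2 * rays$l0 + (3 - rays$si))
  fe <- fe_pairs(L, params$kappa)
  ctx$fe_gi <- as.integer(2 * (fe[, "gi_l"] - 1) + fe[, "gi_s"])
  ctx$fe_go <- as.integer(2 * (fe[, "go_l"] - 1) + fe[, "go_s"])
  ctx$fe_w <- fe[, "w"]
  ctx$cm <- cos(2 * pi * ctx$m_dev / L)^2
  ctx$TN <- sum(ctx$cm)
  ctx$rho0 <- ctx$sigR / sqrt(2 * pi)
  ctx$A2 <- ctx$wV <- ctx$kN <- ctx$taps <- vector("list", N)
  for (n in seq_len(N)) {
    sc <- mult$x * params$mu^(n - 1)
    A <- edge_responses(I, params$sigma_A * sc, L)
    ctx$A2[[n]] <- lapply(seq_len(L), function(l1) A[, , l1]^2)
    ctx$wV[[n]] <- lapply(ctx$A2[[n]], function(a2)
      params$eps_V / (a2 + params$eps_V))
    ctx$kN[[n]] <- gauss_kernel1d(params$sigma_N * sc)
    ones <- matrix(1, H, W)
    ctx$taps[[n]] <- lapply(0:(L - 1), function(d0) {
      tp <- lobe_taps(d0, L, params$lambda_C * sc, params$sigma_phi)
      tp$ofrac <- pmin(pmax(1 - conv2_taps(ones, tp$di, tp$dj, tp$w), 0), 1)
      tp
    })
  }
  ctx
}

# Full evaluation of the functional (and, optionally, its gradient) at one
# relaxation scale.  Returns value, per-component values (unweighted,
# scale-averaged) and the gradient with respect to the raw map b.
bo_cost_eval <- function(b, ctx, grad = FALSE) {
  p <- ctx$params
  L <- ctx$L; N <- ctx$N; Tn <- ctx$Tnorm
  bS <- smooth_bo_with(b, ctx$Wang, ctx$ksx)
  P <- lapply(seq_len(L), function(l1) bS[, , l1]^2)
  comps <- c(FA = 0, FR = 0, FV = 0, FN = 0, FC = 0, FE = 0)
  if (grad) dP <- lapply(seq_len(L), function(l1) matrix(0, ctx$H, ctx$W))
  half <- L / 2
  for (n in seq_len(N)) {
    A2 <- ctx$A2[[n]]; wV <- ctx$wV[[n]]
    # -- quadratic/quartic pointwise components ----------------------------
    fa <- fr <- fv <- 0
    for (l1 in seq_len(L)) {
      fa <- fa - sum(A2[[l1]] * P[[l1]])
      fr <- fr + sum(P[[l1]]^2)
      fv <- fv + sum(wV[[l1]] * P[[l1]])
    }
    comps["FA"] <- comps["FA"] + fa / (Tn * N)
    comps["FR"] <- comps["FR"] + fr / (Tn * N)
    comps["FV"] <- comps["FV"] + fv / (Tn * N)
    # -- one-sidedness -----------------------------------------------------
    Q <- lapply(P, conv2_sep, k = ctx$kN[[n]])
    fn <- 0
    for (l1 in seq_len(L)) for (mi in seq_along(ctx$m_dev)) {
      l2 <- (l1 - 1 + half + ctx$m_dev[mi]) %% L + 1
      fn <- fn + ctx$cm[mi] * sum(Q[[l1]] * Q[[l2]])
    }
    comps["FN"] <- comps["FN"] + fn / (Tn * ctx$TN * N)
    # -- continuity and bending --------------------------------------------
    # lobe maps as a (npix x 2L) matrix; column of (l1, si) = 2*(l1-1)+si;
    # Fof holds the off-canvas lobe fraction per ray
    O <- matrix(0, ctx$H * ctx$W, 2 * L)
    Fof <- matrix(0, ctx$H * ctx$W, 2 * L)
    for (l1 in seq_len(L)) for (si in 1:2) {
      d0 <- ray_dir(l1 - 1, c(1, -1)[si], L)
      tp <- ctx$taps[[n]][[d0 + 1]]
      O[, 2 * (l1 - 1) + si] <- conv2_taps(P[[l1]], tp$di, tp$dj, tp$w)
      Fof[, 2 * (l1 - 1) + si] <- tp$ofrac
    }
    res_fcfe <- fcfe_eval(O, Fof, ctx$cand, ctx$cgam, ctx$ee_idx,
                          ctx$fe_gi, ctx$fe_go,
                          ctx$fe_w, ctx$sigR, p$eps_C,
                          p$alpha_C / (Tn * N), p$alpha_E / (Tn * N), grad)
    comps["FC"] <- comps["FC"] + res_fcfe$fc / (Tn * N)
    comps["FE"] <- comps["FE"] + res_fcfe$fe / (Tn * N)
    # -- gradient accumulation for this scale ------------------------------
    if (grad) {
      dO <- res_fcfe$dO
      for (l1 in seq_len(L)) {
        # lobe adjoints (correlation with the offset-negated taps)
        for (si in 1:2) {
          d0 <- ray_dir(l1 - 1, c(1, -1)[si], L)
          tp <- ctx$taps[[n]][[d0 + 1]]
          dP[[l1]] <- dP[[l1]] +
            conv2_taps(matrix(dO[, 2 * (l1 - 1) + si], ctx$H, ctx$W),
                       -tp$di, -tp$dj, tp$w)
        }
        # pointwise components
        dP[[l1]] <- dP[[l1]] +
          (-p$alpha_A * A2[[l1]] + 2 * p$alpha_R * P[[l1]] +
             p$alpha_V * wV[[l1]]) / (Tn * N)
        # one-sidedness: dFN/dQ_l = 2 sum_m c_m Q_{l+L/2+m}; kernel symmetric
        dQ <- matrix(0, ctx$H, ctx$W)
        for (mi in seq_along(ctx$m_dev)) {
          l2 <- (l1 - 1 + half + ctx$m_dev[mi]) %% L + 1
          dQ <- dQ + 2 * ctx$cm[mi] * Q[[l2]]
        }
        dP[[l1]] <- dP[[l1]] +
          (p$alpha_N / (Tn * ctx$TN * N)) * conv2_sep(dQ, ctx$kN[[n]])
      }
    }
  }
  total <- p$alpha_A * comps["FA"] + p$alpha_R * comps["FR"] +
    p$alpha_V * comps["FV"] + p$alpha_N * comps["FN"] +
    p$alpha_C * comps["FC"] + p$alpha_E * comps["FE"]
  out <- list(value = unname(total), components = comps, bS = bS)
  if (grad) {
    dbS <- array(0, dim(b))
    for (l1 in seq_len(L)) dbS[, , l1] <- 2 * bS[, , l1] * dP[[l1]]
    out$grad <- smooth_bo_with(dbS, ctx$Wang, ctx$ksx)  # smoothing is self-adjoint
  }
  out
}
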