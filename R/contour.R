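# Recovering the top-most object's shape from a border-ownership map:
# a level-set balloon grows from a seed placed inside the owned side of the
# strongest ownership vector and is stopped by a friction term that vanishes
# where strong ownership points against the front.

#' Seed a level-set contour from a border-ownership map
#'
#' Places a small disk (radius 1.5 px) three pixels inside the object side
#' of the map's strongest ownership vector (ties broken by lowest row,
#' then column, then direction index) -- deep enough that the disk clears
#' the few-pixel-thick ownership wall it grows from.  The embedding
#' function `psi` is the signed distance to the disk, negative inside.
#'
#' @param b border-ownership array (`H x W x L`).
#' @return Object of class `bo_levelset`: list with `psi`, `dims`.
#' @export
seed_contour <- function(b) {
  if (all(b == 0)) stop("all-zero map: no seed available", call. = FALSE)
  idx <- which(abs(b) == max(abs(b)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE][1, ]
  L <- dim(b)[3]
  alpha <- 2 * pi * (idx[3] - 1) / L
  # object side: a few pixels along the ownership vector (y up = row down)
  ci <- idx[1] - round(3 * sin(alpha))
  cj <- idx[2] + round(3 * cos(alpha))
  H <- dim(b)[1]; W <- dim(b)[2]
  ci <- min(max(ci, 1), H); cj <- min(max(cj, 1), W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  psi <- sqrt((rows - ci)^2 + (cols - cj)^2) - 1.5
  structure(list(psi = psi, dims = dim(b), seed = c(ci, cj)),
            class = "bo_levelset")
}

#' Border-ownership friction field
#'
#' `q = sum_l w_l * b_l^2` with `w_l = exp(-beta_l^2 / (2 sigma_q^2))`,
#' `beta_l` the angle between direction `l` and the inward contour normal;
#' `h = 1 / (1 + q * R^2)`; `g = h` where `h >= g_t`, else 0.  The front
#' moves at speed proportional to `g`, so it stops where strong ownership
#' points against it.
#'
#' @param b border-ownership array.
#' @param nx,ny inward normal field components (math convention, y up),
#'   matrices matching the map's spatial dimensions.
#' @param R sharpness constant.
#' @param sigma_q angular width (rad) of the perpendicularity weighting.
#' @param g_t threshold below which the friction stops the front entirely.
#' @return Matrix `g` with values in `[0, 1]`.
#' @export
friction_field <- function(b, nx, ny, R, sigma_q, g_t) {
  L <- dim(b)[3]
  alpha <- 2 * pi * (seq_len(L) - 1) / L
  q <- matrix(0, dim(b)[1], dim(b)[2])
  nn <- pmax(sqrt(nx^2 + ny^2), 1e-12)
  for (l1 in seq_len(L)) {
    cosb <- (cos(alpha[l1]) * nx + sin(alpha[l1]) * ny) / nn
    beta <- acos(pmin(1, pmax(-1, cosb)))   # wrapped into [0, pi]
    q <- q + exp(-beta^2 / (2 * sigma_q^2)) * b[, , l1]^2
  }
  h <- 1 / (1 + q * R^2)
  ifelse(h >= g_t, h, 0)
}

#' Evolve the level-set contour to a binary object mask
#'
#' First-order upwind update of `psi` with outward front speed
#' `(v - k_weight * k) * g` (balloon force `v` minus curvature
#' regularization, gated by the friction `g`), CFL time step, and periodic
#' signed-distance reinitialization.  Stops when the mask changes by less
#' than 0.1% of the canvas over 50 steps, or at `max_steps`; the final
#' mask is grown by one pixel so it includes the ownership wall the front
#' stopped against.  A warning is issued if the front reaches the canvas
#' border (it is clipped there).
#'
#' @param state a [seed_contour()] result.
#' @param b border-ownership array.
#' @param settings a [contour_settings()].
#' @param snapshots optional integer vector of step numbers at which to
#'   record intermediate masks (returned as attribute `snapshots`).
#' @return Logical object mask (`TRUE` inside).
#' @export
evolve <- function(state, b, settings = contour_settings(),
                   snapshots = NULL) {
  psi <- state$psi
  H <- nrow(psi); W <- ncol(psi)
  changed_ref <- mask_of(psi)
  stable <- 0L
  snaps <- list()
  warned <- FALSE
  for (step in seq_len(settings$max_steps)) {
    grads <- upwind_gradients(psi)
    # inward normal (math coords): N = -grad(psi)/|grad|; gy flips sign
    # because rows grow downward
    nn <- pmax(sqrt(grads$cx^2 + grads$cy^2), 1e-12)
    nx <- -grads$cx / nn
    ny <- grads$cy / nn
    g <- friction_field(b, nx, ny, settings$R, settings$sigma_Q,
                        settings$g_T)
    k <- curvature(psi)
    speed <- (settings$v - settings$k_weight * k) * g   # outward speed
    dt <- 0.4 / max(max(abs(speed)), 1e-9)
    # Godunov upwind: psi_t = -speed * |grad psi|
    psi <- psi - dt * (pmax(speed, 0) * grads$plus +
                         pmin(speed, 0) * grads$minus)
    if (step %% settings$reinit_every == 0)
      psi <- signed_distance(mask_of(psi))
    m <- mask_of(psi)
    if (!warned && any(m[1, ] | m[H, ] | m[, 1] | m[, W])) {
      warning("contour reached the canvas border; clipping", call. = FALSE)
      warned <- TRUE
    }
    if (!is.null(snapshots) && step %in% snapshots)
      snaps[[as.character(step)]] <- m
    if (step %% 50 == 0) {
      if (sum(xor(m, changed_ref)) < 0.001 * H * W) break
      changed_ref <- m
    }
  }
  out <- dilate1(mask_of(psi))
  if (length(snaps)) attr(out, "snapshots") <- snaps
  out
}

mask_of <- function(psi) psi < 0

# Grow the mask by one pixel (8-neighbourhood): the front freezes one pixel
# short of the ownership wall it stops against, and the wall pixels carry
# the object's boundary, so they belong to the object.
dilate1 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(H) + dr, 1), H)
    cs <- pmin(pmax(seq_len(W) + dc, 1), W)
    out <- out | mask[rs, cs]
  }
  out
}

# Exact Euclidean signed distance to the mask boundary (negative inside).
# Grids here are tiny, so the quadratic-time exact computation is fine.
signed_distance <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(1e3, H, W))
  if (all(mask)) return(matrix(-1e3, H, W))
  shift <- function(m, dr, dc) {
    out <- matrix(NA, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  # boundary = object pixels with at least one background 4-neighbour
  # (off-canvas counts as background)
  inv <- !shift(mask, 1, 0) | !shift(mask, -1, 0) |
    !shift(mask, 0, 1) | !shift(mask, 0, -1)
  inv[is.na(inv)] <- TRUE
  boundary <- which(mask & inv, arr.ind = TRUE)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- matrix(Inf, H, W)
  for (i in seq_len(nrow(boundary)))
    d2 <- pmin(d2, (rows - boundary[i, 1])^2 + (cols - boundary[i, 2])^2)
  d <- sqrt(d2)
  # d is the distance to the nearest boundary *object* pixel; the interface
  # itself lies half a pixel beyond it
  ifelse(mask, -(d + 0.5), d - 0.5)
}

# One-sided and central differences for the upwind scheme.
upwind_gradients <- function(psi) {
  H <- nrow(psi); W <- ncol(psi)
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(H) + dr, 1), H)
    c <- pmin(pmax(seq_len(W) + dc, 1), W)
    m[r, c]
  }
  dxm <- psi - pad(psi, 0, -1); dxp <- pad(psi, 0, 1) - psi
  dym <- psi - pad(psi, -1, 0); dyp <- pad(psi, 1, 0) - psi
  gplus <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 +
                  pmax(dym, 0)^2 + pmin(dyp, 0)^2)
  gminus <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 +
                   pmin(dym, 0)^2 + pmax(dyp, 0)^2)
  cx <- (pad(psi, 0, 1) - pad(psi, 0, -1)) / 2
  cy <- (pad(psi, 1, 0) - pad(psi, -1, 0)) / 2   # along rows (downward)
  list(plus = gplus, minus = gminus, cx = cx, cy = cy)
}

# Mean curvature of the zero level set, clamped for stability.
curvature <- function(psi) {
  H <- nrow(psi); W <- ncol(psi)
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(H) + dr, 1), H)
    c <- pmin(pmax(seq_len(W) + dc, 1), W)
    m[r, c]
  }
  px <- (pad(psi, 0, 1) - pad(psi, 0, -1)) / 2
  py <- (pad(psi, 1, 0) - pad(psi, -1, 0)) / 2
  pxx <- pad(psi, 0, 1) - 2 * psi + pad(psi, 0, -1)
  pyy <- pad(psi, 1, 0) - 2 * psi + pad(psi, -1, 0)
  pxy <- (pad(psi, 1, 1) - pad(psi, 1, -1) -
            pad(psi, -1, 1) + pad(psi, -1, -1)) / 4
  denom <- (px^2 + py^2)^1.5 + 1e-9
  k <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / denom
  pmin(pmax(k, -1), 1)
}

#' Extract the top-most object from an interpretation
#'
#' Convenience wrapper: smooths the map (the raw map can be spiky along
#' the flat directions of the smoothing operator; the smoothed field is
#' the physically meaningful one), seeds the contour at the strongest
#' ownership vector and evolves it to a mask.
#'
#' @param interp an interpretation (list with `b`) or a bare map.
#' @param settings a [contour_settings()].
#' @param params a [model_params()] (smoothing widths).
#' @param snapshots optional step numbers at which to record masks.
#' @return Logical object mask.
#' @export
extract_object <- function(interp, settings = contour_settings(),
                           params = model_params(), snapshots = NULL) {
  b <- if (is.list(interp)) interp$b else interp
  bS <- smooth_bo(b, params$sigma_SA, params$sigma_SX)
  evolve(seed_contour(bS), bS, settings, snapshots = snapshots)
}
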