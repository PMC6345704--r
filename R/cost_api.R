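# User-facing cost-functional surface.  Component functions take the
# already-smoothed map bS (the functional always consumes the smoothed map);
# `total_cost`/`total_gradient` do the smoothing, the multi-scale averaging
# and the relaxation-scale handling themselves.

#' Cost components of the border-ownership functional
#'
#' Single-scale evaluations of the six components on a smoothed map `bS`.
#' All are normalized per site (`1 / (H * W * L)`), so values are
#' comparable across canvas sizes.
#'
#' * `cost_FA`: image-edge alignment, `-(1/T) * sum(A^2 * bS^2)` (negative:
#'   ownership on edges is rewarded; both polarities equally, since the
#'   edge response enters squared).
#' * `cost_FR`: strength limiting, `(1/T) * sum(bS^4)`.
#' * `cost_FV`: suppression away from edges,
#'   `(1/T) * sum(eps_V / (A^2 + eps_V) * bS^2)`.
#' * `cost_FN`: one-sidedness -- squared ownership is spatially blurred and
#'   products between nearly opposite directions (deviation `|m| < L/4`
#'   from `l + L/2`, weighted `cos^2(2*pi*m/L)`) are penalized.
#' * `cost_FC`: boundary continuity -- at every site, direction and travel
#'   sense, the ending-edge strength (half-lobe grouping of `bS^2` behind)
#'   should not exceed the best originating strength (maximal grouping over
#'   all continuations within 90 degrees, including perpendicular
#'   occluders); the excess passes through the smoothed ramp (minus the
#'   same ramp at `-E`, so each term is non-negative), gated by the soft
#'   ending indicator `Ee^2 / (Ee^2 + eps_C^2)` so sites where nothing
#'   ends contribute (essentially) nothing.
#' * `cost_FE`: bending -- products of incoming and outgoing lobe mass over
#'   all turns up to 90 degrees, weighted `(dtheta/pi)^2`, times `kappa`
#'   for concave turns (turns away from the owned side).
#'
#' @param bS smoothed border-ownership array (`H x W x L`).
#' @param A edge-response array from [edge_responses()], same dimensions.
#' @param eps_V softness constant of the suppression weight.
#' @param sigma_n spatial width (px) of the one-sidedness blur.
#' @param params a [model_params()] object (for `lambda_C`, `kappa`,
#'   `sigma_phi`, `sigma_RP`).
#' @return Scalar component value.
#' @name cost_components
NULL

#' @rdname cost_components
#' @export
cost_FA <- function(bS, A) {
  if (!identical(dim(bS), dim(A)))
    stop("bS and A have different dimensions", call. = FALSE)
  -mean(A^2 * bS^2)
}

#' @rdname cost_components
#' @export
cost_FR <- function(bS) mean(bS^4)

#' @rdname cost_components
#' @export
cost_FV <- function(bS, A, eps_V) {
  if (!identical(dim(bS), dim(A)))
    stop("bS and A have different dimensions", call. = FALSE)
  mean(eps_V / (A^2 + eps_V) * bS^2)
}

#' @rdname cost_components
#' @export
cost_FN <- function(bS, sigma_n) {
  d <- dim(bS); L <- d[3]; half <- L / 2
  k <- gauss_kernel1d(sigma_n)
  Q <- lapply(seq_len(L), function(l1) conv2_sep(bS[, , l1]^2, k))
  m_dev <- -(L / 4 - 1):(L / 4 - 1)
  cm <- cos(2 * pi * m_dev / L)^2
  acc <- 0
  for (l1 in seq_len(L)) for (mi in seq_along(m_dev)) {
    l2 <- (l1 - 1 + half + m_dev[mi]) %% L + 1
    acc <- acc + cm[mi] * sum(Q[[l1]] * Q[[l2]])
  }
  acc / (prod(d) * sum(cm))
}

# Shared single-scale lobe maps for the exported FC/FE evaluations.
lobe_maps_single <- function(bS, params, scale = 1) {
  d <- dim(bS); L <- d[3]
  taps <- lapply(0:(L - 1), function(d0)
    lobe_taps(d0, L, params$lambda_C * scale, params$sigma_phi))
  ones <- matrix(1, d[1], d[2])
  O <- vector("list", L)
  for (l1 in seq_len(L)) {
    O[[l1]] <- vector("list", 2)
    for (si in 1:2) {
      tp <- taps[[ray_dir(l1 - 1, c(1, -1)[si], L) + 1]]
      out <- conv2_taps(bS[, , l1]^2, tp$di, tp$dj, tp$w)
      attr(out, "ofrac") <- pmin(pmax(1 - conv2_taps(ones, tp$di, tp$dj, tp$w), 0), 1)
      O[[l1]][[si]] <- out
    }
  }
  O
}

#' @rdname cost_components
#' @export
cost_FC <- function(bS, params = model_params()) {
  d <- dim(bS); L <- d[3]
  O <- lobe_maps_single(bS, params)
  cand_all <- fc_candidates(L)
  sigR <- params$sigma_RP
  acc <- 0
  for (l0 in 0:(L - 1)) for (si in 1:2) {
    Ee <- unclass(O[[l0 + 1]][[3 - si]])
    cand <- cand_all[[2 * l0 + si]]
    E <- NULL
    for (ci in seq_len(nrow(cand))) {
      Oc <- O[[cand[ci, 1]]][[cand[ci, 2]]]
      gam <- if (cand[ci, 3] == 1) 1 else params$gamma_occ
      val <- gam * unclass(Oc) + attr(Oc, "ofrac") * Ee
      E <- if (is.null(E)) val else pmax(E, val)
    }
    gate <- Ee^2 / (Ee^2 + params$eps_C^2)
    acc <- acc +
      sum(gate * (smoothed_ramp(Ee - E, sigR) - smoothed_ramp(-E, sigR)))
  }
  acc / prod(d)
}

#' @rdname cost_components
#' @export
cost_FE <- function(bS, params = model_params()) {
  d <- dim(bS); L <- d[3]
  O <- lobe_maps_single(bS, params)
  tab <- fe_pairs(L, params$kappa)
  acc <- 0
  for (r in seq_len(nrow(tab))) {
    pr <- tab[r, ]
    acc <- acc + pr["w"] *
      sum(O[[pr["gi_l"]]][[pr["gi_s"]]] * O[[pr["go_l"]]][[pr["go_s"]]])
  }
  unname(acc) / prod(d)
}

#' Multi-scale averaging of a cost component
#'
#' Evaluates `component_fn` at the `n_scales` spatial-filter scale factors
#' `mu^0, mu^1, ...` and returns the mean -- the scale smoothing applied to
#' every component of the functional.
#'
#' @param component_fn function of one argument, the scale factor by which
#'   all spatial filter widths are multiplied; returns a scalar.
#' @param n_scales number of scales (`>= 1`).
#' @param mu scale growth factor (`> 1`; `n_scales = 1` reduces to the
#'   plain component).
#' @return Scalar mean over scales.
#' @export
multiscale <- function(component_fn, n_scales, mu) {
  mean(vapply(seq_len(n_scales) - 1,
              function(n) component_fn(mu^n), numeric(1)))
}

#' Total cost and gradient of the border-ownership functional
#'
#' Smooths the raw map (angular width `sigma_SA`; spatial width `sigma_SX`
#' times the schedule's border-ownership multiplier at relaxation scale
#' `s`), evaluates the six weighted components with all spatial filters
#' scaled by the schedule's filter multiplier (and averaged over the
#' `n_scales` multi-scale factors), the ramp width scaled by the ramp
#' multiplier, and returns the weighted sum.  `s = 0` gives the plain
#' ("pure") functional used to rank interpretations.
#'
#' @param b raw border-ownership array (`H x W x L`).
#' @param I image matrix, same spatial dimensions.
#' @param params a [model_params()].
#' @param s relaxation scale parameter (`>= 0`).
#' @param schedule a [relaxation_schedule()] supplying the scale-multiplier
#'   constants.
#' @return `total_cost`: scalar.  `total_gradient`: array like `b` with the
#'   partial derivative of the total cost with respect to every entry.
#'   `total_cost_components`: list with the total and the unweighted
#'   per-component values.
#' @export
total_cost <- function(b, I, params = model_params(), s = 0,
                       schedule = relaxation_schedule()) {
  ctx <- bo_cost_context(I, params, scale_multipliers(schedule, s))
  bo_cost_eval(b, ctx)$value
}

#' @rdname total_cost
#' @export
total_gradient <- function(b, I, params = model_params(), s = 0,
                           schedule = relaxation_schedule()) {
  ctx <- bo_cost_context(I, params, scale_multipliers(schedule, s))
  bo_cost_eval(b, ctx, grad = TRUE)$grad
}

#' @rdname total_cost
#' @export
total_cost_components <- function(b, I, params = model_params(), s = 0,
                                  schedule = relaxation_schedule()) {
  ctx <- bo_cost_context(I, params, scale_multipliers(schedule, s))
  res <- bo_cost_eval(b, ctx)
  list(value = res$value, components = res$components)
}
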