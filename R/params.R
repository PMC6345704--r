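#' Model parameters for the border-ownership cost functional
#'
#' Returns the full set of functional weights and filter widths, with the
#' package's frozen defaults.  The same single configuration is used for
#' every stimulus; see the methods vignette for what each constant does and
#' how the defaults were fixed.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `bo_params` with elements:
#' \describe{
#'   \item{L}{number of discrete directions (divisible by 4; default 12).}
#'   \item{alpha_A, alpha_R, alpha_V, alpha_N, alpha_C, alpha_E}{weights of
#'     the six cost components: image-edge alignment, strength limiting,
#'     suppression off edges, one-sidedness, continuity, bending.}
#'   \item{sigma_A}{width (px) of the oriented odd edge filter.}
#'   \item{eps_V}{softness constant of the off-edge suppression weight.}
#'   \item{sigma_N}{spatial width (px) of the one-sidedness filter.}
#'   \item{sigma_SA, sigma_SX}{angular (direction steps) and spatial (px)
#'     widths of the border-ownership map smoothing.}
#'   \item{sigma_RP}{width of the Gaussian that smooths the ramp function.}
#'   \item{n_scales, mu}{multi-scale averaging: number of scales and the
#'     factor by which spatial filters grow per scale (`mu > 1`).}
#'   \item{lambda_C}{length (px) of the half-lobe grouping used by the
#'     continuity and bending components.}
#'   \item{kappa}{extra penalty factor for concave bends (`> 1`).}
#'   \item{sigma_phi}{angular width (rad) of the half-lobe cone.}
#'   \item{eps_C}{softness of the ending gate in the continuity component
#'     (squared-strength units): sites whose ending mass is well below
#'     `eps_C` contribute (almost) nothing to the continuity cost.}
#'   \item{gamma_occ}{discount applied to originating candidates whose
#'     ownership side is opposite to the ending boundary's: such mass can
#'     only belong to a different, occluding boundary, which restores
#'     continuity almost (but not quite) as well as a true continuation.}
#' }
#' @export
model_params <- function(...) {
  p <- list(
    L = 12L,
    alpha_A = 6.0, alpha_R = 1.0, alpha_V = 0.5,
    alpha_N = 10.0, alpha_C = 1.0, alpha_E = 0.5,
    sigma_A = 1.0, eps_V = 0.01, sigma_N = 1.0,
    sigma_SA = 0.6, sigma_SX = 0.75, sigma_RP = 0.01,
    n_scales = 2L, mu = sqrt(2),
    lambda_C = 3.4, kappa = 3.0, sigma_phi = pi / 12, eps_C = 0.005,
    gamma_occ = 0.8
  )
  p <- override(p, list(...))
  stopifnot(p$L %% 4 == 0, p$mu > 1, p$n_scales >= 1, p$kappa > 1,
            p$sigma_A > 0, p$sigma_N > 0, p$sigma_SA > 0, p$sigma_SX > 0,
            p$sigma_RP > 0, p$lambda_C > 0, p$eps_V > 0, p$eps_C > 0,
            p$gamma_occ > 0, p$gamma_occ <= 1)
  structure(p, class = "bo_params")
}

#' Coarse-to-fine relaxation schedule
#'
#' The scale parameter `s` starts at `s0` and is multiplied by `sR` after
#' each minimization pass until it falls to `sM` or below.  At scale `s` the
#' border-ownership smoothing width is multiplied by `sB0 + sBS * s`, every
#' spatial filter inside the cost components by `sX0 + sXS * s`, and the
#' ramp-smoothing width by `sR0 + sRS * s`, so the functional is heavily
#' smoothed early (few, deep minima) and close to its plain form at the end.
#'
#' @param ... named overrides.
#' @return A list of class `bo_schedule`.
#' @export
relaxation_schedule <- function(...) {
  p <- list(s0 = 1, sR = 0.4, sM = 0.15,
            sB0 = 1, sBS = 1, sX0 = 1, sXS = 3, sR0 = 1, sRS = 1)
  p <- override(p, list(...))
  stopifnot(p$s0 >= p$sM, p$sM > 0, p$sR > 0, p$sR < 1,
            p$sB0 >= 0, p$sX0 >= 0, p$sR0 >= 0,
            p$sB0 + p$sBS * p$sM > 0, p$sX0 + p$sXS * p$sM > 0,
            p$sR0 + p$sRS * p$sM > 0)
  structure(p, class = "bo_schedule")
}

#' Gradient-descent settings
#'
#' Controls for the parabolic-step descent used at each relaxation scale.
#'
#' @param ... named overrides: `max_iter` (per smoothed relaxation pass),
#'   `final_max_iter` (for the last, unsmoothed pass, which defines the
#'   reported minimum and so gets a larger budget), `tol` (relative cost
#'   decrease; descent stops after `tol_streak` consecutive iterations below
#'   it), `step0` (initial trial step along the normalized negative
#'   gradient), `grad_floor` (gradient norm below which the iterate is
#'   declared stationary), `max_backtrack`.
#' @return A list of class `bo_descent`.
#' @export
descent_settings <- function(...) {
  p <- list(max_iter = 150L, final_max_iter = 300L, tol = 1e-6,
            tol_streak = 3L,
            step0 = 0.1, grad_floor = 1e-12, max_backtrack = 30L)
  p <- override(p, list(...))
  stopifnot(p$max_iter >= 1, p$tol > 0, p$step0 > 0, p$grad_floor > 0)
  structure(p, class = "bo_descent")
}

#' Repulsive-particle settings for the multiple-minima search
#'
#' @param ... named overrides: `rho` (base strength of the inverse-distance
#'   repulsion), `dT` (distance threshold, applied to the smoothed maps,
#'   below which two minima count as the same interpretation), `tau`
#'   (escalation factor `> 1`), `tau_max`
#'   (stop once the factor would exceed this), `eps_rep` (regularizer,
#'   default `dT / 10`), `max_interpretations`.
#' @return A list of class `bo_repulsion`.
#' @export
repulsion_settings <- function(...) {
  p <- list(rho = 2e-4, dT = 4e-3, tau = 4, tau_max = 16,
            eps_rep = NULL, max_interpretations = 4L)
  p <- override(p, list(...))
  if (is.null(p$eps_rep)) p$eps_rep <- p$dT / 10
  stopifnot(p$rho > 0, p$dT > 0, p$tau > 1, p$tau_max >= p$tau,
            p$eps_rep > 0, p$max_interpretations >= 1)
  structure(p, class = "bo_repulsion")
}

#' Level-set contour-extraction settings
#'
#' @param ... named overrides: `v` (balloon force), `R` (friction sharpness),
#'   `sigma_Q` (angular width of the perpendicularity weighting, rad),
#'   `g_T` (friction threshold below which the front stops), `max_steps`,
#'   `reinit_every` (signed-distance reinitialization period),
#'   `k_weight` (weight of the curvature term).
#' @return A list of class `bo_contour`.
#' @export
contour_settings <- function(...) {
  p <- list(v = 1.0, R = 16, sigma_Q = pi / 5, g_T = 0.25,
            max_steps = 2000L, reinit_every = 20L, k_weight = 0.25)
  p <- override(p, list(...))
  stopifnot(p$v > 0, p$R > 0, p$sigma_Q > 0, p$g_T >= 0, p$g_T <= 1)
  structure(p, class = "bo_contour")
}

#' Full run configuration
#'
#' Bundles model parameters, relaxation schedule, descent, repulsion and
#' contour settings with a seed.  Round-trips losslessly through YAML via
#' [read_config()] / [write_config()].
#'
#' @param params,schedule,descent,repulsion,contour component settings.
#' @param seed integer seed for the random initial map.
#' @return A list of class `bo_config`.
#' @export
bo_config <- function(params = model_params(),
                      schedule = relaxation_schedule(),
                      descent = descent_settings(),
                      repulsion = repulsion_settings(),
                      contour = contour_settings(),
                      seed = 1L) {
  structure(list(params = params, schedule = schedule, descent = descent,
                 repulsion = repulsion, contour = contour,
                 seed = as.integer(seed), version = "bomap-config-1"),
            class = "bo_config")
}

#' @rdname bo_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- lapply(unclass(config), function(el)
    if (is.list(el)) unclass(el) else el)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname bo_config
#' @param config a `bo_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("params", "schedule", "descent", "repulsion", "contour", "seed")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bo_config(params = do.call(model_params, x$params),
            schedule = do.call(relaxation_schedule, x$schedule),
            descent = do.call(descent_settings, x$descent),
            repulsion = do.call(repulsion_settings, x$repulsion),
            contour = do.call(contour_settings, x$contour),
            seed = x$seed)
}

override <- function(defaults, dots) {
  if (length(dots) == 0) return(defaults)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  modifyList(defaults, dots)
}
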