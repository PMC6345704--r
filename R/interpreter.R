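# Enumerating image interpretations: repeated relaxations with repulsive
# particles at already-found minima, acceptance by map distance, escalation
# of the repulsion when the search keeps falling into a known minimum.

#' Repulsive-particle potential
#'
#' `factor * rho * sum_i 1 / (bo_distance(b, p_i) + eps_rep)` -- an
#' inverse-distance ("electric") potential centered at each particle,
#' added to the cost during repulsed searches only.  Strictly decreasing in
#' the distance to every particle; `eps_rep` keeps it finite at the
#' particle itself.
#'
#' @param b border-ownership map.
#' @param particles list of particle maps (possibly empty).
#' @param repulsion a [repulsion_settings()].
#' @param factor escalation factor (`>= 1`).
#' @return Scalar (0 when `particles` is empty).
#' @export
repulsion_term <- function(b, particles, repulsion = repulsion_settings(),
                           factor = 1) {
  if (length(particles) == 0) return(0)
  sum(vapply(particles, function(p)
    1 / (bo_distance(b, p) + repulsion$eps_rep), numeric(1))) *
    factor * repulsion$rho
}

#' Find multiple image interpretations
#'
#' Enumerates local minima of the functional, each a self-consistent
#' assignment of boundaries and ownership to the image:
#'
#' 1. Relax from the random start `b_R` to the first minimum `b1`.
#' 2. Place a repulsive particle at `b1` and restart from the *same* `b_R`;
#'    the repulsion pushes the search past `b1` to some `b2'`.
#' 3. Re-relax from `b2'` with the repulsion removed, giving a genuine
#'    minimum `b2` of the pure functional.
#' 4. If `b2` is farther than `dT` from every accepted minimum, accept it,
#'    reset the escalation factor and add a particle at `b2`; otherwise
#'    multiply the factor by `tau`, keep an auxiliary particle at the
#'    rejected `b2'` (auxiliaries persist until the next acceptance), and
#'    retry from `b_R`.
#' 5. Stop when the factor would exceed `tau_max` without producing a new
#'    minimum, or when `max_interpretations` are found.
#'
#' @param I image matrix in `[0, 1]`.
#' @param params a [model_params()].
#' @param schedule a [relaxation_schedule()].
#' @param settings a [descent_settings()].
#' @param repulsion a [repulsion_settings()].
#' @param seed integer seed for the random start.
#' @param verbose print per-minimum progress.
#' @return Object of class `bo_interpretations`: a list of interpretations
#'   sorted by ascending pure cost, each with elements `b`, `cost`, `rank`,
#'   `provenance` (seed and repulsion history), plus attributes `seed` and
#'   `image`.
#' @export
find_interpretations <- function(I, params = model_params(),
                                 schedule = relaxation_schedule(),
                                 settings = descent_settings(),
                                 repulsion = repulsion_settings(),
                                 seed = 1L, verbose = FALSE) {
  dims <- c(nrow(I), ncol(I), params$L)
  bR <- random_init(dims, seed)
  smooth_of <- function(b) smooth_bo(b, params$sigma_SA, params$sigma_SX)
  # repulsed searches only need to land in the right basin -- the clean
  # re-descent does the precise minimization -- so they run with a reduced
  # final-pass budget
  settings_light <- settings
  settings_light$final_max_iter <- settings$max_iter
  relax <- function(b0, particles = NULL, factor = 1)
    gradual_relaxation(I, b0, params, schedule,
                       if (length(particles)) settings_light else settings,
                       particles = particles, repulsion = repulsion,
                       factor = factor)
  # the clean re-relaxation after a repulsed search starts from an already
  # fine-structured map; it only runs the final scale and the plain pass,
  # so the coarse smoothing cannot collapse it back into the first basin
  sched_fine <- schedule
  sched_fine$s0 <- schedule$sM
  relax_clean <- function(b0, particles = NULL, factor = 1)
    gradual_relaxation(I, b0, params, sched_fine, settings)
  # an interpretation must beat the null reading (the empty map, cost 0):
  # a candidate that does not is a stray end point of the repulsed search,
  # not a perception of the image
  accepted <- find_minima(relax, bR, repulsion,
                          relax_clean = relax_clean,
                          identity_distance = function(b1, b2)
                            bo_distance(smooth_of(b1), smooth_of(b2)),
                          accept_state = function(st) st$value < 0,
                          verbose = verbose)
  for (i in seq_along(accepted))
    accepted[[i]]$provenance$seed <- seed
  structure(accepted, class = "bo_interpretations", seed = seed, image = I)
}

#' Enumerate local minima of an arbitrary objective by repulsive particles
#'
#' The search loop behind [find_interpretations()], usable with any
#' relaxation routine: `relax(b0, particles, factor)` must minimize the
#' objective (adding the repulsion of `particles` scaled by `factor` when
#' given) and return `list(b, value)` with `value` the repulsion-free cost.
#'
#' @param relax the relaxation closure described above.
#' @param relax_clean relaxation used for the repulsion-free re-descent
#'   from a repulsed end point (defaults to `relax`).
#' @param b0 the common random starting point for every search.
#' @param repulsion a [repulsion_settings()].
#' @param identity_distance function of two states returning the distance
#'   used for the accept/reject decision (defaults to [bo_distance()]).
#' @param accept_state predicate a candidate minimum must satisfy to be
#'   accepted (rejects are treated like duplicates: the repulsion
#'   escalates and the search continues).
#' @param verbose print progress.
#' @return List of minima sorted by ascending value, each with elements
#'   `b`, `cost`, `rank` and `provenance` (escalation factor and attempt
#'   count when found).
#' @export
find_minima <- function(relax, b0, repulsion = repulsion_settings(),
                        relax_clean = relax,
                        identity_distance = bo_distance,
                        accept_state = function(state) TRUE,
                        verbose = FALSE) {
  first <- relax(b0)
  accepted <- list(list(b = first$b, cost = first$value,
                        provenance = list(factor = 1, attempts = 1L)))
  particles <- list(first$b)
  aux <- list()
  factor <- 1
  attempts <- 1L
  repeat {
    if (length(accepted) >= repulsion$max_interpretations) break
    attempts <- attempts + 1L
    repulsed <- relax(b0, particles = c(particles, aux), factor = factor)
    clean <- relax_clean(repulsed$b)
    dists <- vapply(accepted, function(a) identity_distance(clean$b, a$b),
                    numeric(1))
    if (min(dists) > repulsion$dT && accept_state(clean)) {
      accepted[[length(accepted) + 1]] <-
        list(b = clean$b, cost = clean$value,
             provenance = list(factor = factor, attempts = attempts))
      particles[[length(particles) + 1]] <- clean$b
      aux <- list()
      factor <- 1
      if (verbose)
        message(sprintf("accepted minimum %d (cost %.6g)",
                        length(accepted), clean$value))
    } else {
      aux[[length(aux) + 1]] <- repulsed$b
      factor <- factor * repulsion$tau
      if (factor > repulsion$tau_max) break
      if (verbose)
        message(sprintf("duplicate minimum, escalating repulsion to %g",
                        factor))
    }
  }
  ord <- order(vapply(accepted, `[[`, numeric(1), "cost"))
  accepted <- accepted[ord]
  for (i in seq_along(accepted)) accepted[[i]]$rank <- i
  accepted
}

#' @export
print.bo_interpretations <- function(x, ...) {
  cat(sprintf("%d image interpretation(s):\n", length(x)))
  for (it in x)
    cat(sprintf("  rank %d: cost %.6g\n", it$rank, it$cost))
  invisible(x)
}

#' Flag interpretations whose boundaries bridge edge-free image regions
#'
#' Extracts the interpretation's top-most object by level-set evolution
#' (the front stops against the interpretation's own ownership walls, real
#' or illusory) and measures which fraction of the extracted mask's
#' boundary runs through image regions with (almost) no intensity
#' gradient.  A pixel supports a real edge when any pixel in its
#' 8-neighbourhood has an oriented edge-response magnitude of at least 10%
#' of the image-wide maximum; canvas-border pixels are not counted as
#' boundary.  Real objects give scores near 0 -- their extracted outline
#' lies on intensity edges; interpretations with illusory contours, as on
#' the sides of a Kanizsa square, give clearly positive scores because the
#' front also stops along the edge-free bridge segments.
#'
#' @param interp one interpretation (list with element `b`) or a bare map.
#' @param I image matrix.
#' @param params a [model_params()] (edge filter and smoothing widths).
#' @param fraction_threshold score above which the interpretation is
#'   flagged illusory (default 0.05: real-boundary scores sit at 0, while
#'   a single bridged gap already contributes well above this).
#' @param contour a [contour_settings()] for the extraction.
#' @return List with `illusory` (logical flag), `score` (the edge-free
#'   boundary fraction) and `mask` (the extracted object).
#' @export
classify_illusory <- function(interp, I, params = model_params(),
                              fraction_threshold = 0.05,
                              contour = contour_settings()) {
  b <- if (is.list(interp)) interp$b else interp
  mask <- suppressWarnings(extract_object(b, contour, params))
  A <- edge_responses(I, params$sigma_A, params$L)
  amax <- apply(abs(A), c(1, 2), max)
  H <- nrow(I); W <- ncol(I)
  near_edge <- matrix(FALSE, H, W)
  edgy <- if (max(amax) == 0) matrix(FALSE, H, W) else
    amax >= 0.1 * max(amax)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(H) + dr, 1), H)
    cs <- pmin(pmax(seq_len(W) + dc, 1), W)
    near_edge <- near_edge | edgy[rs, cs]
  }
  # mask boundary: object pixels with a background 4-neighbour, interior to
  # the canvas
  shift <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(H) + dr, 1), H)
    c <- pmin(pmax(seq_len(W) + dc, 1), W)
    m[r, c]
  }
  boundary <- mask & (!shift(mask, 1, 0) | !shift(mask, -1, 0) |
                        !shift(mask, 0, 1) | !shift(mask, 0, -1))
  boundary[c(1, H), ] <- FALSE
  boundary[, c(1, W)] <- FALSE
  n_bd <- sum(boundary)
  score <- if (n_bd == 0) 0 else sum(boundary & !near_edge) / n_bd
  list(illusory = score > fraction_threshold, score = score, mask = mask)
}
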