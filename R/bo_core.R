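# Border-ownership map core: representation, smoothing, distance, init, I/O.
#
# A border-ownership map is a 3-D array with dim = c(height, width, L):
# slice l + 1 holds the signed boundary strength for direction
# alpha_l = 2*pi*l/L (counter-clockwise from +x, y up).  Positive and
# negative values mean the same thing -- the map only ever enters the cost
# through its square.

#' Discrete direction set
#'
#' @param L number of equally spaced directions; must be divisible by 4 so
#'   that opposite (`l + L/2`) and perpendicular (`l +- L/4`) directions are
#'   themselves grid directions.
#' @return List with `L`, `alpha` (angles, rad), and unit-vector components
#'   `ux`, `uy` (math convention, y up).
#' @export
direction_set <- function(L = 12L) {
  if (L %% 4 != 0) stop("L must be divisible by 4", call. = FALSE)
  alpha <- 2 * pi * (seq_len(L) - 1) / L
  list(L = as.integer(L), alpha = alpha, ux = cos(alpha), uy = sin(alpha))
}

#' Random initial border-ownership map
#'
#' Values are drawn i.i.d. uniform in `[0.01, 0.02]`.  Starting slightly off
#' zero matters: the zero map is a stationary point of the functional (every
#' component is at least quadratic), so a descent started there would never
#' move.  The caller's RNG state is left untouched.
#'
#' @param dims integer vector `c(height, width, L)`.
#' @param seed integer seed; the same seed always yields the same map.
#' @return A `height x width x L` array.
#' @export
random_init <- function(dims, seed) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  array(runif(prod(dims), 0.01, 0.02), dim = dims)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# Circular angular smoothing matrix: W[k, l] is the weight with which input
# direction k contributes to smoothed direction l; the Gaussian offset j
# runs over [-(L/2 - 1), L/2] wrapped circularly and is normalized to sum 1.
angle_smooth_matrix <- function(L, sigma_sa) {
  j <- seq(-(L / 2 - 1), L / 2)
  f <- exp(-j^2 / (2 * sigma_sa^2))
  f <- f / sum(f)
  W <- matrix(0, L, L)
  for (l in 0:(L - 1)) {
    k <- (l + j) %% L
    W[k + 1, l + 1] <- f
  }
  W
}

# 1-D Gaussian kernel, truncated at ceiling(3 sigma), normalized to sum 1.
gauss_kernel1d <- function(sigma) {
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-m:m)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a border-ownership map in angle and space
#'
#' Circular Gaussian convolution over the direction index (kernel
#' normalized to sum 1) followed by spatial Gaussian filtering of each
#' direction slice (separable, zero-padded: there is no ownership outside
#' the canvas, so border sites attenuate).
#'
#' @param b `height x width x L` array.
#' @param sigma_sa angular width in direction steps (> 0).
#' @param sigma_sx spatial width in pixels (> 0).
#' @return Array of the same dimensions.
#' @export
smooth_bo <- function(b, sigma_sa, sigma_sx) {
  if (sigma_sa <= 0 || sigma_sx <= 0)
    stop("smoothing widths must be positive", call. = FALSE)
  d <- dim(b)
  W <- angle_smooth_matrix(d[3], sigma_sa)
  k <- gauss_kernel1d(sigma_sx)
  smooth_bo_with(b, W, k)
}

# Internals shared with the cost evaluator (kernels precomputed once).
smooth_bo_with <- function(b, W, k) {
  d <- dim(b)
  bm <- matrix(b, d[1] * d[2], d[3]) %*% W
  out <- array(0, d)
  for (l in seq_len(d[3]))
    out[, , l] <- conv2_sep(matrix(bm[, l], d[1], d[2]), k)
  out
}

#' Distance between two border-ownership maps
#'
#' `mean(|b1^2 - b2^2|)` -- the per-site absolute difference of squared
#' strengths.  Sign-blind by construction (a map and its negation are at
#' distance zero), so it is a metric on squared maps, not on the maps
#' themselves.
#'
#' @param b1,b2 arrays of identical dimensions.
#' @return Non-negative scalar.
#' @export
bo_distance <- function(b1, b2) {
  if (!identical(dim(b1), dim(b2)))
    stop("maps have different dimensions", call. = FALSE)
  mean(abs(b1^2 - b2^2))
}

#' Save / load a border-ownership map
#'
#' The `.bo` format is a single JSON header line (dims, cost, and optional
#' metadata) followed by the flat little-endian float64 payload in R array
#' order.  Round trips are bit-exact.
#'
#' @param b `height x width x L` array.
#' @param cost the cost value associated with the map (NA allowed).
#' @param path file path.
#' @param meta optional named list of extra header fields (seed, params
#'   hash, ...); stored as-is and returned on load.
#' @return `load_bo` returns a list with elements `b`, `cost`, `meta`.
#' @export
save_bo <- function(b, cost, path, meta = list()) {
  stopifnot(is.array(b), length(dim(b)) == 3)
  header <- c(list(dims = dim(b), cost = cost), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
                   "\n"), con, eos = NULL)
  writeBin(as.numeric(b), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_bo
#' @export
load_bo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  line <- readLines(con, n = 1)
  header <- tryCatch(jsonlite::fromJSON(line),
                     error = function(e) stop("corrupt .bo header", call. = FALSE))
  if (is.null(header$dims) || length(header$dims) != 3)
    stop("corrupt .bo header: missing dims", call. = FALSE)
  n <- prod(header$dims)
  # readLines consumed through the newline only if the connection is text;
  # on a binary connection we must seek past the header ourselves.
  seek(con, nchar(line, type = "bytes") + 1)
  payload <- readBin(con, "numeric", n + 1, size = 8, endian = "little")
  if (length(payload) != n)
    stop("payload length does not match header dims", call. = FALSE)
  meta <- header[setdiff(names(header), c("dims", "cost"))]
  list(b = array(payload, dim = header$dims),
       cost = if (is.null(header$cost)) NA_real_ else header$cost,
       meta = meta)
}
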