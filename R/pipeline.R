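# End-to-end orchestration: stimulus/image in, ranked interpretations, JSON
# ranking, overlays and (optionally) the extracted top-most object out.

#' Run the full figure-ground pipeline on an image
#'
#' Finds the ranked interpretations of `image` under `config`, writes one
#' `.bo` file and one quiver-overlay PNG per interpretation, a
#' `ranking.json` with costs, illusory flags and pairwise map distances,
#' the resolved configuration (`config.yaml`), and optionally the extracted
#' top-most object mask (`mask.png`).
#'
#' @param image a raster matrix, or a path to a PGM/PNG file.
#' @param config a [bo_config()].
#' @param out_dir output directory (created if missing).
#' @param extract also run the level-set extraction on the first
#'   interpretation and write `mask.png`.
#' @return Invisibly, the interpretation set, with attribute `out_dir`.
#' @export
run_pipeline <- function(image, config = bo_config(), out_dir,
                         extract = FALSE) {
  if (is.character(image)) image <- read_raster(image)
  stopifnot(inherits(config, "bo_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  interps <- find_interpretations(
    image, params = config$params, schedule = config$schedule,
    settings = config$descent, repulsion = config$repulsion,
    seed = config$seed)
  n <- length(interps)
  flags <- lapply(interps, classify_illusory, I = image,
                  params = config$params)
  dists <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    bo_distance(interps[[i]]$b, interps[[j]]$b)))
  for (i in seq_len(n)) {
    stem <- file.path(out_dir, sprintf("interp_%02d", i))
    save_bo(interps[[i]]$b, interps[[i]]$cost, paste0(stem, ".bo"),
            meta = list(seed = config$seed, rank = i))
    render_bo_map(interps[[i]]$b, image, paste0(stem, ".png"))
  }
  ranking <- list(
    n_interpretations = n,
    costs = vapply(interps, `[[`, numeric(1), "cost"),
    illusory = vapply(flags, `[[`, logical(1), "illusory"),
    illusory_score = vapply(flags, `[[`, numeric(1), "score"),
    pairwise_distance = dists,
    seed = config$seed)
  jsonlite::write_json(ranking, file.path(out_dir, "ranking.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (extract) {
    mask <- extract_object(interps[[1]], config$contour)
    write_raster(mask * 1, file.path(out_dir, "mask.png"))
  }
  attr(interps, "out_dir") <- out_dir
  invisible(interps)
}

#' Built-in stimuli by name
#'
#' Convenience constructor used by the command-line tools: `"edge"`
#' (20 x 20 step edge), `"square"` (8 x 8 square on 20 x 20), `"c"`
#' (C-shape), or `"kanizsa"` (pacman figure; `r` sets the support ratio
#' `r / h`).
#'
#' @param name stimulus name.
#' @param ... geometry overrides passed to the generator.
#' @return A raster matrix.
#' @export
make_stimulus <- function(name = c("edge", "square", "c", "kanizsa"), ...) {
  name <- match.arg(name)
  switch(name,
         edge = make_edge_image(20, 20),
         square = make_square_image(20, 8),
         c = make_c_image(24, 12, 4, 6),
         kanizsa = make_kanizsa_image(kanizsa_spec(...)))
}
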