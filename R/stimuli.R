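#' Generate a two-region step-edge image
#'
#' The simplest test stimulus: the left half of the canvas is white (1), the
#' right half black (0), separated by a vertical straight boundary down the
#' middle.  Both interpretations of this image (object left / object right)
#' are equally good, which makes it the canonical check that the
#' interpretation search finds two minima of equal cost.
#'
#' @param width,height canvas size in pixels; both must be positive and even
#'   so the boundary falls exactly on the midline.
#' @return A numeric matrix (`height` x `width`) with values in \{0, 1\}.
#' @export
#' @examples
#' img <- make_edge_image(20, 20)
#' sum(img == 1)  # 200 white pixels
make_edge_image <- function(width, height) {
  check_dims(width, height)
  m <- matrix(0, nrow = height, ncol = width)
  m[, seq_len(width / 2)] <- 1
  m
}

#' Generate a centered white square on a black background
#'
#' @param canvas canvas side in pixels.
#' @param side side of the white square in pixels; must be smaller than
#'   `canvas`.
#' @return A numeric `canvas` x `canvas` matrix in \{0, 1\}.
#' @export
make_square_image <- function(canvas, side) {
  check_dims(canvas, canvas, even = FALSE)
  if (side >= canvas) stop("`side` must be smaller than `canvas`", call. = FALSE)
  if (side < 1) stop("`side` must be at least 1", call. = FALSE)
  off <- floor((canvas - side) / 2)
  m <- matrix(0, canvas, canvas)
  m[off + seq_len(side), off + seq_len(side)] <- 1
  m
}

#' Generate a C-shaped object (square with a rectangular notch)
#'
#' A centered white square of side `outer` with a rectangular mouth of size
#' `mouth_width` (along the side) by `mouth_depth` (into the square) removed
#' from the middle of its right side.  With `mouth_depth = 0` the output
#' equals `make_square_image(canvas, outer)`.
#'
#' @param canvas canvas side in pixels.
#' @param outer side of the full square in pixels.
#' @param mouth_width vertical extent of the notch in pixels (> 0).
#' @param mouth_depth horizontal depth of the notch in pixels (>= 0).
#' @return A numeric `canvas` x `canvas` matrix in \{0, 1\}.
#' @export
make_c_image <- function(canvas, outer, mouth_width, mouth_depth) {
  if (mouth_depth >= outer || mouth_width >= outer)
    stop("notch must be smaller than the square", call. = FALSE)
  if (mouth_width < 1 || mouth_depth < 0)
    stop("degenerate notch: `mouth_width` must be >= 1 and `mouth_depth` >= 0",
         call. = FALSE)
  m <- make_square_image(canvas, outer)
  if (mouth_depth > 0) {
    off <- floor((canvas - outer) / 2)
    right <- off + outer
    rows <- off + floor((outer - mouth_width) / 2) + seq_len(mouth_width)
    cols <- (right - mouth_depth + 1):right
    m[rows, cols] <- 0
  }
  m
}

#' Specify a Kanizsa pacman figure
#'
#' Four black "pacman" inducers (disks with the quadrant facing the canvas
#' center removed) on a white background.  Their centers form an
#' axis-aligned square of side `2 * h` centered on the canvas; the straight
#' mouth edges are collinear with the sides of the illusory square.  The
#' support ratio -- visible edge length over total illusory edge length --
#' is `r / h`.
#'
#' @param canvas canvas side in pixels (default 36).
#' @param h half the side of the illusory square in pixels (default 9).
#' @param r pacman radius in pixels, `0 < r <= h`.
#' @return An object of class `kanizsa_spec`.
#' @export
#' @examples
#' spec <- kanizsa_spec(r = 6)    # support ratio 6/9 = 0.67
#' support_ratio(spec)
kanizsa_spec <- function(canvas = 36, h = 9, r = 6) {
  if (r <= 0 || r > h)
    stop("need 0 < r <= h (pacmans must not overlap)", call. = FALSE)
  cc <- (canvas + 1) / 2
  if (cc - h - r < 0.5 || cc + h + r > canvas + 0.5)
    stop("pacmans do not fit on the canvas", call. = FALSE)
  structure(list(canvas = canvas, h = h, r = r),
            class = "kanizsa_spec")
}

#' @rdname kanizsa_spec
#' @param spec a `kanizsa_spec`.
#' @export
support_ratio <- function(spec) spec$r / spec$h

#' Rasterize a Kanizsa figure
#'
#' A pixel is black iff its center lies inside one of the four inducer disks
#' and outside that inducer's mouth quadrant; there is no anti-aliasing, so
#' the image is binary and the edge filters stay well defined.
#'
#' @param spec a [kanizsa_spec()].
#' @return A numeric `canvas` x `canvas` matrix in \{0, 1\}; white (1)
#'   background, black (0) inducers.
#' @export
make_kanizsa_image <- function(spec) {
  stopifnot(inherits(spec, "kanizsa_spec"))
  n <- spec$canvas
  cc <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE)   # column coordinate
  y <- matrix(seq_len(n), n, n)                 # row coordinate
  m <- matrix(1, n, n)
  for (sy in c(-1, 1)) for (sx in c(-1, 1)) {
    cx <- cc + sx * spec$h
    cy <- cc + sy * spec$h
    inside <- (x - cx)^2 + (y - cy)^2 <= spec$r^2
    # mouth quadrant opens toward the canvas center
    mouth <- ((x - cx) * (-sx) >= 0) & ((y - cy) * (-sy) >= 0)
    m[inside & !mouth] <- 0
  }
  m
}

#' Read and write gray-scale rasters (PGM or PNG)
#'
#' `write_raster` infers the format from the file extension (`.pgm`, `.png`);
#' `read_raster` inspects the file content.  PGM supports both the ASCII
#' (P2) and binary (P5) variants.  Values are quantized to 8 bits on write
#' and rescaled to `[0, 1]` on read (16-bit PGM/PNG are rescaled by their
#' stated maximum), so binary stimuli round-trip losslessly.  Color images
#' are rejected.
#'
#' @param path file path.
#' @param raster numeric matrix with values in `[0, 1]`.
#' @param ascii for PGM, write ASCII P2 (default) instead of binary P5.
#' @return `read_raster` returns a numeric matrix in `[0, 1]`.
#' @export
read_raster <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2)
  close(con)
  tag <- rawToChar(magic)
  if (tag %in% c("P2", "P5")) return(read_pgm(path))
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop("unsupported raster format: ", path, call. = FALSE))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3 &&
        !(all(img[, , 1] == img[, , 2]) && all(img[, , 1] == img[, , 3])))
      stop("color images are not supported", call. = FALSE)
    img <- img[, , 1]
  }
  img
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path, ascii = TRUE) {
  stopifnot(is.matrix(raster), all(raster >= 0), all(raster <= 1))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(raster, path)
  } else if (ext == "pgm") {
    write_pgm(raster, path, ascii = ascii)
  } else stop("unsupported raster extension: ", ext, call. = FALSE)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  toks <- character(0)
  # header: magic, width, height, maxval -- comments (#...) allowed
  read_tok <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("truncated PGM header", call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_tok()
  w <- as.integer(read_tok()); h <- as.integer(read_tok())
  maxval <- as.integer(read_tok())
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", w * h))
    } else {
      vals <- readBin(con, "integer", w * h, size = 2, signed = FALSE,
                      endian = "big")
    }
  } else stop("not a PGM file", call. = FALSE)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(raster, path, ascii = TRUE) {
  vals <- round(t(raster) * 255)  # row-major order
  h <- nrow(raster); w <- ncol(raster)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(as.integer(vals), con, ncolumns = min(w, 17))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", w, " ", h, "\n255\n"), con, eos = NULL)
    writeBin(as.raw(as.integer(vals)), con)
  }
  invisible(path)
}

check_dims <- function(width, height, even = TRUE) {
  if (width < 2 || height < 2)
    stop("canvas must be at least 2 x 2 pixels", call. = FALSE)
  if (even && (width %% 2 != 0 || height %% 2 != 0))
    stop("dimensions must be even", call. = FALSE)
  invisible(NULL)
}
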