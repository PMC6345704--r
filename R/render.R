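# Quiver-style display of border-ownership maps, following the display
# convention of the result figures: one arrow per site and direction with
# length proportional to |b|, arrows above 80% of the map maximum
# highlighted in magenta, input-image edges overdrawn in green.

#' Render a border-ownership map over its input image
#'
#' @param b border-ownership array (`H x W x L`).
#' @param image the input raster (matrix), drawn in gray underneath.
#' @param path optional PNG output path; when `NULL`, draws on the current
#'   device.
#' @param display_floor arrows with `|b|` below this fraction of the map
#'   maximum are omitted (default 0.15, declutters the plot).
#' @param highlight fraction of the map maximum above which arrows are
#'   drawn in magenta (default 0.8).
#' @param px device pixels per image pixel when writing a file.
#' @return Invisibly, `path` (or `NULL`).
#' @export
render_bo_map <- function(b, image, path = NULL, display_floor = 0.15,
                          highlight = 0.8, px = 24) {
  H <- dim(b)[1]; W <- dim(b)[2]; L <- dim(b)[3]
  if (!is.null(path)) {
    grDevices::png(path, width = W * px, height = H * px)
    on.exit(grDevices::dev.off())
  }
  op <- par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(par(op), add = TRUE)
  # image() draws rows along x; transpose and flip so row 1 is on top
  image(x = seq_len(W), y = seq_len(H),
        z = t(image_flip(image)), zlim = c(0, 1),
        col = gray(seq(0.25, 0.95, length.out = 64)),
        asp = 1, axes = FALSE, xlab = "", ylab = "")
  points(rep(seq_len(W), each = H), rep(rev(seq_len(H)), W),
         pch = 3, cex = 0.2, col = "red")
  draw_image_edges(image)
  mx <- max(abs(b))
  if (mx > 0) {
    alpha <- 2 * pi * (seq_len(L) - 1) / L
    for (l1 in seq_len(L)) {
      sl <- abs(b[, , l1])
      sel <- which(sl >= display_floor * mx, arr.ind = TRUE)
      if (nrow(sel) == 0) next
      len <- 0.9 * sl[sel] / mx
      x0 <- sel[, 2]; y0 <- H + 1 - sel[, 1]
      cols <- ifelse(sl[sel] >= highlight * mx, "magenta", "black")
      suppressWarnings(
        arrows(x0, y0, x0 + len * cos(alpha[l1]), y0 + len * sin(alpha[l1]),
               length = 0.04, col = cols, lwd = 1.2))
    }
  }
  invisible(path)
}

image_flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# Overdraw intensity discontinuities of the raster as green segments along
# pixel borders.
draw_image_edges <- function(image) {
  H <- nrow(image); W <- ncol(image)
  for (i in seq_len(H)) for (j in seq_len(W - 1))
    if (abs(image[i, j] - image[i, j + 1]) > 0.5) {
      y <- H + 1 - i
      graphics::segments(j + 0.5, y - 0.5, j + 0.5, y + 0.5,
                         col = "green3", lwd = 2)
    }
  for (i in seq_len(H - 1)) for (j in seq_len(W))
    if (abs(image[i, j] - image[i + 1, j]) > 0.5) {
      y <- H + 1 - i
      graphics::segments(j - 0.5, y - 0.5, j + 0.5, y - 0.5,
                         col = "green3", lwd = 2)
    }
  invisible(NULL)
}
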