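test_that("step-edge generator produces the two-region image", {
  img <- make_edge_image(20, 20)
  expect_equal(dim(img), c(20, 20))
  expect_equal(sum(img == 1), 200)
  expect_equal(sum(img == 0), 200)
  expect_true(all(img[, 1:10] == 1) && all(img[, 11:20] == 0))

  expect_equal(make_edge_image(2, 2), matrix(c(1, 1, 0, 0), 2, 2))

  # horizontal mirror equals the color-swapped image
  img20 <- make_edge_image(20, 20)
  expect_equal(img20[, 20:1], 1 - img20)

  expect_error(make_edge_image(0, 20), "at least")
  expect_error(make_edge_image(19, 20), "even")
})

test_that("square generator is centered, counted, and 4-fold symmetric", {
  img <- make_square_image(20, 8)
  expect_equal(sum(img == 1), 64)
  expect_equal(sum(img == 0), 336)
  # invariance under 90-degree rotation
  rot90 <- function(m) t(m)[ncol(m):1, ]
  expect_equal(rot90(img), img)
  # side = canvas - 2 leaves a 1-px frame
  frame <- make_square_image(20, 18)
  expect_true(all(frame[1, ] == 0) && all(frame[, 20] == 0))
  expect_true(all(frame[2:19, 2:19] == 1))
  expect_error(make_square_image(20, 20), "smaller")
})

test_that("C-shape generator removes exactly the notch", {
  img <- make_c_image(24, 12, 4, 6)
  expect_equal(sum(img == 1), 12 * 12 - 4 * 6)
  # zero-depth notch degenerates to the plain square
  expect_equal(make_c_image(24, 12, 4, 0), make_square_image(24, 12))
  # single mirror symmetry: across the horizontal axis through the mouth
  expect_equal(img[24:1, ], img)
  expect_false(isTRUE(all.equal(img[, 24:1], img)))
  expect_error(make_c_image(24, 12, 0, 6), "degenerate")
})

test_that("Kanizsa rasterization matches the disk geometry", {
  spec <- kanizsa_spec(36, 9, 6)
  expect_equal(support_ratio(spec), 6 / 9)
  img <- make_kanizsa_image(spec)
  black <- sum(img == 0)
  ideal <- 4 * (3 / 4) * pi * 6^2
  expect_lt(abs(black - ideal), 4 * (2 * pi * 6 + 4))
  # 4-fold rotational symmetry
  rot90 <- function(m) t(m)[ncol(m):1, ]
  expect_equal(rot90(img), img)
  # r = h: visible edges span the full illusory side
  full <- make_kanizsa_image(kanizsa_spec(40, 9, 9))
  # mouth edge rows: the row just above the top side must be black right up
  # to the side's midline gap -- no gap remains
  cc <- (40 + 1) / 2
  toprow <- full[floor(cc - 9), ]
  expect_true(all(toprow[round(cc - 9):round(cc + 9)] == 0))
  expect_error(kanizsa_spec(36, 9, 10), "overlap")
  expect_error(kanizsa_spec(20, 9, 6), "fit")
})

test_that("support ratio is monotone in the pacman radius", {
  rs <- c(4.8, 5.1, 6)
  ratios <- vapply(rs, function(r) support_ratio(kanizsa_spec(36, 9, r)),
                   numeric(1))
  expect_equal(ratios, rs / 9)
  expect_true(all(diff(ratios) > 0))
})

test_that("raster I/O round-trips PGM and PNG losslessly for binary images", {
  img <- make_square_image(20, 8)
  for (ext in c("pgm", "png")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_raster(img, path)
    expect_equal(read_raster(path), img, ignore_attr = TRUE)
    unlink(path)
  }
  # binary PGM (P5)
  path <- tempfile(fileext = ".pgm")
  write_raster(img, path, ascii = FALSE)
  expect_equal(read_raster(path), img, ignore_attr = TRUE)
  unlink(path)
})

test_that("16-bit gray PNG is rescaled to [0, 1] and RGB is rejected", {
  path <- tempfile(fileext = ".png")
  vals <- matrix(seq(0, 1, length.out = 16), 4, 4)
  png::writePNG(vals, path, dpi = NULL)  # 8-bit write
  rd <- read_raster(path)
  expect_true(all(rd >= 0 & rd <= 1))
  rgb <- array(runif(4 * 4 * 3), c(4, 4, 3))
  png::writePNG(rgb, path)
  expect_error(read_raster(path), "color")
  unlink(path)
})
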