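# Image loading, canvas resize, and the quadrant/patch division geometry.

test_that("PNG loading promotes grayscale, keeps RGB, and rejects garbage", {
  tmp <- withr::local_tempdir()
  # grayscale 10x12
  g <- EBImage::Image(matrix(runif(120), 12, 10))   # x=12, y=10
  gp <- file.path(tmp, "gray.png")
  EBImage::writeImage(g, gp)
  img <- load_image(gp)
  expect_equal(dim(img$pixels), c(10L, 12L, 3L))
  expect_equal(img$pixels[, , 1], img$pixels[, , 2])
  expect_equal(img$pixels[, , 2], img$pixels[, , 3])
  # RGB round trip: values preserved and in range
  px <- array(sample(0:255, 8 * 6 * 3, replace = TRUE), c(8, 6, 3))
  rp <- file.path(tmp, "rgb.png")
  write_image(fundus_image(px), rp)
  back <- load_image(rp)
  expect_equal(back$pixels, px)
  expect_true(all(back$pixels >= 0 & back$pixels <= 255))
  # truncated / undecodable file is an input error naming the path
  bad <- file.path(tmp, "broken.png")
  writeBin(as.raw(c(137, 80, 78, 71, 1, 2, 3)), bad)
  expect_error(load_image(bad), "broken.png")
  expect_error(load_image(file.path(tmp, "absent.png")), "does not exist")
})

test_that("alpha channels are dropped with a warning", {
  tmp <- withr::local_tempdir()
  rgba <- EBImage::Image(array(runif(5 * 4 * 4), c(5, 4, 4)),
                         colormode = "Color")
  fp <- file.path(tmp, "rgba.png")
  EBImage::writeImage(rgba, fp)
  expect_warning(img <- load_image(fp), "alpha")
  expect_equal(dim(img$pixels)[3], 3L)
})

test_that("canvas resize honours its contract", {
  # constant field stays constant under interpolation
  const <- fundus_image(array(77, c(512, 512, 3)))
  out <- resize_to_canvas(const, 256)
  expect_equal(dim(out$pixels), c(256L, 256L, 3L))
  expect_true(all(out$pixels == 77))
  # identity case is bitwise unchanged
  img <- random_canvas(256, seed = 5)
  expect_identical(resize_to_canvas(img, 256)$pixels, img$pixels)
  # odd side violates the equal-quadrant precondition
  expect_error(resize_to_canvas(img, 255), "even")
  expect_error(resize_to_canvas(img, 0), "even")
})

test_that("nearest-neighbour resize matches an independent index-mapping oracle", {
  set.seed(11)
  px <- array(sample(0:255, 300 * 400 * 3, replace = TRUE), c(300, 400, 3))
  got <- resize_to_canvas(fundus_image(px), 256, method = "nearest")$pixels
  expect_equal(got, nearest_resize_oracle(px, 256, 256))
  # corner pixels specifically
  oracle <- nearest_resize_oracle(px, 256, 256)
  for (r in c(1, 256)) for (cc in c(1, 256)) {
    expect_identical(got[r, cc, ], oracle[r, cc, ])
  }
})

test_that("division yields eight patches with the published shapes and order", {
  ps <- divide_into_patches(random_canvas(256, seed = 2))
  expect_length(ps$patches, 8L)
  shapes <- t(vapply(ps$patches, function(p) dim(p$pixels)[1:2], integer(2)))
  # horizontal patches (P1,P2,P7,P8): 64 rows x 128 cols; vertical: 128 x 64
  expect_equal(shapes[c(1, 2, 7, 8), ], matrix(c(64L, 128L), 4, 2, byrow = TRUE))
  expect_equal(shapes[c(3, 4, 5, 6), ], matrix(c(128L, 64L), 4, 2, byrow = TRUE))
  expect_equal(vapply(ps$patches, `[[`, character(1), "quadrant"),
               c("UL", "UL", "UR", "UR", "LL", "LL", "LR", "LR"))
  expect_equal(vapply(ps$patches, `[[`, character(1), "orientation"),
               c("horizontal", "horizontal", "vertical", "vertical",
                 "vertical", "vertical", "horizontal", "horizontal"))
  expect_equal(vapply(ps$patches, `[[`, integer(1), "index"), 1:8)
  # orientation follows the quadrant rule
  for (p in ps$patches) {
    expect_equal(p$orientation,
                 if (p$quadrant %in% c("UL", "LR")) "horizontal" else "vertical")
  }
  # areas tile the full canvas exactly
  expect_equal(sum(shapes[, 1] * shapes[, 2]), 256L^2)
})

test_that("patches partition the canvas: reassembly reproduces the input", {
  for (seed in 1:8) {
    img <- random_canvas(256, seed = seed)
    ps <- divide_into_patches(img)
    expect_identical(reassemble_patches(ps), img$pixels)
  }
  # all-zero image gives all-zero patches
  z <- fundus_image(array(0, c(256, 256, 3)))
  expect_true(all(vapply(divide_into_patches(z)$patches,
                         function(p) all(p$pixels == 0), logical(1))))
})

test_that("division rejects non-canvas inputs and is deterministic", {
  expect_error(divide_into_patches(fundus_image(array(0, c(100, 120, 3)))),
               "resize_to_canvas")
  expect_error(divide_into_patches(fundus_image(array(0, c(102, 102, 3)))),
               "resize_to_canvas")
  img <- random_canvas(256, seed = 9)
  a <- divide_into_patches(img)
  b <- divide_into_patches(img)
  expect_identical(a, b)
})

test_that("labels CSV reader enforces the header contract", {
  tmp <- withr::local_tempdir()
  fp <- file.path(tmp, "labels.csv")
  writeLines(c("filename,label", "a.png,0", "b.png,2"), fp)
  tab <- read_labels_csv(fp)
  expect_equal(tab$filename, c("a.png", "b.png"))
  expect_s3_class(tab$label, "factor")
  writeLines(c("file,class", "a.png,0"), fp)
  expect_error(read_labels_csv(fp), "filename")
})
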