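test_that("8-bit round trips are bounded by half a quantization step", {
  set.seed(101)
  img <- grayImage(matrix(runif(48 * 40), 48, 40))
  for (ext in c("png", "tif", "pgm")) {
    path <- tempfile(fileext = paste0(".", ext))
    saveGray(img, path)
    back <- loadGray(path)
    expect_identical(dim(back), dim(img))
    expect_lte(max(abs(pixels(back) - pixels(img))), 1 / 255 + 1e-12)
    unlink(path)
  }
})

test_that("extreme 8-bit levels map to the ends of the unit interval", {
  path <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "8 8", "255", paste(rep(255, 64), collapse = " ")), path)
  expect_true(all(pixels(loadGray(path)) == 1))
  writeLines(c("P2", "8 8", "255", paste(rep(0, 64), collapse = " ")), path)
  expect_true(all(pixels(loadGray(path)) == 0))
  unlink(path)
})

test_that("RGB input collapses to Rec. 601 luminance", {
  arr <- array(0, c(10, 12, 3)) # EBImage layout [x, y, channel]
  arr[, , 1] <- 0.8; arr[, , 2] <- 0.4; arr[, , 3] <- 0.1
  path <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  lum <- 0.299 * 0.8 + 0.587 * 0.4 + 0.114 * 0.1
  got <- pixels(loadGray(path))
  expect_identical(dim(got), c(12L, 10L)) # transposed to [row, col]
  expect_lt(max(abs(got - lum)), 2 / 255)
  unlink(path)
})

test_that("missing and malformed files are rejected", {
  expect_error(loadGray(tempfile(fileext = ".png")), "no such file")
  bad <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "4 4", "255", "1 2 3"), bad)
  expect_error(loadGray(bad), "truncated")
  unlink(bad)
})

test_that("crop extracts the exact sub-raster and composes idempotently", {
  set.seed(102)
  big <- grayImage(matrix(runif(480 * 640), 480, 640))
  roi <- cropImage(big, 0, 0, 128)
  expect_identical(pixels(roi), pixels(big)[1:128, 1:128])
  again <- cropImage(cropImage(big, 100, 200, 64), 0, 0, 64)
  expect_identical(pixels(again), pixels(big)[101:164, 201:264])
  expect_error(cropImage(big, 400, 600, 128), "outside")
  expect_error(cropImage(big, -1, 0, 64), "outside")
})

test_that("histogram bins by rounded 8-bit level and conserves mass", {
  flat <- grayImage(matrix(0.5, 10, 10))
  h <- grayHistogram(flat)
  expect_identical(unname(h[as.character(floor(0.5 * 255 + 0.5))]), 100L)
  expect_identical(sum(h), 100L)

  ph <- makePhantom(smallPhantomSpec(speckleLooks = Inf, blurSigma = 0))
  h2 <- grayHistogram(ph$image)
  expect_identical(sum(h2 > 0), 3L) # one bin per flat region
  counts <- as.vector(table(ph$labels))
  expect_setequal(unname(h2[h2 > 0]), counts)

  for (seed in 1:5) {
    set.seed(seed)
    img <- grayImage(matrix(runif(9 * 17), 9, 17))
    expect_identical(sum(grayHistogram(img)), 9L * 17L)
  }
})

test_that("GrayImage validity enforces the intensity and size contracts", {
  expect_error(grayImage(matrix(2, 8, 8)), "0,1")
  expect_error(grayImage(matrix(0.5, 4, 8)), "8x8")
  expect_error(grayImage(matrix(NaN, 8, 8)), "finite")
  expect_identical(max(pixels(grayImage(matrix(3, 8, 8), clip = TRUE))), 1)
})
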