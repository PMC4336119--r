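test_that("GL coefficients hit the identity, first-difference and half-order values", {
  expect_identical(glCoefficients(0, 4), c(1, 0, 0, 0))
  expect_identical(glCoefficients(1, 4), c(1, -1, 0, 0))
  expect_equal(glCoefficients(0.5, 4), c(1, -0.5, -0.125, -0.0625))
  expect_equal(sum(glCoefficients(0.5, 3)), 0.375)
  expect_error(glCoefficients(0.5, 0), "positive integer")
  expect_error(glCoefficients(1.5, 4), "0, 1")
})

test_that("truncated GL sums stay positive for interior orders", {
  for (v in c(0.1, 0.5, 0.9))
    for (K in 2:6)
      expect_gt(sum(glCoefficients(v, K)), 0)
})

test_that("mask construction follows the symmetric two-arm layout", {
  ms <- buildMasks(0.5, 5)
  expect_equal(ms@masks$x[3, ], c(-0.125, -0.5, 2, -0.5, -0.125))
  expect_true(all(ms@masks$x[-3, ] == 0))
  expect_identical(ms@masks$y, t(ms@masks$x))
  expect_equal(ms@maskSum, 0.75)
  expect_equal(sum(ms@masks$rdiag), 0.75)
  expect_equal(sum(ms@masks$ldiag), 0.75)
  ## diagonal masks are the 45-degree rotations: entries on the diagonals
  expect_equal(diag(ms@masks$ldiag), c(-0.125, -0.5, 2, -0.5, -0.125))

  expect_error(buildMasks(1, 5), "mask sum is 0|strictly in")
  expect_error(buildMasks(0.5, 4), "odd")

  t1 <- buildMasks(0.3, variant = "table1")
  expect_equal(t1@maskSum, 8 - 8 * 0.3)
  expect_identical(dim(t1@masks$x), c(3L, 3L))
  expect_equal(t1@masks$x[2, 2], 8)
})

test_that("response to constants is the mask sum times the level", {
  for (k in c(0.2, 0.7)) {
    ms <- buildMasks(0.5, 5)
    resp <- fractionalResponse(grayImage(matrix(k, 16, 16)), ms)
    expect_lt(max(abs(resp - 0.75 * k)), 1e-12)
  }
})

test_that("a vertical step responds maximally at the edge, flat far away", {
  p <- matrix(0.2, 16, 16); p[, 9:16] <- 0.8
  ms <- buildMasks(0.5, 5)
  resp <- fractionalResponse(grayImage(p), ms)
  xresp <- thynseg:::conv2Mirror(p, ms@masks$x)
  ## at the bright edge column the x-direction mask attains the fused max
  expect_equal(resp[, 9], pmax(xresp, 0)[, 9])
  ## two or more columns from the edge every mask sees a constant patch
  expect_lt(max(abs(resp[, 1:6] - 0.75 * 0.2)), 1e-12)
  expect_lt(max(abs(resp[, 11:16] - 0.75 * 0.8)), 1e-12)
})

test_that("the operator is exactly 90-degree rotation equivariant", {
  set.seed(401)
  p <- matrix(runif(24 * 24), 24, 24)
  rot <- thynseg:::rot90ccw
  for (v in c(0.3, 0.5, 0.8)) {
    ms <- buildMasks(v, 5)
    a <- rot(fractionalResponse(grayImage(p), ms))
    b <- fractionalResponse(grayImage(rot(p)), ms)
    expect_lt(max(abs(a - b)), 1e-13) # exact up to summation order
  }
})

test_that("gradient stacking is flat-invariant and edge-expanding", {
  ms <- buildMasks(0.5, 5)
  flat <- grayImage(matrix(0.4, 16, 16))
  enh <- enhanceWithGradient(flat, fractionalResponse(flat, ms), ms)
  expect_identical(pixels(enh), pixels(flat))

  p <- matrix(0.3, 16, 16); p[, 9:16] <- 0.6
  img <- grayImage(p)
  enh2 <- pixels(enhanceWithGradient(img, fractionalResponse(img, ms), ms))
  contrast <- function(m) mean(m[, 10:16]) - mean(m[, 1:7])
  expect_gte(contrast(enh2), contrast(p))

  ident <- enhanceWithGradient(img, fractionalResponse(img, ms), ms, lambda = 0)
  expect_identical(pixels(ident), p)

  expect_error(enhanceWithGradient(img, matrix(0, 4, 4), ms), "shapes differ")
})
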