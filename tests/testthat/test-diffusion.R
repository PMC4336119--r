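test_that("local frame vanishes on constants and planes, curves on paraboloids", {
  expect_true(all(vapply(localFrame(matrix(0.3, 16, 16)),
                         function(m) all(m == 0), logical(1))))

  ramp <- matrix(rep(seq_len(20) * 0.02, each = 20), 20, 20)
  fr <- localFrame(ramp)
  interior <- 3:18
  expect_lt(max(abs(fr$gradMag[interior, interior] - 0.02)), 1e-12)
  expect_lt(max(abs(fr$umm[interior, interior])), 1e-9)
  expect_lt(max(abs(fr$unn[interior, interior])), 1e-9)

  x <- seq(-1, 1, length.out = 21)
  par <- outer(x, x, function(a, b) a^2 + b^2) # h = 0.1
  fp <- localFrame(par)
  h2 <- (x[2] - x[1])^2
  ## away from the critical point (where the gradient direction is undefined)
  away <- c(5:8, 14:17)
  expect_lt(max(abs(fp$umm[away, away] / h2 - 2)), 0.05)
  expect_lt(max(abs(fp$unn[away, away] / h2 - 2)), 0.05)
})

test_that("conductivities respect their flat, edge and anisotropy contracts", {
  pr <- diffusionParams()
  flat <- localFrame(matrix(0.5, 16, 16))
  co <- diffusionCoefficients(flat, pr)
  expect_true(all(co$f1 == 1) && all(co$f2 == 1))
  expect_true(all(co$f3 == 0))

  set.seed(301)
  fr <- localFrame(matrix(runif(32 * 32), 32, 32))
  for (b in c(1, 1.4, 3)) {
    co <- diffusionCoefficients(fr, diffusionParams(b = b))
    expect_true(all(co$f1 <= co$f2 + 1e-15))
  }
  ## the gradient-direction coefficient is the flux derivative: negative
  ## (sharpening) beyond the edge scale, unity in the flat limit
  g <- fr$gradMag
  co <- diffusionCoefficients(fr, diffusionParams(a = 0.15))
  expect_true(all(co$f1[g > 0.15] < 0))
  expect_true(all(co$f1[g < 0.1] > 0))
})

test_that("constant images are exact fixed points of the diffusion", {
  flat <- grayImage(matrix(0.37, 24, 24))
  for (pr in list(diffusionParams(nIters = 5),
                  diffusionParams(dt = 0.3, a = 0.5, b = 2, nIters = 5),
                  diffusionParams(c = 0.3, l = 1, nIters = 5)))
    expect_identical(pixels(diffuse(flat, pr)), pixels(flat))
})

test_that("the linear limit reproduces an independent heat-equation loop", {
  set.seed(302)
  u0 <- matrix(runif(64 * 64, 0.2, 0.8), 64, 64)
  n <- 12
  out <- pixels(diffuse(grayImage(u0),
                        diffusionParams(dt = 0.1, nIters = n, a = Inf, c = 0)))
  ## independent oracle: explicit 5-point heat equation, mirror boundaries
  ref <- u0
  refl <- function(i, nn) { i <- (i - 1) %% (2 * nn); ifelse(i >= nn, 2 * nn - 1 - i, i) + 1 }
  sh <- function(m, dr, dc)
    m[refl(seq_len(nrow(m)) + dr, nrow(m)), refl(seq_len(ncol(m)) + dc, ncol(m))]
  for (it in seq_len(n)) {
    lap <- sh(ref, 1, 0) + sh(ref, -1, 0) + sh(ref, 0, 1) + sh(ref, 0, -1) - 4 * ref
    ref <- pmin(pmax(ref + 0.1 * lap, 0), 1)
  }
  expect_lt(max(abs(out - ref)), 1e-10)
})

test_that("speckle variance decreases monotonically on flat regions", {
  u0 <- mkSpeckle(matrix(0.5, 64, 64), seed = 303)
  tr <- diffuse(u0, diffusionParams(nIters = 10), trace = TRUE)
  expect_true(all(diff(tr$stats$var) < 0))
})

test_that("halving the iteration count at doubled step is consistent", {
  u0 <- mkSpeckle(matrix(0.5, 64, 64), seed = 304)
  a <- pixels(diffuse(u0, diffusionParams(dt = 0.1, nIters = 20)))
  b <- pixels(diffuse(u0, diffusionParams(dt = 0.2, nIters = 10)))
  expect_lt(max(abs(a - b)), 0.02)
})

test_that("one iteration equals a single explicit step and bounds hold", {
  u0 <- mkSpeckle(matrix(0.6, 32, 32), seed = 305)
  expect_identical(pixels(diffuse(u0, diffusionParams(nIters = 1))),
                   pixels(diffuseStep(u0, diffusionParams(nIters = 1))))
  expect_error(diffusionParams(nIters = 0), "nIters")
  out <- u0
  for (k in 1:5) {
    out <- diffuseStep(out, diffusionParams())
    p <- pixels(out)
    expect_true(min(p) >= 0 && max(p) <= 1)
  }
})
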