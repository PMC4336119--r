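test_that("weight matrix follows the intensity-proximity kernel", {
  flat <- grayImage(matrix(0.5, 8, 128))
  g <- buildWeightMatrix(flat, affinityParams(radius = 3))
  W <- graphWeights(g)
  expect_true(all(Matrix::diag(W) == 1))
  ## identical gray, adjacent pixels, 128-wide frame: spatial factor only
  expect_equal(W[1, 2], exp(-(1 / 128)^2 / 0.1^2), tolerance = 1e-10)
  ## beyond the radius the similarity is defined as zero
  expect_identical(W[1, 8 * 4 + 1], 0) # horizontal distance 4 > r = 3
  expect_lt(max(abs(W - Matrix::t(W))), 1e-12)
  expect_identical(nodeDegrees(g), as.numeric(Matrix::rowSums(W)))
})

test_that("intensity differences attenuate the weights", {
  p <- matrix(0.5, 8, 16); p[, 9:16] <- 0.9
  g <- buildWeightMatrix(grayImage(p), affinityParams(radius = 2))
  W <- graphWeights(g)
  sameSide <- W[8 * 6 + 1, 8 * 7 + 1]   # cols 7-8, both 0.5
  crossEdge <- W[8 * 7 + 1, 8 * 8 + 1]  # cols 8-9, 0.5 vs 0.9
  expect_equal(crossEdge / sameSide, exp(-0.4^2 / 0.3^2), tolerance = 1e-10)
})

test_that("oversized images are refused with downscale advice", {
  big <- grayImage(matrix(0.5, 129, 128))
  expect_error(buildWeightMatrix(big), "cap; downscale")
})

test_that("ncut values match hand-computed and enumerated references", {
  ## two disconnected 2-cliques: splitting them costs nothing
  W2 <- matrix(c(1, 1, 1, 1), 2, 2)
  g0 <- affinityGraph(Matrix::bdiag(W2, W2))
  expect_identical(ncutValue(g0, c(TRUE, TRUE, FALSE, FALSE)), 0)

  ## 2-node graph, off-diagonal w, unit self-loops
  for (w in c(0.1, 0.5, 0.9)) {
    g2 <- affinityGraph(matrix(c(1, w, w, 1), 2, 2))
    expect_equal(ncutValue(g2, c(TRUE, FALSE)), 2 * w / (w + 1))
  }

  ## 4-node barbell: bridge 0.01, internal 1, unit self-loops
  Wb <- diag(4); Wb[1, 2] <- Wb[2, 1] <- 1; Wb[3, 4] <- Wb[4, 3] <- 1
  Wb[2, 3] <- Wb[3, 2] <- 0.01
  gb <- affinityGraph(Wb)
  split <- c(TRUE, TRUE, FALSE, FALSE)
  ## assoc includes the unit self-loops: each side 1 + (1 + 1) + 1.01 = 4.01
  expect_equal(ncutValue(gb, split), 2 * 0.01 / 4.01, tolerance = 1e-12)
  expect_equal(exhaustiveMinNcut(gb), ncutValue(gb, split), tolerance = 1e-12)

  expect_error(ncutValue(gb, rep(TRUE, 4)), "non-empty")
})

test_that("ncut is symmetric and bounded on random graphs", {
  for (s in 1:10) {
    g <- randGraph(8, 500 + s)
    set.seed(s)
    mask <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    if (all(mask) || !any(mask)) mask[1] <- !mask[1]
    v1 <- ncutValue(g, mask); v2 <- ncutValue(g, !mask)
    expect_identical(v1, v2)
    expect_gte(v1, 0); expect_lte(v1, 2)
  }
})

test_that("the Fiedler pair matches analytic and dense-oracle references", {
  ## complete graph on 3 nodes, no self-loops: lambda = {0, 3/2, 3/2}
  K3 <- affinityGraph(matrix(1, 3, 3) - diag(3))
  expect_equal(solveFiedler(K3)$value, 1.5, tolerance = 1e-12)

  ## disconnected graph: zero eigenvalue, component-wise constant signs
  W2 <- matrix(1, 2, 2)
  gd <- affinityGraph(Matrix::bdiag(W2, W2, 1))
  fd <- solveFiedler(gd)
  expect_lt(fd$value, 1e-12)
  y <- fd$vector
  expect_lt(diff(range(y[1:2])), 1e-9)
  expect_lt(diff(range(y[3:4])), 1e-9)

  ## dense generalized-eigenproblem oracle on random 10-node graphs
  for (s in 1:10) {
    g <- randGraph(10, 600 + s)
    f <- solveFiedler(g)
    W <- as.matrix(graphWeights(g)); D <- diag(nodeDegrees(g))
    E <- eigen(solve(D) %*% (D - W))
    ord <- order(Re(E$values))
    lam2 <- Re(E$values[ord[2]])
    v2 <- Re(E$vectors[, ord[2]]); v2 <- v2 / sqrt(sum(v2^2))
    if (v2[which(abs(v2) > 1e-12)[1]] < 0) v2 <- -v2
    expect_lt(abs(f$value - lam2), 1e-8)
    expect_lt(max(abs(f$vector - v2)), 1e-8)
  }
})

test_that("discretization recovers components, barbells and sweep optima", {
  W2 <- matrix(1, 2, 2)
  gd <- affinityGraph(Matrix::bdiag(W2, W2))
  fd <- solveFiedler(gd)
  bd <- discretizeFiedler(fd$vector, gd)
  expect_identical(bd$ncut, 0)
  expect_setequal(which(bd$mask), if (bd$mask[1]) 1:2 else 3:4)

  Wb <- diag(4); Wb[1, 2] <- Wb[2, 1] <- 1; Wb[3, 4] <- Wb[4, 3] <- 1
  Wb[2, 3] <- Wb[3, 2] <- 0.01
  gb <- affinityGraph(Wb)
  bb <- discretizeFiedler(solveFiedler(gb)$vector, gb)
  expect_equal(bb$ncut, exhaustiveMinNcut(gb), tolerance = 1e-12)
  expect_setequal(which(bb$mask), if (bb$mask[1]) 1:2 else 3:4)

  ## monotone vector on a path graph: sweep equals exhaustive thresholding
  n <- 9
  Wp <- diag(n)
  for (i in 1:(n - 1)) Wp[i, i + 1] <- Wp[i + 1, i] <- runif(1, 0.2, 1)
  gp <- affinityGraph(Wp)
  y <- seq_len(n) / n
  best <- discretizeFiedler(y, gp, nCandidates = 32)
  exact <- min(vapply(1:(n - 1), function(k)
    ncutValue(gp, y > y[k]), numeric(1)))
  expect_equal(best$ncut, exact, tolerance = 1e-12)

  expect_error(discretizeFiedler(rep(0, 4), gb), "degenerate")
})

test_that("spectral splits stay near the exhaustive optimum on small graphs", {
  worst <- 0
  for (s in 1:20) {
    g <- randGraph(6 + (s %% 7), 700 + s)
    sp <- spectralSplitNcut(g)
    ex <- exhaustiveMinNcut(g)
    expect_gte(sp, ex - 1e-12)
    worst <- max(worst, sp / ex)
  }
  expect_lte(worst, 1.25)
})

test_that("recursive ncut leaves uniform images whole and partitions cleanly", {
  flat <- grayImage(matrix(0.5, 32, 32))
  seg <- recursiveNcut(flat, affinityParams(radius = 5))
  expect_identical(nRegions(seg), 1L)
  expect_gte(rejectedNcuts(seg)[1], 0.065)

  ph <- makePhantom(smallPhantomSpec(speckleLooks = Inf, blurSigma = 0))
  seg3 <- recursiveNcut(ph$image, affinityParams(radius = 8))
  expect_identical(sort(unique(as.vector(labels(seg3)))),
                   0:(nRegions(seg3) - 1L))
  expect_identical(dim(labels(seg3)), dim(ph$labels))
  expect_true(all(splitNcuts(seg3) < 0.065))

  ## determinism: identical reruns produce identical label rasters
  seg3b <- recursiveNcut(ph$image, affinityParams(radius = 8))
  expect_identical(labels(seg3), labels(seg3b))
})
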