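## Shared fixture builders. All randomness is seeded per call site.

## PSF-correlated speckle: multiplicative L-look Gamma noise followed by a
## Gaussian blur, matching how the phantom generator (and a B-mode system
## point spread) produces speckle.
mkSpeckle <- function(scene, seed, L = 16, blur = 1) {
  set.seed(seed)
  img <- scene * matrix(stats::rgamma(length(scene), L, L), nrow(scene))
  grayImage(pmin(pmax(thynseg:::gaussianBlur(img, blur), 0), 1))
}

## small 3-region phantom that keeps graph builds fast in unit tests
smallPhantomSpec <- function(size = 48, ...) {
  phantomSpec(size = size,
              noduleEllipse = c(18, 24, 8, 11, 15),
              tracheaEllipse = c(38, 10, 6, 5, 0), ...)
}

## random connected affinity graph with unit self-loops
randGraph <- function(n, seed, density = 0.5) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    m <- n * (n - 1) / 2
    A[upper.tri(A)] <- ifelse(stats::runif(m) < density, stats::runif(m), 0)
    W <- A + t(A) + diag(n)
    g <- affinityGraph(W)
    if (max(thynseg:::componentsW(graphWeights(g))) == 1L) return(g)
  }
}

## brute-force minimum Ncut over all 2^(n-1) - 1 bipartitions
exhaustiveMinNcut <- function(g) {
  n <- nNodes(g)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    best <- min(best, ncutValue(g, mask))
  }
  best
}

## best discrete split found by the package's multi-eigenvector sweep
spectralSplitNcut <- function(g, nVectors = 4) {
  f <- solveFiedler(g, nVectors = nVectors)
  best <- Inf
  for (j in seq_len(ncol(f$vectors)))
    best <- min(best, discretizeFiedler(f$vectors[, j], g)$ncut)
  best
}

## count of columns whose mean profile lies strictly inside the 10%-90%
## band of a 0.2|0.8 step -- a noise-robust edge transition width
edgeWidth1090 <- function(p, lo = 0.2, hi = 0.8) {
  prof <- colMeans(p)
  band <- c(lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))
  sum(prof > band[1] & prof < band[2])
}

diceFor <- function(ev, truthLabel) {
  d <- ev$dice[!is.na(ev$truth_label) & ev$truth_label == truthLabel]
  if (length(d)) d else 0
}
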