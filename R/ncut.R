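#' Build the intensity + proximity affinity graph of an image
#'
#' Pixel similarity combines gray-value and spatial Gaussians:
#' \deqn{W_{ij} = e^{-(F(i)-F(j))^2/\sigma_I^2}\,
#'               e^{-\|X(i)-X(j)\|_2^2/\sigma_X^2}}
#' for pixel pairs at raw distance \eqn{\le r}, and 0 beyond (similarity of
#' pixels farther apart than the effective distance is taken as zero).
#' Gray values F lie in \eqn{[0,1]}; coordinates X are normalized by
#' \code{max(height, width)} so they live on the unit square, which makes
#' the shipped \eqn{\sigma_X = 0.1} consistent with a radius of r = 20 raw
#' pixels on a 128 x 128 image. Self-similarity is maximal:
#' \eqn{W_{ii} = 1}, and self-loops count toward degrees and associations.
#'
#' @param img a [GrayImage-class] (the feature image F).
#' @param params an [AffinityParams-class].
#' @param cap maximum pixel count (default 16384 = 128^2); larger images are
#'   refused with advice to downscale or crop.
#' @return An [AffinityGraph-class] with \code{shape} set to the raster
#'   dimensions; nodes map to pixels in R's column-major order.
#' @examples
#' ph <- makePhantom(phantomSpec(size = 32, speckleLooks = Inf, blurSigma = 0,
#'                               noduleEllipse = c(12, 16, 6, 8, 0),
#'                               tracheaEllipse = c(25, 7, 4, 3, 0)))
#' g <- buildWeightMatrix(ph$image, affinityParams(radius = 5))
#' g
#' @export
buildWeightMatrix <- function(img, params = affinityParams(), cap = 16384L) {
  stopifnot(is(params, "AffinityParams"))
  validObject(params)
  p <- pixels(grayImage(img))
  h <- nrow(p); w <- ncol(p); n <- h * w
  if (n > cap)
    stop(sprintf(
      "image has %d pixels, above the %d-pixel cap; downscale or crop first",
      n, cap))
  r <- params@radius
  sc <- max(h, w)
  Fv <- as.vector(p) # column-major: node = (col-1)*h + row
  ## enumerate each unordered pixel-offset once (lower half-plane)
  offs <- expand.grid(dr = 0:floor(r), dc = -floor(r):floor(r))
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 &
                 (offs$dr > 0 | (offs$dr == 0 & offs$dc > 0)), , drop = FALSE]
  il <- vector("list", nrow(offs)); jl <- il; xl <- il
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rr <- 1:(h - dr)
    cc <- if (dc >= 0) 1:(w - dc) else (1 - dc):w
    if (!length(rr) || !length(cc)) next
    i1 <- as.vector(outer(rr, (cc - 1L) * h, "+"))
    i2 <- as.vector(outer(rr + dr, (cc + dc - 1L) * h, "+"))
    spatial <- exp(-((dr^2 + dc^2) / sc^2) / params@sigmaX^2)
    il[[k]] <- i1; jl[[k]] <- i2
    xl[[k]] <- exp(-(Fv[i1] - Fv[i2])^2 / params@sigmaI^2) * spatial
  }
  i <- unlist(il); j <- unlist(jl); x <- unlist(xl)
  W <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = c(x, x, rep(1, n)), dims = c(n, n))
  new("AffinityGraph", weights = W,
      degrees = as.numeric(Matrix::rowSums(W)), shape = c(h, w))
}

## internal workers on a raw (W, d) pair so the recursion can operate on
## restricted sub-graphs without re-validating S4 objects

ncutValueW <- function(W, d, mask) {
  a <- as.numeric(mask)
  cutAB <- sum((W %*% a)[!mask])
  cutAB / sum(d[mask]) + cutAB / sum(d[!mask])
}

## connected components by frontier propagation with sparse mat-vec;
## converges in diameter steps
componentsW <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  k <- 0L
  while (any(comp == 0L)) {
    k <- k + 1L
    reach <- logical(n)
    reach[which(comp == 0L)[1]] <- TRUE
    repeat {
      nxt <- reach | (as.vector(W %*% as.numeric(reach)) > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp[reach] <- k
  }
  comp
}

solveFiedlerW <- function(W, d, nVectors = 1L, tol = 1e-10, maxiter = 5000L) {
  n <- nrow(W)
  if (any(d <= 0)) stop("all node degrees must be positive")
  nVectors <- min(as.integer(nVectors), n - 1L)
  isd <- 1 / sqrt(d)
  if (n <= 256L) {
    ## dense path: eigen of the symmetrically scaled weight operator
    M <- as.matrix(W) * (isd %o% isd)
    E <- eigen((M + t(M)) / 2, symmetric = TRUE)
    Z <- E$vectors[, 1L + seq_len(nVectors), drop = FALSE]
    lambda <- 1 - E$values[1L + seq_len(nVectors)]
  } else {
    Mi <- Matrix::Diagonal(x = isd) %*% W %*% Matrix::Diagonal(x = isd)
    nev <- nVectors + 1L
    res <- tryCatch(
      igraph::arpack(function(x, extra) as.vector(Mi %*% x),
                     options = list(n = n, nev = nev,
                                    ncv = min(n, max(30L, 2L * nev + 1L)),
                                    which = "LA", maxiter = maxiter,
                                    tol = tol),
                     sym = TRUE),
      error = function(e)
        stop("Fiedler eigensolver failed to converge (n = ", n,
             ", maxiter = ", maxiter, "): ", conditionMessage(e)))
    ord <- order(res$values, decreasing = TRUE)
    Z <- res$vectors[, ord[1L + seq_len(nVectors)], drop = FALSE]
    lambda <- 1 - res$values[ord[1L + seq_len(nVectors)]]
  }
  Y <- Z * isd
  for (j in seq_len(ncol(Y))) {
    Y[, j] <- Y[, j] / sqrt(sum(Y[, j]^2))
    k <- which(abs(Y[, j]) > 1e-12)[1]
    if (!is.na(k) && Y[k, j] < 0) Y[, j] <- -Y[, j]
  }
  list(value = max(lambda[1L], 0), vector = Y[, 1L],
       values = pmax(lambda, 0), vectors = Y)
}

discretizeFiedlerW <- function(y, W, d, nCandidates = 32L) {
  ## two complementary candidate ladders: evenly spaced quantiles track the
  ## mass of y, evenly spaced values land inside the wide gaps that separate
  ## small clusters (which occupy almost no quantile width)
  qs <- stats::quantile(y, probs = seq_len(nCandidates) / (nCandidates + 1),
                        names = FALSE)
  vs <- seq(min(y), max(y), length.out = nCandidates + 2L)
  thresholds <- sort(unique(c(qs, vs[-c(1L, nCandidates + 2L)])))
  best <- NULL
  seen <- integer(0)
  for (th in thresholds) {
    mask <- y > th
    nA <- sum(mask)
    if (nA == 0L || nA == length(y) || nA %in% seen) next
    seen <- c(seen, nA)
    nc <- ncutValueW(W, d, mask)
    bal <- min(nA, length(y) - nA)
    if (is.null(best) || nc < best$ncut - 1e-15 ||
        (abs(nc - best$ncut) <= 1e-15 && bal > best$balance)) {
      best <- list(mask = mask, ncut = nc, balance = bal, threshold = th)
    }
  }
  if (is.null(best))
    stop("degenerate Fiedler vector: every candidate threshold empties a side")
  best
}

#' Normalized-cut value of a bipartition
#'
#' \deqn{\mathrm{Ncut}(A,B) = \frac{\mathrm{cut}(A,B)}{\mathrm{assoc}(A,V)} +
#'      \frac{\mathrm{cut}(A,B)}{\mathrm{assoc}(B,V)}}
#' with \eqn{\mathrm{cut}(A,B) = \sum_{i \in A, j \in B} W_{ij}} and
#' \eqn{\mathrm{assoc}(A,V) = \sum_{i \in A, j \in V} W_{ij}}. Self-loops,
#' being entries of W, count toward the associations. The value is symmetric
#' in A and B and lies in \eqn{[0, 2]}; it is 0 exactly when the split
#' separates disconnected components.
#'
#' @param graph an [AffinityGraph-class].
#' @param mask logical vector over nodes: \code{TRUE} = side A. Both sides
#'   must be non-empty.
#' @return The Ncut value.
#' @export
ncutValue <- function(graph, mask) {
  stopifnot(is(graph, "AffinityGraph"))
  mask <- as.logical(mask)
  if (length(mask) != nNodes(graph))
    stop("mask length must equal the node count")
  if (!any(mask) || all(mask))
    stop("both sides of the partition must be non-empty")
  ncutValueW(graph@weights, graph@degrees, mask)
}

#' Fiedler vector of the generalized graph Laplacian
#'
#' Solves \eqn{(D - W)\,y = \lambda D y} for the eigenvector with the
#' second-smallest eigenvalue (the Fiedler vector), via the equivalent
#' symmetric problem on \eqn{D^{-1/2} W D^{-1/2}}: a dense full-spectrum
#' solve for graphs of up to 256 nodes, ARPACK (Lanczos, deterministic
#' across runs) above that. Sign convention: the first nonzero entry of the
#' returned vector is positive. For a disconnected graph the eigenvalue is 0
#' and the vector is constant on components with opposite signs.
#'
#' @param graph an [AffinityGraph-class] with strictly positive degrees.
#' @param nVectors how many of the smallest non-trivial eigenvectors to
#'   return (default 1, the Fiedler vector alone).
#' @param tol,maxiter ARPACK tolerance and iteration cap (large graphs).
#' @return List with \code{value} (the eigenvalue \eqn{\lambda_2}),
#'   \code{vector} (unit-norm Fiedler vector), and -- when
#'   \code{nVectors > 1} is requested -- \code{values}/\code{vectors} for
#'   eigenpairs \eqn{2, \dots, 1 + nVectors} in ascending eigenvalue order.
#' @export
solveFiedler <- function(graph, nVectors = 1L, tol = 1e-10, maxiter = 5000L) {
  stopifnot(is(graph, "AffinityGraph"))
  solveFiedlerW(graph@weights, graph@degrees, nVectors = nVectors,
                tol = tol, maxiter = maxiter)
}

#' Discretize a Fiedler vector into the best threshold bipartition
#'
#' Sweeps \code{nCandidates} thresholds placed at evenly spaced quantiles of
#' the Fiedler vector, evaluates the exact [ncutValue()] of each non-empty
#' split, and returns the minimizer. Ties go to the more balanced split
#' (larger minority side), then to the lower threshold.
#'
#' @param y Fiedler vector from [solveFiedler()].
#' @param graph the [AffinityGraph-class] the vector was computed on.
#' @param nCandidates number of candidate thresholds (default 32).
#' @return List with \code{mask} (logical partition, \code{TRUE} where
#'   \code{y > threshold}), \code{ncut}, and \code{threshold}.
#' @export
discretizeFiedler <- function(y, graph, nCandidates = 32L) {
  stopifnot(is(graph, "AffinityGraph"), length(y) == nNodes(graph))
  discretizeFiedlerW(y, graph@weights, graph@degrees,
                     nCandidates = as.integer(nCandidates))
}

#' Recursive normalized-cut segmentation
#'
#' Builds the affinity graph once, then recursively bipartitions regions
#' (largest active region first) by Fiedler-vector spectral splitting.
#' A split is accepted while its Ncut value is below \code{threshold}, both
#' sides have at least \code{minRegionPx} pixels, and fewer than
#' \code{maxRegions} regions exist; otherwise the region becomes a leaf. The
#' minimum-region guard excludes the isolated-point/small-region degeneracy
#' that plain minimum cut is prone to. Sub-graphs are the restriction of W
#' to the region's nodes with degrees recomputed; disconnected regions are
#' first split along components (Ncut 0). The traversal is deterministic.
#'
#' @param img a [GrayImage-class] (the feature image), or an
#'   [AffinityGraph-class] built beforehand.
#' @param params an [AffinityParams-class] (ignored when \code{img} is
#'   already a graph).
#' @param threshold Ncut acceptance threshold per split (default 0.065).
#' @param maxRegions upper bound on the number of regions (default 8).
#' @param minRegionPx minimum region size in pixels (default 16).
#' @param nCandidates thresholds swept per eigenvector discretization.
#' @param nVectors number of smallest non-trivial eigenvectors searched per
#'   split (default 4): the discrete split of minimal Ncut over the
#'   candidate thresholds of each of these eigenvectors is taken. The
#'   Fiedler vector alone favours smooth balanced modes; compact structures
#'   (a nodule, the trachea) often live in the next few eigenvectors.
#' @param cap pixel-count cap passed to [buildWeightMatrix()].
#' @return A [SegmentationResult-class]. Region labels are 0-based and
#'   assigned in raster order of each region's first pixel.
#' @examples
#' ph <- makePhantom(phantomSpec(size = 48, speckleLooks = Inf, blurSigma = 0,
#'                               noduleEllipse = c(18, 24, 8, 11, 15),
#'                               tracheaEllipse = c(38, 10, 6, 5, 0)))
#' seg <- recursiveNcut(ph$image, affinityParams(radius = 8))
#' nRegions(seg)
#' @export
recursiveNcut <- function(img, params = affinityParams(), threshold = 0.065,
                          maxRegions = 8L, minRegionPx = 16L,
                          nCandidates = 32L, nVectors = 4L, cap = 16384L) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (maxRegions < 2L) stop("maxRegions must be >= 2")
  graph <- if (is(img, "AffinityGraph")) img
           else buildWeightMatrix(grayImage(img), params, cap = cap)
  if (!length(graph@shape))
    stop("graph has no raster shape; segment images, not abstract graphs")
  W <- graph@weights
  n <- nNodes(graph)
  active <- list(seq_len(n))
  leaves <- list()
  splits <- numeric(0)
  rejected <- numeric(0)
  nReg <- function() length(active) + length(leaves)
  while (length(active)) {
    sizes <- vapply(active, length, integer(1))
    pick <- which.max(sizes)
    idx <- active[[pick]]
    active[[pick]] <- NULL
    if (length(idx) < 2L * minRegionPx || nReg() + 2L > maxRegions) {
      leaves <- c(leaves, list(idx)); rejected <- c(rejected, NA_real_)
      next
    }
    Ws <- W[idx, idx, drop = FALSE]
    ds <- as.numeric(Matrix::rowSums(Ws))
    comp <- componentsW(Ws)
    if (max(comp) > 1L) {
      ## free splits along components, as many as the region budget allows
      parts <- split(seq_along(idx), comp)
      keep <- min(length(parts), maxRegions - nReg())
      if (keep < length(parts)) {
        merged <- unlist(parts[keep:length(parts)])
        parts <- c(parts[seq_len(keep - 1L)], list(merged))
      }
      active <- c(active, lapply(parts, function(s) idx[s]))
      splits <- c(splits, rep(0, length(parts) - 1L))
      next
    }
    fied <- solveFiedlerW(Ws, ds, nVectors = nVectors)
    best <- NULL
    for (j in seq_len(ncol(fied$vectors))) {
      cand <- tryCatch(
        discretizeFiedlerW(fied$vectors[, j], Ws, ds, nCandidates),
        error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(best) || cand$ncut < best$ncut - 1e-15 ||
           (abs(cand$ncut - best$ncut) <= 1e-15 && cand$balance > best$balance)))
        best <- cand
    }
    if (!is.null(best) && best$ncut < threshold &&
        sum(best$mask) >= minRegionPx &&
        sum(!best$mask) >= minRegionPx) {
      splits <- c(splits, best$ncut)
      active <- c(active, list(idx[best$mask]), list(idx[!best$mask]))
    } else {
      leaves <- c(leaves, list(idx))
      rejected <- c(rejected, if (is.null(best)) NA_real_ else best$ncut)
    }
  }
  ## deterministic label order: by each region's first (column-major) pixel
  ord <- order(vapply(leaves, min, numeric(1)))
  lab <- integer(n)
  for (k in seq_along(ord)) lab[leaves[[ord[k]]]] <- k - 1L
  labels <- matrix(lab, graph@shape[1], graph@shape[2])
  new("SegmentationResult", labels = labels, splitNcuts = splits,
      rejectedNcuts = rejected)
}
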