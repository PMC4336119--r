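#' @import methods
#' @importClassesFrom Matrix Matrix dgCMatrix
#' @importFrom Matrix sparseMatrix Diagonal rowSums t colSums
#' @importFrom stats fft quantile rgamma runif var
#' @importFrom utils modifyList write.table
#' @importFrom tools file_ext
NULL

## Central S4 containers. Intensities live in [0,1] throughout; 8-bit
## conversion happens only at the I/O boundary (loadGray/saveGray).

#' GrayImage: a single-channel intensity raster
#'
#' The common currency of every pipeline stage: a numeric matrix of
#' intensities in \eqn{[0,1]}, indexed \code{[row, col]}. Images entering the
#' pipeline must be at least 8 pixels along each side.
#'
#' @slot pixels numeric matrix of intensities in \eqn{[0,1]}.
#' @seealso [grayImage()], [loadGray()], [cropImage()]
#' @exportClass GrayImage
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 8L || ncol(p) < 8L)
    return("image must be at least 8x8 pixels")
  if (any(!is.finite(p))) return("pixels must all be finite")
  if (min(p) < 0 || max(p) > 1)
    return("pixel intensities must lie in [0,1]")
  TRUE
})

#' Construct a GrayImage
#'
#' @param x numeric matrix of intensities.
#' @param clip if \code{TRUE}, clip values into \eqn{[0,1]} instead of
#'   rejecting out-of-range input.
#' @return A [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
grayImage <- function(x, clip = FALSE) {
  if (is(x, "GrayImage")) return(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (clip) x <- clip01(x)
  new("GrayImage", pixels = x)
}

#' @describeIn grayImage extract the pixel matrix.
#' @param img a \code{GrayImage}.
#' @export
pixels <- function(img) {
  if (is(img, "GrayImage")) img@pixels else as.matrix(img)
}

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d, intensity range [%.3f, %.3f]\n",
              nrow(p), ncol(p), min(p), max(p)))
})

#' Parameters of the homomorphic contrast filter
#'
#' Gaussian high-frequency-emphasis transfer
#' \eqn{H(D) = (\gamma_H-\gamma_L)(1 - e^{-s D^2/D_0^2}) + \gamma_L}
#' applied to the log-image in the 2-D frequency domain. Low-frequency gain
#' \eqn{\gamma_L < 1} compresses the illumination/brightness range while
#' \eqn{\gamma_H > 1} boosts reflectance detail.
#'
#' @slot gammaLow low-frequency gain (> 0, conventionally < 1).
#' @slot gammaHigh high-frequency gain (>= gammaLow).
#' @slot cutoff transfer-function scale \eqn{D_0} in frequency-index units.
#' @slot sharpness slope constant \eqn{s} (> 0).
#' @slot epsilon offset added before the logarithm (> 0).
#' @exportClass HomomorphicParams
setClass("HomomorphicParams",
         representation(gammaLow = "numeric", gammaHigh = "numeric",
                        cutoff = "numeric", sharpness = "numeric",
                        epsilon = "numeric"))

setValidity("HomomorphicParams", function(object) {
  if (object@gammaLow <= 0) return("gammaLow must be > 0")
  if (object@gammaHigh < object@gammaLow)
    return("gammaHigh must be >= gammaLow")
  if (object@cutoff <= 0) return("cutoff must be > 0")
  if (object@sharpness <= 0) return("sharpness must be > 0")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  TRUE
})

#' @rdname HomomorphicParams-class
#' @param gammaLow,gammaHigh,cutoff,sharpness,epsilon see slot documentation.
#' @return A \code{HomomorphicParams} object.
#' @export
homomorphicParams <- function(gammaLow = 0.9, gammaHigh = 1.8, cutoff = 20,
                              sharpness = 1, epsilon = 1e-3) {
  new("HomomorphicParams", gammaLow = gammaLow, gammaHigh = gammaHigh,
      cutoff = cutoff, sharpness = sharpness, epsilon = epsilon)
}

#' Parameters of the edge-enhancing anisotropic diffusion model
#'
#' Governs the explicit-Euler evolution
#' \deqn{u \leftarrow u + \Delta t\,[f_1 u_{MM} + f_2 u_{NN}
#'       - f_3\,\mathrm{th}(l v_{MM})\,|\nabla u|]}
#' where \eqn{M} is the local gradient direction, \eqn{N} its perpendicular,
#' and \eqn{v = G_\sigma * u} a Gaussian-smoothed copy of the evolving image.
#' \eqn{a} sets the gradient scale that separates edges from noise (edge and
#' local-detail retention), \eqn{b} the tangent/gradient anisotropy (structure
#' retention), \eqn{c} the edge-enhancement gain, and \eqn{l} the slope of the
#' hyperbolic tangent that gates the enhancement.
#'
#' @slot dt time step (stable range used here: (0, 0.5]; typical 0.06--0.3).
#' @slot nIters number of iterations (default 50).
#' @slot a gradient scale for the diffusion coefficients (> 0).
#' @slot b tangent/gradient anisotropy ratio (> 0).
#' @slot c edge-enhancement gain (> 0; 0 allowed to disable enhancement).
#' @slot l hyperbolic-tangent slope (> 0).
#' @slot smoothSigma std-dev (pixels) of the Gaussian used to form v.
#' @exportClass DiffusionParams
setClass("DiffusionParams",
         representation(dt = "numeric", nIters = "integer", a = "numeric",
                        b = "numeric", c = "numeric", l = "numeric",
                        smoothSigma = "numeric"))

setValidity("DiffusionParams", function(object) {
  if (object@dt <= 0 || object@dt > 0.5) return("dt must lie in (0, 0.5]")
  if (object@nIters < 1L) return("nIters must be >= 1")
  if (object@a <= 0) return("a must be > 0")
  if (object@b <= 0) return("b must be > 0")
  if (object@c < 0) return("c must be >= 0")
  if (object@l <= 0) return("l must be > 0")
  if (object@smoothSigma <= 0) return("smoothSigma must be > 0")
  TRUE
})

#' @rdname DiffusionParams-class
#' @param dt,nIters,a,b,c,l,smoothSigma see slot documentation. Defaults are
#'   the recommended operating point: dt = 0.1, n = 50,
#'   (a, b, c, l) = (0.15, 1.4, 0.015, 0.015).
#' @return A \code{DiffusionParams} object.
#' @export
diffusionParams <- function(dt = 0.1, nIters = 50L, a = 0.15, b = 1.4,
                            c = 0.015, l = 0.015, smoothSigma = 0.4) {
  new("DiffusionParams", dt = dt, nIters = as.integer(nIters), a = a, b = b,
      c = c, l = l, smoothSigma = smoothSigma)
}

#' Fractional-differential mask set
#'
#' Four directional Gruenwald-Letnikov convolution masks (x, y, right
#' diagonal, left diagonal) of odd side \code{support} and order
#' \code{order} in (0,1). All four masks share the same nonzero coefficient
#' sum \code{maskSum}, which is what a locally constant patch responds with.
#'
#' @slot order fractional order v in (0,1).
#' @slot support odd mask side length (>= 3).
#' @slot masks list of four matrices named x, y, rdiag, ldiag.
#' @slot maskSum common coefficient sum of each mask (nonzero).
#' @slot variant "symmetric" (two-arm GL layout) or "table1"
#'   (3x3 center-8/ring \eqn{-v} operator).
#' @seealso [buildMasks()]
#' @exportClass FractionalMaskSet
setClass("FractionalMaskSet",
         representation(order = "numeric", support = "integer",
                        masks = "list", maskSum = "numeric",
                        variant = "character"))

setValidity("FractionalMaskSet", function(object) {
  if (length(object@masks) != 4L ||
      !all(c("x", "y", "rdiag", "ldiag") %in% names(object@masks)))
    return("masks must be a named list x, y, rdiag, ldiag")
  if (abs(object@maskSum) < 1e-12)
    return("mask coefficient sum must be nonzero")
  TRUE
})

setMethod("show", "FractionalMaskSet", function(object) {
  cat(sprintf("FractionalMaskSet: v = %.3f, support %d, variant '%s', mask sum %.4f\n",
              object@order, object@support, object@variant, object@maskSum))
})

#' Affinity-graph parameters for the normalized cut
#'
#' Weight function between pixels i and j:
#' \deqn{W_{ij} = e^{-(F(i)-F(j))^2/\sigma_I^2}\; e^{-\|X(i)-X(j)\|^2/\sigma_X^2}}
#' when the raw pixel distance is at most \code{radius}, else 0. Gray values
#' F lie in [0,1]; coordinates X are normalized by max(height, width) so
#' \code{sigmaX} is on the unit square while \code{radius} stays in pixels.
#'
#' @slot sigmaI gray-similarity scale (default 0.3).
#' @slot sigmaX spatial scale in normalized coordinates (default 0.1).
#' @slot radius connection radius in raw pixels (default 20).
#' @exportClass AffinityParams
setClass("AffinityParams",
         representation(sigmaI = "numeric", sigmaX = "numeric",
                        radius = "numeric"))

setValidity("AffinityParams", function(object) {
  if (object@sigmaI <= 0) return("sigmaI must be > 0")
  if (object@sigmaX <= 0) return("sigmaX must be > 0")
  if (object@radius < 1) return("radius must be >= 1")
  TRUE
})

#' @rdname AffinityParams-class
#' @param sigmaI,sigmaX,radius see slot documentation.
#' @return An \code{AffinityParams} object.
#' @export
affinityParams <- function(sigmaI = 0.3, sigmaX = 0.1, radius = 20) {
  new("AffinityParams", sigmaI = sigmaI, sigmaX = sigmaX, radius = radius)
}

#' Sparse pixel affinity graph
#'
#' Symmetric non-negative weight matrix W over image pixels (or abstract
#' nodes), with unit self-loops for image graphs, plus the degree vector
#' \eqn{D_i = \sum_j W_{ij}}. When built from an image, \code{shape} records
#' the (height, width) raster so node k maps to pixel
#' (row, col) in R's column-major order.
#'
#' @slot weights sparse symmetric \code{dgCMatrix} of non-negative weights.
#' @slot degrees numeric degree vector.
#' @slot shape integer(2) raster shape, or integer(0) for abstract graphs.
#' @seealso [buildWeightMatrix()], [affinityGraph()]
#' @exportClass AffinityGraph
setClass("AffinityGraph",
         representation(weights = "Matrix", degrees = "numeric",
                        shape = "integer"))

setValidity("AffinityGraph", function(object) {
  W <- object@weights
  if (nrow(W) != ncol(W)) return("weight matrix must be square")
  if (length(object@degrees) != nrow(W))
    return("degree vector length must equal node count")
  if (length(object@shape) &&
      prod(object@shape) != nrow(W))
    return("shape must multiply out to the node count")
  TRUE
})

#' Construct an AffinityGraph from an explicit weight matrix
#'
#' @param W square symmetric non-negative (sparse or dense) matrix.
#' @param shape optional integer(2) (height, width) when nodes are pixels.
#' @return An [AffinityGraph-class].
#' @examples
#' W <- matrix(c(1, .5, .5, 1), 2, 2)
#' g <- affinityGraph(rbind(cbind(W, 0 * W), cbind(0 * W, W)))
#' nNodes(g)
#' @export
affinityGraph <- function(W, shape = NULL) {
  W <- methods::as(methods::as(methods::as(W, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (any(W@x < 0)) stop("affinity weights must be non-negative")
  n <- nrow(W)
  ## exact symmetry check is affordable below ~1e6 nonzeros; larger graphs
  ## come from buildWeightMatrix, which constructs symmetrically
  if (length(W@x) < 1e6) {
    if (max(abs(W - Matrix::t(W))) > 1e-12)
      stop("affinity weight matrix must be symmetric")
  }
  new("AffinityGraph", weights = W, degrees = as.numeric(Matrix::rowSums(W)),
      shape = if (is.null(shape)) integer(0) else as.integer(shape))
}

#' @describeIn affinityGraph number of nodes.
#' @param graph an \code{AffinityGraph}.
#' @export
nNodes <- function(graph) nrow(graph@weights)

#' @describeIn affinityGraph sparse weight matrix W.
#' @export
graphWeights <- function(graph) graph@weights

#' @describeIn affinityGraph degree vector D.
#' @export
nodeDegrees <- function(graph) graph@degrees

setMethod("show", "AffinityGraph", function(object) {
  cat(sprintf("AffinityGraph: %d nodes, %d stored weights%s\n",
              nNodes(object), length(object@weights@x),
              if (length(object@shape))
                sprintf(", raster %d x %d", object@shape[1], object@shape[2])
              else ""))
})

#' Result of recursive normalized-cut segmentation
#'
#' @slot labels integer label raster (0-based labels 0..k-1).
#' @slot splitNcuts Ncut values of the accepted splits, in acceptance order
#'   (0 for splits along disconnected components).
#' @slot rejectedNcuts the first Ncut value that exceeded the threshold on
#'   each finalized leaf (NA where no split was attempted).
#' @seealso [recursiveNcut()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
         representation(labels = "matrix", splitNcuts = "numeric",
                        rejectedNcuts = "numeric"))

setValidity("SegmentationResult", function(object) {
  lab <- object@labels
  if (!is.numeric(lab) || any(!is.finite(lab)))
    return("labels must be a finite numeric raster")
  u <- sort(unique(as.numeric(lab)))
  if (!isTRUE(all.equal(u, as.numeric(seq_along(u) - 1))))
    return("labels must be contiguous integers starting at 0")
  TRUE
})

#' @describeIn SegmentationResult-class the label raster.
#' @param object,x a \code{SegmentationResult}.
#' @param ... unused.
#' @export
setMethod("labels", "SegmentationResult", function(object, ...) object@labels)

#' @describeIn SegmentationResult-class number of regions k.
#' @export
nRegions <- function(x) length(unique(as.vector(x@labels)))

#' @describeIn SegmentationResult-class Ncut values of accepted splits.
#' @export
splitNcuts <- function(x) x@splitNcuts

#' @describeIn SegmentationResult-class rejected (stopping) Ncut values.
#' @export
rejectedNcuts <- function(x) x@rejectedNcuts

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d region(s) on a %d x %d raster\n",
              nRegions(object), nrow(object@labels), ncol(object@labels)))
  if (length(object@splitNcuts))
    cat("  accepted split Ncuts:",
        paste(sprintf("%.4f", object@splitNcuts), collapse = ", "), "\n")
})

#' Specification of a synthetic B-mode thyroid phantom
#'
#' Describes a piecewise-constant scene -- mid-gray parenchyma background, a
#' darker elliptical nodule and a nearly black tracheal ellipse -- degraded
#' by multiplicative L-look speckle and a Gaussian point-spread blur.
#' Ellipses are (centerRow, centerCol, semiAxisRow, semiAxisCol, rotationDeg)
#' in 0-based pixel coordinates.
#'
#' @slot size image side length in pixels.
#' @slot backgroundLevel,noduleLevel,tracheaLevel region intensities, ordered
#'   \code{0 <= tracheaLevel < noduleLevel < backgroundLevel <= 1}.
#' @slot noduleEllipse,tracheaEllipse numeric(5) ellipse descriptors.
#' @slot speckleLooks number of looks L (>= 1); \code{Inf} disables speckle.
#' @slot blurSigma Gaussian PSF std-dev in pixels (0 disables blur).
#' @slot seed integer RNG seed; the phantom is fully determined by it.
#' @seealso [phantomSpec()], [makePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(size = "integer", backgroundLevel = "numeric",
                        noduleLevel = "numeric", tracheaLevel = "numeric",
                        noduleEllipse = "numeric", tracheaEllipse = "numeric",
                        speckleLooks = "numeric", blurSigma = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@size < 16L) return("phantom size must be >= 16")
  lv <- c(object@tracheaLevel, object@noduleLevel, object@backgroundLevel)
  if (any(diff(lv) <= 0) || lv[1] < 0 || lv[3] > 1)
    return("levels must satisfy 0 <= trachea < nodule < background <= 1")
  for (e in list(object@noduleEllipse, object@tracheaEllipse))
    if (length(e) != 5L || any(!is.finite(e)) || e[3] <= 0 || e[4] <= 0)
      return("ellipses must be numeric(5) with positive semi-axes")
  if (object@speckleLooks < 1) return("speckleLooks must be >= 1 (or Inf)")
  if (object@blurSigma < 0) return("blurSigma must be >= 0")
  nm <- ellipseMask(object@size, object@noduleEllipse)
  tm <- ellipseMask(object@size, object@tracheaEllipse)
  if (any(nm & tm)) return("nodule and trachea ellipses must not overlap")
  border <- rep(FALSE, object@size^2); dim(border) <- c(object@size, object@size)
  border[c(1, object@size), ] <- TRUE; border[, c(1, object@size)] <- TRUE
  if (any((nm | tm) & border)) return("ellipses must lie fully inside the frame")
  TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%d: levels bg %.2f / nodule %.2f / trachea %.2f, L = %s, blur %.2f, seed %d\n",
    object@size, object@size, object@backgroundLevel, object@noduleLevel,
    object@tracheaLevel, format(object@speckleLooks), object@blurSigma,
    object@seed))
})
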