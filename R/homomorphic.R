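#' Homomorphic contrast filter
#'
#' Compresses the brightness (illumination) range and boosts contrast in one
#' pass: the image is taken to the log domain, \eqn{\log(u + \epsilon)}, a
#' radial Gaussian high-emphasis transfer
#' \deqn{H(D) = (\gamma_H - \gamma_L)\,(1 - e^{-s D^2 / D_0^2}) + \gamma_L}
#' is applied in the centered 2-D frequency domain (D is the radial
#' frequency index), the result is exponentiated, the offset removed, and the
#' output affinely rescaled to \eqn{[0,1]}. Under the multiplicative
#' illumination-reflectance model, low frequencies (illumination, speckle
#' "DC") are attenuated by \eqn{\gamma_L < 1} while reflectance detail is
#' amplified by \eqn{\gamma_H > 1}.
#'
#' A constant image has zero output range; by convention it maps to all
#' zeros after the rescale. With \code{rescale = FALSE} the raw (unscaled)
#' matrix is returned, which with \eqn{\gamma_L = \gamma_H = g} equals
#' \eqn{(u + \epsilon)^g - \epsilon} pixelwise.
#'
#' @param img a [GrayImage-class].
#' @param params a [HomomorphicParams-class].
#' @param rescale rescale the result affinely to \eqn{[0,1]} (default). If
#'   \code{FALSE}, the raw numeric matrix is returned for diagnostics.
#' @return A [GrayImage-class], or a numeric matrix when
#'   \code{rescale = FALSE}.
#' @examples
#' ph <- makePhantom(phantomSpec(seed = 1))
#' out <- homomorphicFilter(ph$image)
#' range(pixels(out))
#' @export
homomorphicFilter <- function(img, params = homomorphicParams(),
                              rescale = TRUE) {
  stopifnot(is(params, "HomomorphicParams"))
  validObject(params)
  p <- pixels(grayImage(img))
  M <- nrow(p); N <- ncol(p)
  L <- log(p + params@epsilon)
  ## radial frequency index, centered: index k of an M-point DFT has
  ## frequency min(k, M - k); no fftshift needed this way
  fr <- pmin(0:(M - 1), M - (0:(M - 1)))
  fc <- pmin(0:(N - 1), N - (0:(N - 1)))
  D2 <- outer(fr^2, fc^2, "+")
  H <- (params@gammaHigh - params@gammaLow) *
    (1 - exp(-params@sharpness * D2 / params@cutoff^2)) + params@gammaLow
  filt <- Re(stats::fft(stats::fft(L) * H, inverse = TRUE)) / (M * N)
  out <- exp(filt) - params@epsilon
  if (any(!is.finite(out)))
    stop("homomorphic filter produced non-finite values; check params")
  if (!rescale) return(out)
  rng <- max(out) - min(out)
  if (rng < 1e-12) return(grayImage(matrix(0, M, N)))
  grayImage((out - min(out)) / rng)
}
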