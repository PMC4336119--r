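#' Gruenwald-Letnikov fractional-difference coefficients
#'
#' Binomial weights of the order-v fractional backward difference at unit
#' step: \eqn{c_0 = 1}, \eqn{c_k = c_{k-1}\,(k - 1 - v)/k}. At v = 0 this is
#' the identity \code{[1, 0, 0, ...]}; at v = 1 the first backward
#' difference \code{[1, -1, 0, ...]}. For 0 < v < 1 the infinite sum of the
#' weights is 0, but every truncation has a strictly positive sum -- the
#' nonzero-mask-sum property the fractional gradient operator relies on to
#' retain low-frequency texture while boosting high-frequency detail.
#'
#' @param v fractional order in \eqn{[0, 1]}.
#' @param K number of coefficients (>= 1).
#' @return Numeric vector \eqn{c_0, \dots, c_{K-1}}.
#' @examples
#' glCoefficients(0.5, 4)  # 1, -0.5, -0.125, -0.0625
#' @export
glCoefficients <- function(v, K) {
  if (length(K) != 1L || K < 1 || K != round(K))
    stop("K must be a positive integer")
  if (v < 0 || v > 1) stop("order v must lie in [0, 1]")
  co <- numeric(K)
  co[1] <- 1
  k <- 1
  while (k < K) {
    co[k + 1] <- co[k] * (k - 1 - v) / k
    k <- k + 1
  }
  co
}

#' Build the four-direction fractional-differential mask set
#'
#' The default \code{"symmetric"} layout places the GL coefficients
#' symmetrically outward from the center along the row through the center
#' (the two arms share the center, which therefore carries \eqn{2 c_0}), and
#' obtains the y, right-diagonal and left-diagonal masks as 90 and 45 degree
#' rotations of that generator. Each mask has coefficient sum
#' \eqn{2 \sum_k c_k}, which is strictly positive for 0 < v < 1; v = 1 would
#' give a zero-sum (pure Laplacian-like) mask and is rejected. The
#' \code{"table1"} variant is the literal 3x3 center-8 / ring \eqn{-v}
#' operator (sum \eqn{8 - 8v}), applied identically in all four directions.
#'
#' @param v fractional order, strictly inside (0, 1). Default 0.5.
#' @param support odd mask side length >= 3 (default 5). Forced to 3 for the
#'   \code{"table1"} variant.
#' @param variant \code{"symmetric"} (default) or \code{"table1"}.
#' @return A [FractionalMaskSet-class].
#' @examples
#' ms <- buildMasks(0.5, 5)
#' ms@masks$x[3, ]   # -0.125 -0.5 2 -0.5 -0.125
#' ms@maskSum        # 0.75
#' @export
buildMasks <- function(v = 0.5, support = 5L, variant = c("symmetric", "table1")) {
  variant <- match.arg(variant)
  if (v <= 0 || v >= 1)
    stop("order v must lie strictly in (0, 1): at v = 1 the mask sum is 0, ",
         "which defeats the texture-retaining nonzero-sum property")
  if (variant == "table1") {
    m <- matrix(-v, 3L, 3L)
    m[2L, 2L] <- 8
    masks <- list(x = m, y = m, rdiag = m, ldiag = m)
    return(new("FractionalMaskSet", order = v, support = 3L, masks = masks,
               maskSum = 8 - 8 * v, variant = variant))
  }
  support <- as.integer(support)
  if (support < 3L || support %% 2L == 0L)
    stop("support must be an odd integer >= 3")
  K <- (support + 1L) %/% 2L
  co <- glCoefficients(v, K)
  cc <- K # center index
  mx <- matrix(0, support, support)
  mx[cc, cc] <- 2 * co[1]
  for (k in seq_len(K - 1L)) {
    mx[cc, cc + k] <- co[k + 1L]
    mx[cc, cc - k] <- co[k + 1L]
  }
  my <- t(mx)
  ld <- matrix(0, support, support) # main diagonal (top-left to bottom-right)
  rd <- matrix(0, support, support) # anti-diagonal (top-right to bottom-left)
  ld[cc, cc] <- 2 * co[1]; rd[cc, cc] <- 2 * co[1]
  for (k in seq_len(K - 1L)) {
    ld[cc + k, cc + k] <- co[k + 1L]; ld[cc - k, cc - k] <- co[k + 1L]
    rd[cc - k, cc + k] <- co[k + 1L]; rd[cc + k, cc - k] <- co[k + 1L]
  }
  new("FractionalMaskSet", order = v, support = support,
      masks = list(x = mx, y = my, rdiag = rd, ldiag = ld),
      maskSum = 2 * sum(co), variant = variant)
}

#' Fractional-differential gradient response
#'
#' Convolves the image with each of the four directional masks under mirror
#' boundaries, fuses them by per-pixel maximum (which makes the operator
#' equivariant under 90-degree rotation), and clips negative responses to 0.
#' A locally constant patch of value k responds with \code{maskSum * k}, so
#' the response carries the low-frequency component alongside the boosted
#' edges -- the defining property of fractional (as opposed to integer-order)
#' differentiation.
#'
#' @param img a [GrayImage-class].
#' @param masks a [FractionalMaskSet-class].
#' @return Numeric response matrix (same shape as the image; values may
#'   exceed 1 and are not rescaled).
#' @export
fractionalResponse <- function(img, masks = buildMasks()) {
  stopifnot(is(masks, "FractionalMaskSet"))
  p <- pixels(grayImage(img))
  resp <- conv2Mirror(p, masks@masks$x)
  for (nm in c("y", "rdiag", "ldiag"))
    resp <- pmax(resp, conv2Mirror(p, masks@masks[[nm]]))
  pmax(resp, 0)
}

#' Stack the fractional gradient onto the image
#'
#' Point-to-point addition of the fractional-differential response onto the
#' source, after removing the locally constant baseline
#' \code{maskSum * img} so flat regions are left exactly unchanged:
#' \deqn{u' = \mathrm{clip}(u + \lambda\,(R - S\,u),\, 0,\, 1)}
#' where R is the response and S the mask coefficient sum.
#'
#' @param img a [GrayImage-class].
#' @param response response matrix from [fractionalResponse()].
#' @param masks the [FractionalMaskSet-class] that produced the response
#'   (supplies the baseline mask sum).
#' @param lambda stacking gain; \code{lambda = 0} is the identity.
#' @return The enhanced [GrayImage-class].
#' @examples
#' ph <- makePhantom(phantomSpec(seed = 3))
#' ms <- buildMasks(0.5, 5)
#' enh <- enhanceWithGradient(ph$image, fractionalResponse(ph$image, ms), ms)
#' @export
enhanceWithGradient <- function(img, response, masks, lambda = 1) {
  p <- pixels(grayImage(img))
  if (!identical(dim(p), dim(response)))
    stop("image and response shapes differ")
  stopifnot(is(masks, "FractionalMaskSet"))
  grayImage(clip01(p + lambda * (response - masks@maskSum * p)))
}
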