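#' Specify a synthetic B-mode thyroid phantom
#'
#' The phantom emulates the appearance of a cropped B-mode thyroid scan: a
#' mid-gray parenchyma background, a darker (hypoechoic) elliptical nodule,
#' a nearly black tracheal ellipse, multiplicative L-look speckle, and a
#' Gaussian point-spread blur. Defaults place the intensity mass in a narrow
#' gray band around the background level, mirroring the low dynamic range of
#' real thyroid scans.
#'
#' @param size side length in pixels (default 128).
#' @param backgroundLevel,noduleLevel,tracheaLevel region intensities
#'   (defaults 0.7 / 0.2 / 0.05).
#' @param noduleEllipse,tracheaEllipse numeric(5)
#'   (centerRow, centerCol, semiAxisRow, semiAxisCol, rotationDeg),
#'   0-based pixel coordinates.
#' @param speckleLooks number of looks L of the multiplicative Gamma speckle
#'   (mean-1, variance 1/L); \code{Inf} turns speckle off. Default 16,
#'   a moderate post-compression speckle strength.
#' @param blurSigma Gaussian PSF std-dev in pixels (default 1).
#' @param seed integer seed; the phantom is bit-reproducible given it.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(size = 128L,
                        backgroundLevel = 0.7, noduleLevel = 0.2,
                        tracheaLevel = 0.05,
                        noduleEllipse = c(54, 78, 18, 24, 20),
                        tracheaEllipse = c(96, 30, 16, 11, 0),
                        speckleLooks = 16, blurSigma = 1.0, seed = 0L) {
  new("PhantomSpec", size = as.integer(size),
      backgroundLevel = backgroundLevel, noduleLevel = noduleLevel,
      tracheaLevel = tracheaLevel,
      noduleEllipse = as.numeric(noduleEllipse),
      tracheaEllipse = as.numeric(tracheaEllipse),
      speckleLooks = speckleLooks, blurSigma = blurSigma,
      seed = as.integer(seed))
}

#' Generate a phantom image and its ground-truth label raster
#'
#' Renders the piecewise-constant scene from the two ellipses, multiplies by
#' per-pixel mean-1 Gamma(shape = L, rate = L) speckle (skipped when
#' \code{speckleLooks} is \code{Inf}), blurs with the Gaussian PSF (the
#' system point spread acts on the echo field, hence after the noise), and
#' clips to \eqn{[0,1]}. The label raster is 0 = background, 1 = nodule,
#' 2 = trachea. Output is fully determined by \code{spec@seed}; the caller's
#' RNG state is left untouched.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with \code{image} (a [GrayImage-class]), \code{labels}
#'   (integer matrix), and \code{scene} (the noise-free piecewise-constant
#'   matrix).
#' @examples
#' ph <- makePhantom(phantomSpec(seed = 7))
#' table(ph$labels)
#' @export
makePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  s <- spec@size
  nm <- ellipseMask(s, spec@noduleEllipse)
  tm <- ellipseMask(s, spec@tracheaEllipse)
  scene <- matrix(spec@backgroundLevel, s, s)
  scene[nm] <- spec@noduleLevel
  scene[tm] <- spec@tracheaLevel
  labels <- matrix(0L, s, s)
  labels[nm] <- 1L
  labels[tm] <- 2L
  img <- scene
  if (is.finite(spec@speckleLooks)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec@seed)
    L <- spec@speckleLooks
    img <- img * matrix(stats::rgamma(s * s, shape = L, rate = L), s, s)
  }
  img <- gaussianBlur(img, spec@blurSigma)
  list(image = grayImage(clip01(img)), labels = labels, scene = scene)
}

#' Dice overlap coefficient of two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; returns 1 when both masks are empty.
#'
#' @param pred,truth logical rasters (or coercibles) of identical shape.
#' @return Dice coefficient in \eqn{[0, 1]}.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
#' diceCoefficient(a, a)
#' @export
diceCoefficient <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth))
    stop("mask shapes differ")
  tot <- sum(pred) + sum(truth)
  if (tot == 0L) return(1.0)
  2 * sum(pred & truth) / tot
}

#' Round-trip a phantom spec through YAML
#'
#' @param spec a [PhantomSpec-class].
#' @param path YAML file path.
#' @return \code{writePhantomSpec}: \code{path}, invisibly.
#'   \code{readPhantomSpec}: the [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  yaml::write_yaml(list(
    size = spec@size, background_level = spec@backgroundLevel,
    nodule_level = spec@noduleLevel, trachea_level = spec@tracheaLevel,
    nodule_ellipse = as.numeric(spec@noduleEllipse),
    trachea_ellipse = as.numeric(spec@tracheaEllipse),
    speckle_looks = if (is.finite(spec@speckleLooks)) spec@speckleLooks
                    else "inf",
    blur_sigma = spec@blurSigma, seed = spec@seed), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  looks <- y$speckle_looks
  if (is.character(looks)) looks <- Inf
  phantomSpec(size = y$size, backgroundLevel = y$background_level,
              noduleLevel = y$nodule_level, tracheaLevel = y$trachea_level,
              noduleEllipse = y$nodule_ellipse,
              tracheaEllipse = y$trachea_ellipse,
              speckleLooks = looks, blurSigma = y$blur_sigma, seed = y$seed)
}
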