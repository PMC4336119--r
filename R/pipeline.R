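#' Default pipeline configuration
#'
#' Nested list of per-stage settings whose defaults are the recommended
#' operating point of the whole method: diffusion dt = 0.1 (valid range
#' 0.06--0.3), n = 50 iterations, (a, b, c, l) = (0.15, 1.4, 0.015, 0.015),
#' Ncut threshold 0.065 with sigma_I = 0.3, sigma_X = 0.1, r = 20.
#'
#' @return Nested configuration list with blocks \code{homomorphic},
#'   \code{diffusion}, \code{fractional}, \code{ncut}, \code{output}.
#' @seealso [runPipeline()], [readPipelineConfig()]
#' @export
pipelineConfig <- function() {
  list(
    homomorphic = list(gamma_low = 0.9, gamma_high = 1.8, cutoff = 20,
                       sharpness = 1, epsilon = 1e-3, skip = FALSE),
    diffusion = list(dt = 0.1, n_iters = 50L, a = 0.15, b = 1.4, c = 0.015,
                     l = 0.015, smooth_sigma = 0.4, skip = FALSE),
    fractional = list(order = 0.5, support = 5L, variant = "symmetric",
                      lambda = 1, skip = FALSE),
    ncut = list(sigma_i = 0.3, sigma_x = 0.1, radius = 20,
                threshold = 0.065, max_regions = 8L, min_region_px = 16L,
                n_candidates = 32L, feature = "enhanced"),
    output = list(dir = ".", dump_intermediates = FALSE, verbose = FALSE))
}

#' Read a pipeline configuration from YAML
#'
#' Two-level keys matching [pipelineConfig()]; unspecified keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @param base configuration to override (default [pipelineConfig()]).
#' @return Nested configuration list.
#' @export
readPipelineConfig <- function(path, base = pipelineConfig()) {
  y <- yaml::read_yaml(path)
  for (blk in intersect(names(y), names(base)))
    base[[blk]] <- utils::modifyList(base[[blk]], y[[blk]])
  base
}

#' Run the full enhancement + segmentation pipeline
#'
#' Executes the enabled stages in fixed order -- homomorphic contrast
#' filter, edge-enhancing anisotropic diffusion, fractional-differential
#' gradient stacking, recursive normalized cut -- and returns the
#' segmentation together with every intermediate image. The Ncut stage
#' consumes the enhanced image (\code{ncut$feature = "enhanced"}) or the
#' untouched input (\code{"original"}).
#'
#' @param input a [GrayImage-class], an image file path, or a
#'   [PhantomSpec-class] (rendered via [makePhantom()]).
#' @param config nested configuration list, see [pipelineConfig()].
#' @param outputDir directory for dumped artifacts; overrides
#'   \code{config$output$dir}.
#' @return List with \code{result} (a [SegmentationResult-class]),
#'   \code{images} (original / homomorphic / diffused / enhanced),
#'   \code{report} (per-region data.frame: label, pixels, mean gray), and
#'   \code{truth} (label raster, phantom input only).
#' @examples
#' cfg <- pipelineConfig()
#' cfg$diffusion$n_iters <- 3L
#' out <- runPipeline(phantomSpec(size = 48, speckleLooks = Inf, blurSigma = 0,
#'                                noduleEllipse = c(18, 24, 8, 11, 15),
#'                                tracheaEllipse = c(38, 10, 6, 5, 0)),
#'                    config = cfg)
#' out$report
#' @export
runPipeline <- function(input, config = pipelineConfig(), outputDir = NULL) {
  truth <- NULL
  if (is(input, "PhantomSpec")) {
    ph <- makePhantom(input)
    img <- ph$image
    truth <- ph$labels
  } else if (is.character(input)) {
    img <- loadGray(input)
  } else {
    img <- grayImage(input)
  }
  say <- function(...) if (isTRUE(config$output$verbose)) message(...)
  images <- list(original = img)
  cur <- img

  if (!isTRUE(config$homomorphic$skip)) {
    t0 <- proc.time()[3]
    hp <- config$homomorphic
    cur <- homomorphicFilter(cur, homomorphicParams(
      gammaLow = hp$gamma_low, gammaHigh = hp$gamma_high, cutoff = hp$cutoff,
      sharpness = hp$sharpness, epsilon = hp$epsilon))
    say(sprintf("homomorphic stage: %.2fs", proc.time()[3] - t0))
  }
  images$homomorphic <- cur

  if (!isTRUE(config$diffusion$skip)) {
    t0 <- proc.time()[3]
    dp <- config$diffusion
    cur <- diffuse(cur, diffusionParams(
      dt = dp$dt, nIters = dp$n_iters, a = dp$a, b = dp$b, c = dp$c,
      l = dp$l, smoothSigma = dp$smooth_sigma))
    say(sprintf("diffusion stage (%d iters): %.2fs", dp$n_iters,
                proc.time()[3] - t0))
  }
  images$diffused <- cur

  if (!isTRUE(config$fractional$skip)) {
    t0 <- proc.time()[3]
    fp <- config$fractional
    masks <- buildMasks(fp$order, fp$support, fp$variant)
    cur <- enhanceWithGradient(cur, fractionalResponse(cur, masks), masks,
                               lambda = fp$lambda)
    say(sprintf("fractional stage: %.2fs", proc.time()[3] - t0))
  }
  images$enhanced <- cur

  np <- config$ncut
  feature <- if (identical(np$feature, "original")) img else cur
  t0 <- proc.time()[3]
  result <- recursiveNcut(feature,
                          affinityParams(sigmaI = np$sigma_i,
                                         sigmaX = np$sigma_x,
                                         radius = np$radius),
                          threshold = np$threshold,
                          maxRegions = np$max_regions,
                          minRegionPx = np$min_region_px,
                          nCandidates = np$n_candidates)
  say(sprintf("ncut stage: %.2fs; accepted split Ncuts: %s",
              proc.time()[3] - t0,
              paste(sprintf("%.4f", splitNcuts(result)), collapse = ", ")))

  lab <- labels(result)
  report <- do.call(rbind, lapply(sort(unique(as.vector(lab))), function(k) {
    m <- lab == k
    data.frame(label = k, pixels = sum(m),
               mean_gray = mean(pixels(img)[m]))
  }))

  dir <- if (!is.null(outputDir)) outputDir else config$output$dir
  if (isTRUE(config$output$dump_intermediates) || !is.null(outputDir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    saveGray(images$original, file.path(dir, "00_original.png"))
    saveGray(images$homomorphic, file.path(dir, "01_homomorphic.png"))
    saveGray(images$diffused, file.path(dir, "02_diffused.png"))
    saveGray(images$enhanced, file.path(dir, "03_enhanced.png"))
    k <- max(lab)
    saveGray(grayImage(lab / max(1, k)), file.path(dir, "04_labels.png"))
    utils::write.table(report, file.path(dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(config, file.path(dir, "config.yaml"))
  }
  list(result = result, images = images, report = report, truth = truth)
}

#' Match predicted to true regions and score overlap
#'
#' Greedy matching by maximal pixel overlap: repeatedly pair the (truth,
#' predicted) label pair with the largest remaining overlap, then report the
#' Dice coefficient of each matched pair. Matching ignores label identity,
#' so permuting label IDs leaves the scores unchanged. Predicted labels left
#' unmatched (over-segmentation) are reported with \code{truth_label = NA}.
#'
#' @param labels predicted integer label raster.
#' @param truth ground-truth integer label raster of the same shape.
#' @return data.frame with columns \code{truth_label}, \code{pred_label},
#'   \code{truth_px}, \code{pred_px}, \code{overlap}, \code{dice}.
#' @export
evaluateSegmentation <- function(labels, truth) {
  if (is(labels, "SegmentationResult")) labels <- labels(labels)
  if (!identical(dim(labels), dim(truth)))
    stop("label and truth rasters have different shapes")
  tl <- sort(unique(as.vector(truth)))
  pl <- sort(unique(as.vector(labels)))
  ov <- outer(tl, pl, Vectorize(function(a, b) sum(truth == a & labels == b)))
  rows <- list()
  while (any(ov > 0)) {
    ij <- which(ov == max(ov), arr.ind = TRUE)[1, ]
    a <- tl[ij[1]]; b <- pl[ij[2]]
    rows[[length(rows) + 1L]] <- data.frame(
      truth_label = a, pred_label = b,
      truth_px = sum(truth == a), pred_px = sum(labels == b),
      overlap = ov[ij[1], ij[2]],
      dice = diceCoefficient(labels == b, truth == a))
    ov[ij[1], ] <- -1L
    ov[, ij[2]] <- -1L
  }
  matchedPred <- vapply(rows, function(r) r$pred_label, numeric(1))
  for (b in setdiff(pl, matchedPred)) {
    rows[[length(rows) + 1L]] <- data.frame(
      truth_label = NA_real_, pred_label = b, truth_px = NA_integer_,
      pred_px = sum(labels == b), overlap = 0L, dice = NA_real_)
  }
  out <- do.call(rbind, rows)
  out[order(out$pred_label), , drop = FALSE]
}
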