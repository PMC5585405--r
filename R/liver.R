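#' Configuration of the liver attenuation pipeline
#'
#' @param seedQuantile quantile of the positive DT1*P values used to
#'   extract the seed sample (stage G).
#' @param finalQuantile quantile of the positive DT2*P values used for the
#'   final mask (stage J).
#' @param rangeRule how the adaptive attenuation range R is derived from
#'   the seed HU sample: \code{"quantile"} = [p2.5, p97.5] or
#'   \code{"meansd"} = mean +/- 2 SD; either way clamped to the lean band.
#' @param binWidth histogram bin width (HU) for the Gaussian fit.
#' @return named list of class \code{"LiverConfig"}.
#' @export
liverConfig <- function(seedQuantile = 0.90, finalQuantile = 0.50,
                        rangeRule = c("quantile", "meansd"), binWidth = 1) {
  rangeRule <- match.arg(rangeRule)
  stopifnot(seedQuantile > 0, seedQuantile < 1,
            finalQuantile > 0, finalQuantile < 1, binWidth > 0)
  structure(list(seedQuantile = seedQuantile, finalQuantile = finalQuantile,
                 rangeRule = rangeRule, binWidth = binWidth),
            class = "LiverConfig")
}

#' Least-squares Gaussian center of a histogram
#'
#' Histograms the values at the given bin width and fits
#' \code{A * exp(-(x - c)^2 / (2 w^2))} to the bin counts by nonlinear
#' least squares, returning the fitted center.  Fitting the dominant mode
#' makes the estimate robust against a secondary tissue population in the
#' mask, unlike a plain mean.
#'
#' @param values numeric vector (>= 100 values unless degenerate).
#' @param binWidth histogram bin width in HU.
#' @param binOrigin left edge alignment of the first bin (defaults to
#'   \code{floor(min(values))}).
#' @return the fitted Gaussian center (HU).
#' @export
fitGaussianCenter <- function(values, binWidth = 1, binOrigin = NULL) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (stats::sd(values) == 0) return(values[1])
  if (length(values) < 100)
    stop("argument error: need at least 100 values for a histogram fit")
  lo <- if (is.null(binOrigin)) floor(min(values)) else binOrigin
  breaks <- seq(lo, max(values) + binWidth, by = binWidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  x <- h$mids; y <- h$counts
  start <- list(A = max(y), c = stats::median(values), w = stats::sd(values))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - c)^2 / (2 * w^2)), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("numeric error: Gaussian fit failed (n = ", length(values),
           ", sd = ", signif(stats::sd(values), 4), "): ",
           conditionMessage(e)))
  unname(stats::coef(fit)["c"])
}

.gaussianFitCoef <- function(values, binWidth) {
  lo <- floor(min(values))
  breaks <- seq(lo, max(values) + binWidth, by = binWidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  x <- h$mids; y <- h$counts
  fit <- minpack.lm::nlsLM(y ~ A * exp(-(x - c)^2 / (2 * w^2)),
                           start = list(A = max(y),
                                        c = stats::median(values),
                                        w = stats::sd(values)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(stats::coef(fit))
}

#' Automated liver attenuation
#'
#' Atlas-guided approximate liver segmentation with two distance-transform
#' refinement passes and an adaptive attenuation range:
#' (1) lean-band threshold within the body; (2) Euclidean distance
#' transform DT1 of the lean mask; (3) multiply by the shape prior P
#' aligned via the cavity span; (4) threshold DT1*P at the seed quantile;
#' (5) estimate the subject-specific attenuation range R from the seed HU
#' sample; (6) re-threshold the original image by R; (7) distance
#' transform DT2; (8) multiply by P; (9) threshold at the final quantile;
#' (10) read the attenuation from the center of a Gaussian fitted to the
#' histogram of the final mask.
#'
#' @param slice a liver-station \linkS4class{CTSlice}.
#' @param atlas liver \linkS4class{ShapeAtlas} (P_liver).
#' @param bands \code{\link{huBands}}.
#' @param ilt cavity-pass \code{\link{iltParams}} used for the span.
#' @param cfg \code{\link{liverConfig}}.
#' @return a \linkS4class{LiverResult}.
#' @export
segmentLiver <- function(slice, atlas, bands = huBands(),
                         ilt = defaultIltParams("liver"),
                         cfg = liverConfig()) {
  stopifnot(is(slice, "CTSlice"), is(atlas, "ShapeAtlas"))
  if (slice@station != "liver") stop("argument error: not a liver slice")
  body <- bodyMask(slice, bands)
  lean <- leanBandMask(slice, bands) & body
  dt1 <- distanceTransform(lean, slice@spacing)
  span <- cavitySpan(slice, ilt, body = body)
  P <- alignAtlas(atlas, span, dim(slice@pixels))@pixels
  prod1 <- dt1 * P
  pos1 <- prod1[prod1 > 0]
  if (!length(pos1))
    stop("segmentation error [seed]: DT1*P is zero everywhere")
  seed <- prod1 >= stats::quantile(pos1, cfg$seedQuantile)
  if (!any(seed)) stop("segmentation error [seed]: empty seed mask")
  huSeed <- slice@pixels[seed]
  R <- if (cfg$rangeRule == "quantile") {
    unname(stats::quantile(huSeed, c(0.025, 0.975)))
  } else {
    mean(huSeed) + c(-2, 2) * stats::sd(huSeed)
  }
  ## clamp to the lean band (open below, closed above)
  R[1] <- max(R[1], bands$adipose[2])
  R[2] <- min(R[2], bands$lean[2])
  if (R[1] >= R[2]) stop("segmentation error [range]: degenerate range R")
  mask2 <- (slice@pixels > R[1] & slice@pixels <= R[2]) & body
  dt2 <- distanceTransform(mask2, slice@spacing)
  prod2 <- dt2 * P
  pos2 <- prod2[prod2 > 0]
  if (!length(pos2))
    stop("segmentation error [final]: DT2*P is zero everywhere")
  final <- prod2 >= stats::quantile(pos2, cfg$finalQuantile)
  if (!any(final)) stop("segmentation error [final]: empty final mask")
  ## keep one compact region: fill holes left by the product threshold and
  ## drop satellite fragments
  final <- largestComponent(cpp_fill_holes(final, 4L), 8L)
  vals <- slice@pixels[final]
  fit <- .gaussianFitCoef(vals, cfg$binWidth)
  new("LiverResult", mask = final, attenuationHu = fit$c,
      rangeR = as.numeric(R), nPixels = as.integer(sum(final)), fit = fit)
}
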