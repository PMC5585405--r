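#' Segment and separate the two thighs
#'
#' Body components are extracted with the table excluded; the two largest
#' are labelled left/right by centroid column (image left = smaller
#' columns).  If the thighs touch and form a single component, one binary
#' opening is attempted before giving up.
#'
#' @param slice a thigh-station \linkS4class{CTSlice}.
#' @param bands \code{\link{huBands}}.
#' @return list of logical masks \code{left}, \code{right}.
#' @export
separateThighs <- function(slice, bands = huBands()) {
  stopifnot(is(slice, "CTSlice"))
  if (slice@station != "thigh") stop("argument error: not a thigh slice")
  both <- bodyMask(slice, bands, nKeep = 2L)
  lab <- cpp_label(both, 8L)
  if (max(lab) < 2L) {
    ## touching thighs: one opening attempt
    opened <- EBImage::opening(EBImage::Image(both + 0),
                               EBImage::makeBrush(3, "box")) > 0
    opened <- matrix(opened, nrow(both), ncol(both))
    lab <- cpp_label(opened, 8L)
    if (max(lab) < 2L)
      stop("segmentation error: could not separate two thighs")
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- order(sizes, decreasing = TRUE)[1:2]
  cols <- vapply(keep, function(k) mean(which(lab == k, arr.ind = TRUE)[, 2]),
                 numeric(1))
  left <- lab == keep[which.min(cols)]
  right <- lab == keep[which.max(cols)]
  list(left = cpp_fill_holes(left, 4L), right = cpp_fill_holes(right, 4L))
}

#' Separate muscle, adipose tissue and bone within one thigh
#'
#' Adipose and lean (muscle) tissue by HU bands; bone as the cortical
#' threshold with the enclosed marrow added by hole filling, and excluded
#' from both soft-tissue masks (marrow HU falls in the adipose band but
#' is not a target depot).
#'
#' @param thigh logical mask of one thigh.
#' @param slice the thigh \linkS4class{CTSlice}.
#' @param bands \code{\link{huBands}}.
#' @return list of logical masks \code{muscle}, \code{adipose},
#'   \code{bone}.
#' @export
segmentMuscleAt <- function(thigh, slice, bands = huBands()) {
  if (!any(thigh)) stop("argument error: empty thigh mask")
  cortical <- corticalBoneMask(slice, bands) & thigh
  bone <- cpp_fill_holes(cortical, 4L)
  adipose <- adiposeBandMask(slice, bands) & thigh & !bone
  muscle <- leanBandMask(slice, bands) & thigh & !bone
  list(muscle = muscle, adipose = adipose, bone = bone)
}

#' Thigh SAT via the ILT filter
#'
#' The ILT response restricted to the thigh identifies everything inside
#' lean tissue (deep to the fascia); SAT is the adipose tissue outside
#' that region.
#'
#' @param adipose logical adipose mask of the thigh.
#' @param slice the thigh \linkS4class{CTSlice}.
#' @param thigh logical mask of the thigh (restricts the filter).
#' @param ilt \code{\link{iltParams}} for the thigh SAT pass.
#' @return logical SAT mask.
#' @export
thighSat <- function(adipose, slice, thigh,
                     ilt = defaultIltParams("thigh")) {
  resp <- iltResponse(slice, ilt, within = thigh)
  inside <- insideMask(resp, ilt@pmThreshold, largestOnly = TRUE)
  if (!any(inside)) {
    warning("empty inside mask; all adipose tissue labelled SAT")
    return(adipose)
  }
  adipose & !inside
}

#' SFAT/IMAT separation, method 1 (ILT)
#'
#' A second, stricter ILT pass isolates the deep muscle compartment;
#' inner adipose tissue inside it is intermuscular (IMAT), the rim just
#' beneath the fascia lata is subfascial (SFAT).
#'
#' @param adiposeInner logical mask of non-SAT adipose tissue.
#' @param slice the thigh \linkS4class{CTSlice}.
#' @param thigh logical mask of the thigh.
#' @param ilt2 stricter \code{\link{iltParams}}
#'   (\code{defaultIltParams("thigh_deep")}).
#' @return list of logical masks \code{sfat}, \code{imat}.
#' @export
sfatImatIlt <- function(adiposeInner, slice, thigh,
                        ilt2 = defaultIltParams("thigh_deep")) {
  if (!any(adiposeInner))
    return(list(sfat = adiposeInner, imat = adiposeInner))
  resp <- iltResponse(slice, ilt2, within = thigh)
  deep <- insideMask(resp, ilt2@pmThreshold, largestOnly = TRUE)
  list(sfat = adiposeInner & !deep, imat = adiposeInner & deep)
}

#' SFAT/IMAT separation, method 2 (morphological)
#'
#' The union of muscle and inner adipose tissue is hole-filled and
#' shrunk by \code{depthMm} using the spacing-aware distance transform
#' (with a half-pixel discretization correction); inner adipose tissue in
#' the shrunken deep zone is IMAT, the remaining rim of thickness about
#' \code{depthMm} beneath the fascia is SFAT.
#'
#' @param adiposeInner logical mask of non-SAT adipose tissue.
#' @param muscle logical muscle mask.
#' @param depthMm erosion depth in mm (default 7, calibrated on phantom training sets).
#' @param spacing pixel spacing (row_mm, col_mm).
#' @return list of logical masks \code{sfat}, \code{imat}.
#' @export
sfatImatMorph <- function(adiposeInner, muscle, depthMm = 7, spacing) {
  if (depthMm <= 0) stop("argument error: depthMm must be positive")
  if (!any(adiposeInner))
    return(list(sfat = adiposeInner, imat = adiposeInner))
  region <- cpp_fill_holes(adiposeInner | muscle, 4L)
  dt <- distanceTransform(region, spacing)
  ## pixel-center DT overestimates the distance to the continuous region
  ## boundary by about half a pixel
  deep <- (dt - 0.25 * min(spacing)) >= depthMm
  if (!any(deep)) {
    warning("erosion depth annihilates the region; all inner adipose -> SFAT")
    return(list(sfat = adiposeInner, imat = adiposeInner & FALSE))
  }
  list(sfat = adiposeInner & !deep, imat = adiposeInner & deep)
}

#' Mean attenuation over the muscle mask
#'
#' @param slice the thigh \linkS4class{CTSlice}.
#' @param muscle logical muscle mask (non-empty).
#' @param method \code{"mean"} (default) or \code{"gaussian"} (histogram
#'   fit, for symmetry with the liver pipeline).
#' @param binWidth histogram bin width for the Gaussian variant.
#' @return muscle attenuation (HU).
#' @export
muscleAttenuation <- function(slice, muscle, method = c("mean", "gaussian"),
                              binWidth = 1) {
  method <- match.arg(method)
  if (!any(muscle)) stop("argument error: empty muscle mask")
  vals <- slice@pixels[muscle]
  if (method == "mean") mean(vals) else fitGaussianCenter(vals, binWidth)
}

#' Full per-thigh segmentation
#'
#' Runs the whole chain -- muscle/AT/bone separation, SAT via the ILT
#' filter, and the SFAT/IMAT split with the selected method -- on one
#' thigh.
#'
#' @param slice the thigh \linkS4class{CTSlice}.
#' @param thigh logical mask of one thigh.
#' @param side \code{"left"} or \code{"right"}.
#' @param method \code{"ilt"} or \code{"morphological"} SFAT/IMAT split.
#' @param bands \code{\link{huBands}}.
#' @param ilt thigh SAT pass parameters.
#' @param ilt2 deep-compartment pass parameters (method 1).
#' @param depthMm erosion depth (method 2).
#' @return a \linkS4class{ThighResult}.
#' @export
segmentThigh <- function(slice, thigh, side = "left",
                         method = c("ilt", "morphological"),
                         bands = huBands(),
                         ilt = defaultIltParams("thigh"),
                         ilt2 = defaultIltParams("thigh_deep"),
                         depthMm = 7) {
  method <- match.arg(method)
  tis <- segmentMuscleAt(thigh, slice, bands)
  sat <- thighSat(tis$adipose, slice, thigh, ilt)
  inner <- tis$adipose & !sat
  split <- if (method == "ilt") {
    sfatImatIlt(inner, slice, thigh, ilt2)
  } else {
    sfatImatMorph(inner, tis$muscle, depthMm, slice@spacing)
  }
  sp <- slice@spacing
  areas <- c(muscle = areaCm2(tis$muscle, sp), sat = areaCm2(sat, sp),
             sfat = areaCm2(split$sfat, sp), imat = areaCm2(split$imat, sp))
  new("ThighResult", side = side, muscle = tis$muscle, sat = sat,
      sfat = split$sfat, imat = split$imat, bone = tis$bone, areas = areas,
      muscleAttenuationHu = muscleAttenuation(slice, tis$muscle),
      method = method)
}

#' Calibrate thigh SFAT/IMAT parameters on a phantom training set
#'
#' Grid search that primarily optimizes the adipose-tissue area
#' correlation with ground truth and secondarily the mean Dice of the
#' SFAT and IMAT masks, mirroring how the methods were trained.
#'
#' @param phantoms list of thigh \linkS4class{LabeledPhantom} objects.
#' @param pmGrid candidate \code{pmThreshold} values for the deep ILT
#'   pass (method 1).
#' @param depthGrid candidate erosion depths in mm (method 2).
#' @return list with elements \code{ilt2} (best deep-pass params),
#'   \code{depthMm} (best erosion depth) and the search table
#'   \code{scores}.
#' @export
calibrateThighParams <- function(phantoms,
                                 pmGrid = c(0.10, 0.14, 0.18, 0.22, 0.26),
                                 depthGrid = c(3, 4, 5, 6, 7)) {
  evalCase <- function(fun) {
    truthA <- autoA <- diceV <- numeric(0)
    for (ph in phantoms) {
      sl <- ph@slice
      thighs <- separateThighs(sl)
      for (side in c("left", "right")) {
        th <- thighs[[side]]
        tis <- segmentMuscleAt(th, sl)
        sat <- thighSat(tis$adipose, sl, th)
        inner <- tis$adipose & !sat
        sp <- fun(sl, th, inner, tis$muscle)
        tSfat <- labelMask(ph, "sfat") & th
        tImat <- labelMask(ph, "imat") & th
        truthA <- c(truthA, sum(tSfat), sum(tImat))
        autoA <- c(autoA, sum(sp$sfat), sum(sp$imat))
        diceV <- c(diceV, overlap(sp$sfat, tSfat)@dice,
                   overlap(sp$imat, tImat)@dice)
      }
    }
    r <- if (stats::sd(truthA) > 0 && stats::sd(autoA) > 0)
      stats::cor(truthA, autoA) else 0
    c(r = r, dice = mean(diceV))
  }
  scores <- list()
  for (pm in pmGrid) {
    p2 <- defaultIltParams("thigh_deep"); p2@pmThreshold <- pm
    s <- evalCase(function(sl, th, inner, muscle)
      sfatImatIlt(inner, sl, th, p2))
    scores[[length(scores) + 1L]] <- data.frame(method = "ilt", param = pm,
                                                r = s["r"], dice = s["dice"])
  }
  for (dd in depthGrid) {
    s <- evalCase(function(sl, th, inner, muscle)
      sfatImatMorph(inner, muscle, dd, sl@spacing))
    scores[[length(scores) + 1L]] <- data.frame(method = "morph", param = dd,
                                                r = s["r"], dice = s["dice"])
  }
  tab <- do.call(rbind, scores)
  rownames(tab) <- NULL
  pick <- function(m) {
    sub <- tab[tab$method == m, ]
    sub <- sub[order(-round(sub$r, 3), -sub$dice), ]
    sub$param[1]
  }
  p2 <- defaultIltParams("thigh_deep")
  p2@pmThreshold <- pick("ilt")
  list(ilt2 = p2, depthMm = pick("morph"), scores = tab)
}
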