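#' @import methods
NULL

.STATIONS <- c("liver", "abdomen", "thigh")

#' CTSlice: a single axial CT slice in Hounsfield units
#'
#' The universal input of the package: a 2D raster of attenuation values
#' (HU) with its pixel spacing in mm and the anatomical station the slice
#' was acquired at.
#'
#' @slot pixels numeric matrix of HU values (rows = image rows).
#' @slot spacing numeric length-2, (row_mm, col_mm), both > 0.
#' @slot station one of \code{"liver"}, \code{"abdomen"}, \code{"thigh"}.
#' @export
setClass("CTSlice",
  representation(pixels = "matrix", spacing = "numeric", station = "character"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (any(!is.finite(p))) return("pixels must be finite")
    if (min(p) < -1024 || max(p) > 3071)
      return("HU values must lie within [-1024, 3071]")
    if (length(object@spacing) != 2 || any(object@spacing <= 0))
      return("spacing must be two strictly positive mm values")
    if (length(object@station) != 1 || !(object@station %in% .STATIONS))
      return("station must be one of liver/abdomen/thigh")
    TRUE
  })

#' Construct a CTSlice
#'
#' @param pixels numeric matrix of HU values.
#' @param spacing numeric length-2 pixel spacing (row_mm, col_mm).
#' @param station station label: \code{"liver"}, \code{"abdomen"} or
#'   \code{"thigh"}.
#' @return A \linkS4class{CTSlice}.
#' @examples
#' s <- ctSlice(matrix(-1000, 4, 4), c(1, 1), "abdomen")
#' @export
ctSlice <- function(pixels, spacing, station) {
  new("CTSlice", pixels = pixels, spacing = as.numeric(spacing),
      station = station)
}

#' ProbabilityMap: per-pixel values in [0, 1]
#'
#' Holds the ILT filter response (P_inside) and the aligned shape priors
#' (P_liver, P_back).
#'
#' @slot pixels numeric matrix with all values in [0, 1].
#' @export
setClass("ProbabilityMap",
  representation(pixels = "matrix"),
  validity = function(object) {
    p <- object@pixels
    if (any(!is.finite(p))) return("probabilities must be finite")
    if (min(p) < 0 || max(p) > 1) return("probabilities must lie in [0, 1]")
    TRUE
  })

#' Construct a ProbabilityMap
#' @param pixels numeric matrix with values in [0, 1].
#' @return A \linkS4class{ProbabilityMap}.
#' @export
probabilityMap <- function(pixels) new("ProbabilityMap", pixels = pixels)

#' ShapeAtlas: a shape prior bound to a reference frame
#'
#' A probability map sampled on a canonical grid whose coordinates span the
#' reference rectangle (in practice the bounding box of the abdominal
#' cavity).  Alignment to a new image maps the target's cavity box onto the
#' canonical grid, so the atlas travels with anisotropic affine scaling.
#'
#' @slot prob numeric matrix, the canonical-grid probability values.
#' @slot frame numeric length-4 (rmin, rmax, cmin, cmax): the mean source
#'   frame the atlas was built from, kept as metadata.
#' @export
setClass("ShapeAtlas",
  representation(prob = "matrix", frame = "numeric"),
  validity = function(object) {
    if (min(object@prob) < 0 || max(object@prob) > 1)
      return("atlas probabilities must lie in [0, 1]")
    f <- object@frame
    if (length(f) != 4) return("frame must be (rmin, rmax, cmin, cmax)")
    if (f[2] <= f[1] || f[4] <= f[3])
      return("frame must have positive height and width")
    TRUE
  })

#' Liver attenuation result
#'
#' @slot mask logical matrix, the final approximate liver segmentation.
#' @slot attenuationHu center of the Gaussian fitted to the masked HU
#'   histogram.
#' @slot rangeR numeric length-2, the adaptive attenuation range (lo, hi)
#'   estimated from the seed sample.
#' @slot nPixels number of pixels in the final mask.
#' @slot fit list with the fitted Gaussian parameters (amp, center, width).
#' @export
setClass("LiverResult",
  representation(mask = "matrix", attenuationHu = "numeric",
                 rangeR = "numeric", nPixels = "integer", fit = "list"),
  validity = function(object) {
    if (object@rangeR[1] >= object@rangeR[2]) return("range must have lo < hi")
    if (object@nPixels <= 0L) return("final mask is empty")
    TRUE
  })

#' Abdominal VAT/SAT segmentation result
#'
#' @slot vat,sat,backAt logical matrices: visceral and subcutaneous adipose
#'   tissue and the excluded paraspinal (back) adipose tissue.
#' @slot cavity logical matrix, the ILT cavity mask used for the split.
#' @slot areas named numeric (cm^2): tat, vat, sat.
#' @export
setClass("AbdomenResult",
  representation(vat = "matrix", sat = "matrix", backAt = "matrix",
                 cavity = "matrix", areas = "numeric"),
  validity = function(object) {
    if (any(object@vat & object@sat)) return("VAT and SAT must be disjoint")
    if (any(object@vat & object@backAt))
      return("VAT and excluded back AT must be disjoint")
    a <- object@areas
    if (!all(c("tat", "vat", "sat") %in% names(a)))
      return("areas must contain tat, vat, sat")
    if (abs(a["tat"] - a["vat"] - a["sat"]) > 1e-8)
      return("tat must equal vat + sat")
    TRUE
  })

#' Per-thigh segmentation result
#'
#' @slot side \code{"left"} or \code{"right"} (image left = smaller column
#'   indices).
#' @slot muscle,sat,sfat,imat,bone logical matrices.
#' @slot areas named numeric (cm^2): muscle, sat, sfat, imat.
#' @slot muscleAttenuationHu mean HU over the muscle mask.
#' @slot method \code{"ilt"} or \code{"morphological"} (SFAT/IMAT split).
#' @export
setClass("ThighResult",
  representation(side = "character", muscle = "matrix", sat = "matrix",
                 sfat = "matrix", imat = "matrix", bone = "matrix",
                 areas = "numeric", muscleAttenuationHu = "numeric",
                 method = "character"),
  validity = function(object) {
    if (any(object@sat & object@sfat) || any(object@sat & object@imat) ||
        any(object@sfat & object@imat))
      return("sat, sfat, imat must be pairwise disjoint")
    if (any(object@muscle & (object@sat | object@sfat | object@imat)))
      return("muscle must not overlap adipose depots")
    TRUE
  })

#' Segmentation overlap statistics
#'
#' Pixel-level agreement between an automated and a reference mask:
#' Dice = 2 TP / (2 TP + FP + FN), plus false positive / negative counts
#' expressed as fractions of the reference pixel count.
#'
#' @slot tp,fp,fn integer pixel counts.
#' @slot dice Dice coefficient in [0, 1].
#' @slot fpRatio,fnRatio FP and FN as fractions of the reference count
#'   (NA when the reference is empty).
#' @export
setClass("OverlapStats",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 dice = "numeric", fpRatio = "numeric", fnRatio = "numeric"),
  validity = function(object) {
    if (object@dice < 0 || object@dice > 1) return("dice must lie in [0, 1]")
    TRUE
  })

#' Parametric description of a synthetic CT phantom slice
#'
#' @slot station phantom station, one of liver/abdomen/thigh.
#' @slot imageSize integer length-2 (rows, cols).
#' @slot spacing numeric length-2 (row_mm, col_mm).
#' @slot geometry named list of station-specific shape parameters, all
#'   lengths in mm (see \code{\link{phantomSpec}}).
#' @slot tissueHu named list of c(mean, sd) HU per tissue label.
#' @slot noiseSeed integer seed for the additive Gaussian noise.
#' @export
setClass("PhantomSpec",
  representation(station = "character", imageSize = "integer",
                 spacing = "numeric", geometry = "list", tissueHu = "list",
                 noiseSeed = "integer"),
  validity = function(object) {
    if (!(object@station %in% .STATIONS)) return("unknown station")
    if (any(object@imageSize < 8L)) return("image too small")
    if (any(object@spacing <= 0)) return("spacing must be positive")
    TRUE
  })

#' A synthetic phantom with ground-truth labels
#'
#' @slot slice the rendered \linkS4class{CTSlice}.
#' @slot labels integer matrix of per-pixel tissue labels (codes index
#'   \code{labelNames}; 1 = air).
#' @slot labelNames character vector naming the label codes.
#' @slot truth data.frame with per-label pixel counts, areas (cm^2) and the
#'   specified mean HU.
#' @export
setClass("LabeledPhantom",
  representation(slice = "CTSlice", labels = "matrix",
                 labelNames = "character", truth = "data.frame"),
  validity = function(object) {
    if (!identical(dim(object@labels), dim(object@slice@pixels)))
      return("labels must match the slice shape")
    if (min(object@labels) < 1L || max(object@labels) > length(object@labelNames))
      return("label codes must index labelNames")
    TRUE
  })
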