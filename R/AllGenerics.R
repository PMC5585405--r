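#' Accessors for package data objects
#'
#' \code{pixels} returns the raster of a \linkS4class{CTSlice} or
#' \linkS4class{ProbabilityMap}; \code{spacing} and \code{station} the
#' slice metadata; \code{atlasProb} and \code{atlasFrame} the slots of a
#' \linkS4class{ShapeAtlas}; \code{depotAreas} the per-depot areas (cm^2)
#' of a segmentation result; \code{truthTable} the ground-truth table of a
#' \linkS4class{LabeledPhantom}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("station", function(x) standardGeneric("station"))
#' @rdname accessors
#' @export
setGeneric("atlasProb", function(x) standardGeneric("atlasProb"))
#' @rdname accessors
#' @export
setGeneric("atlasFrame", function(x) standardGeneric("atlasFrame"))
#' @rdname accessors
#' @export
setGeneric("depotAreas", function(x) standardGeneric("depotAreas"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setMethod("pixels", "CTSlice", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "ProbabilityMap", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("spacing", "CTSlice", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("station", "CTSlice", function(x) x@station)
#' @rdname accessors
#' @export
setMethod("atlasProb", "ShapeAtlas", function(x) x@prob)
#' @rdname accessors
#' @export
setMethod("atlasFrame", "ShapeAtlas", function(x) x@frame)
#' @rdname accessors
#' @export
setMethod("depotAreas", "AbdomenResult", function(x) x@areas)
#' @rdname accessors
#' @export
setMethod("depotAreas", "ThighResult", function(x) x@areas)
#' @rdname accessors
#' @export
setMethod("truthTable", "LabeledPhantom", function(x) x@truth)

#' @describeIn accessors slice of a phantom
#' @export
setGeneric("phantomSlice", function(x) standardGeneric("phantomSlice"))
#' @rdname accessors
#' @export
setMethod("phantomSlice", "LabeledPhantom", function(x) x@slice)

#' Ground-truth mask of one or more phantom tissue labels
#'
#' @param x a \linkS4class{LabeledPhantom}.
#' @param labels character vector of label names (see
#'   \code{x@labelNames}).
#' @return logical matrix, TRUE where the pixel carries one of the labels.
#' @export
labelMask <- function(x, labels) {
  stopifnot(is(x, "LabeledPhantom"))
  bad <- setdiff(labels, x@labelNames)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  codes <- match(labels, x@labelNames)
  matrix(x@labels %in% codes, nrow(x@labels), ncol(x@labels))
}

setMethod("show", "CTSlice", function(object) {
  cat(sprintf("CTSlice [%s]: %d x %d px, %.3g x %.3g mm, HU range [%g, %g]\n",
              object@station, nrow(object@pixels), ncol(object@pixels),
              object@spacing[1], object@spacing[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap: %d x %d px, max %.4g\n",
              nrow(object@pixels), ncol(object@pixels), max(object@pixels)))
})

setMethod("show", "ShapeAtlas", function(object) {
  cat(sprintf("ShapeAtlas: %d x %d canonical grid, mean frame [%.1f, %.1f] x [%.1f, %.1f]\n",
              nrow(object@prob), ncol(object@prob), object@frame[1],
              object@frame[2], object@frame[3], object@frame[4]))
})

setMethod("show", "LiverResult", function(object) {
  cat(sprintf("LiverResult: attenuation %.2f HU, range R [%.1f, %.1f] HU, %d px\n",
              object@attenuationHu, object@rangeR[1], object@rangeR[2],
              object@nPixels))
})

setMethod("show", "AbdomenResult", function(object) {
  a <- object@areas
  cat(sprintf("AbdomenResult: TAT %.1f, VAT %.1f, SAT %.1f cm^2 (back AT excluded: %d px)\n",
              a["tat"], a["vat"], a["sat"], sum(object@backAt)))
})

setMethod("show", "ThighResult", function(object) {
  a <- object@areas
  cat(sprintf("ThighResult [%s, %s]: muscle %.1f, SAT %.1f, SFAT %.1f, IMAT %.1f cm^2, muscle %.1f HU\n",
              object@side, object@method, a["muscle"], a["sat"], a["sfat"],
              a["imat"], object@muscleAttenuationHu))
})

setMethod("show", "OverlapStats", function(object) {
  cat(sprintf("OverlapStats: Dice %.4f (TP %d, FP %d, FN %d; FP ratio %.3f, FN ratio %.3f)\n",
              object@dice, object@tp, object@fp, object@fn,
              object@fpRatio, object@fnRatio))
})

setMethod("show", "LabeledPhantom", function(object) {
  cat(sprintf("LabeledPhantom [%s]: %d x %d px, %d labels\n",
              object@slice@station, nrow(object@labels), ncol(object@labels),
              length(unique(as.vector(object@labels)))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec [%s]: %d x %d px at %.3g x %.3g mm, seed %d\n",
              object@station, object@imageSize[1], object@imageSize[2],
              object@spacing[1], object@spacing[2], object@noiseSeed))
})
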