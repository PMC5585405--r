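#' Segment abdominal VAT and SAT
#'
#' Three stages: (1) adipose tissue is segmented by HU thresholding within
#' the body; (2) the ILT filter identifies the abdominal cavity (pixels
#' inside lean tissue), splitting adipose tissue into visceral (inside)
#' and subcutaneous (outside); (3) adipose tissue near the spinal column
#' -- inter/perimuscular back fat that is neither VAT nor SAT -- is
#' removed using an aligned back probability map (P_back) thresholded at
#' \code{backThreshold}.
#'
#' @param slice an abdomen-station \linkS4class{CTSlice}.
#' @param ilt cavity-pass \code{\link{iltParams}}.
#' @param backAtlas \linkS4class{ShapeAtlas} of the paraspinal back-fat
#'   region, or NULL to skip back removal.
#' @param bands \code{\link{huBands}}.
#' @param backThreshold threshold on the aligned P_back.
#' @return an \linkS4class{AbdomenResult}.  VAT, SAT and the excluded
#'   back fat partition the adipose-in-body mask.
#' @export
segmentVatSat <- function(slice, ilt = defaultIltParams("abdomen"),
                          backAtlas = NULL, bands = huBands(),
                          backThreshold = 0.5) {
  stopifnot(is(slice, "CTSlice"))
  if (slice@station != "abdomen") stop("argument error: not an abdomen slice")
  body <- bodyMask(slice, bands)
  adipose <- adiposeBandMask(slice, bands) & body
  resp <- iltResponse(slice, ilt, within = body)
  cavity <- insideMask(resp, ilt@pmThreshold, largestOnly = TRUE) & body
  if (!any(cavity)) stop("segmentation error: empty cavity mask")
  if (!any(adipose)) {
    warning("no adipose-band pixels in the body; zero areas")
  }
  back <- matrix(FALSE, nrow(adipose), ncol(adipose))
  if (!is.null(backAtlas)) {
    ## same frame convention as cavitySpan: non-lean interior of the mask
    interior <- cavity & !leanBandMask(slice, bands)
    if (!any(interior)) interior <- cavity
    idx <- which(interior, arr.ind = TRUE)
    span <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
    pback <- alignAtlas(backAtlas, span, dim(adipose))@pixels
    back <- adipose & cavity & (pback >= backThreshold)
  }
  vat <- adipose & cavity & !back
  sat <- adipose & !cavity
  sp <- slice@spacing
  areas <- c(tat = areaCm2(vat, sp) + areaCm2(sat, sp),
             vat = areaCm2(vat, sp), sat = areaCm2(sat, sp))
  new("AbdomenResult", vat = vat, sat = sat, backAt = back,
      cavity = cavity, areas = areas)
}

#' Build the back (paraspinal) adipose-tissue atlas
#'
#' Reference back-fat masks aligned via the bounding boxes of their
#' abdominal cavities; identical to \code{\link{buildShapeAtlas}} with
#' cavity boxes as frames.
#'
#' @param masks list of logical back-fat masks.
#' @param cavityBoxes list of numeric length-4 cavity bounding boxes.
#' @param gridDim canonical grid size.
#' @return a \linkS4class{ShapeAtlas} (P_back).
#' @export
buildBackAtlas <- function(masks, cavityBoxes, gridDim = c(96L, 96L)) {
  buildShapeAtlas(masks, cavityBoxes, gridDim)
}

.polyAngles <- function(pts, centroid) {
  atan2(pts[, 2] - centroid[2], -(pts[, 1] - centroid[1]))
}

#' Split SAT by a traced fascia into deep and superficial parts
#'
#' SAT pixels on the body-centroid side of the fascia polyline become
#' deep SAT (DSAT), the rest superficial (SSAT).  The anterior and
#' posterior halves (relative to the row through the body's center of
#' gravity; anterior = smaller row indices) are handled separately, and a
#' half is reported as valid only when the fascia delineation spans it.
#'
#' @param sat logical SAT mask.
#' @param fascia numeric matrix of polyline vertices, columns (row, col)
#'   in 1-based pixel coordinates; must lie within the SAT annulus.
#' @param bodyCentroidRow row index of the body's center of gravity.
#' @param bodyCentroidCol column of the center of gravity (defaults to
#'   the SAT centroid column).
#' @param coverage minimum fraction of a half's SAT pixels whose polar
#'   angle is covered by the fascia for the half to be valid.
#' @return list with logical masks \code{dsat}, \code{ssat} and logical
#'   flags \code{valid = c(anterior, posterior)}; pixels of invalid
#'   halves are left unassigned (FALSE in both masks).
#' @export
splitSatByFascia <- function(sat, fascia, bodyCentroidRow,
                             bodyCentroidCol = NULL, coverage = 0.99) {
  fascia <- as.matrix(fascia)
  if (ncol(fascia) != 2) stop("geometry error: fascia must be (row, col)")
  grown <- sat | EBImage::dilate(EBImage::Image(sat + 0),
                                 EBImage::makeBrush(3, "box")) > 0
  vidx <- cbind(pmin(pmax(round(fascia[, 1]), 1), nrow(sat)),
                pmin(pmax(round(fascia[, 2]), 1), ncol(sat)))
  if (!all(grown[vidx]))
    stop("geometry error: fascia vertices must lie within the SAT annulus")
  if (is.null(bodyCentroidCol))
    bodyCentroidCol <- mean(which(sat, arr.ind = TRUE)[, 2])
  centroid <- c(bodyCentroidRow, bodyCentroidCol)
  ## polar angle measured from the anterior direction (-row axis)
  vang <- .polyAngles(fascia, centroid)
  vrad <- sqrt((fascia[, 1] - centroid[1])^2 + (fascia[, 2] - centroid[2])^2)
  o <- order(vang)
  vang <- vang[o]; vrad <- vrad[o]
  idx <- which(sat, arr.ind = TRUE)
  pang <- .polyAngles(idx, centroid)
  prad <- sqrt((idx[, 1] - centroid[1])^2 + (idx[, 2] - centroid[2])^2)
  covered <- pang >= min(vang) & pang <= max(vang)
  frad <- rep(NA_real_, length(pang))
  if (any(covered))
    frad[covered] <- stats::approx(vang, vrad, xout = pang[covered],
                                   ties = mean)$y
  anterior <- idx[, 1] < bodyCentroidRow
  valid <- c(anterior = FALSE, posterior = FALSE)
  for (half in c(TRUE, FALSE)) {
    inHalf <- anterior == half
    if (!any(inHalf)) next
    if (mean(covered[inHalf]) >= coverage)
      valid[if (half) "anterior" else "posterior"] <- TRUE
  }
  dsat <- ssat <- matrix(FALSE, nrow(sat), ncol(sat))
  assign_half <- function(half) {
    inHalf <- (anterior == half) & covered & !is.na(frad)
    deep <- inHalf & (prad <= frad)
    sup <- inHalf & (prad > frad)
    dsat[idx[deep, , drop = FALSE]] <<- TRUE
    ssat[idx[sup, , drop = FALSE]] <<- TRUE
  }
  if (valid["anterior"]) assign_half(TRUE)
  if (valid["posterior"]) assign_half(FALSE)
  list(dsat = dsat, ssat = ssat, valid = valid)
}

.segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1]-a[1])*(c[2]-a[2]) - (b[2]-a[2])*(c[1]-a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Split VAT by a traced retroperitoneal contour
#'
#' VAT pixels inside the closed contour become RPAT, the rest IPAT
#' (even-odd rule, pixel centers decide membership).
#'
#' @param vat logical VAT mask.
#' @param contour numeric matrix of closed, simple polyline vertices,
#'   columns (row, col).
#' @return list with logical masks \code{ipat} and \code{rpat}
#'   (disjoint; their union is \code{vat}).
#' @export
splitVatByContour <- function(vat, contour) {
  contour <- as.matrix(contour)
  if (ncol(contour) != 2) stop("geometry error: contour must be (row, col)")
  n <- nrow(contour)
  if (n < 3) stop("geometry error: contour needs at least 3 vertices")
  ## reject self-intersection between non-adjacent edges
  closed <- rbind(contour, contour[1, ])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (j == 1 && i == n)) next
      if (.segmentsIntersect(closed[i, ], closed[i + 1, ],
                             closed[j, ], closed[j + 1, ]))
        stop("geometry error: self-intersecting contour")
    }
  }
  idx <- which(vat, arr.ind = TRUE)
  rpat <- ipat <- matrix(FALSE, nrow(vat), ncol(vat))
  if (nrow(idx)) {
    inside <- pracma::inpolygon(idx[, 1], idx[, 2],
                                contour[, 1], contour[, 2],
                                boundary = TRUE)
    rpat[idx[inside, , drop = FALSE]] <- TRUE
    ipat[idx[!inside, , drop = FALSE]] <- TRUE
  }
  list(ipat = ipat, rpat = rpat)
}
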