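#' Hounsfield-unit tissue bands
#'
#' The global attenuation bands used by every pipeline: body/air separation
#' above -300 HU, adipose tissue in [-190, -30] HU, lean tissue in
#' (-30, +151] HU and cortical bone above +400 HU.  Adjacent bands are
#' treated as closed-below/open-above so that they partition the HU axis
#' without double counting.
#'
#' @param bodyMin HU threshold separating body (and table) from air.
#' @param adipose numeric length-2, closed adipose band (lo, hi).
#' @param lean numeric length-2; lean pixels satisfy
#'   \code{hu > adipose[2] & hu <= lean[2]} (on integer HU this is the
#'   conventional -29..+151 band).
#' @param corticalBoneMin HU; cortical bone is \code{hu > corticalBoneMin}.
#' @return named list of class \code{"HUBands"}.
#' @examples
#' b <- huBands()
#' b$adipose
#' @export
huBands <- function(bodyMin = -300, adipose = c(-190, -30),
                    lean = c(-29, 151), corticalBoneMin = 400) {
  if (adipose[1] > adipose[2]) stop("adipose band must have lo <= hi")
  if (adipose[2] >= lean[1]) stop("adipose band must end below the lean band")
  if (lean[2] >= corticalBoneMin) stop("lean band must end below cortical bone")
  if (bodyMin > adipose[1]) stop("bodyMin must not exceed the adipose band")
  structure(list(bodyMin = bodyMin, adipose = adipose, lean = lean,
                 corticalBoneMin = corticalBoneMin), class = "HUBands")
}

#' Threshold a slice to a closed HU band
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param lo,hi band limits in HU, \code{lo <= hi}; the interval is closed
#'   on both ends.
#' @return logical matrix, TRUE where \code{lo <= HU <= hi}.
#' @export
thresholdBand <- function(slice, lo, hi) {
  stopifnot(is(slice, "CTSlice"))
  if (lo > hi) stop("band must have lo <= hi")
  p <- slice@pixels
  p >= lo & p <= hi
}

## lean band is open below so that it abuts the adipose band without
## double counting (float convention; equals [-29, 151] on integers)
leanBandMask <- function(slice, bands) {
  p <- slice@pixels
  p > bands$adipose[2] & p <= bands$lean[2]
}

adiposeBandMask <- function(slice, bands) {
  thresholdBand(slice, bands$adipose[1], bands$adipose[2])
}

corticalBoneMask <- function(slice, bands) {
  slice@pixels > bands$corticalBoneMin
}

#' Body mask: separate the subject from air and the patient table
#'
#' Thresholds the slice above the body/air limit, labels connected
#' components, discards candidate components whose centroid falls in the
#' bottom rows of the image (the patient table), keeps the \code{nKeep}
#' largest remaining components and fills internal holes (gas pockets,
#' bone marrow cavities, ...).
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param bands \code{\link{huBands}}.
#' @param nKeep number of components to keep (1 for liver/abdomen, 2 for
#'   the two thighs).
#' @param conn connectivity for component labelling (8 or 4).
#' @param fillConn connectivity for hole filling (4 or 8).
#' @param tableFraction components with centroid row below
#'   \code{tableFraction * nrow} are table candidates and are dropped.
#' @return logical matrix (union of the kept, hole-filled components).
#' @export
bodyMask <- function(slice, bands = huBands(), nKeep = 1L, conn = 8L,
                     fillConn = 4L, tableFraction = 0.8) {
  stopifnot(is(slice, "CTSlice"))
  above <- slice@pixels > bands$bodyMin
  if (!any(above)) stop("segmentation error: no pixels above the body threshold")
  lab <- cpp_label(above, as.integer(conn))
  sizes <- tabulate(lab[lab > 0L])
  centroidRows <- vapply(seq_along(sizes), function(k) {
    mean(which(lab == k, arr.ind = TRUE)[, 1L])
  }, numeric(1))
  ok <- which(centroidRows <= tableFraction * nrow(lab))
  if (!length(ok)) stop("segmentation error: only table-like components found")
  keep <- ok[order(sizes[ok], decreasing = TRUE)][seq_len(min(nKeep, length(ok)))]
  cpp_fill_holes(matrix(lab %in% keep, nrow(lab), ncol(lab)),
                 as.integer(fillConn))
}

#' Area of a binary mask in cm^2
#'
#' @param mask logical matrix.
#' @param spacing numeric length-2 pixel spacing in mm.
#' @return \code{sum(mask) * row_mm * col_mm / 100}.
#' @examples
#' areaCm2(matrix(TRUE, 10, 10), c(1, 1))  # 1 cm^2
#' @export
areaCm2 <- function(mask, spacing) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(mask) * spacing[1] * spacing[2] / 100
}

#' Label connected components of a mask
#'
#' @param mask logical matrix.
#' @param conn 4 or 8 connectivity.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
labelComponents <- function(mask, conn = 8L) {
  cpp_label(mask, as.integer(conn))
}

#' Fill holes in a binary mask
#'
#' Background regions not connected to the image border (with the given
#' connectivity) become foreground.
#'
#' @param mask logical matrix.
#' @param conn background connectivity (4 or 8).
#' @return logical matrix.
#' @export
fillHoles <- function(mask, conn = 4L) {
  cpp_fill_holes(mask, as.integer(conn))
}

largestComponent <- function(mask, conn = 8L) {
  lab <- cpp_label(mask, as.integer(conn))
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Spacing-aware Euclidean distance transform
#'
#' For each foreground pixel, the Euclidean distance (mm) to the nearest
#' background pixel center; 0 on background.
#'
#' @param mask logical matrix.
#' @param spacing numeric length-2 pixel spacing in mm.
#' @return numeric matrix of distances in mm.
#' @export
distanceTransform <- function(mask, spacing) {
  stopifnot(length(spacing) == 2, all(spacing > 0))
  cpp_edt(mask, spacing[1], spacing[2])
}

## ---- I/O ------------------------------------------------------------------

#' Read a single axial CT slice
#'
#' Supported formats: the package's plain-text fixture format
#' (\code{.cts}, see \code{\link{writeSliceFixture}}), NIfTI-1 (a 2D image
#' or a slice of a 3D volume; values are assumed rescaled to HU) and
#' uncompressed single-frame little-endian DICOM (rescale slope/intercept
#' applied).
#'
#' @param path input file.
#' @param station station label; for the fixture format the stored tag is
#'   used when \code{station} is missing.
#' @param sliceIndex for 3D NIfTI volumes, index of the axial plane.
#' @return a \linkS4class{CTSlice}.
#' @export
readSlice <- function(path, station = NULL, sliceIndex = 1L) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (grepl("\\.cts$", path, ignore.case = TRUE)) {
    return(readSliceFixture(path, station = station))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(img)
    arr <- as.array(img)
    if (length(dim(arr)) == 3L) arr <- arr[, , sliceIndex]
    if (length(dim(arr)) != 2L) stop("format error: expected a 2D plane")
    if (is.null(pd) || length(pd) < 2 || any(pd[1:2] <= 0))
      stop("metadata error: missing pixel spacing in NIfTI header")
    if (is.null(station)) stop("metadata error: station label required")
    return(ctSlice(matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2]),
                   pd[1:2], station))
  }
  ## fall through: DICOM
  if (is.null(station)) stop("metadata error: station label required")
  readDicomSlice(path, station)
}

#' Write a slice in the plain-text fixture format
#'
#' An uncompressed, bit-exact container used for test fixtures: a four-line
#' header (magic, station, spacing, dims) followed by one image row per
#' line with values printed at full double precision.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param path output file (conventionally \code{.cts}).
#' @return \code{path}, invisibly.
#' @export
writeSliceFixture <- function(slice, path) {
  stopifnot(is(slice, "CTSlice"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CTSLICE v1",
               paste("station", slice@station),
               paste("spacing", sprintf("%.17g", slice@spacing[1]),
                     sprintf("%.17g", slice@spacing[2])),
               paste("dims", nrow(slice@pixels), ncol(slice@pixels))), con)
  for (i in seq_len(nrow(slice@pixels))) {
    writeLines(paste(sprintf("%.17g", slice@pixels[i, ]), collapse = " "), con)
  }
  invisible(path)
}

readSliceFixture <- function(path, station = NULL) {
  lines <- readLines(path)
  if (length(lines) < 5 || lines[1] != "CTSLICE v1")
    stop("format error: not a CTSLICE fixture: ", path)
  hdr <- strsplit(lines[2:4], " +")
  if (hdr[[1]][1] != "station" || hdr[[2]][1] != "spacing" ||
      hdr[[3]][1] != "dims")
    stop("metadata error: malformed fixture header")
  st <- hdr[[1]][2]
  sp <- as.numeric(hdr[[2]][2:3])
  dm <- as.integer(hdr[[3]][2:3])
  vals <- lapply(lines[5:(4 + dm[1])], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]]))
  if (any(lengths(vals) != dm[2])) stop("format error: row length mismatch")
  px <- do.call(rbind, vals)
  ctSlice(px, sp, if (is.null(station)) st else station)
}

#' Write a label map as NIfTI
#'
#' @param labels integer matrix.
#' @param spacing numeric length-2 pixel spacing in mm.
#' @param path output \code{.nii} or \code{.nii.gz} file.
#' @return \code{path}, invisibly.
#' @export
writeLabelsNifti <- function(labels, spacing, path) {
  arr <- array(as.integer(labels), dim = c(dim(labels), 1L))
  attr(arr, "pixdim") <- c(spacing[1], spacing[2], 1)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write a PNG overlay of masks on a slice
#'
#' The slice is windowed to [-200, 200] HU grayscale and each mask blended
#' in colour on top.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param masks named list of logical matrices.
#' @param path output PNG path.
#' @param colours matrix of RGB rows (one per mask), recycled.
#' @param alpha blend weight for the overlays.
#' @return \code{path}, invisibly.
#' @export
writeOverlayPng <- function(slice, masks, path,
                            colours = rbind(c(1, 0, 0), c(0, 0.8, 0),
                                            c(0.2, 0.4, 1), c(1, 0.8, 0)),
                            alpha = 0.5) {
  g <- pmin(pmax((slice@pixels + 200) / 400, 0), 1)
  img <- array(g, dim = c(dim(g), 3L))
  for (k in seq_along(masks)) {
    col <- colours[(k - 1L) %% nrow(colours) + 1L, ]
    m <- masks[[k]]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- (1 - alpha) * plane[m] + alpha * col[ch]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write per-depot results to CSV
#'
#' One row per slice and depot: slice id, depot, area_cm2, mean_HU.
#'
#' @param rows data.frame with columns slice, depot, area_cm2, mean_hu.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeResultsCsv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
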