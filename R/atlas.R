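#' Build a shape atlas from reference masks
#'
#' Each reference mask is affinely rescaled so that its reference frame
#' (in practice, the bounding box of the abdominal cavity) maps onto a
#' canonical unit rectangle sampled on a fixed grid; the atlas value is
#' the per-pixel mean of the aligned masks.  No rotation is applied
#' (subjects are supine).
#'
#' @param masks list of logical matrices (reference segmentations).
#' @param frames list of numeric length-4 frames (rmin, rmax, cmin, cmax)
#'   in 1-based pixel coordinates, one per mask.
#' @param gridDim canonical grid size (rows, cols).
#' @return a \linkS4class{ShapeAtlas}.
#' @export
buildShapeAtlas <- function(masks, frames, gridDim = c(96L, 96L)) {
  if (length(masks) != length(frames))
    stop("argument error: masks and frames must have equal length")
  if (length(masks) < 1L) stop("argument error: at least one mask required")
  gr <- gridDim[1]; gc <- gridDim[2]
  u <- (seq_len(gr) - 0.5) / gr
  v <- (seq_len(gc) - 0.5) / gc
  acc <- matrix(0, gr, gc)
  for (k in seq_along(masks)) {
    m <- masks[[k]]; f <- as.numeric(frames[[k]])
    if (f[2] <= f[1] || f[4] <= f[3]) stop("argument error: degenerate frame")
    ri <- round(f[1] + u * (f[2] - f[1]))
    ci <- round(f[3] + v * (f[4] - f[3]))
    ri <- pmin(pmax(ri, 1L), nrow(m))
    ci <- pmin(pmax(ci, 1L), ncol(m))
    acc <- acc + (m[ri, , drop = FALSE][, ci, drop = FALSE] + 0)
  }
  fr <- rowMeans(vapply(frames, as.numeric, numeric(4)))
  new("ShapeAtlas", prob = acc / length(masks),
      frame = as.numeric(fr))
}

#' Align a shape atlas to a target image
#'
#' Maps the target's reference frame onto the canonical atlas grid and
#' samples the atlas bilinearly; pixels outside the frame get 0.
#'
#' @param atlas a \linkS4class{ShapeAtlas}.
#' @param frame numeric length-4 target frame (rmin, rmax, cmin, cmax),
#'   1-based pixel coordinates.
#' @param dim target image dimension (rows, cols).
#' @return a \linkS4class{ProbabilityMap} of the target shape.
#' @export
alignAtlas <- function(atlas, frame, dim) {
  stopifnot(is(atlas, "ShapeAtlas"))
  f <- as.numeric(frame)
  if (f[2] <= f[1] || f[4] <= f[3]) stop("argument error: degenerate frame")
  gr <- nrow(atlas@prob); gc <- ncol(atlas@prob)
  out <- matrix(0, dim[1], dim[2])
  rows <- seq_len(dim[1]); cols <- seq_len(dim[2])
  u <- (rows - f[1]) / (f[2] - f[1])  # 0..1 inside the frame
  v <- (cols - f[3]) / (f[4] - f[3])
  rin <- which(u >= 0 & u <= 1)
  cin <- which(v >= 0 & v <= 1)
  if (!length(rin) || !length(cin)) return(probabilityMap(out))
  ## continuous canonical coordinates (grid cell centers at (i-0.5)/gr)
  rg <- pmin(pmax(u[rin] * gr - 0.5, 0), gr - 1)
  cg <- pmin(pmax(v[cin] * gc - 0.5, 0), gc - 1)
  i0 <- pmin(floor(rg), gr - 2); fr <- rg - i0
  j0 <- pmin(floor(cg), gc - 2); fc <- cg - j0
  p <- atlas@prob
  block <- outer(1 - fr, 1 - fc) * p[i0 + 1, j0 + 1, drop = FALSE] +
           outer(fr, 1 - fc) * p[i0 + 2, j0 + 1, drop = FALSE] +
           outer(1 - fr, fc) * p[i0 + 1, j0 + 2, drop = FALSE] +
           outer(fr, fc) * p[i0 + 2, j0 + 2, drop = FALSE]
  out[rin, cin] <- block
  probabilityMap(pmin(pmax(out, 0), 1))
}

#' Span of the abdominal cavity
#'
#' Runs the ILT filter on the slice and returns the bounding rectangle of
#' the largest connected component of the inside mask.  This rectangle is
#' the reference coordinate system used to build and align shape atlases.
#'
#' The inside mask includes the enclosing muscle wall itself (tangential
#' rays inside the wall accumulate lean tissue), so the span is taken
#' over the non-lean interior of the mask -- the cavity contents proper.
#' When the cavity is entirely lean the full inside mask is used.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param params \code{\link{iltParams}} for the cavity pass.
#' @param body optional precomputed body mask (restricts the filter).
#' @param bands \code{\link{huBands}} (for the lean-band exclusion).
#' @return numeric length-4 (rmin, rmax, cmin, cmax), 1-based inclusive.
#' @export
cavitySpan <- function(slice, params = defaultIltParams("abdomen"),
                       body = NULL, bands = huBands()) {
  resp <- iltResponse(slice, params, within = body)
  m <- insideMask(resp, params@pmThreshold, largestOnly = TRUE)
  if (!any(m)) stop("segmentation error: empty cavity mask")
  interior <- m & !leanBandMask(slice, bands)
  if (!any(interior)) interior <- m
  idx <- which(interior, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

#' Serialize a shape atlas
#'
#' The probability grid is written as NIfTI and the frame as a JSON
#' sidecar (\code{<path>.json}).
#'
#' @param atlas a \linkS4class{ShapeAtlas}.
#' @param path output \code{.nii} or \code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  RNifti::writeNifti(RNifti::asNifti(array(atlas@prob,
                                           dim = c(dim(atlas@prob), 1L))),
                     path)
  jsonlite::write_json(list(frame = atlas@frame),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  prob <- matrix(pmin(pmax(as.numeric(arr), 0), 1), dim(arr)[1], dim(arr)[2])
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ShapeAtlas", prob = prob, frame = as.numeric(meta$frame))
}
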