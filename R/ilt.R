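#' Parameters of the inside-lean-tissue (ILT) filter
#'
#' The ILT filter shoots \code{nDir} equally spaced rays from every pixel,
#' accumulates lean-tissue probability along each ray, pools the smallest
#' \code{ceiling(dirPercent * nDir)} accumulations and normalizes the
#' resulting map to [0, 1].  Lean-tissue probability is a linear ramp in
#' HU between \code{l1} (probability 0) and \code{l2} (probability 1).
#'
#' @slot nDir integer >= 4, number of ray directions.
#' @slot l1,l2 HU levels of the linear ramp, \code{l1 < l2}.
#' @slot dirPercent fraction in (0, 1] of directions pooled (smallest
#'   accumulations).
#' @slot stepMm ray sampling step in mm (NA = use \code{min(spacing)} of
#'   the image).
#' @slot pmThreshold threshold in [0, 1] applied to the normalized
#'   response to extract the enclosed ("inside") region.
#' @slot interp \code{"bilinear"} or \code{"nearest"} ray sampling.
#' @export
setClass("ILTParams",
  representation(nDir = "integer", l1 = "numeric", l2 = "numeric",
                 dirPercent = "numeric", stepMm = "numeric",
                 pmThreshold = "numeric", interp = "character"),
  validity = function(object) {
    if (object@nDir < 4L) return("nDir must be >= 4")
    if (object@l1 >= object@l2) return("l1 must be < l2")
    if (object@dirPercent <= 0 || object@dirPercent > 1)
      return("dirPercent must lie in (0, 1]")
    if (!is.na(object@stepMm) && object@stepMm <= 0)
      return("stepMm must be positive")
    if (object@pmThreshold < 0 || object@pmThreshold > 1)
      return("pmThreshold must lie in [0, 1]")
    if (!(object@interp %in% c("bilinear", "nearest")))
      return("interp must be bilinear or nearest")
    TRUE
  })

#' Construct ILT filter parameters
#'
#' @param nDir number of equally spaced ray directions (angles
#'   \code{2*pi*d/nDir}, d = 0..nDir-1, measured from the +column axis).
#' @param l1,l2 HU levels of the lean-probability ramp.
#' @param dirPercent fraction of directions pooled.
#' @param stepMm ray sampling step (mm); NA for \code{min(spacing)}.
#' @param pmThreshold threshold on the normalized response.
#' @param interp ray sampling: \code{"bilinear"} (default) or
#'   \code{"nearest"}.
#' @return an \linkS4class{ILTParams} object.
#' @export
iltParams <- function(nDir = 32L, l1 = -30, l2 = 20, dirPercent = 0.5,
                      stepMm = NA_real_, pmThreshold = 0.1,
                      interp = "bilinear") {
  new("ILTParams", nDir = as.integer(nDir), l1 = l1, l2 = l2,
      dirPercent = dirPercent, stepMm = as.numeric(stepMm),
      pmThreshold = pmThreshold, interp = interp)
}

#' Station defaults for the ILT filter
#'
#' Thresholds were calibrated once on the default synthetic phantoms (see
#' the methods vignette): the cavity pass (abdomen and liver stations)
#' separates visceral regions from subcutaneous fat, the thigh pass
#' separates SAT from everything inside the fascia, and the stricter
#' \code{"thigh_deep"} pass isolates the deep muscle compartment for the
#' SFAT/IMAT split.
#'
#' @param station one of \code{"abdomen"}, \code{"liver"}, \code{"thigh"},
#'   \code{"thigh_deep"}.
#' @return an \linkS4class{ILTParams} object.
#' @export
defaultIltParams <- function(station = c("abdomen", "liver", "thigh",
                                         "thigh_deep")) {
  station <- match.arg(station)
  switch(station,
    abdomen    = iltParams(pmThreshold = 0.05),
    liver      = iltParams(pmThreshold = 0.05),
    thigh      = iltParams(pmThreshold = 0.01),
    thigh_deep = iltParams(pmThreshold = 0.18))
}

#' Map attenuation to lean-tissue probability
#'
#' Linear ramp: 0 at or below \code{l1}, 1 at or above \code{l2}.
#'
#' @param hu numeric HU values (vector or matrix).
#' @param l1,l2 ramp levels, \code{l1 < l2}.
#' @return values in [0, 1], same shape as \code{hu}.
#' @examples
#' huToLeanProb(c(-30, -5, 20), -30, 20)  # 0, 0.5, 1
#' @export
huToLeanProb <- function(hu, l1 = -30, l2 = 20) {
  if (l1 >= l2) stop("l1 must be < l2")
  pmin(pmax((hu - l1) / (l2 - l1), 0), 1)
}

#' Accumulate lean probability along one ray
#'
#' Samples the probability image every \code{stepMm} mm along the given
#' physical direction starting one step beyond the origin pixel and stops
#' at the first sample outside the grid.
#'
#' @param prob a \linkS4class{ProbabilityMap} or numeric matrix.
#' @param origin numeric length-2, 0-based (row, col) pixel coordinates.
#' @param direction numeric length-2 direction in physical (row, col) mm
#'   space; normalized internally, must be non-zero.
#' @param stepMm sampling step (mm).
#' @param spacing pixel spacing (row_mm, col_mm).
#' @param interp \code{"bilinear"} or \code{"nearest"}.
#' @return the accumulated probability (A_lt-prob), a scalar >= 0.
#' @export
accumulateDirection <- function(prob, origin, direction, stepMm, spacing,
                                interp = "bilinear") {
  p <- if (is(prob, "ProbabilityMap")) prob@pixels else prob
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("direction must be non-zero")
  if (origin[1] < 0 || origin[1] > nrow(p) - 1 ||
      origin[2] < 0 || origin[2] > ncol(p) - 1)
    stop("origin must lie inside the image")
  cpp_accumulate_ray(p, origin[1], origin[2], direction[1] / n,
                     direction[2] / n, stepMm, spacing[1], spacing[2],
                     if (interp == "bilinear") 0L else 1L)
}

.iltPrepare <- function(slice, params, within) {
  px <- slice@pixels
  if (nrow(px) < 2L || ncol(px) < 2L)
    stop("argument error: degenerate image for the ILT filter")
  prob <- huToLeanProb(px, params@l1, params@l2)
  if (!is.null(within)) prob[!within] <- 0
  step <- if (is.na(params@stepMm)) min(slice@spacing) else params@stepMm
  m <- as.integer(ceiling(params@dirPercent * params@nDir))
  list(prob = prob, step = step, m = m)
}

#' ILT filter response (P_inside)
#'
#' Per pixel, lean-tissue probabilities are accumulated along
#' \code{nDir} equally spaced rays; the \code{ceiling(dirPercent*nDir)}
#' smallest accumulations are summed, and the map is divided by its
#' global maximum so it spans [0, 1] (an all-zero map passes through
#' unchanged).
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param params \code{\link{iltParams}}.
#' @param within optional logical matrix; pixels outside it are treated as
#'   air (probability 0) and their response is not computed.  Used to run
#'   the filter on one thigh at a time.
#' @param normalize divide by the global maximum (default); set FALSE for
#'   the raw pooled sums.
#' @return a \linkS4class{ProbabilityMap} (or plain matrix when
#'   \code{normalize = FALSE}).
#' @export
iltResponse <- function(slice, params = defaultIltParams(slice@station),
                        within = NULL, normalize = TRUE) {
  stopifnot(is(slice, "CTSlice"), is(params, "ILTParams"))
  pre <- .iltPrepare(slice, params, within)
  compute <- if (is.null(within)) matrix(1L, 0, 0)
             else matrix(as.integer(within), nrow(within), ncol(within))
  raw <- cpp_ilt_raw(pre$prob, params@nDir, pre$m, pre$step,
                     slice@spacing[1], slice@spacing[2],
                     if (params@interp == "bilinear") 0L else 1L, compute)
  if (!normalize) return(raw)
  mx <- max(raw)
  probabilityMap(if (mx > 0) raw / mx else raw)
}

#' Reference (plain-R) ILT response
#'
#' An independent implementation of the same contract as
#' \code{\link{iltResponse}}, written as explicit ray marching in R and
#' used to verify the production path.  Intended for small images.
#'
#' @inheritParams iltResponse
#' @return a \linkS4class{ProbabilityMap} (or matrix when
#'   \code{normalize = FALSE}).
#' @export
iltResponseRef <- function(slice, params = defaultIltParams(slice@station),
                           within = NULL, normalize = TRUE) {
  stopifnot(is(slice, "CTSlice"), is(params, "ILTParams"))
  pre <- .iltPrepare(slice, params, within)
  prob <- pre$prob
  nr <- nrow(prob); nc <- ncol(prob)
  rowMm <- slice@spacing[1]; colMm <- slice@spacing[2]
  nDir <- params@nDir
  kmax <- ceiling(sqrt((nr * rowMm)^2 + (nc * colMm)^2) / pre$step) + 2L
  I <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  J <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  bilinAt <- function(r, c) {
    i0 <- pmin(floor(r), nr - 2); j0 <- pmin(floor(c), nc - 2)
    fr <- r - i0; fc <- c - j0
    (1 - fr) * (1 - fc) * prob[cbind(i0 + 1, j0 + 1)] +
      fr * (1 - fc) * prob[cbind(i0 + 2, j0 + 1)] +
      (1 - fr) * fc * prob[cbind(i0 + 1, j0 + 2)] +
      fr * fc * prob[cbind(i0 + 2, j0 + 2)]
  }
  nearestAt <- function(r, c) {
    i <- pmin(pmax(floor(r + 0.5), 0), nr - 1)
    j <- pmin(pmax(floor(c + 0.5), 0), nc - 1)
    prob[cbind(i + 1, j + 1)]
  }
  sample1 <- if (params@interp == "bilinear") bilinAt else nearestAt
  computeIdx <- if (is.null(within)) rep(TRUE, nr * nc) else as.vector(within)
  accs <- matrix(0, nr * nc, nDir)
  for (d in seq_len(nDir) - 1L) {
    th <- 2 * pi * d / nDir
    di <- pre$step * sin(th) / rowMm
    dj <- pre$step * cos(th) / colMm
    active <- computeIdx
    acc <- numeric(nr * nc)
    for (k in seq_len(kmax)) {
      r <- as.vector(I) + k * di
      c <- as.vector(J) + k * dj
      inb <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
      active <- active & inb
      if (!any(active)) break
      acc[active] <- acc[active] + sample1(r[active], c[active])
    }
    accs[, d + 1L] <- acc
  }
  pooled <- apply(accs, 1L, function(a) sum(sort(a)[seq_len(pre$m)]))
  pooled[!computeIdx] <- 0
  raw <- matrix(pooled, nr, nc)
  if (!normalize) return(raw)
  mx <- max(raw)
  probabilityMap(if (mx > 0) raw / mx else raw)
}

#' Threshold the ILT response to an inside mask
#'
#' @param response a \linkS4class{ProbabilityMap} (normalized ILT
#'   response).
#' @param pmThreshold threshold in [0, 1]; the mask is
#'   \code{response >= pmThreshold}.
#' @param largestOnly keep only the largest connected component.
#' @param conn connectivity used when \code{largestOnly}.
#' @return logical matrix.
#' @export
insideMask <- function(response, pmThreshold, largestOnly = FALSE,
                       conn = 8L) {
  stopifnot(is(response, "ProbabilityMap"))
  if (pmThreshold < 0 || pmThreshold > 1)
    stop("pmThreshold must lie in [0, 1]")
  m <- response@pixels >= pmThreshold
  if (largestOnly && any(m)) m <- largestComponent(m, conn)
  m
}
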