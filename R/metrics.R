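#' Overlap between an automated and a reference segmentation
#'
#' Pixel contingency counts and Dice = 2 TP / (2 TP + FP + FN); the false
#' positive and false negative ratios are expressed as fractions of the
#' reference pixel count.  Two empty masks agree perfectly (Dice 1).
#'
#' @param auto logical matrix, the automated mask.
#' @param reference logical matrix, the reference mask (same shape).
#' @return an \linkS4class{OverlapStats}.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE
#' r <- matrix(FALSE, 4, 4); r[1:2, 1:3] <- TRUE
#' overlap(a, r)  # dice 0.6
#' @export
overlap <- function(auto, reference) {
  if (!identical(dim(auto), dim(reference)))
    stop("argument error: masks must have the same shape")
  tp <- sum(auto & reference)
  fp <- sum(auto & !reference)
  fn <- sum(!auto & reference)
  nref <- tp + fn
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  new("OverlapStats", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), dice = dice,
      fpRatio = if (nref > 0) fp / nref else NA_real_,
      fnRatio = if (nref > 0) fn / nref else NA_real_)
}

#' Coefficient of variation of repeated measurements
#'
#' Root-mean-square within-pair CV:
#' \code{sqrt(mean((sd_pair / mean_pair)^2)) * 100}.  An alternative
#' definition (SD of the pairwise differences over the grand mean,
#' divided by sqrt(2)) is available for comparison.
#'
#' @param pairs numeric matrix or data.frame with two columns (repeated
#'   measurements), at least two rows unless \code{single = TRUE}
#'   semantics are wanted -- a single pair is accepted.
#' @param method \code{"rms"} (default) or \code{"sd_diff"}.
#' @return CV in percent.
#' @examples
#' cvRepeated(rbind(c(90, 110)))  # 14.14
#' @export
cvRepeated <- function(pairs, method = c("rms", "sd_diff")) {
  method <- match.arg(method)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("argument error: pairs must have two columns")
  means <- rowMeans(pairs)
  if (any(means <= 0)) stop("argument error: non-positive pair mean")
  if (method == "rms") {
    sds <- apply(pairs, 1, stats::sd)
    sqrt(mean((sds / means)^2)) * 100
  } else {
    d <- pairs[, 1] - pairs[, 2]
    stats::sd(d) / mean(means) / sqrt(2) * 100
  }
}

#' Pearson correlation
#'
#' Thin wrapper over the standard product-moment correlation with the
#' module's argument checks.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient r.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("argument error: need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("numeric error: zero variance")
  stats::cor(x, y)
}

#' Two-tailed paired t-test with paired difference summaries
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{t}, \code{p}, \code{meanDiff},
#'   \code{percentDiff} (mean of the per-pair percent differences
#'   relative to y) and \code{degenerate} (TRUE when the differences have
#'   zero variance; then \code{p} is 1 for identical vectors and NA
#'   otherwise).
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("argument error: need equal lengths >= 3")
  d <- x - y
  pct <- mean(100 * d[y != 0] / y[y != 0])
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_,
                p = if (all(d == 0)) 1 else NA_real_,
                meanDiff = mean(d), percentDiff = pct, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, meanDiff = mean(d),
       percentDiff = pct, degenerate = FALSE)
}

#' Summarize a phantom-ensemble evaluation
#'
#' Batch analog of a study evaluation table: per-depot mean +/- SD of
#' automated and reference areas, Pearson r, paired-t p, mean FP/FN
#' ratios and mean Dice.
#'
#' @param autoAreas,refAreas data.frames (one row per phantom, one column
#'   per depot) of areas in cm^2.
#' @param overlaps list (per phantom) of named lists of
#'   \linkS4class{OverlapStats} per depot.
#' @return data.frame with one row per depot.
#' @export
summarizeEnsemble <- function(autoAreas, refAreas, overlaps) {
  depots <- colnames(autoAreas)
  rows <- lapply(depots, function(dp) {
    a <- autoAreas[[dp]]; r <- refAreas[[dp]]
    ov <- lapply(overlaps, `[[`, dp)
    data.frame(
      depot = dp,
      auto_mean = mean(a), auto_sd = stats::sd(a),
      ref_mean = mean(r), ref_sd = stats::sd(r),
      p = pairedT(a, r)$p,
      r = pearsonR(a, r),
      fp = mean(vapply(ov, function(o) o@fpRatio, numeric(1))),
      fn = mean(vapply(ov, function(o) o@fnRatio, numeric(1))),
      dice_mean = mean(vapply(ov, function(o) o@dice, numeric(1))),
      dice_sd = stats::sd(vapply(ov, function(o) o@dice, numeric(1))))
  })
  do.call(rbind, rows)
}
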