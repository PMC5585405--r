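## Minimal read-only DICOM support: uncompressed single-frame CT images,
## little-endian transfer syntaxes (implicit 1.2.840.10008.1.2 and explicit
## 1.2.840.10008.1.2.1).  Only the handful of tags the pipelines need are
## extracted; everything else is skipped by length.

.u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
.u32 <- function(raw, off) {
  .u16(raw, off) + 65536 * .u16(raw, off + 2L)
}

#' Read an uncompressed single-frame CT DICOM file
#'
#' Applies RescaleSlope/RescaleIntercept so pixel values are HU, and takes
#' the pixel spacing from PixelSpacing (row spacing first, per the
#' standard).  Compressed transfer syntaxes, sequences of undefined length
#' and multi-frame objects are not supported.
#'
#' @param path DICOM file.
#' @param station station label for the resulting slice.
#' @return a \linkS4class{CTSlice}.
#' @export
readDicomSlice <- function(path, station) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || !identical(raw[129:132], charToRaw("DICM")))
    stop("format error: not a DICOM part-10 file: ", path)
  pos <- 132L  # 0-based offset just past "DICM"
  tags <- list()
  explicit <- TRUE  # file meta group is always explicit LE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw)) {
    group <- .u16(raw, pos); elem <- .u16(raw, pos + 2L)
    if (group > 2L && !explicit) {
      len <- .u32(raw, pos + 4L)
      hdr <- 8L
      vr <- ""
    } else {
      vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
      if (vr %in% long_vrs) {
        len <- .u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L)
        hdr <- 8L
      }
    }
    if (len == 4294967295) stop("format error: undefined-length element")
    key <- sprintf("%04x,%04x", group, elem)
    body <- if (len > 0) raw[(pos + hdr + 1L):(pos + hdr + len)] else raw(0)
    if (key %in% c("0002,0010", "0028,0010", "0028,0011", "0028,0100",
                   "0028,0103", "0028,0030", "0028,1052", "0028,1053",
                   "7fe0,0010")) {
      tags[[key]] <- body
    }
    if (key == "0002,0010") {
      ts <- sub("\\x00+$", "", rawToChar(body))
      ts <- trimws(ts)
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("format error: unsupported transfer syntax: ", ts)
    }
    pos <- pos + hdr + len
    if (key == "7fe0,0010") break
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(tags)))
    stop("format error: missing Rows/Columns/PixelData")
  rows <- .u16(tags[["0028,0010"]], 0L)
  cols <- .u16(tags[["0028,0011"]], 0L)
  bits <- if (!is.null(tags[["0028,0100"]])) .u16(tags[["0028,0100"]], 0L) else 16L
  if (bits != 16L) stop("format error: only 16-bit pixel data supported")
  signed <- !is.null(tags[["0028,0103"]]) && .u16(tags[["0028,0103"]], 0L) == 1L
  if (is.null(tags[["0028,0030"]]))
    stop("metadata error: missing PixelSpacing")
  spacing <- as.numeric(strsplit(trimws(rawToChar(tags[["0028,0030"]])),
                                 "\\\\")[[1]])
  getNum <- function(key, default) {
    if (is.null(tags[[key]])) return(default)
    as.numeric(trimws(rawToChar(tags[[key]])))
  }
  intercept <- getNum("0028,1052", 0)
  slope <- getNum("0028,1053", 1)
  pd <- tags[["7fe0,0010"]]
  if (length(pd) < 2L * rows * cols)
    stop("format error: truncated PixelData")
  stored <- readBin(pd, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  if (!signed) stored <- ifelse(stored < 0, stored + 65536, stored)
  hu <- slope * stored + intercept
  px <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)
  ctSlice(px, spacing[1:2], station)
}
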