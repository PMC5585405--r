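## Shared fixture builders and independent oracles; everything is generated
## in code so the suite is self-contained.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## a body of fat containing a circular lean annulus with fat inside it
leanAnnulusSlice <- function(n = 80, rOuter = 30, rInner = 24, spacing = c(2, 2)) {
  ctr <- (n + 1) / 2
  d <- outer(((1:n) - ctr) * spacing[1], ((1:n) - ctr) * spacing[2],
             function(a, b) sqrt(a^2 + b^2))
  px <- matrix(-1000, n, n)
  px[d <= rOuter * spacing[1]] <- 45
  px[d <= rInner * spacing[1]] <- -95
  ctSlice(px, spacing, "abdomen")
}

## rectangular lean wall: body fat block, lean frame, fat interior
rectWallSlice <- function() {
  px <- matrix(-1000, 120, 120)
  px[20:100, 15:105] <- -95
  px[35:85, 30:90] <- 45
  px[40:80, 35:85] <- -95
  ctSlice(px, c(2, 2), "abdomen")
}

## even-odd crossing point-in-polygon, independent of pracma
pipOracle <- function(pr, pc, vr, vc) {
  n <- length(vr)
  vapply(seq_along(pr), function(i) {
    x <- pr[i]; y <- pc[i]; inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      if ((vc[k] > y) != (vc[j] > y) &&
          x < (vr[j] - vr[k]) * (y - vc[k]) / (vc[j] - vc[k]) + vr[k])
        inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
}

## exhaustive counting oracle for overlap statistics
overlapOracle <- function(auto, ref) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(auto)) {
    if (auto[i] && ref[i]) tp <- tp + 1L
    else if (auto[i]) fp <- fp + 1L
    else if (ref[i]) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn,
       dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn))
}

## brute-force spacing-aware distance transform
edtOracle <- function(mask, spacing) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(bg) == 0L) { out[mask] <- Inf; return(out) }
  for (k in seq_len(nrow(fg))) {
    d <- sqrt(((fg[k, 1] - bg[, 1]) * spacing[1])^2 +
              ((fg[k, 2] - bg[, 2]) * spacing[2])^2)
    out[fg[k, 1], fg[k, 2]] <- min(d)
  }
  out
}

## minimal uncompressed explicit-VR little-endian DICOM byte stream
dicomBytes <- function(rows, cols, stored, spacing = c(1, 1),
                       intercept = -1024, slope = 1) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  evenStr <- function(s) {
    b <- charToRaw(s); if (length(b) %% 2) b <- c(b, as.raw(0)); b
  }
  el <- function(g, e, vr, body) {
    hdr <- c(u16(g), u16(e), charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
      c(hdr, as.raw(c(0, 0)), u32(length(body)), body)
    else c(hdr, u16(length(body)), body)
  }
  pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  c(rep(as.raw(0), 128), charToRaw("DICM"),
    el(0x0002, 0x0010, "UI", evenStr("1.2.840.10008.1.2.1")),
    el(0x0028, 0x0010, "US", u16(rows)),
    el(0x0028, 0x0011, "US", u16(cols)),
    el(0x0028, 0x0030, "DS", evenStr(paste(spacing, collapse = "\\"))),
    el(0x0028, 0x0100, "US", u16(16)),
    el(0x0028, 0x0103, "US", u16(0)),
    el(0x0028, 0x1052, "DS", evenStr(as.character(intercept))),
    el(0x0028, 0x1053, "DS", evenStr(as.character(slope))),
    el(0x7fe0, 0x0010, "OW", pix))
}

defaultThighPhantom <- function() {
  cached("thigh_default", makePhantom(phantomSpec("thigh", noiseSeed = 5)))
}

defaultAbdomenPhantom <- function() {
  cached("abdomen_default", makePhantom(phantomSpec("abdomen", noiseSeed = 3)))
}

liverAtlasSmall <- function(n = 10) {
  cached(paste0("liver_atlas_", n), {
    train <- makeEnsemble(phantomSpec("liver", noiseSeed = 1), n, seed = 101)
    masks <- lapply(train, function(ph) labelMask(ph, "liver"))
    frames <- lapply(train, function(ph) {
      sl <- phantomSlice(ph)
      cavitySpan(sl, defaultIltParams("liver"), body = bodyMask(sl))
    })
    buildShapeAtlas(masks, frames)
  })
}
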