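.PHANTOM_LABELS <- c("air", "table", "sat", "muscle_wall", "vat", "back_at",
                     "back_muscle", "organ", "spine_bone", "spine_core",
                     "liver", "spleen", "thigh_sat", "fascia", "sfat",
                     "thigh_muscle", "imat", "bone", "marrow")

.defaultTissueHu <- function() {
  list(air = c(-1000, 5), table = c(0, 5), sat = c(-95, 10),
       muscle_wall = c(45, 10), vat = c(-95, 10), back_at = c(-95, 10),
       back_muscle = c(45, 10), organ = c(35, 10), spine_bone = c(1200, 10),
       spine_core = c(150, 10), liver = c(50, 10), spleen = c(50, 10),
       thigh_sat = c(-95, 10), fascia = c(60, 10), sfat = c(-95, 10),
       thigh_muscle = c(45, 10), imat = c(-95, 10), bone = c(1200, 10),
       marrow = c(-80, 10))
}

.defaultGeometry <- function(station) {
  common <- list(centerOffset = c(0, 0), table = TRUE, tableRowFrac = 0.91,
                 tableThicknessMm = 8, tableWidthFrac = 0.6)
  geo <- switch(station,
    abdomen = list(
      bodySemi = c(140, 170), satThickness = 20, wallThickness = 10,
      wallGapMm = 0,
      organs = list(list(center = c(-30, 0), semi = c(70, 90)),
                    list(center = c(40, -75), semi = c(18, 14)),
                    list(center = c(40, 75), semi = c(18, 14))),
      spineSemi = c(20, 18), spineCoreSemi = c(12, 10),
      spineOffsetFromCavity = 26,
      backMuscleSemi = c(26, 30), backMuscleColOffset = 38,
      backMuscleRowExtra = 4, backAtSemi = c(26, 28)),
    liver = list(
      bodySemi = c(130, 170), satThickness = 16, wallThickness = 8,
      wallGapMm = 0,
      liverCenter = c(-16, -68), liverSemi = c(68, 60),
      spleenCenter = c(-30, 96), spleenSemi = c(24, 18),
      organs = list(list(center = c(40, 30), semi = c(30, 34)),
                    list(center = c(62, -30), semi = c(22, 30))),
      spineSemi = c(20, 18), spineCoreSemi = c(12, 10),
      spineOffsetFromCavity = 24,
      backMuscleSemi = c(24, 28), backMuscleColOffset = 36,
      backMuscleRowExtra = 4, backAtSemi = c(24, 26)),
    thigh = list(
      thighRadius = 72, satThickness = 12, fasciaThickness = 2,
      sfatThickness = 4, centerColOffset = 82, centerRowOffset = 0,
      boneRadius = 14, corticalThickness = 4,
      islandDist = 30, islandRadius = 5, islandAngles = c(20, 140, 260)))
  c(geo, common)
}

#' Describe a synthetic CT phantom slice
#'
#' Builds a \linkS4class{PhantomSpec} with station-appropriate default
#' geometry (all lengths in mm) and tissue HU means/SDs inside the
#' standard tissue bands.  Supplied geometry or tissue entries override
#' the defaults.  The abdomen phantom has a body outline with patient
#' table, SAT ring, abdominal muscle wall (optionally with an anterior
#' gap), cavity with organs and VAT, spine with paraspinal back muscles
#' and a perispinal back-fat ring; the liver phantom adds a liver (HU
#' adjustable over 0-60), spleen and organs; the thigh phantom has two
#' thighs with cortical bone and fatty marrow, muscle, SAT, a thin
#' fascia lata with a subfascial fat band, and IMAT islands.
#'
#' @param station \code{"liver"}, \code{"abdomen"} or \code{"thigh"}.
#' @param imageSize integer length-2 (rows, cols).
#' @param spacing numeric length-2 (row_mm, col_mm).
#' @param geometry named list of overrides for the station defaults.
#' @param tissueHu named list of c(mean, sd) overrides.
#' @param noiseSeed integer seed for the pixel noise.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' sp <- phantomSpec("abdomen", noiseSeed = 7)
#' @export
phantomSpec <- function(station, imageSize = c(192L, 192L),
                        spacing = c(2, 2), geometry = list(),
                        tissueHu = list(), noiseSeed = 1L) {
  geo <- .defaultGeometry(station)
  geo[names(geometry)] <- geometry
  hu <- .defaultTissueHu()
  hu[names(tissueHu)] <- tissueHu
  new("PhantomSpec", station = station,
      imageSize = as.integer(imageSize), spacing = as.numeric(spacing),
      geometry = geo, tissueHu = hu, noiseSeed = as.integer(noiseSeed))
}

## mask of an axis-aligned ellipse given center in px and semi-axes in mm
.ellipse <- function(nr, nc, center, semiMm, spacing) {
  r <- (seq_len(nr) - center[1]) * spacing[1] / semiMm[1]
  c <- (seq_len(nc) - center[2]) * spacing[2] / semiMm[2]
  outer(r^2, c^2, `+`) <= 1
}

.renderAbdominal <- function(spec, withLiver) {
  g <- spec@geometry
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  sp <- spec@spacing
  ctr <- c((nr + 1) / 2 + g$centerOffset[1] / sp[1],
           (nc + 1) / 2 + g$centerOffset[2] / sp[2])
  if (g$satThickness + g$wallThickness >= min(g$bodySemi))
    stop("spec error: SAT + wall exceed the body semi-axes")
  cavSemi <- g$bodySemi - g$satThickness - g$wallThickness
  L <- function(name) match(name, .PHANTOM_LABELS)
  lab <- matrix(L("air"), nr, nc)
  paint <- function(mask, name) lab[mask] <<- L(name)
  paint(.ellipse(nr, nc, ctr, g$bodySemi, sp), "sat")
  paint(.ellipse(nr, nc, ctr, g$bodySemi - g$satThickness, sp), "muscle_wall")
  cavity <- .ellipse(nr, nc, ctr, cavSemi, sp)
  paint(cavity, "vat")
  for (o in g$organs)
    paint(.ellipse(nr, nc, ctr + o$center / sp, o$semi, sp) & cavity, "organ")
  if (withLiver) {
    paint(.ellipse(nr, nc, ctr + g$liverCenter / sp, g$liverSemi, sp) & cavity,
          "liver")
    paint(.ellipse(nr, nc, ctr + g$spleenCenter / sp, g$spleenSemi, sp) & cavity,
          "spleen")
  }
  spineCtr <- ctr + c((cavSemi[1] - g$spineOffsetFromCavity) / sp[1], 0)
  bmCtr <- spineCtr + c(g$backMuscleRowExtra / sp[1], 0)
  for (s in c(-1, 1))
    paint(.ellipse(nr, nc, bmCtr + c(0, s * g$backMuscleColOffset / sp[2]),
                   g$backMuscleSemi, sp), "back_muscle")
  insideWallOuter <- .ellipse(nr, nc, ctr, g$bodySemi - g$satThickness, sp)
  paint(.ellipse(nr, nc, spineCtr, g$backAtSemi, sp) & insideWallOuter,
        "back_at")
  paint(.ellipse(nr, nc, spineCtr, g$spineSemi, sp), "spine_bone")
  paint(.ellipse(nr, nc, spineCtr, g$spineCoreSemi, sp), "spine_core")
  if (!is.null(g$wallGapMm) && g$wallGapMm > 0) {
    wall <- lab == L("muscle_wall")
    cols <- abs((seq_len(nc) - ctr[2]) * sp[2]) <= g$wallGapMm / 2
    anterior <- seq_len(nr) < ctr[1]
    gap <- wall & outer(anterior, cols, `&`)
    paint(gap, "vat")
  }
  if (isTRUE(g$table)) {
    r0 <- round(g$tableRowFrac * nr)
    rr <- r0:min(nr, r0 + max(1L, round(g$tableThicknessMm / sp[1])) - 1L)
    halfw <- round(g$tableWidthFrac * nc / 2)
    cc <- max(1L, round(ctr[2] - halfw)):min(nc, round(ctr[2] + halfw))
    lab[rr, cc] <- L("table")
  }
  lab
}

.renderThigh <- function(spec) {
  g <- spec@geometry
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  sp <- spec@spacing
  if (g$satThickness + g$fasciaThickness + g$sfatThickness + g$boneRadius >=
      g$thighRadius)
    stop("spec error: thigh layers exceed the thigh radius")
  L <- function(name) match(name, .PHANTOM_LABELS)
  lab <- matrix(L("air"), nr, nc)
  paint <- function(mask, name) lab[mask] <<- L(name)
  for (s in c(-1, 1)) {
    ctr <- c((nr + 1) / 2 + g$centerRowOffset / sp[1],
             (nc + 1) / 2 + s * g$centerColOffset / sp[2])
    circ <- function(radius, off = c(0, 0))
      .ellipse(nr, nc, ctr + off / sp, c(radius, radius), sp)
    rFascia <- g$thighRadius - g$satThickness
    rSfat <- rFascia - g$fasciaThickness
    rMuscle <- rSfat - g$sfatThickness
    paint(circ(g$thighRadius), "thigh_sat")
    paint(circ(rFascia), "fascia")
    paint(circ(rSfat), "sfat")
    paint(circ(rMuscle), "thigh_muscle")
    for (a in g$islandAngles) {
      off <- g$islandDist * c(sin(a * pi / 180), cos(a * pi / 180))
      paint(circ(g$islandRadius, off), "imat")
    }
    paint(circ(g$boneRadius), "bone")
    paint(circ(g$boneRadius - g$corticalThickness), "marrow")
  }
  if (isTRUE(g$table)) {
    r0 <- round(g$tableRowFrac * nr)
    rr <- r0:min(nr, r0 + max(1L, round(g$tableThicknessMm / sp[1])) - 1L)
    halfw <- round(g$tableWidthFrac * nc / 2)
    mid <- (nc + 1) / 2
    cc <- max(1L, round(mid - halfw)):min(nc, round(mid + halfw))
    lab[rr, cc] <- L("table")
  }
  lab
}

#' Render a synthetic phantom
#'
#' Deterministic given the spec (including its noise seed): each pixel is
#' its tissue's mean HU plus Gaussian noise with the tissue SD, clamped to
#' the valid HU range.  The global RNG state is preserved.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{LabeledPhantom} with ground-truth labels and a
#'   per-label truth table.
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  lab <- switch(spec@station,
                abdomen = .renderAbdominal(spec, withLiver = FALSE),
                liver = .renderAbdominal(spec, withLiver = TRUE),
                thigh = .renderThigh(spec))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec@noiseSeed)
  px <- matrix(0, nrow(lab), ncol(lab))
  for (code in seq_along(.PHANTOM_LABELS)) {
    n <- sum(lab == code)
    if (n == 0L) next
    hu <- spec@tissueHu[[.PHANTOM_LABELS[code]]]
    px[lab == code] <- stats::rnorm(n, hu[1], hu[2])
  }
  px <- pmin(pmax(px, -1024), 3071)
  slice <- ctSlice(px, spec@spacing, spec@station)
  present <- sort(unique(as.vector(lab)))
  truth <- data.frame(
    label = .PHANTOM_LABELS[present],
    pixels = vapply(present, function(k) sum(lab == k), integer(1)),
    stringsAsFactors = FALSE)
  truth$area_cm2 <- truth$pixels * spec@spacing[1] * spec@spacing[2] / 100
  truth$mean_hu <- vapply(truth$label,
                          function(l) spec@tissueHu[[l]][1], numeric(1))
  new("LabeledPhantom", slice = slice, labels = lab,
      labelNames = .PHANTOM_LABELS, truth = truth)
}

#' Ground-truth depot mask of a phantom
#'
#' Convenience grouping of the raw tissue labels into the depots the
#' pipelines report: for the abdomen \code{"vat"}, \code{"sat"},
#' \code{"back"} and \code{"adipose"} (their union); for the thigh
#' \code{"muscle"}, \code{"sat"}, \code{"sfat"}, \code{"imat"} and
#' \code{"adipose"}; for the liver \code{"liver"}.
#'
#' @param x a \linkS4class{LabeledPhantom}.
#' @param depot depot name.
#' @return logical matrix.
#' @export
truthDepotMask <- function(x, depot) {
  st <- x@slice@station
  labels <- if (st %in% c("abdomen", "liver")) {
    switch(depot,
           vat = "vat", sat = "sat", back = "back_at", liver = "liver",
           adipose = c("vat", "sat", "back_at"),
           stop("unknown depot for station ", st, ": ", depot))
  } else {
    switch(depot,
           muscle = c("thigh_muscle", "fascia"),  # reference muscle is the
           # lean band within the thigh, which includes the fascia
           sat = "thigh_sat", sfat = "sfat",
           imat = "imat", adipose = c("thigh_sat", "sfat", "imat"),
           stop("unknown depot for station thigh: ", depot))
  }
  labelMask(x, labels)
}

.defaultJitter <- function(station) {
  switch(station,
    abdomen = list(bodySemi = 8, satThickness = 6, wallThickness = 2,
                   centerOffset = 8, organScale = 0.15,
                   backMuscleColOffset = 4),
    liver = list(bodySemi = 8, satThickness = 4, wallThickness = 2,
                 centerOffset = 8, liverCenter = 8, liverSemi = 8,
                 organScale = 0.12),
    thigh = list(thighRadius = 4, satThickness = 3, sfatThickness = 1,
                 centerColOffset = 3, boneRadius = 2, islandDist = 5,
                 islandAngleShift = 30))
}

#' Generate an ensemble of jittered phantoms
#'
#' Stands in for a multi-subject study set: \code{n} phantoms whose
#' geometry entries are independently perturbed by uniform draws within
#' the jitter half-widths, each with its own noise seed, all reproducible
#' from \code{seed}.
#'
#' @param baseSpec a \linkS4class{PhantomSpec}.
#' @param n number of phantoms.
#' @param jitter named list of jitter half-widths (mm, or fraction for
#'   \code{organScale}, degrees for \code{islandAngleShift}); NULL for
#'   station defaults, an empty list for no jitter.
#' @param seed integer RNG seed.
#' @return list of \linkS4class{LabeledPhantom} objects.
#' @export
makeEnsemble <- function(baseSpec, n, jitter = NULL, seed = 1L) {
  stopifnot(is(baseSpec, "PhantomSpec"), n >= 1)
  if (is.null(jitter)) jitter <- .defaultJitter(baseSpec@station)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    g <- baseSpec@geometry
    for (nm in names(jitter)) {
      h <- jitter[[nm]]
      if (nm == "organScale") {
        s <- 1 + stats::runif(1, -h, h)
        g$organs <- lapply(g$organs, function(o) {
          o$semi <- o$semi * s; o
        })
        if (!is.null(g$liverSemi) && is.null(jitter$liverSemi))
          g$liverSemi <- g$liverSemi * s
      } else if (nm == "islandAngleShift") {
        g$islandAngles <- g$islandAngles + stats::runif(1, -h, h)
      } else if (nm %in% names(g)) {
        d <- stats::runif(length(g[[nm]]), -h, h)
        g[[nm]] <- g[[nm]] + d
      }
    }
    sp <- new("PhantomSpec", station = baseSpec@station,
              imageSize = baseSpec@imageSize, spacing = baseSpec@spacing,
              geometry = g, tissueHu = baseSpec@tissueHu,
              noiseSeed = sample.int(2147483646L, 1L))
    out[[k]] <- makePhantom(sp)
  }
  out
}

#' Write a phantom to disk
#'
#' Fixture-format image, NIfTI label map and a JSON truth record.
#'
#' @param phantom a \linkS4class{LabeledPhantom}.
#' @param prefix output path prefix; writes \code{<prefix>.cts},
#'   \code{<prefix>_labels.nii.gz} and \code{<prefix>_truth.json}.
#' @return \code{prefix}, invisibly.
#' @export
writePhantom <- function(phantom, prefix) {
  writeSliceFixture(phantom@slice, paste0(prefix, ".cts"))
  writeLabelsNifti(phantom@labels, phantom@slice@spacing,
                   paste0(prefix, "_labels.nii.gz"))
  jsonlite::write_json(phantom@truth, paste0(prefix, "_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(prefix)
}
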