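#' Default run configuration
#'
#' All tunables of the three station pipelines in one (serializable)
#' list: HU bands, per-station and per-pass ILT parameters, the liver
#' configuration, the back-atlas threshold, the thigh SFAT/IMAT method
#' and erosion depth, atlas file paths, output directory and seed.
#'
#' @return named list of class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function() {
  structure(list(
    bands = huBands(),
    ilt = list(abdomen = defaultIltParams("abdomen"),
               liver = defaultIltParams("liver"),
               thigh = defaultIltParams("thigh"),
               thigh_deep = defaultIltParams("thigh_deep")),
    liver = liverConfig(),
    backThreshold = 0.5,
    thighMethod = "ilt",
    depthMm = 7,
    atlasFiles = list(liver = NULL, back = NULL),
    outputDir = ".",
    writeOverlays = FALSE,
    seed = 1L), class = "RunConfig")
}

.iltFromList <- function(x, base) {
  for (nm in intersect(names(x), c("nDir", "l1", "l2", "dirPercent",
                                   "stepMm", "pmThreshold", "interp"))) {
    slot(base, nm) <- if (nm == "nDir") as.integer(x[[nm]]) else x[[nm]]
  }
  validObject(base)
  base
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; every omitted key keeps its default.
#'
#' @param path YAML file.
#' @return a \code{"RunConfig"} list (see \code{\link{defaultRunConfig}}).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  known <- c("bands", "ilt", "liver", "backThreshold", "thighMethod",
             "depthMm", "atlasFiles", "outputDir", "writeOverlays", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("config error: unknown keys: ",
                        paste(bad, collapse = ", "))
  if (!is.null(y$bands))
    cfg$bands <- do.call(huBands, y$bands)
  if (!is.null(y$ilt))
    for (st in names(y$ilt))
      cfg$ilt[[st]] <- .iltFromList(y$ilt[[st]], cfg$ilt[[st]])
  if (!is.null(y$liver)) cfg$liver <- do.call(liverConfig, y$liver)
  for (nm in c("backThreshold", "thighMethod", "depthMm", "outputDir",
               "writeOverlays", "seed"))
    if (!is.null(y[[nm]])) cfg[[nm]] <- y[[nm]]
  if (!is.null(y$atlasFiles)) cfg$atlasFiles[names(y$atlasFiles)] <- y$atlasFiles
  if (!cfg$thighMethod %in% c("ilt", "morphological"))
    stop("config error: thighMethod must be ilt or morphological")
  cfg
}

.runOne <- function(cfg, station, path, atlases) {
  slice <- readSlice(path, station = station)
  sliceId <- sub("\\.[^.]*$", "", basename(path))
  if (station == "liver") {
    if (is.null(atlases$liver))
      stop("config error: liver atlas required for the liver station")
    res <- segmentLiver(slice, atlases$liver, cfg$bands,
                        cfg$ilt$liver, cfg$liver)
    data.frame(slice = sliceId, depot = "liver",
               area_cm2 = areaCm2(res@mask, slice@spacing),
               mean_hu = res@attenuationHu,
               range_lo = res@rangeR[1], range_hi = res@rangeR[2],
               n_pixels = res@nPixels)
  } else if (station == "abdomen") {
    res <- segmentVatSat(slice, cfg$ilt$abdomen, atlases$back, cfg$bands,
                         cfg$backThreshold)
    px <- slice@pixels
    data.frame(slice = sliceId,
               depot = c("vat", "sat", "tat"),
               area_cm2 = unname(res@areas[c("vat", "sat", "tat")]),
               mean_hu = c(mean(px[res@vat]), mean(px[res@sat]),
                           mean(px[res@vat | res@sat])),
               range_lo = NA_real_, range_hi = NA_real_,
               n_pixels = c(sum(res@vat), sum(res@sat),
                            sum(res@vat) + sum(res@sat)))
  } else {
    thighs <- separateThighs(slice, cfg$bands)
    rows <- lapply(c("left", "right"), function(side) {
      res <- segmentThigh(slice, thighs[[side]], side,
                          method = cfg$thighMethod, bands = cfg$bands,
                          ilt = cfg$ilt$thigh, ilt2 = cfg$ilt$thigh_deep,
                          depthMm = cfg$depthMm)
      px <- slice@pixels
      data.frame(slice = sliceId,
                 depot = paste(side, c("muscle", "sat", "sfat", "imat"),
                               sep = "_"),
                 area_cm2 = unname(res@areas[c("muscle", "sat", "sfat",
                                               "imat")]),
                 mean_hu = c(res@muscleAttenuationHu,
                             mean(px[res@sat]), mean(px[res@sfat]),
                             mean(px[res@imat])),
                 range_lo = NA_real_, range_hi = NA_real_,
                 n_pixels = c(sum(res@muscle), sum(res@sat),
                              sum(res@sfat), sum(res@imat)))
    })
    do.call(rbind, rows)
  }
}

#' Run one station pipeline over a list of slices
#'
#' Deterministic given the configuration; per-slice failures are logged
#' and skipped, never silent (they are returned in \code{failures} and
#' reflected in the exit status of the CLI).
#'
#' @param config a \code{"RunConfig"} list.
#' @param station \code{"liver"}, \code{"abdomen"} or \code{"thigh"}.
#' @param inputs character vector of slice paths.
#' @param writeCsv write \code{<station>_results.csv} to the output
#'   directory.
#' @return list with \code{table} (one row per slice and depot),
#'   \code{failures} (named character of error messages) and
#'   \code{timings} (seconds per slice).
#' @export
runStation <- function(config, station, inputs, writeCsv = TRUE) {
  stopifnot(inherits(config, "RunConfig") || is.list(config))
  station <- match.arg(station, c("liver", "abdomen", "thigh"))
  atlases <- list(liver = NULL, back = NULL)
  for (nm in c("liver", "back"))
    if (!is.null(config$atlasFiles[[nm]]))
      atlases[[nm]] <- readAtlas(config$atlasFiles[[nm]])
  if (!is.null(config$atlases)) atlases[names(config$atlases)] <- config$atlases
  rows <- list(); failures <- character(0); timings <- numeric(0)
  for (path in inputs) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(.runOne(config, station, path, atlases),
                    error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[basename(path)] <- conditionMessage(res)
      message("FAILED ", basename(path), ": ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
      timings[basename(path)] <- dt
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = character(0), depot = character(0),
               area_cm2 = numeric(0), mean_hu = numeric(0),
               range_lo = numeric(0), range_hi = numeric(0),
               n_pixels = integer(0))
  if (writeCsv && length(inputs)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeResultsCsv(tab, file.path(config$outputDir,
                                   paste0(station, "_results.csv")))
  }
  list(table = tab, failures = failures, timings = timings)
}
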