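test_that("VAT/SAT/back partition the adipose tissue exactly", {
  ph <- defaultAbdomenPhantom()
  sl <- phantomSlice(ph)
  ## back atlas from same-geometry siblings (only the noise differs), so
  ## the aligned prior should land on this phantom's perispinal ring
  sibs <- makeEnsemble(phantomSpec("abdomen", noiseSeed = 1), 4,
                       jitter = list(), seed = 31)
  atlas <- buildBackAtlas(
    lapply(sibs, labelMask, "back_at"),
    lapply(sibs, function(p) cavitySpan(phantomSlice(p))))
  res <- segmentVatSat(sl, backAtlas = atlas)
  adipose <- thresholdBand(sl, -190, -30) & bodyMask(sl)
  expect_identical(res@vat | res@sat | res@backAt, adipose)
  expect_false(any(res@vat & res@sat))
  expect_false(any(res@vat & res@backAt))
  expect_false(any(res@sat & res@backAt))
  a <- depotAreas(res)
  expect_equal(unname(a["tat"]), unname(a["vat"] + a["sat"]))
  ## both depots recovered well on the default phantom
  expect_gt(overlap(res@vat, truthDepotMask(ph, "vat"))@dice, 0.95)
  expect_gt(overlap(res@sat, truthDepotMask(ph, "sat"))@dice, 0.95)
  ## the aligned prior concentrates on the perispinal ring: much higher
  ## there than over VAT, and the thresholded region catches part of the
  ## thin ring (thresholding a resampled prior at 0.5 erodes ~1 px from
  ## each edge, so full coverage is not expected)
  interior <- res@cavity & !bodycompCT:::leanBandMask(sl, huBands())
  idx <- which(interior, arr.ind = TRUE)
  span <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
  pback <- pixels(alignAtlas(atlas, span, dim(pixels(sl))))
  ring <- labelMask(ph, "back_at")
  expect_gt(mean(pback[ring]), 5 * mean(pback[truthDepotMask(ph, "vat")]))
  expect_gt(mean(res@backAt[ring]), 0.2)
})

test_that("a phantom without visceral fat yields zero VAT", {
  sp <- phantomSpec("abdomen",
                    geometry = list(organs = list(list(center = c(0, 0),
                                                       semi = c(130, 160))),
                                    backAtSemi = c(0.01, 0.01)),
                    noiseSeed = 21)
  ph <- makePhantom(sp)
  expect_equal(sum(labelMask(ph, "vat")), 0)
  res <- segmentVatSat(phantomSlice(ph))
  expect_equal(unname(depotAreas(res)["vat"]), 0)
  trueSat <- sum(truthDepotMask(ph, "sat")) * 0.04
  expect_lt(abs(depotAreas(res)["sat"] - trueSat) / trueSat, 0.02)
})

test_that("a narrow anterior wall gap barely perturbs the assignment", {
  ph0 <- makePhantom(phantomSpec("abdomen", noiseSeed = 11))
  ph1 <- makePhantom(phantomSpec("abdomen",
                                 geometry = list(wallGapMm = 2),
                                 noiseSeed = 11))
  r0 <- segmentVatSat(phantomSlice(ph0))
  r1 <- segmentVatSat(phantomSlice(ph1))
  adipose <- r0@vat | r0@sat
  changed <- sum((r0@vat != r1@vat) | (r0@sat != r1@sat))
  expect_lt(changed / sum(adipose), 0.01)
})

test_that("translation moves all output masks identically", {
  hu0 <- lapply(bodycompCT:::.defaultTissueHu(), function(x) c(x[1], 0))
  ph0 <- makePhantom(phantomSpec("abdomen", tissueHu = hu0, noiseSeed = 1))
  ph1 <- makePhantom(phantomSpec("abdomen", tissueHu = hu0,
                                 geometry = list(centerOffset = c(6, -8)),
                                 noiseSeed = 1))
  r0 <- segmentVatSat(phantomSlice(ph0))
  r1 <- segmentVatSat(phantomSlice(ph1))
  sh <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + 3):nrow(m), 1:(ncol(m) - 4)] <- m[1:(nrow(m) - 3), (1 + 4):ncol(m)]
    out
  }
  expect_identical(r1@vat, sh(r0@vat))
  expect_identical(r1@sat, sh(r0@sat))
})

test_that("growing the SAT ring never shrinks the SAT area", {
  hu0 <- lapply(bodycompCT:::.defaultTissueHu(), function(x) c(x[1], 0))
  areas <- vapply(c(16, 20, 24, 28), function(th) {
    ph <- makePhantom(phantomSpec("abdomen", tissueHu = hu0,
                                  geometry = list(satThickness = th),
                                  noiseSeed = 2))
    unname(depotAreas(segmentVatSat(phantomSlice(ph)))["sat"])
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("SAT splits at a traced fascia into analytic halves", {
  n <- 101; ctr <- 51
  d <- outer((1:n) - ctr, (1:n) - ctr, function(a, b) sqrt(a^2 + b^2))
  sat <- d >= 30 & d <= 44
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  fascia <- cbind(ctr + 37 * cos(th), ctr + 37 * sin(th))
  sp <- splitSatByFascia(sat, fascia, bodyCentroidRow = ctr)
  expect_true(all(sp$valid))
  ## exact ring geometry: each part matches its analytic annulus; the
  ## superficial (outer) part is the larger one at mid-depth
  aD <- sum(sp$dsat); aS <- sum(sp$ssat)
  expect_equal(aD / sum(d >= 30 & d < 37), 1, tolerance = 0.05)
  expect_equal(aS / sum(d > 37 & d <= 44), 1, tolerance = 0.05)
  expect_gt(aS, aD)

  ## fascia only anterior: posterior half flagged invalid
  thA <- seq(-pi / 2, pi / 2, length.out = 91)
  ## anterior = smaller rows: angle measured from -row axis
  fasciaA <- cbind(ctr - 37 * cos(thA), ctr + 37 * sin(thA))
  spA <- splitSatByFascia(sat, fasciaA, bodyCentroidRow = ctr)
  expect_true(spA$valid["anterior"])
  expect_false(spA$valid["posterior"])

  ## fascia on the outer boundary: everything is deep
  fasciaO <- cbind(ctr + 44 * cos(th), ctr + 44 * sin(th))
  spO <- splitSatByFascia(sat, fasciaO, bodyCentroidRow = ctr)
  expect_equal(sum(spO$ssat), 0)
  expect_gt(sum(spO$dsat) / sum(sat), 0.97)

  ## fascia off the annulus is a geometry error
  bad <- cbind(ctr + 5 * cos(th), ctr + 5 * sin(th))
  expect_error(splitSatByFascia(sat, bad, ctr), "geometry error")
})

test_that("VAT splits by a closed contour with even-odd membership", {
  ph <- defaultAbdomenPhantom()
  vat <- truthDepotMask(ph, "vat")
  ## half-integer vertices keep pixel centers off the contour itself
  rect <- cbind(c(60.5, 60.5, 130.5, 130.5), c(60.5, 120.5, 120.5, 60.5))
  sp <- splitVatByContour(vat, rect)
  expect_identical(sp$ipat | sp$rpat, vat)
  expect_false(any(sp$ipat & sp$rpat))
  idx <- which(vat, arr.ind = TRUE)
  oracle <- pipOracle(idx[, 1], idx[, 2], rect[, 1], rect[, 2])
  expect_identical(sp$rpat[idx], oracle)

  all_in <- cbind(c(1, 1, 192, 192), c(1, 192, 192, 1))
  expect_equal(sum(splitVatByContour(vat, all_in)$ipat), 0)
  none <- cbind(c(1, 1, 3, 3), c(1, 3, 3, 1))
  expect_equal(sum(splitVatByContour(vat, none)$rpat), 0)

  bowtie <- cbind(c(10, 40, 10, 40), c(10, 40, 40, 10))
  expect_error(splitVatByContour(vat, bowtie), "self-intersecting")
})
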