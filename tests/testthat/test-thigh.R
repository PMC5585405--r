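test_that("two thighs are separated and the table excluded", {
  ph <- defaultThighPhantom()
  sl <- phantomSlice(ph)
  th <- separateThighs(sl)
  expect_false(any(th$left & th$right))
  expect_false(any((th$left | th$right) & labelMask(ph, "table")))
  ## left/right by centroid column
  expect_lt(mean(which(th$left, arr.ind = TRUE)[, 2]),
            mean(which(th$right, arr.ind = TRUE)[, 2]))

  ## two clean disks are recovered exactly
  px <- matrix(-1000, 80, 80)
  d1 <- outer((1:80) - 40, (1:80) - 22, function(a, b) sqrt(a^2 + b^2))
  d2 <- outer((1:80) - 40, (1:80) - 58, function(a, b) sqrt(a^2 + b^2))
  px[d1 <= 14] <- 45; px[d2 <= 14] <- 45
  th2 <- separateThighs(ctSlice(px, c(2, 2), "thigh"))
  expect_identical(th2$left, d1 <= 14)
  expect_identical(th2$right, d2 <= 14)

  ## a 1-px bridge is broken by one opening
  px[40, 36:44] <- 45
  th3 <- separateThighs(ctSlice(px, c(2, 2), "thigh"))
  expect_gt(sum(th3$left & (d1 <= 14)) / sum(d1 <= 14), 0.95)

  ## a single blob cannot be separated
  px2 <- matrix(-1000, 40, 40); px2[10:30, 10:30] <- 45
  expect_error(separateThighs(ctSlice(px2, c(2, 2), "thigh")),
               "could not separate")
})

test_that("muscle/adipose/bone separation keeps marrow in bone", {
  ph <- defaultThighPhantom()
  sl <- phantomSlice(ph)
  th <- separateThighs(sl)$left
  tis <- segmentMuscleAt(th, sl)
  marrow <- labelMask(ph, "marrow") & th
  expect_true(all(tis$bone[marrow]))
  expect_false(any(tis$adipose & marrow))
  expect_false(any(tis$muscle & tis$adipose))
  ## outside bone the masks follow the HU bands exactly
  outside <- th & !tis$bone
  b <- huBands()
  px <- pixels(sl)
  expect_identical(tis$adipose[outside],
                   (px >= -190 & px <= -30)[outside])
  expect_identical(tis$muscle[outside],
                   (px > b$adipose[2] & px <= b$lean[2])[outside])

  ## no adipose-band pixels -> empty adipose
  solid <- matrix(45, 30, 30)
  slm <- ctSlice(solid, c(2, 2), "thigh")
  thm <- matrix(TRUE, 30, 30)
  expect_equal(sum(segmentMuscleAt(thm, slm)$adipose), 0)
  expect_error(segmentMuscleAt(matrix(FALSE, 30, 30), slm), "empty thigh")
})

test_that("thigh SAT via ILT matches truth; islands stay excluded", {
  ph <- defaultThighPhantom()
  sl <- phantomSlice(ph)
  for (side in c("left", "right")) {
    th <- separateThighs(sl)[[side]]
    tis <- segmentMuscleAt(th, sl)
    sat <- thighSat(tis$adipose, sl, th)
    expect_gt(overlap(sat, labelMask(ph, "thigh_sat") & th)@dice, 0.99)
    expect_false(any(sat & labelMask(ph, "imat")))
  }
  ## adipose-only thigh: everything is SAT, with a warning
  px <- matrix(-1000, 40, 40)
  d <- outer((1:40) - 20, (1:40) - 20, function(a, b) sqrt(a^2 + b^2))
  px[d <= 12] <- -95
  slf <- ctSlice(px, c(2, 2), "thigh")
  adf <- d <= 12
  expect_warning(satf <- thighSat(adf, slf, adf), "all adipose")
  expect_identical(satf, adf)
})

test_that("both SFAT/IMAT methods recover the phantom depots", {
  ph <- defaultThighPhantom()
  sl <- phantomSlice(ph)
  th <- separateThighs(sl)$left
  tis <- segmentMuscleAt(th, sl)
  sat <- thighSat(tis$adipose, sl, th)
  inner <- tis$adipose & !sat
  tS <- labelMask(ph, "sfat") & th
  tI <- labelMask(ph, "imat") & th
  m1 <- sfatImatIlt(inner, sl, th)
  m2 <- sfatImatMorph(inner, tis$muscle, spacing = spacing(sl))
  for (m in list(m1, m2)) {
    expect_identical(m$sfat | m$imat, inner)   # conservation
    expect_false(any(m$sfat & m$imat))
    expect_gt(overlap(m$sfat, tS)@dice, 0.8)
    expect_gt(overlap(m$imat, tI)@dice, 0.9)
  }
  expect_gt(overlap(m1$imat, m2$imat)@dice, 0.9)

  ## empty inner adipose propagates
  none <- inner & FALSE
  expect_equal(sum(sfatImatIlt(none, sl, th)$imat), 0)
  expect_equal(sum(sfatImatMorph(none, tis$muscle, spacing = c(2, 2))$sfat), 0)
})

test_that("morphological split matches analytic disk geometry", {
  nr <- 140; sp <- c(1, 1); ctr <- c(70.5, 70.5)
  d <- outer(((1:nr) - ctr[1]), ((1:nr) - ctr[2]),
             function(a, b) sqrt(a^2 + b^2))
  disk <- d <= 50
  m <- sfatImatMorph(disk, matrix(FALSE, nr, nr), 5, sp)
  expect_lt(abs(areaCm2(m$sfat, sp) - pi * (50^2 - 45^2) / 100) /
              (pi * (50^2 - 45^2) / 100), 0.02)
  expect_lt(abs(areaCm2(m$imat, sp) - pi * 45^2 / 100) / (pi * 45^2 / 100),
            0.02)

  ## vanishing depth: the subfascial rim vanishes with it
  m0 <- sfatImatMorph(disk, matrix(FALSE, nr, nr), 0.25, sp)
  expect_lt(sum(m0$sfat) / sum(disk), 0.05)

  ## depth beyond the radius: everything is rim, nothing deep
  expect_warning(mAll <- sfatImatMorph(disk, matrix(FALSE, nr, nr), 60, sp),
                 "annihilates")
  expect_equal(sum(mAll$imat), 0)
  expect_identical(mAll$sfat, disk)
  expect_error(sfatImatMorph(disk, disk, 0, sp), "positive")
})

test_that("muscle attenuation estimators", {
  sl <- ctSlice(matrix(45, 20, 20), c(1, 1), "thigh")
  expect_equal(muscleAttenuation(sl, matrix(TRUE, 20, 20)), 45)
  set.seed(8)
  px <- matrix(stats::rnorm(1e4, 45, 4), 100, 100)
  sl2 <- ctSlice(px, c(1, 1), "thigh")
  expect_lt(abs(muscleAttenuation(sl2, matrix(TRUE, 100, 100)) - 45), 0.1)
  one <- matrix(FALSE, 20, 20); one[3, 4] <- TRUE
  sl3 <- ctSlice(matrix(60, 20, 20), c(1, 1), "thigh")
  expect_equal(muscleAttenuation(sl3, one), 60)
  expect_error(muscleAttenuation(sl3, one & FALSE), "empty muscle")
})

test_that("mirroring the image mirrors every output exactly", {
  ph <- defaultThighPhantom()
  sl <- phantomSlice(ph)
  mir <- ctSlice(pixels(sl)[, ncol(pixels(sl)):1], spacing(sl), "thigh")
  flip <- function(m) m[, ncol(m):1]
  for (method in c("ilt", "morphological")) {
    a <- segmentThigh(sl, separateThighs(sl)$left, "left", method)
    b <- segmentThigh(mir, separateThighs(mir)$right, "right", method)
    expect_identical(flip(b@muscle), a@muscle)
    expect_identical(flip(b@sat), a@sat)
    expect_identical(flip(b@sfat), a@sfat)
    expect_identical(flip(b@imat), a@imat)
    expect_equal(b@muscleAttenuationHu, a@muscleAttenuationHu)
  }
})

test_that("calibration prefers parameters that track truth areas", {
  train <- cached("thigh_train4",
                  makeEnsemble(phantomSpec("thigh", noiseSeed = 1), 4,
                               seed = 501))
  cal <- calibrateThighParams(train, pmGrid = c(0.14, 0.18),
                              depthGrid = c(4, 7))
  expect_equal(cal$depthMm, 7)
  expect_true(cal$ilt2@pmThreshold %in% c(0.14, 0.18))
  expect_true(all(c("method", "param", "r", "dice") %in% colnames(cal$scores)))
})
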