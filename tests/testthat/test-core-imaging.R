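test_that("HU band thresholding uses closed intervals and partitions", {
  s <- ctSlice(matrix(-1000, 4, 4), c(1, 1), "abdomen")
  expect_false(any(thresholdBand(s, -190, -30)))

  s2 <- ctSlice(matrix(c(-190, -30, -29.5, 151), 2, 2), c(1, 1), "abdomen")
  m <- thresholdBand(s2, -190, -30)
  expect_true(m[1, 1])   # lower endpoint included
  expect_true(m[2, 1])   # upper endpoint included
  expect_false(m[1, 2])

  expect_error(thresholdBand(s, -30, -190), "lo <= hi")

  set.seed(1)
  px <- matrix(runif(400, -1024, 3071), 20, 20)
  sr <- ctSlice(px, c(1, 1), "liver")
  expect_identical(thresholdBand(sr, -190, -30), px >= -190 & px <= -30)

  ## abutting adipose/lean bands never double-count a pixel
  b <- huBands()
  adip <- thresholdBand(sr, b$adipose[1], b$adipose[2])
  lean <- px > b$adipose[2] & px <= b$lean[2]
  expect_false(any(adip & lean))
  expect_identical(adip | lean, px >= b$adipose[1] & px <= b$lean[2])
})

test_that("band constructor rejects inconsistent bands", {
  expect_error(huBands(adipose = c(-30, -190)))
  expect_error(huBands(adipose = c(-190, -20), lean = c(-29, 151)))
  expect_error(huBands(bodyMin = -100))
})

test_that("body mask removes the table and fills internal gas pockets", {
  ph <- defaultAbdomenPhantom()
  sl <- phantomSlice(ph)
  b <- bodyMask(sl)
  expect_false(any(b & labelMask(ph, "table")))
  expect_true(all(b[labelMask(ph, "vat")]))

  ## gas pocket: fat ellipse with an air hole inside
  px <- matrix(-1000, 60, 60)
  d <- outer((1:60) - 30, (1:60) - 30, function(a, b) sqrt(a^2 + b^2))
  px[d <= 20] <- -95
  px[d <= 4] <- -1000
  bm <- bodyMask(ctSlice(px, c(1, 1), "abdomen"))
  expect_true(all(bm[d <= 4]))

  expect_error(bodyMask(ctSlice(matrix(-1000, 8, 8), c(1, 1), "abdomen")),
               "segmentation error")
})

test_that("mask area is exact and additive", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(areaCm2(m, c(1, 1)), 1.0)
  expect_equal(areaCm2(matrix(FALSE, 5, 5), c(1, 1)), 0.0)
  m2 <- matrix(FALSE, 20, 20); m2[seq_len(123)] <- TRUE
  expect_equal(areaCm2(m2, c(0.8, 0.8)), 0.7872)
  ## additivity over disjoint masks
  a <- matrix(FALSE, 10, 10); a[1:3, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, ] <- TRUE
  expect_equal(areaCm2(a | b, c(1.3, 0.7)),
               areaCm2(a, c(1.3, 0.7)) + areaCm2(b, c(1.3, 0.7)))
  expect_error(areaCm2(a, c(0, 1)), "positive")
})

test_that("connected components and hole filling honour connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # touch diagonally
  expect_equal(max(labelComponents(m, 8L)), 1L)
  expect_equal(max(labelComponents(m, 4L)), 2L)

  ring <- matrix(FALSE, 7, 7); ring[2:6, 2:6] <- TRUE; ring[3:5, 3:5] <- FALSE
  expect_true(all(fillHoles(ring, 4L)[3:5, 3:5]))
})

test_that("distance transform matches the brute-force oracle (anisotropic)", {
  set.seed(7)
  m <- matrix(runif(12 * 9) > 0.4, 12, 9)
  sp <- c(1.7, 0.6)
  expect_equal(distanceTransform(m, sp), edtOracle(m, sp), tolerance = 1e-12)
})

test_that("fixture format round-trips bit-exactly", {
  ph <- defaultThighPhantom()
  f <- tempfile(fileext = ".cts")
  writeSliceFixture(phantomSlice(ph), f)
  sl <- readSlice(f)
  expect_identical(pixels(sl), pixels(phantomSlice(ph)))
  expect_identical(spacing(sl), spacing(phantomSlice(ph)))
  expect_identical(station(sl), "thigh")
})

test_that("reading a 4x4 uniform fixture returns the stored values", {
  s <- ctSlice(matrix(-1000, 4, 4), c(1, 1), "abdomen")
  f <- tempfile(fileext = ".cts")
  writeSliceFixture(s, f)
  expect_identical(pixels(readSlice(f)), matrix(-1000, 4, 4))
  expect_error(readSlice(tempfile(fileext = ".cts")), "not found")
})

test_that("DICOM rescale and pixel spacing are applied", {
  stored <- 1024L + 0:11  # row-major 3x4
  f <- tempfile(fileext = ".dcm")
  writeBin(dicomBytes(3L, 4L, stored, spacing = c(1.5, 0.8)), f)
  sl <- readSlice(f, "liver")
  expect_equal(dim(pixels(sl)), c(3L, 4L))
  expect_equal(spacing(sl), c(1.5, 0.8))
  expect_equal(pixels(sl)[1, 1], 0)       # 1024 - 1024
  expect_equal(pixels(sl)[2, 3], 6)       # row-major order preserved
  writeBin(dicomBytes(3L, 4L, stored)[-(1:64)], f)
  expect_error(readSlice(f, "liver"), "format error")
})

test_that("NIfTI slices carry their header spacing", {
  px <- matrix(seq(-100, 100, length.out = 600), 30, 20)
  arr <- array(px, c(30, 20, 1))
  attr(arr, "pixdim") <- c(1.2, 0.9, 5)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  sl <- readSlice(f, "abdomen")
  expect_equal(pixels(sl), px, tolerance = 1e-4)
  expect_equal(spacing(sl), c(1.2, 0.9), tolerance = 1e-6)  # float32 header
})

test_that("label maps, overlays and CSV exports are written", {
  ph <- defaultAbdomenPhantom()
  f <- tempfile(fileext = ".nii.gz")
  writeLabelsNifti(ph@labels, c(2, 2), f)
  back <- as.array(RNifti::readNifti(f))
  if (length(dim(back)) == 3L) back <- back[, , 1]
  expect_equal(matrix(as.numeric(back), 192, 192), ph@labels + 0)

  fp <- tempfile(fileext = ".png")
  writeOverlayPng(phantomSlice(ph), list(vat = labelMask(ph, "vat")), fp)
  expect_gt(file.size(fp), 0)

  fc <- tempfile(fileext = ".csv")
  writeResultsCsv(data.frame(slice = "a", depot = "vat",
                             area_cm2 = 1, mean_hu = -90), fc)
  expect_equal(utils::read.csv(fc)$area_cm2, 1)
})

test_that("CTSlice validity enforces finite HU and positive spacing", {
  expect_error(ctSlice(matrix(c(1, NA, 2, 3), 2), c(1, 1), "liver"), "finite")
  expect_error(ctSlice(matrix(0, 2, 2), c(0, 1), "liver"), "positive")
  expect_error(ctSlice(matrix(0, 2, 2), c(1, 1), "brain"), "station")
  expect_error(ctSlice(matrix(5000, 2, 2), c(1, 1), "liver"), "3071")
})
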