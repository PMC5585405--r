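test_that("lean-probability ramp hits its endpoints and midpoint", {
  expect_equal(huToLeanProb(-30, -30, 20), 0)
  expect_equal(huToLeanProb(20, -30, 20), 1)
  expect_equal(huToLeanProb(-5, -30, 20), 0.5)
  expect_equal(huToLeanProb(c(-500, 500), -30, 20), c(0, 1))
  expect_error(huToLeanProb(0, 20, -30), "l1 must be < l2")
})

test_that("ray accumulation matches explicit ray marching", {
  z <- probabilityMap(matrix(0, 10, 10))
  expect_equal(accumulateDirection(z, c(4, 5), c(1, 1), 0.7, c(1, 1)), 0)

  ones <- probabilityMap(matrix(1, 10, 10))
  ## axis-aligned ray from column 3 (0-based): samples at 4..9
  expect_equal(accumulateDirection(ones, c(2, 3), c(0, 1), 1, c(1, 1)), 6)

  set.seed(11)
  pm <- matrix(runif(15 * 12), 15, 12)
  sp <- c(1.3, 0.8)
  dirs <- list(c(0.3, -0.8), c(-1, 0.2), c(0.5, 0.5))
  for (d in dirs) {
    got <- accumulateDirection(pm, c(6, 4), d, 0.6, sp)
    u <- d / sqrt(sum(d^2))
    acc <- 0; k <- 1
    repeat {
      r <- 6 + k * 0.6 * u[1] / sp[1]; c <- 4 + k * 0.6 * u[2] / sp[2]
      if (r < 0 || r > 14 || c < 0 || c > 11) break
      i0 <- min(floor(r), 13); j0 <- min(floor(c), 10)
      fr <- r - i0; fc <- c - j0
      acc <- acc + (1 - fr) * (1 - fc) * pm[i0 + 1, j0 + 1] +
        fr * (1 - fc) * pm[i0 + 2, j0 + 1] +
        (1 - fr) * fc * pm[i0 + 1, j0 + 2] + fr * fc * pm[i0 + 2, j0 + 2]
      k <- k + 1
    }
    expect_equal(got, acc, tolerance = 1e-9)
  }
  expect_error(accumulateDirection(pm, c(6, 4), c(0, 0), 1, sp), "non-zero")
  expect_error(accumulateDirection(pm, c(-1, 4), c(1, 0), 1, sp), "inside")
})

test_that("production ILT response equals the reference implementation", {
  for (seed in c(3, 17, 99)) {
    set.seed(seed)
    px <- matrix(runif(32 * 32, -1024, 500), 32, 32)
    sl <- ctSlice(px, c(1.5, 1.2), "abdomen")
    p <- iltParams(nDir = 16, dirPercent = 0.5)
    expect_lt(max(abs(pixels(iltResponse(sl, p)) -
                      pixels(iltResponseRef(sl, p)))), 1e-9)
  }
  ## nearest-neighbour sampling agrees too
  set.seed(4)
  px <- matrix(runif(24 * 24, -1024, 500), 24, 24)
  sl <- ctSlice(px, c(1, 1), "abdomen")
  p <- iltParams(nDir = 12, dirPercent = 0.75, interp = "nearest")
  expect_lt(max(abs(pixels(iltResponse(sl, p)) -
                    pixels(iltResponseRef(sl, p)))), 1e-9)
})

test_that("response is maximal at the center of a lean disk, zero on air", {
  n <- 41
  d <- outer((1:n) - 21, (1:n) - 21, function(a, b) sqrt(a^2 + b^2))
  px <- matrix(-1000, n, n); px[d <= 15] <- 45
  sl <- ctSlice(px, c(1, 1), "abdomen")
  r <- pixels(iltResponse(sl, iltParams(nDir = 16)))
  expect_equal(r[21, 21], 1)                   # center attains the max
  expect_lt(r[2, 2], min(r[d <= 10]))          # air corner below disk interior
  expect_true(all(r >= 0 & r <= 1))

  allAir <- ctSlice(matrix(-1000, 20, 20), c(1, 1), "abdomen")
  expect_true(all(pixels(iltResponse(allAir)) == 0))

  expect_error(iltResponse(ctSlice(matrix(0, 1, 1), c(1, 1), "abdomen")),
               "degenerate")
})

test_that("raising a pixel's attenuation never lowers any raw response", {
  set.seed(23)
  px <- matrix(runif(12 * 12, -200, 100), 12, 12)
  sl <- ctSlice(px, c(1, 1), "abdomen")
  p <- iltParams(nDir = 8, dirPercent = 0.5)
  r1 <- iltResponse(sl, p, normalize = FALSE)
  px2 <- px; px2[6, 7] <- px2[6, 7] + 150
  r2 <- iltResponse(ctSlice(px2, c(1, 1), "abdomen"), p, normalize = FALSE)
  expect_true(all(r2 - r1 >= -1e-12))
})

test_that("a closed lean ring separates inside from outside", {
  sl <- leanAnnulusSlice()
  p <- iltParams(nDir = 32, dirPercent = 1)
  r <- pixels(iltResponse(sl, p))
  n <- nrow(r); ctr <- (n + 1) / 2
  d <- outer(((1:n) - ctr) * 2, ((1:n) - ctr) * 2,
             function(a, b) sqrt(a^2 + b^2))
  ## equal distance from the ring (at radius 48-60mm): inside 36mm vs outside 72mm
  expect_gt(min(r[abs(d - 36) < 2]), max(r[abs(d - 72) < 2]))

  ## thresholded inside mask covers the cavity and stays off the exterior
  p2 <- iltParams(nDir = 32, dirPercent = 0.5)
  m <- insideMask(iltResponse(sl, p2), 0.05, largestOnly = TRUE)
  expect_true(all(m[d <= 40]))
  expect_false(any(m[d >= 70]))
})

test_that("inside-mask thresholds behave at the extremes", {
  set.seed(5)
  px <- matrix(runif(100, -200, 100), 10, 10)
  r <- iltResponse(ctSlice(px, c(1, 1), "abdomen"), iltParams(nDir = 8))
  expect_true(all(insideMask(r, 0)))
  am <- insideMask(r, 1)
  expect_identical(am, pixels(r) >= 1)
  expect_true(any(am))  # the argmax survives
  expect_error(insideMask(r, 1.5), "pmThreshold")
})

test_that("ILT parameter validity is enforced", {
  expect_error(iltParams(nDir = 3), "nDir")
  expect_error(iltParams(l1 = 20, l2 = -30), "l1")
  expect_error(iltParams(dirPercent = 0), "dirPercent")
  expect_error(iltParams(pmThreshold = 2), "pmThreshold")
  expect_error(iltParams(interp = "cubic"), "interp")
})
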