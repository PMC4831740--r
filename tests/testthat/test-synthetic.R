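test_that("saturating phantom at t = 0 is exactly I0 inside the disc", {
  spec <- smallSaturating(radius0 = 0.4)
  sl <- generatePhantomSlice(spec, 0)$slice
  px <- pixels(sl)
  expect_setequal(unique(as.vector(px)), c(spec@backgroundLevel, spec@I0))
  # the disc is there: a plausible number of I0 pixels
  nIn <- sum(px == spec@I0)
  expect_gt(nIn, 0.95 * pi * (spec@radius0 / spec@pixelSize)^2)
})

test_that("front-mode truth and pixels match the closed form", {
  # d(t) = C(1 - e^{-Kt}); C = 3, K = 0.5, t = 1 -> 1.180 mm
  spec3 <- PhantomSpec("front", radius0 = 3, C = 3, K = 0.5, noiseSigma = 0)
  expect_equal(trueFrontDepth(spec3, 1), 3 * (1 - exp(-0.5)))
  expect_equal(round(trueFrontDepth(spec3, 1), 3), 1.180)

  # pixel-wise check against an independent per-pixel loop (small phantom)
  spec <- smallFront(radius0 = 0.25, C = 0.2)
  t <- 1.3
  sl <- generatePhantomSlice(spec, t, marginPx = 10L)$slice
  px <- pixels(sl)
  n <- nrow(px)
  centre <- (n + 1) / 2
  d <- trueFrontDepth(spec, t)
  w <- spec@frontWidth
  R <- shrunkRadius(spec, t)
  expected <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- sqrt((i - centre)^2 + (j - centre)^2) * spec@pixelSize
    x <- R - r
    expected[i, j] <- if (x < 0) spec@backgroundLevel
    else if (x <= d - w / 2) spec@IOut
    else if (x >= d + w / 2) spec@IIn
    else spec@IOut + (spec@IIn - spec@IOut) * (x - (d - w / 2)) / w
  }
  expect_equal(px, expected, tolerance = 1e-12)

  # centre profile: IOut outside the front depth, IIn inside (+- w/2)
  p <- phantomProfile(spec3, 1, widthPx = 1L)
  pos <- positions(p)
  depth <- shrunkRadius(spec3, 1) - abs(pos - mean(range(pos)))
  v <- intensities(p)  # normalised by the profile maximum, i.e. by IOut
  outer <- depth > 0.05 & depth < 1.180 - 0.15
  inner <- depth > 1.180 + 0.15
  expect_true(all(abs(v[outer] - spec3@IOut / spec3@IOut) < 1e-6))
  expect_true(all(abs(v[inner] - spec3@IIn / spec3@IOut) < 1e-6))
})

test_that("depth-to-saturation time scales as exp(cK x) in the saturating phantom", {
  # this is what makes the staining-time model recoverable end to end
  spec <- smallSaturating()
  f <- 0.9
  tAt <- function(x) {
    uniroot(function(t) phantomIntensity(spec, x, t) - f * spec@Imax,
            c(1e-9, 400), tol = 1e-12)$root
  }
  t0 <- tAt(0)
  for (x in c(0.3, 0.7, 1.2))
    expect_equal(tAt(x), t0 * exp(spec@cK * x), tolerance = 1e-8)
})

test_that("phantoms are reproducible from the seed and monotone in time", {
  spec <- smallSaturating(radius0 = 0.3, noiseSigma = 0.02)
  a <- generatePhantomSlice(spec, 2)$slice
  b <- generatePhantomSlice(spec, 2)$slice
  expect_identical(pixels(a), pixels(b))
  spec2 <- smallSaturating(radius0 = 0.3, noiseSigma = 0.02, seed = 999L)
  expect_false(identical(pixels(a),
                         pixels(generatePhantomSlice(spec2, 2)$slice)))

  # intensity non-decreasing in t at fixed depth (noise-free)
  clean <- smallSaturating()
  for (x in c(0, 0.4, 0.9)) {
    iv <- phantomIntensity(clean, x, 0)
    for (t in c(0.5, 1, 2, 4)) {
      nxt <- phantomIntensity(clean, x, t)
      expect_gte(nxt, iv)
      iv <- nxt
    }
  }
  # front depth strictly increasing, bounded by C
  fr <- smallFront()
  d <- trueFrontDepth(fr, c(0, 0.5, 1, 2, 4, 10))
  expect_true(all(diff(d) > 0))
  expect_true(all(d < fr@C))
})

test_that("shrunk radius follows the exponential-plateau law", {
  spec <- smallSaturating(shrinkFraction = 0.0513, shrinkRate = 2)
  expect_equal(shrunkRadius(spec, 0), spec@radius0)
  expect_equal(shrunkRadius(spec, 1e6), spec@radius0 * (1 - 0.0513))
  # ~10% steady-state area loss
  expect_equal((shrunkRadius(spec, 1e6) / shrunkRadius(spec, 0))^2,
               0.90, tolerance = 1e-3)
})

test_that("degenerate phantom requests error out", {
  spec <- smallSaturating()
  expect_error(generatePhantomSlice(spec, -1), "non-negative")
  tiny <- smallSaturating(radius0 = 0.02, shrinkFraction = 0.5,
                          shrinkRate = 5)
  expect_error(generatePhantomSlice(tiny, 10), "degenerate")
})

test_that("noise-free phantom segments to the true disc area", {
  # midpoint threshold between background and I0; R = 67 px >= 50
  spec <- smallSaturating(radius0 = 0.5)
  sl <- generatePhantomSlice(spec, 0)$slice
  mask <- segmentCrossSection(sl, "fixed",
                              (spec@backgroundLevel + spec@I0) / 2)
  area <- crossSectionalArea(mask, pixelSize(sl))
  expect_equal(area, pi * spec@radius0^2, tolerance = 0.02)
})

test_that("generateCohort writes deterministic slices plus a faithful manifest", {
  spec <- smallSaturating(radius0 = 0.2, noiseSigma = 0.02,
                          shrinkFraction = 0.1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generateCohort(spec, d1)
  expect_length(m1$files, length(spec@timepoints))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  generateCohort(spec, d2)
  for (f in m1$files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # manifest truth equals closed-form recomputation; spec round-trips
  m <- readCohortManifest(d1)
  s <- m$samples[[spec@sampleId]]
  spec2 <- phantomSpecFromList(s$params)
  expect_equal(StainKinetics:::.specToList(spec2),
               StainKinetics:::.specToList(spec))
  for (tp in s$timepoints) {
    expect_equal(tp$true_radius_mm, shrunkRadius(spec, tp$t))
    if (spec@mode == "front")
      expect_equal(tp$true_front_depth_mm, trueFrontDepth(spec, tp$t))
  }
})

test_that("PGM slices round-trip within quantisation error", {
  spec <- smallFront(radius0 = 0.2, noiseSigma = 0.015)
  sl <- generatePhantomSlice(spec, 1, marginPx = 10L)$slice
  path <- withr::local_tempfile(fileext = ".pgm")
  writePGM(sl, path)
  back <- readPGM(path)
  expect_equal(pixels(back), pixels(sl), tolerance = 1 / 65535)
  expect_identical(sampleId(back), sampleId(sl))
  expect_identical(stain(back), stain(sl))
  expect_identical(stainDay(back), stainDay(sl))
  expect_equal(pixelSize(back), pixelSize(sl))
})
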