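test_that("extractLineProfile averages a centred pixel band", {
  img <- SliceImage(matrix(5, 40, 30), pixelSize = 0.01)
  p <- extractLineProfile(img)
  expect_equal(intensities(p), rep(5, 30))
  expect_equal(positions(p), (0:29) * 0.01)

  # rows alternating 0/1, width 10 -> constant 0.5
  alt <- SliceImage(matrix(rep(c(0, 1), length.out = 40 * 30), 40, 30),
                    pixelSize = 0.01)
  expect_equal(intensities(extractLineProfile(alt, widthPx = 10L)),
               rep(0.5, 30))

  expect_error(extractLineProfile(img, row = 2L, widthPx = 10L), "bounds")
})

test_that("noise-free phantom profile matches the closed-form intensity", {
  spec <- smallSaturating(radius0 = 0.6)
  t <- 2
  sl <- generatePhantomSlice(spec, t)$slice
  p <- extractLineProfile(sl, widthPx = 1L)
  pos <- positions(p)
  depth <- spec@radius0 - abs(pos - mean(range(pos)))
  interior <- depth > 2 * spec@pixelSize
  truth <- phantomIntensity(spec, depth[interior], t)
  # within one pixel of interpolation error: bound by max slope * pixel
  maxSlope <- max(abs(diff(intensities(p)))) / spec@pixelSize
  expect_lt(max(abs(intensities(p)[interior] - truth)),
            maxSlope * spec@pixelSize + 1e-9)
})

test_that("normaliseCohort divides by the single global maximum", {
  p1 <- LineProfile((0:9) * 0.01, seq(10, 100, by = 10))
  p2 <- LineProfile((0:9) * 0.01, seq(20, 200, by = 20))
  norm <- normaliseCohort(list(p1, p2))
  expect_equal(max(unlist(lapply(norm, intensities))), 1.0)
  expect_equal(max(intensities(norm[[1L]])), 0.5)  # global, not per-profile
  expect_true(all(vapply(norm, isNormalised, TRUE)))

  # single profile: divided by its own max
  one <- normaliseCohort(LineProfile((0:4) * 0.01, c(50, 100, 200, 80, 10)))
  expect_equal(max(intensities(one[[1L]])), 1.0)

  expect_error(normaliseCohort(list()), "empty")
  expect_error(normaliseCohort(LineProfile((0:2) * 0.01, c(0, 0, 0))),
               "maximum")
})

test_that("normaliseCohort is idempotent and scale-invariant", {
  set.seed(42)
  raw <- lapply(1:4, function(i)
    LineProfile((0:49) * 0.0075, runif(50, 0, 300)))
  n1 <- normaliseCohort(raw)
  n2 <- normaliseCohort(n1)
  expect_equal(lapply(n1, intensities), lapply(n2, intensities))
  scaled <- lapply(raw, function(p)
    LineProfile(positions(p), 7.3 * intensities(p)))
  n3 <- normaliseCohort(scaled)
  expect_equal(lapply(n1, intensities), lapply(n3, intensities))
})

test_that("smoothing matches a direct-convolution oracle", {
  p <- randomProfile(120L, seed = 7L)
  for (sigma in c(2, 4)) {
    sm <- smoothProfile(p, sigma)
    expect_equal(intensities(sm), oracleSmooth(intensities(p), sigma),
                 tolerance = 1e-10)
  }
  # constant unchanged; interior impulse conserves mass
  const <- LineProfile((0:99) * 0.0075, rep(2.5, 100))
  expect_equal(intensities(smoothProfile(const)), rep(2.5, 100))
  imp <- LineProfile((0:99) * 0.0075, c(rep(0, 50), 1, rep(0, 49)))
  expect_equal(sum(intensities(smoothProfile(imp))), 1)
  expect_error(smoothProfile(randomProfile(10L), 4), "shorter")
})

test_that("gradient matches a finite-difference oracle", {
  ramp <- LineProfile((0:49) * 0.0075, 2 * (0:49) * 0.0075)
  expect_equal(gradientPerMm(ramp), rep(2, 50))
  const <- LineProfile((0:49) * 0.0075, rep(1, 50))
  expect_equal(gradientPerMm(const), rep(0, 50))
  p <- randomProfile(60L, seed = 3L)
  expect_identical(gradientPerMm(p),
                   oracleGradient(intensities(p), 0.0075))
})

test_that("neighbourhood averaging matches a windowed-mean oracle", {
  p <- randomProfile(90L, seed = 9L)
  for (w in c(0.03, 0.1)) {
    na <- neighbourhoodAverage(p, w)
    expect_equal(intensities(na),
                 oracleNeighbourhood(positions(p), intensities(p), w),
                 tolerance = 1e-12)
  }
  const <- LineProfile((0:49) * 0.0075, rep(3, 50))
  expect_equal(intensities(neighbourhoodAverage(const)), rep(3, 50))
  # window narrower than the spacing: identity
  expect_identical(intensities(neighbourhoodAverage(p, 0.001)),
                   intensities(p))
})

test_that("edge detection finds the phantom boundary", {
  expect_error(detectSampleEdges(LineProfile((0:99) * 0.0075, rep(0.3, 100))),
               "no edge")

  for (R in c(0.4, 0.8)) for (w in c(0.1, 0.2)) {
    spec <- smallFront(radius0 = R, C = R * 0.8, frontWidth = w)
    p <- phantomProfile(spec, 1)
    e <- detectSampleEdges(p)
    centre <- mean(range(positions(p)))
    # symmetric phantom: edges symmetric about the centre within 2 px
    expect_lt(abs((centre - leftEdge(e)) - (rightEdge(e) - centre)),
              2 * spec@pixelSize + 1e-12)
    # each edge within 4 sigma pixels of the true boundary
    tol <- 4 * 4 * spec@pixelSize
    expect_lt(abs(leftEdge(e) - (centre - R)), tol)
    expect_lt(abs(rightEdge(e) - (centre + R)), tol)
  }
})

test_that("detected sample width shrinks with the phantom radius", {
  widths <- vapply(c(0.9, 0.7, 0.5, 0.35), function(R) {
    spec <- smallSaturating(radius0 = R)
    sampleWidth(detectSampleEdges(phantomProfile(spec, 1)))
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("stain-front detection recovers the front depth", {
  # C = 3, K = 0.5, t = 1: d = 1.180 mm; detected depth within w of d + w/2
  spec <- PhantomSpec("front", radius0 = 3, C = 3, K = 0.5,
                      frontWidth = 0.3, noiseSigma = 0)
  p <- phantomProfile(spec, 1)
  e <- detectSampleEdges(p)
  d <- 3 * (1 - exp(-0.5))
  for (side in c("left", "right")) {
    f <- detectStainFront(p, e, side)
    expect_true(frontFound(f))
    expect_lt(abs(frontDepth(f) - (d + 0.15)), 0.3)
  }

  # saturating phantom: gentle gradient, no front
  ps <- phantomProfile(smallSaturating(), 2)
  es <- detectSampleEdges(ps)
  expect_false(frontFound(detectStainFront(ps, es, "left")))
  expect_false(frontFound(detectStainFront(ps, es, "right")))

  # front beyond the centre (fully stained): flagged not-found
  full <- smallFront(C = 5, K = 2)
  pf <- phantomProfile(full, 4)
  ef <- detectSampleEdges(pf)
  expect_false(frontFound(detectStainFront(pf, ef, "left")))
})

test_that("front depth is non-decreasing in staining time", {
  spec <- smallFront()
  depths <- vapply(1:4, function(t) {
    p <- phantomProfile(spec, t)
    frontDepth(detectStainFront(p, detectSampleEdges(p), "left"))
  }, 0)
  expect_true(all(diff(depths) >= 0))
})

test_that("depth series matches the phantom closed form", {
  spec <- smallSaturating(radius0 = 0.9)
  days <- 0:4
  profs <- lapply(days, function(t) phantomProfile(spec, t))
  # one cohort-wide normalisation across days
  raw <- lapply(days, function(t)
    extractLineProfile(generatePhantomSlice(spec, t)$slice))
  profs <- normaliseCohort(raw)
  edges <- lapply(profs, detectSampleEdges)
  ds <- toDepthSeries(profs, edges)

  # symmetry: left and right series agree
  expect_equal(ds$intensity_left, ds$intensity_right, tolerance = 0.02)

  # the normalising maximum is the day-4 edge peak ~ I(0, 4)
  gmax <- max(vapply(raw, function(p) max(intensities(p)), 0))
  ok <- is.finite(ds$intensity) & ds$depth_mm > 0.05
  truth <- vapply(which(ok), function(i)
    phantomIntensity(spec, ds$depth_mm[i], ds$day[i]), 0) / gmax
  expect_equal(ds$intensity[ok], truth, tolerance = 0.03)

  # depths beyond the half-width are missing
  expect_true(all(is.na(ds$intensity[ds$depth_mm >
    vapply(ds$day + 1L, function(i) sampleWidth(edges[[i]]) / 2, 0)])))

  expect_error(toDepthSeries(list(profs[[1L]],
    LineProfile((0:9) * 0.0075, runif(10), sampleId = "zzz")),
    edges[1:2]), "different samples")
})
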