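test_that("fitSaturation recovers exact parameters from noiseless data", {
  t <- 0:4
  I <- 0.1 + (0.5 - 0.1) * (1 - exp(-1.0 * t))
  fit <- fitSaturation(t, I)
  expect_equal(unname(coef(fit)), c(0.1, 0.5, 1.0), tolerance = 1e-6)
  expect_lt(fit@residualNorm, 1e-10)

  expect_error(fitSaturation(c(0, 1), c(0.1, 0.2)), "3 distinct")
  expect_error(fitSaturation(t, rep(0.3, 5)), "unidentifiable")
})

test_that("saturation fractions reproduce the published reference values", {
  ref <- referenceFits()
  # I|t=4 / Imax per stain, rounded to 2 dp / nearest percent
  expect_equal(round(saturationFraction(ref$saturation$I2KI, 4), 2), 0.99)
  expect_equal(round(saturationFraction(ref$saturation$PTA, 4), 2), 0.87)
  expect_equal(round(saturationFraction(ref$saturation$PMA, 4), 2), 0.98)
  # t = 0 gives I0/Imax
  f <- ref$saturation$I2KI
  expect_equal(saturationFraction(f, 0), f@I0 / f@Imax)
})

test_that("saturationTime inverts saturationFraction", {
  fit <- SaturationFit(I0 = 0.065, Imax = 0.357, k = 1.108)
  for (f in c(0.5, 0.9, 0.95, 0.99)) {
    t <- saturationTime(fit, f)
    expect_equal(saturationFraction(fit, t), f, tolerance = 1e-10)
  }
  # against a numerical root-finding oracle at the 99% level
  oracle <- uniroot(function(t) saturationFraction(fit, t) - 0.99,
                    c(0, 50), tol = 1e-12)$root
  expect_equal(saturationTime(fit, 0.99), oracle, tolerance = 1e-8)
  expect_equal(round(oracle, 2), 3.97)  # consistent with 99% by day 4

  expect_warning(t0 <- saturationTime(fit, 0.1), "already")
  expect_equal(t0, 0)
  expect_error(saturationTime(fit, 1), "unreachable")
})

test_that("per-depth fits recover the depth-dependent rate within 1%", {
  spec <- smallSaturating(radius0 = 0.9)
  raw <- lapply(0:4, function(t)
    extractLineProfile(generatePhantomSlice(spec, t)$slice))
  profs <- normaliseCohort(raw)
  # depths measured from the true boundary, to test the fits in isolation
  # from the (slightly inward-biased) edge detector
  centre <- mean(range(positions(profs[[1L]])))
  edges <- rep(list(EdgePair(centre - 0.9, centre + 0.9)), length(profs))
  ds <- toDepthSeries(profs, edges)
  fits <- fitDepthProfile(ds)
  for (d in c(0.2, 0.4, 0.6)) {
    k <- coef(fits[[sprintf("%g", d)]])[["k"]]
    expect_equal(k, spec@k0 * exp(-spec@cK * d), tolerance = 0.01)
  }
})

test_that("fitDepthProfile bookkeeping: identical series, missing depths", {
  days <- 0:4
  I <- 0.1 + 0.4 * (1 - exp(-0.8 * days))
  ds <- do.call(rbind, lapply(c(0, 0.1, 0.2), function(d)
    data.frame(depth_mm = d, day = days, intensity = I)))
  fits <- fitDepthProfile(ds)
  expect_length(fits, 3L)
  expect_equal(coef(fits[["0"]]), coef(fits[["0.2"]]))

  # a depth observed < 3 days is flagged, others survive
  ds$intensity[ds$depth_mm == 0.2 & ds$day >= 2] <- NA
  fits2 <- fitDepthProfile(ds)
  expect_equal(attr(fits2, "failed"), 0.2)
  expect_length(fits2, 2L)
})

test_that("staining-time model fits exactly and predicts the reference times", {
  x <- seq(0, 2, by = 0.25)
  t <- 2 * exp(0.5 * x)
  m <- fitStainingTimeModel(x, t, level = 0.9)
  expect_equal(unname(coef(m)), c(2, 0.5), tolerance = 1e-8)

  expect_error(fitStainingTimeModel(c(1, 2), c(1, 2)), "3")
  expect_error(fitStainingTimeModel(x, -t), "positive")

  ref <- StainTimeModel(A = 1.007, c = 0.313, level = 0.90)
  expect_equal(round(predictStainingTime(ref, 1.5), 1), 1.6)
  expect_equal(round(predictStainingTime(ref, 3.0), 1), 2.6)
  expect_equal(predictStainingTime(ref, 0), 1.007)
})

test_that("front model fits exactly and reports penetration limits", {
  t <- 0:5
  x <- 3 * (1 - exp(-0.5 * t))
  m <- fitFrontModel(t, x)
  expect_equal(unname(coef(m)), c(3, 0.5), tolerance = 1e-8)

  expect_error(fitFrontModel(0:4, rep(NA_real_, 5)), "fewer than 3")

  # asymptotic radius limits from the published front constants
  expect_equal(round(maxPenetrationDepth(FrontModel(3.094, 0.367)), 1), 3.1)
  expect_equal(round(maxPenetrationDepth(FrontModel(2.056, 0.607)), 1), 2.1)

  pta <- FrontModel(3.094, 0.367)
  expect_equal(predictFrontDepth(pta, 0), 0)
  # closed form cross-checked by series expansion of 1 - e^{-K}
  K <- 0.367
  series <- sum(vapply(1:12, function(n) -(-K)^n / factorial(n), 0))
  expect_equal(predictFrontDepth(pta, 1), 3.094 * series, tolerance = 1e-9)
  expect_equal(round(predictFrontDepth(pta, 1), 3), 0.950)
  # monotone in t, bounded by C
  d <- predictFrontDepth(pta, seq(0, 20, by = 0.5))
  expect_true(all(diff(d) > 0))
  expect_true(all(d < maxPenetrationDepth(pta)))
})

test_that("noise shrinks parameter bias and CIs behave sanely", {
  t <- 0:4
  truth <- c(0.1, 0.5, 1.0)
  model <- function(tt) truth[1] + diff(truth[1:2]) * (1 - exp(-truth[3] * tt))
  set.seed(99)
  errAt <- function(sigma) {
    median(vapply(1:40, function(i) {
      f <- fitSaturation(t, model(t) + rnorm(5, 0, sigma))
      abs(coef(f)[["k"]] - truth[3])
    }, 0))
  }
  e1 <- errAt(0.02); e2 <- errAt(0.002)
  expect_lt(e2, e1)
  # noiseless fit: CI exists and collapses onto the truth
  f0 <- fitSaturation(t, model(t))
  ci <- confint(f0)
  expect_true(all(abs(ci[, "upper"] - ci[, "lower"]) < 1e-4))
})
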