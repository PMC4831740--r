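# Nonlinear model fits: exponential saturation of intensity with staining
# time, optimal staining time against depth, and stain-front propagation.

# Generic bounded least squares: nls(port) first, L-BFGS-B on the residual
# sum of squares as fallback (nls can fail on exact, zero-residual data).
# fn(par, x) must be vectorised over x. Returns list(par, rss, se, ci).
.lsqFit <- function(fn, start, lower, upper, x, y) {
  n <- length(y)
  p <- length(start)
  dat <- list(x = x, y = y)
  form <- if (p == 3L) y ~ fn(c(p1, p2, p3), x) else y ~ fn(c(p1, p2), x)
  st <- setNames(as.list(unname(start)), paste0("p", seq_len(p)))
  res <- tryCatch({
    fit <- nls(form, data = dat, start = st, algorithm = "port",
               lower = lower, upper = upper,
               control = nls.control(maxiter = 500))
    list(par = unname(coef(fit)), rss = sum(stats::residuals(fit)^2))
  }, error = function(e) NULL)
  if (is.null(res)) {
    sse <- function(q) sum((y - fn(q, x))^2)
    opt <- optim(start, sse, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = 500, factr = 1e4))
    # polish once from the optimum for tighter convergence
    opt <- optim(opt$par, sse, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 500, factr = 1e1))
    res <- list(par = unname(opt$par), rss = opt$value)
  }
  par <- res$par
  # linearised covariance: sigma^2 (J'J)^-1 with numerical Jacobian
  se <- rep(NA_real_, p)
  ci <- NULL
  if (n > p) {
    J <- matrix(0, n, p)
    eps <- pmax(abs(par), 1e-4) * 1e-6
    for (j in seq_len(p)) {
      dp <- par; dm <- par
      dp[j] <- dp[j] + eps[j]; dm[j] <- dm[j] - eps[j]
      J[, j] <- (fn(dp, x) - fn(dm, x)) / (2 * eps[j])
    }
    JtJ <- crossprod(J)
    cv <- tryCatch(solve(JtJ) * res$rss / (n - p), error = function(e) NULL)
    if (!is.null(cv)) {
      se <- sqrt(pmax(diag(cv), 0))
      tq <- qt(0.975, n - p)
      ci <- cbind(lower = par - tq * se, upper = par + tq * se)
    }
  }
  list(par = par, rss = res$rss, se = se, ci = ci)
}

#' Fit the exponential saturation model to an intensity time series
#'
#' Least-squares fit of
#' \deqn{I(t) = I_0 + (I_{max} - I_0)(1 - e^{-kt})}
#' to normalised intensity against staining time. Initialisation: `I0` from
#' the earliest observation, `Imax` from the maximum, `k = 1`/day; bounds
#' \eqn{0 \le I_0 < I_{max} \le 1.5}, \eqn{k > 0}. Linearised 95\%
#' confidence intervals are attached when the residual degrees of freedom
#' allow.
#'
#' @param times staining times in days (>= 3 distinct values).
#' @param intensities normalised intensities, same length.
#' @param depthMm,stain provenance recorded on the fit.
#' @return A [SaturationFit-class].
#' @examples
#' t <- 0:4
#' I <- 0.1 + 0.4 * (1 - exp(-1.0 * t))
#' coef(fitSaturation(t, I))
#' @export
fitSaturation <- function(times, intensities, depthMm = NA_real_,
                          stain = "other") {
  ok <- is.finite(times) & is.finite(intensities)
  times <- times[ok]; intensities <- intensities[ok]
  if (length(unique(times)) < 3L)
    stop("fitSaturation needs at least 3 distinct timepoints")
  if (any(times < 0)) stop("times must be >= 0")
  if (sd(intensities) == 0)
    stop("fit failed: constant intensity series, k is unidentifiable")
  fn <- function(q, t) q[1L] + (q[2L] - q[1L]) * (1 - exp(-q[3L] * t))
  i0 <- intensities[which.min(times)]
  imax <- max(intensities)
  start <- c(max(i0, 1e-6), max(imax, i0 + 0.01), 1)
  fit <- .lsqFit(fn, start, lower = c(0, 1e-6, 1e-6),
                 upper = c(1.5, 1.5, Inf), x = times, y = intensities)
  par <- fit$par
  if (par[2L] <= par[1L] + 1e-12)
    stop("fit failed: Imax did not exceed I0 (flat or decreasing series)")
  ci <- fit$ci
  if (!is.null(ci)) rownames(ci) <- c("I0", "Imax", "k")
  SaturationFit(I0 = par[1L], Imax = par[2L], k = par[3L], se = fit$se,
                ci = ci, residualNorm = fit$rss, n = length(times),
                depthMm = depthMm, stain = stain)
}

#' Saturation fraction reached at time t
#'
#' The modelled intensity at time `t` as a fraction of the fitted maximum:
#' \eqn{[I_0 + (I_{max}-I_0)(1-e^{-kt})] / I_{max}}. Reported as, e.g.,
#' "99\% of Imax after 4 days of staining".
#'
#' @param fit a [SaturationFit-class].
#' @param t staining time in days (vectorised).
#' @return fraction of `Imax` (in [I0/Imax, 1)).
#' @export
saturationFraction <- function(fit, t) {
  stopifnot(is(fit, "SaturationFit"))
  if (any(t < 0)) stop("t must be >= 0")
  (fit@I0 + (fit@Imax - fit@I0) * (1 - exp(-fit@k * t))) / fit@Imax
}

#' Time to reach a saturation level
#'
#' Closed-form inverse of the saturation model: the time at which intensity
#' reaches `f * Imax`,
#' \deqn{t = -\frac{1}{k}\ln\left(1 - \frac{f I_{max} - I_0}{I_{max} - I_0}\right).}
#' The level is a fraction of the absolute fitted maximum, not of the span
#' `Imax - I0`.
#'
#' @param fit a [SaturationFit-class].
#' @param f target fraction of `Imax`, in (0, 1).
#' @return time in days. If the target is already met at t = 0 (`f * Imax
#'   <= I0`) returns 0 with a warning; a target at or above `Imax` is
#'   unreachable and errors.
#' @export
saturationTime <- function(fit, f) {
  stopifnot(is(fit, "SaturationFit"), length(f) == 1L, f > 0)
  target <- f * fit@Imax
  if (target >= fit@Imax)
    stop("saturation level ", f, " is unreachable (target >= Imax)")
  if (target <= fit@I0) {
    warning("target intensity already reached at t = 0")
    return(0)
  }
  -log(1 - (target - fit@I0) / (fit@Imax - fit@I0)) / fit@k
}

#' Fit the saturation model independently at each depth
#'
#' Runs [fitSaturation()] on each depth increment of a depth-resolved
#' intensity series ([toDepthSeries()]). Depths with fewer than 3 observed
#' days (e.g. lost to shrinkage) or failed fits are flagged and excluded.
#'
#' @param depthSeries data.frame with columns `depth_mm`, `day`,
#'   `intensity` (and optionally `stain`).
#' @return A named list of [SaturationFit-class] (names: depth in mm);
#'   attribute `"failed"` lists depths that could not be fitted.
#' @export
fitDepthProfile <- function(depthSeries) {
  stopifnot(all(c("depth_mm", "day", "intensity") %in% names(depthSeries)))
  stn <- if ("stain" %in% names(depthSeries))
    as.character(depthSeries$stain[1L]) else "other"
  depths <- sort(unique(depthSeries$depth_mm))
  fits <- list()
  failed <- numeric()
  for (d in depths) {
    sub <- depthSeries[depthSeries$depth_mm == d &
                         is.finite(depthSeries$intensity), ]
    f <- if (nrow(sub) >= 3L)
      tryCatch(fitSaturation(sub$day, sub$intensity, depthMm = d,
                             stain = stn),
               error = function(e) NULL) else NULL
    if (is.null(f)) failed <- c(failed, d)
    else fits[[sprintf("%g", d)]] <- f
  }
  if (length(fits) == 0L) stop("saturation fit failed at every depth")
  attr(fits, "failed") <- failed
  fits
}

#' Optimal staining times per depth from per-depth saturation fits
#'
#' @param fits output of [fitDepthProfile()].
#' @param levels saturation levels (fractions of `Imax`).
#' @return data.frame with `depth_mm` and one `t<level>` column per level
#'   (days); unreachable levels give `NA`.
#' @export
stainingTimeTable <- function(fits, levels = c(0.90, 0.95, 0.99)) {
  stopifnot(length(fits) > 0L, all(levels > 0 & levels < 1))
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    ts <- vapply(levels, function(f)
      tryCatch(suppressWarnings(saturationTime(fit, f)),
               error = function(e) NA_real_), 0)
    out <- data.frame(depth_mm = as.numeric(nm))
    out[paste0("t", round(100 * levels))] <- as.list(ts)
    out
  })
  do.call(rbind, rows)
}

#' Fit the staining-time-against-depth model
#'
#' Nonlinear least squares on the original (linear) scale for
#' \eqn{t_{stain} = A e^{cx}}, initialised from the log-linear regression
#' \eqn{\ln t = \ln A + c x}. Pairs with missing times are dropped.
#'
#' @param depths depths in mm.
#' @param times required staining times in days (> 0), same length.
#' @param level the saturation level these times correspond to.
#' @return A [StainTimeModel-class].
#' @export
fitStainingTimeModel <- function(depths, times, level = 0.90) {
  ok <- is.finite(depths) & is.finite(times)
  depths <- depths[ok]; times <- times[ok]
  if (length(depths) < 3L)
    stop("fitStainingTimeModel needs at least 3 (depth, time) pairs")
  if (any(times <= 0)) stop("staining times must be positive")
  init <- coef(lm(log(times) ~ depths))
  start <- c(exp(init[[1L]]), max(init[[2L]], 1e-4))
  fn <- function(q, x) q[1L] * exp(q[2L] * x)
  fit <- .lsqFit(fn, start, lower = c(1e-8, 1e-8), upper = c(Inf, Inf),
                 x = depths, y = times)
  StainTimeModel(A = fit$par[1L], c = fit$par[2L], level = level)
}

#' Predicted staining time at a depth
#'
#' Evaluates \eqn{t_{stain} = A e^{cx}}: the recommended immersion time for
#' the stain to reach the model's saturation level at depth `depth` mm.
#'
#' @param m a [StainTimeModel-class].
#' @param depthMm depth in mm (vectorised, >= 0).
#' @return time in days.
#' @examples
#' predictStainingTime(StainTimeModel(1.007, 0.313, 0.90), c(1.5, 3))
#' @export
predictStainingTime <- function(m, depthMm) {
  stopifnot(is(m, "StainTimeModel"))
  if (any(depthMm < 0)) stop("depthMm must be >= 0")
  m@A * exp(m@c * depthMm)
}

#' Fit the stain-front propagation model
#'
#' Nonlinear least squares for \eqn{x(t) = C(1 - e^{-Kt})}, the saturating
#' depth of a sharp stain front. Initialisation: `C` at 1.2x the deepest
#' observed front, `K` from the reciprocal mean time. Days with no detected
#' front (`NA` depth) are excluded.
#'
#' @param times staining times in days.
#' @param frontDepths detected front depths in mm (NA = front not found).
#' @param stain provenance label.
#' @return A [FrontModel-class] with linearised 95\% confidence intervals.
#' @export
fitFrontModel <- function(times, frontDepths, stain = "other") {
  ok <- is.finite(times) & is.finite(frontDepths)
  times <- times[ok]; frontDepths <- frontDepths[ok]
  if (length(times) < 3L)
    stop("fit failed: fewer than 3 observed front depths")
  fn <- function(q, t) q[1L] * (1 - exp(-q[2L] * t))
  start <- c(1.2 * max(frontDepths),
             1 / max(mean(times[times > 0]), 0.1))
  fit <- .lsqFit(fn, start, lower = c(1e-8, 1e-8), upper = c(Inf, Inf),
                 x = times, y = frontDepths)
  ci <- fit$ci
  if (!is.null(ci)) rownames(ci) <- c("C", "K")
  FrontModel(C = fit$par[1L], K = fit$par[2L], se = fit$se, ci = ci,
             residualNorm = fit$rss, n = length(times), stain = stain)
}

#' Maximum stain penetration depth
#'
#' The asymptote `C` of the front-propagation model: the deepest the front
#' ever reaches, hence an upper limit on the radius of a sample that this
#' stain can penetrate fully.
#'
#' @param m a [FrontModel-class].
#' @return depth in mm.
#' @examples
#' maxPenetrationDepth(FrontModel(C = 3.094, K = 0.367))  # PTA-like limit
#' @export
maxPenetrationDepth <- function(m) {
  stopifnot(is(m, "FrontModel"))
  m@C
}

#' Predicted front depth at time t
#'
#' Evaluates \eqn{x(t) = C(1 - e^{-Kt})}; strictly increasing in `t` and
#' bounded above by `C`.
#'
#' @param m a [FrontModel-class].
#' @param t staining time in days (vectorised, >= 0).
#' @return depth in mm.
#' @export
predictFrontDepth <- function(m, t) {
  stopifnot(is(m, "FrontModel"))
  if (any(t < 0)) stop("t must be >= 0")
  m@C * (1 - exp(-m@K * t))
}
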