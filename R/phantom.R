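# Synthetic stained-disc phantoms with closed-form ground truth. These stand
# in for scan data: every detector and fit in the package is validated by
# recovering the parameters that generated a phantom.

#' Shrunk phantom radius at time t
#'
#' \deqn{R(t) = R_0 (1 - s (1 - e^{-\lambda t}))}
#' Radial shrinkage approaches the plateau \eqn{R_0 (1 - s)} exponentially;
#' with the default rate most of the shrinkage occurs during the first day,
#' as observed for over-stained connective tissue. The true normalised
#' cross-sectional area is \eqn{(R(t)/R(0))^2}.
#'
#' @param spec a [PhantomSpec-class].
#' @param t staining time in days (vectorised).
#' @return radius in mm.
#' @examples
#' spec <- PhantomSpec(shrinkFraction = 1 - sqrt(0.9))
#' (shrunkRadius(spec, 100) / shrunkRadius(spec, 0))^2  # ~0.9 area plateau
#' @export
shrunkRadius <- function(spec, t) {
  stopifnot(is(spec, "PhantomSpec"))
  if (any(t < 0)) stop("t must be >= 0")
  spec@radius0 *
    (1 - spec@shrinkFraction * (1 - exp(-spec@shrinkRate * t)))
}

#' True stain-front depth at time t (front mode)
#'
#' \eqn{d(t) = C (1 - e^{-Kt})}: strictly increasing, bounded by `C`.
#'
#' @inheritParams shrunkRadius
#' @return depth in mm; `NA` in saturating mode.
#' @export
trueFrontDepth <- function(spec, t) {
  stopifnot(is(spec, "PhantomSpec"))
  if (any(t < 0)) stop("t must be >= 0")
  if (spec@mode != "front") return(rep(NA_real_, length(t)))
  spec@C * (1 - exp(-spec@K * t))
}

#' Closed-form phantom intensity at depth x and time t
#'
#' The noise-free intensity a phantom pixel at depth `x` (mm, measured
#' inward from the shrunk disc boundary) takes at time `t`. Negative depths
#' (outside the disc) return the background level. This is the ground truth
#' that generated pixels, extracted profiles and fitted kinetics are all
#' compared against.
#'
#' @param spec a [PhantomSpec-class].
#' @param x depth from the disc boundary in mm (vectorised).
#' @param t staining time in days (scalar).
#' @return normalised intensity.
#' @export
phantomIntensity <- function(spec, x, t) {
  stopifnot(is(spec, "PhantomSpec"), length(t) == 1L, t >= 0)
  out <- rep(spec@backgroundLevel, length(x))
  inside <- x >= 0
  if (spec@mode == "saturating") {
    kx <- spec@k0 * exp(-spec@cK * x[inside])
    out[inside] <- spec@I0 + (spec@Imax - spec@I0) * (1 - exp(-kx * t))
  } else {
    d <- spec@C * (1 - exp(-spec@K * t))
    w <- spec@frontWidth
    xi <- x[inside]
    v <- ifelse(xi <= d - w / 2, spec@IOut,
         ifelse(xi >= d + w / 2, spec@IIn,
                spec@IOut + (spec@IIn - spec@IOut) * (xi - (d - w / 2)) / w))
    out[inside] <- v
  }
  out
}

# Run fn with a private RNG stream, restoring the caller's .Random.seed.
.withPhantomSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate one phantom slice with its ground truth
#'
#' Renders the disc phantom described by `spec` at staining time `t`: a disc
#' of radius \eqn{R(t)} (see [shrunkRadius()]) centred in the image, with
#' each interior pixel set to the closed-form intensity
#' [phantomIntensity()] at its Euclidean depth from the disc boundary,
#' background outside, and (when `noiseSigma > 0`) additive Gaussian noise
#' clipped to [0, 1]. Noise is reproducible: the RNG stream is derived from
#' `spec@seed` and `t` only.
#'
#' @param spec a [PhantomSpec-class].
#' @param t staining time in days (any t >= 0).
#' @param marginPx background margin around the unstained disc, in pixels.
#' @return A list with elements `slice` ([SliceImage-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @examples
#' spec <- PhantomSpec(radius0 = 0.3, noiseSigma = 0)
#' ph <- generatePhantomSlice(spec, 1)
#' ph$truth
#' @export
generatePhantomSlice <- function(spec, t, marginPx = 40L) {
  stopifnot(is(spec, "PhantomSpec"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single non-negative number of days")
  R <- shrunkRadius(spec, t)
  if (R / spec@pixelSize < 3)
    stop("degenerate phantom: radius at t = ", t, " is below 3 pixels")
  rpx <- ceiling(spec@radius0 / spec@pixelSize)
  n <- 2L * (rpx + as.integer(marginPx)) + 1L
  centre <- (n + 1) / 2
  ax <- (seq_len(n) - centre) * spec@pixelSize
  r <- sqrt(outer(ax^2, ax^2, `+`))   # radial distance of each pixel, mm
  depth <- R - r                      # >= 0 inside the shrunk disc
  px <- matrix(phantomIntensity(spec, as.vector(depth), t), n, n)
  if (spec@noiseSigma > 0) {
    noise <- .withPhantomSeed(spec@seed + as.integer(round(997 * t)) %% 100000L,
                              function() rnorm(n * n, 0, spec@noiseSigma))
    px <- pmin(pmax(px + matrix(noise, n, n), 0), 1)
  }
  slice <- SliceImage(px, pixelSize = spec@pixelSize,
                      sampleId = spec@sampleId, stain = spec@stain,
                      day = as.integer(round(t)))
  truth <- new("PhantomTruth", spec = spec, t = t, radiusMm = R,
               frontDepthMm = if (spec@mode == "front")
                 trueFrontDepth(spec, t) else NA_real_)
  list(slice = slice, truth = truth)
}

#' Generate a phantom cohort on disk
#'
#' Writes one 16-bit PGM slice per (sample, timepoint) with deterministic
#' filenames `<sample>_<stain>_day<d>.pgm`, plus a machine-readable
#' `manifest.json` holding each spec's parameters and the closed-form truth
#' (radius, front depth) per timepoint.
#'
#' @param specs a [PhantomSpec-class] or list of them (sample ids should be
#'   unique).
#' @param outDir output directory, created if needed.
#' @param marginPx background margin, as in [generatePhantomSlice()].
#' @return The manifest (a list), invisibly. `manifest$files` gives relative
#'   slice paths.
#' @seealso [readCohortManifest()]
#' @export
generateCohort <- function(specs, outDir, marginPx = 40L) {
  if (is(specs, "PhantomSpec")) specs <- list(specs)
  stopifnot(length(specs) > 0L, all(vapply(specs, is, TRUE, "PhantomSpec")))
  ids <- vapply(specs, function(s) s@sampleId, "")
  if (anyDuplicated(ids)) stop("sample ids must be unique across specs")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  samples <- list()
  files <- character()
  for (spec in specs) {
    truth <- lapply(spec@timepoints, function(t) {
      ph <- generatePhantomSlice(spec, t, marginPx = marginPx)
      fn <- sprintf("%s_%s_day%d.pgm", spec@sampleId, spec@stain,
                    as.integer(round(t)))
      path <- file.path(outDir, fn)
      tryCatch(writePGM(ph$slice, path),
               error = function(e) stop("writing ", path, ": ",
                                        conditionMessage(e)))
      files <<- c(files, fn)
      list(t = t, file = fn, true_radius_mm = ph$truth@radiusMm,
           true_front_depth_mm = ph$truth@frontDepthMm)
    })
    samples[[spec@sampleId]] <- list(
      sample = spec@sampleId, stain = spec@stain, mode = spec@mode,
      params = .specToList(spec), timepoints = truth)
  }
  manifest <- list(pixel_size_mm = specs[[1L]]@pixelSize,
                   files = files, samples = samples)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.specToList <- function(spec) {
  list(mode = spec@mode, radius0_mm = spec@radius0,
       pixel_size_mm = spec@pixelSize, timepoints_days = spec@timepoints,
       background_level = spec@backgroundLevel,
       noise_sigma = spec@noiseSigma, seed = spec@seed,
       shrink_fraction = spec@shrinkFraction, shrink_rate = spec@shrinkRate,
       I0 = spec@I0, Imax = spec@Imax, k0 = spec@k0, c_k = spec@cK,
       C = spec@C, K = spec@K, front_width_mm = spec@frontWidth,
       I_in = spec@IIn, I_out = spec@IOut,
       sample = spec@sampleId, stain = spec@stain)
}

#' Rebuild a PhantomSpec from its serialised parameter list
#' @param params a list as stored under `params` in a cohort manifest.
#' @return A [PhantomSpec-class].
#' @export
phantomSpecFromList <- function(params) {
  PhantomSpec(mode = params$mode, radius0 = params$radius0_mm,
              pixelSize = params$pixel_size_mm,
              timepoints = unlist(params$timepoints_days),
              backgroundLevel = params$background_level,
              noiseSigma = params$noise_sigma, seed = params$seed,
              shrinkFraction = params$shrink_fraction,
              shrinkRate = params$shrink_rate, I0 = params$I0,
              Imax = params$Imax, k0 = params$k0, cK = params$c_k,
              C = params$C, K = params$K,
              frontWidth = params$front_width_mm, IIn = params$I_in,
              IOut = params$I_out, sampleId = params$sample,
              stain = params$stain)
}

#' Read a cohort manifest written by [generateCohort()]
#' @param path the manifest file or the cohort directory containing it.
#' @return The manifest list.
#' @export
readCohortManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
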