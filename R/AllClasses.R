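#' @import methods
#' @importFrom stats approx aov coef dnorm lm na.omit nls nls.control optim
#'   pf ptukey qt TukeyHSD uniroot vcov rnorm sd setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib StainKinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SliceImage: a 2D grayscale tomographic slice
#'
#' A single reconstructed transverse slice with its physical pixel size and
#' the sample metadata every downstream detector needs (sample identifier,
#' stain and staining day).
#'
#' @slot pixels numeric matrix of grayscale values (rows x columns).
#' @slot pixelSize physical size of one pixel in mm (7.5e-3 for the scans
#'   this pipeline was designed around).
#' @slot sampleId sample identifier.
#' @slot stain one of `"I2KI"`, `"PTA"`, `"PMA"` or `"other"`.
#' @slot day integer staining day (0 = unstained).
#' @export
setClass("SliceImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 sampleId = "character", stain = "character", day = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number (mm)")
    if (nrow(object@pixels) == 0L || ncol(object@pixels) == 0L)
      msg <- c(msg, "pixel grid must be non-empty")
    if (!object@stain %in% c("I2KI", "PTA", "PMA", "other"))
      msg <- c(msg, "stain must be one of I2KI, PTA, PMA, other")
    if (length(object@day) != 1L || is.na(object@day) || object@day < 0L)
      msg <- c(msg, "day must be a single non-negative integer")
    if (length(msg)) msg else TRUE
  })

#' Construct a SliceImage
#'
#' @param pixels numeric matrix of grayscale values.
#' @param pixelSize pixel size in mm.
#' @param sampleId,stain,day sample metadata.
#' @return A [SliceImage-class] object.
#' @examples
#' img <- SliceImage(matrix(runif(100), 10), pixelSize = 0.0075)
#' pixelSize(img)
#' @export
SliceImage <- function(pixels, pixelSize = 0.0075, sampleId = "sample",
                       stain = "other", day = 0L) {
  new("SliceImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      sampleId = as.character(sampleId), stain = as.character(stain),
      day = as.integer(day))
}

#' LineProfile: width-averaged intensity along a line through a slice
#'
#' Intensity sampled along a horizontal line through a slice, averaged over a
#' perpendicular band of `widthPx` pixels, with positions in mm from the
#' image edge. Values are raw grayscale until [normaliseCohort()] divides the
#' whole cohort by its single global maximum.
#'
#' @slot positions strictly increasing positions in mm, uniformly spaced.
#' @slot values intensity at each position.
#' @slot widthPx width of the averaging band in pixels.
#' @slot sampleId,stain,day sample metadata (as for [SliceImage-class]).
#' @slot normalised `TRUE` once the cohort-wide normalisation has been
#'   applied.
#' @export
setClass("LineProfile",
  representation(positions = "numeric", values = "numeric",
                 widthPx = "integer", sampleId = "character",
                 stain = "character", day = "integer",
                 normalised = "logical"),
  validity = function(object) {
    msg <- character()
    n <- length(object@positions)
    if (n != length(object@values))
      msg <- c(msg, "positions and values must have the same length")
    if (n >= 2L) {
      d <- diff(object@positions)
      if (any(d <= 0)) msg <- c(msg, "positions must be strictly increasing")
      if (diff(range(d)) > 1e-9 * max(d))
        msg <- c(msg, "positions must be uniformly spaced")
    }
    if (object@widthPx < 1L) msg <- c(msg, "widthPx must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a LineProfile
#'
#' @param positions positions in mm (uniformly spaced, increasing).
#' @param values intensities, same length as `positions`.
#' @param widthPx averaging band width in pixels.
#' @param sampleId,stain,day sample metadata.
#' @param normalised whether values are already cohort-normalised.
#' @return A [LineProfile-class] object.
#' @export
LineProfile <- function(positions, values, widthPx = 10L, sampleId = "sample",
                        stain = "other", day = 0L, normalised = FALSE) {
  new("LineProfile", positions = as.numeric(positions),
      values = as.numeric(values), widthPx = as.integer(widthPx),
      sampleId = as.character(sampleId), stain = as.character(stain),
      day = as.integer(day), normalised = isTRUE(normalised))
}

#' EdgePair: the two detected sample edges on a line profile
#'
#' @slot leftMm,rightMm positions (mm) of the left and right sample edge on
#'   the profile axis.
#' @export
setClass("EdgePair",
  representation(leftMm = "numeric", rightMm = "numeric"),
  validity = function(object) {
    if (object@leftMm >= object@rightMm)
      "leftMm must be strictly less than rightMm" else TRUE
  })

#' Construct an EdgePair
#' @param leftMm,rightMm edge positions in mm.
#' @return An [EdgePair-class] object.
#' @export
EdgePair <- function(leftMm, rightMm)
  new("EdgePair", leftMm = as.numeric(leftMm), rightMm = as.numeric(rightMm))

#' FrontLocation: a detected stain-front edge
#'
#' @slot depthMm depth of the front edge from the sample edge, in mm (`NA`
#'   when no front was found).
#' @slot side which sample edge the search started from.
#' @slot found `FALSE` when no point on the inward walk passed the gradient
#'   drop threshold (bulk-stained or unstained sample).
#' @export
setClass("FrontLocation",
  representation(depthMm = "numeric", side = "character", found = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@side %in% c("left", "right"))
      msg <- c(msg, "side must be 'left' or 'right'")
    if (isTRUE(object@found) && (is.na(object@depthMm) || object@depthMm < 0))
      msg <- c(msg, "a found front must have a non-negative depth")
    if (length(msg)) msg else TRUE
  })

FrontLocation <- function(depthMm, side, found = TRUE)
  new("FrontLocation", depthMm = as.numeric(depthMm),
      side = as.character(side), found = isTRUE(found))

#' SaturationFit: exponential saturation model of intensity vs time
#'
#' Parameters of the saturation model
#' \deqn{I(t) = I_0 + (I_{max} - I_0)(1 - e^{-kt})}
#' fitted to normalised intensity against staining time at one tissue depth
#' (or for the bulk sample). `I0` is the unstained intensity, `Imax` the
#' asymptotic maximum and `k` (1/days) is associated with the diffusion
#' rate. The exponent is negative: only \eqn{e^{-kt}} produces a curve that
#' rises from `I0` to `Imax`.
#'
#' @slot I0,Imax,k fitted parameters.
#' @slot se linearised standard errors (`NA` when unavailable).
#' @slot ci 3x2 matrix of linearised 95\% confidence limits, or `NULL`.
#' @slot residualNorm residual sum of squares of the fit.
#' @slot n number of points fitted.
#' @slot depthMm depth the fit belongs to, `NA` for a bulk fit.
#' @slot stain stain label, for provenance.
#' @export
setClass("SaturationFit",
  representation(I0 = "numeric", Imax = "numeric", k = "numeric",
                 se = "numeric", ci = "matrixOrNULL",
                 residualNorm = "numeric", n = "integer",
                 depthMm = "numeric", stain = "character"),
  validity = function(object) {
    msg <- character()
    if (object@I0 < 0) msg <- c(msg, "I0 must be >= 0")
    if (object@Imax <= object@I0) msg <- c(msg, "Imax must exceed I0")
    if (object@k <= 0) msg <- c(msg, "k must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a SaturationFit directly from known constants
#'
#' Used both by [fitSaturation()] and to evaluate published constants, e.g.
#' the reference values shipped with the package ([referenceFits()]).
#'
#' @param I0,Imax,k model constants (normalised intensity, intensity, 1/days).
#' @param se,ci,residualNorm,n,depthMm,stain optional fit provenance.
#' @return A [SaturationFit-class] object.
#' @examples
#' fit <- SaturationFit(I0 = 0.065, Imax = 0.357, k = 1.108)
#' saturationFraction(fit, 4)   # ~0.99
#' @export
SaturationFit <- function(I0, Imax, k, se = rep(NA_real_, 3), ci = NULL,
                          residualNorm = NA_real_, n = NA_integer_,
                          depthMm = NA_real_, stain = "other") {
  new("SaturationFit", I0 = as.numeric(I0), Imax = as.numeric(Imax),
      k = as.numeric(k), se = as.numeric(se), ci = ci,
      residualNorm = as.numeric(residualNorm), n = as.integer(n),
      depthMm = as.numeric(depthMm), stain = as.character(stain))
}

#' StainTimeModel: staining time as an exponential function of depth
#'
#' Parameters of \eqn{t_{stain}(x) = A e^{cx}}: the time required for the
#' intensity at depth \eqn{x} (mm) to reach a given fraction of its fitted
#' maximum.
#'
#' @slot A time scale in days (the staining time at depth 0).
#' @slot c exponential depth coefficient in 1/mm.
#' @slot level the saturation level the model was fitted for, in (0, 1).
#' @export
setClass("StainTimeModel",
  representation(A = "numeric", c = "numeric", level = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@A <= 0) msg <- c(msg, "A must be positive")
    if (object@c <= 0) msg <- c(msg, "c must be positive")
    if (object@level <= 0 || object@level >= 1)
      msg <- c(msg, "level must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Construct a StainTimeModel
#' @param A,c model constants (days, 1/mm).
#' @param level saturation level in (0, 1).
#' @return A [StainTimeModel-class] object.
#' @examples
#' m <- StainTimeModel(A = 1.007, c = 0.313, level = 0.90)
#' predictStainingTime(m, 1.5)  # ~1.6 days
#' @export
StainTimeModel <- function(A, c, level = 0.90)
  new("StainTimeModel", A = as.numeric(A), c = as.numeric(c),
      level = as.numeric(level))

#' FrontModel: saturating stain-front propagation model
#'
#' Parameters of \eqn{x(t) = C(1 - e^{-Kt})}: the depth of the stain front
#' as a function of staining time for front-forming stains (PTA, PMA). `C`
#' (mm) is the asymptotic maximum penetration depth; `K` (1/days) sets how
#' quickly the front approaches it.
#'
#' @slot C asymptotic front depth in mm.
#' @slot K rate constant in 1/days.
#' @slot se,ci linearised standard errors and 95\% confidence limits.
#' @slot residualNorm residual sum of squares.
#' @slot n number of points fitted.
#' @slot stain stain label, for provenance.
#' @export
setClass("FrontModel",
  representation(C = "numeric", K = "numeric", se = "numeric",
                 ci = "matrixOrNULL", residualNorm = "numeric",
                 n = "integer", stain = "character"),
  prototype(C = 1, K = 1),
  validity = function(object) {
    msg <- character()
    if (object@C <= 0) msg <- c(msg, "C must be positive")
    if (object@K <= 0) msg <- c(msg, "K must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a FrontModel
#' @param C,K model constants (mm, 1/days).
#' @param se,ci,residualNorm,n,stain optional fit provenance.
#' @return A [FrontModel-class] object.
#' @examples
#' m <- FrontModel(C = 3.094, K = 0.367)
#' maxPenetrationDepth(m)  # 3.094 mm
#' @export
FrontModel <- function(C, K, se = rep(NA_real_, 2), ci = NULL,
                       residualNorm = NA_real_, n = NA_integer_,
                       stain = "other") {
  # "C = " would partially match new()'s Class argument; assign it by slot
  obj <- new("FrontModel", K = as.numeric(K), se = as.numeric(se),
             ci = ci, residualNorm = as.numeric(residualNorm),
             n = as.integer(n), stain = as.character(stain))
  obj@C <- as.numeric(C)
  validObject(obj)
  obj
}

#' PhantomSpec: parameters of a synthetic stained-disc phantom
#'
#' Describes a circular tissue phantom whose staining behaviour is one of
#' two idealised modes observed in contrast-enhanced CT of ligaments:
#' \describe{
#'   \item{saturating}{bulk staining with a depth-dependent rate, emulating
#'     I2KI: \eqn{I(x,t) = I_0 + (I_{max}-I_0)(1-e^{-k(x)t})} with
#'     \eqn{k(x) = k_0 e^{-c_k x}}.}
#'   \item{front}{a sharp stain front at depth \eqn{d(t) = C(1-e^{-Kt})},
#'     emulating PTA/PMA: intensity `IOut` outside the front, `IIn` inside,
#'     with a linear ramp of width `frontWidth` between them.}
#' }
#' The disc radius shrinks over staining days as
#' \eqn{R(t) = R_0 (1 - s(1 - e^{-\lambda t}))} and additive Gaussian noise
#' of standard deviation `noiseSigma` (clipped to [0, 1]) is applied per
#' pixel.
#'
#' @slot mode `"saturating"` or `"front"`.
#' @slot radius0 unstained disc radius in mm.
#' @slot pixelSize pixel size in mm.
#' @slot timepoints staining days at which slices are generated.
#' @slot backgroundLevel normalised intensity outside the disc.
#' @slot noiseSigma additive Gaussian noise sd (normalised intensity units).
#' @slot seed integer RNG seed for reproducible noise.
#' @slot shrinkFraction s, asymptotic radial shrinkage fraction in [0, 1).
#' @slot shrinkRate lambda, shrinkage rate in 1/days.
#' @slot I0,Imax,k0,cK saturating-mode parameters (k0 in 1/days, cK in 1/mm).
#' @slot C,K,frontWidth,IIn,IOut front-mode parameters (mm, 1/days, mm,
#'   normalised intensities with `IOut > IIn`).
#' @slot sampleId,stain metadata stamped on generated slices.
#' @export
setClass("PhantomSpec",
  representation(mode = "character", radius0 = "numeric",
                 pixelSize = "numeric", timepoints = "numeric",
                 backgroundLevel = "numeric", noiseSigma = "numeric",
                 seed = "integer", shrinkFraction = "numeric",
                 shrinkRate = "numeric", I0 = "numeric", Imax = "numeric",
                 k0 = "numeric", cK = "numeric", C = "numeric", K = "numeric",
                 frontWidth = "numeric", IIn = "numeric", IOut = "numeric",
                 sampleId = "character", stain = "character"),
  prototype(C = 3, K = 0.5),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("saturating", "front"))
      msg <- c(msg, "mode must be 'saturating' or 'front'")
    if (object@radius0 <= 0) msg <- c(msg, "radius0 must be positive")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
    if (length(object@timepoints) == 0L || any(object@timepoints < 0))
      msg <- c(msg, "timepoints must be non-negative")
    if (is.unsorted(object@timepoints, strictly = TRUE))
      msg <- c(msg, "timepoints must be sorted strictly ascending")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (object@shrinkFraction < 0 || object@shrinkFraction >= 1)
      msg <- c(msg, "shrinkFraction must be in [0, 1)")
    if (object@shrinkRate <= 0) msg <- c(msg, "shrinkRate must be positive")
    if (object@I0 < 0 || object@I0 >= object@Imax || object@Imax > 1)
      msg <- c(msg, "saturating mode requires 0 <= I0 < Imax <= 1")
    if (object@k0 <= 0) msg <- c(msg, "k0 must be positive")
    if (object@cK < 0) msg <- c(msg, "cK must be >= 0")
    if (object@C <= 0) msg <- c(msg, "C must be positive")
    if (object@K <= 0) msg <- c(msg, "K must be positive")
    if (object@frontWidth <= 0) msg <- c(msg, "frontWidth must be positive")
    if (object@IOut <= object@IIn) msg <- c(msg, "IOut must exceed IIn")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults describe a 3 mm-radius phantom imaged at 7.5 um/pixel over five
#' daily scans (day 0 unstained), matching the acquisition geometry the
#' pipeline targets. Saturating-mode kinetics default to an I2KI-like
#' phantom, front mode to a PTA-like one.
#'
#' @param mode `"saturating"` or `"front"`.
#' @param radius0 unstained radius in mm.
#' @param pixelSize pixel size in mm.
#' @param timepoints staining days.
#' @param backgroundLevel intensity outside the disc (kept below `I0`/`IIn`).
#' @param noiseSigma additive Gaussian noise sd.
#' @param seed RNG seed.
#' @param shrinkFraction,shrinkRate radial shrinkage parameters.
#' @param I0,Imax,k0,cK saturating-mode kinetics.
#' @param C,K,frontWidth,IIn,IOut front-mode kinetics.
#' @param sampleId,stain metadata for generated slices.
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec("front", radius0 = 1, noiseSigma = 0)
#' trueFrontDepth(spec, 1)
#' @export
PhantomSpec <- function(mode = c("saturating", "front"), radius0 = 3,
                        pixelSize = 0.0075, timepoints = 0:4,
                        backgroundLevel = 0.02, noiseSigma = 0.01,
                        seed = 1L, shrinkFraction = 0, shrinkRate = 2,
                        I0 = 0.1, Imax = 0.6, k0 = 1, cK = 0.3,
                        C = 3, K = 0.5, frontWidth = 0.3,
                        IIn = 0.2, IOut = 0.8,
                        sampleId = "phantom",
                        stain = if (match.arg(mode) == "front") "PTA" else "I2KI") {
  mode <- match.arg(mode)
  # "C = " would partially match new()'s Class argument; assign it by slot
  obj <- new("PhantomSpec", mode = mode, radius0 = as.numeric(radius0),
             pixelSize = as.numeric(pixelSize),
             timepoints = as.numeric(timepoints),
             backgroundLevel = as.numeric(backgroundLevel),
             noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed),
             shrinkFraction = as.numeric(shrinkFraction),
             shrinkRate = as.numeric(shrinkRate), I0 = as.numeric(I0),
             Imax = as.numeric(Imax), k0 = as.numeric(k0),
             cK = as.numeric(cK), K = as.numeric(K),
             frontWidth = as.numeric(frontWidth), IIn = as.numeric(IIn),
             IOut = as.numeric(IOut), sampleId = as.character(sampleId),
             stain = as.character(stain))
  obj@C <- as.numeric(C)
  validObject(obj)
  obj
}

#' PhantomTruth: closed-form ground truth of a phantom at one timepoint
#'
#' @slot spec the generating [PhantomSpec-class].
#' @slot t the staining time in days.
#' @slot radiusMm true (shrunk) disc radius R(t).
#' @slot frontDepthMm true front depth d(t) (`NA` in saturating mode).
#' @export
setClass("PhantomTruth",
  representation(spec = "PhantomSpec", t = "numeric", radiusMm = "numeric",
                 frontDepthMm = "numeric"))
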