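# Accessor generics. Slot access from user code goes through these.

#' @rdname SliceImage
#' @param object,x a StainKinetics object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname SliceImage
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname SliceImage
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname SliceImage
#' @export
setGeneric("stain", function(x) standardGeneric("stain"))
#' @rdname SliceImage
#' @export
setGeneric("stainDay", function(x) standardGeneric("stainDay"))

#' @rdname LineProfile
#' @param x a [LineProfile-class].
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname LineProfile
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname LineProfile
#' @export
setGeneric("isNormalised", function(x) standardGeneric("isNormalised"))

#' @rdname EdgePair
#' @param x an [EdgePair-class].
#' @export
setGeneric("leftEdge", function(x) standardGeneric("leftEdge"))
#' @rdname EdgePair
#' @export
setGeneric("rightEdge", function(x) standardGeneric("rightEdge"))
#' @rdname EdgePair
#' @export
setGeneric("sampleWidth", function(x) standardGeneric("sampleWidth"))

#' @rdname FrontLocation
#' @param x a [FrontLocation-class].
#' @export
setGeneric("frontDepth", function(x) standardGeneric("frontDepth"))
#' @rdname FrontLocation
#' @export
setGeneric("frontFound", function(x) standardGeneric("frontFound"))

setMethod("pixels", "SliceImage", function(x) x@pixels)
setMethod("pixelSize", "SliceImage", function(x) x@pixelSize)
setMethod("sampleId", "SliceImage", function(x) x@sampleId)
setMethod("stain", "SliceImage", function(x) x@stain)
setMethod("stainDay", "SliceImage", function(x) x@day)

setMethod("positions", "LineProfile", function(x) x@positions)
setMethod("intensities", "LineProfile", function(x) x@values)
setMethod("isNormalised", "LineProfile", function(x) x@normalised)
setMethod("sampleId", "LineProfile", function(x) x@sampleId)
setMethod("stain", "LineProfile", function(x) x@stain)
setMethod("stainDay", "LineProfile", function(x) x@day)
setMethod("pixelSize", "LineProfile",
          function(x) if (length(x@positions) > 1L)
            x@positions[2L] - x@positions[1L] else NA_real_)

setMethod("leftEdge", "EdgePair", function(x) x@leftMm)
setMethod("rightEdge", "EdgePair", function(x) x@rightMm)
setMethod("sampleWidth", "EdgePair", function(x) x@rightMm - x@leftMm)

setMethod("frontDepth", "FrontLocation", function(x) x@depthMm)
setMethod("frontFound", "FrontLocation", function(x) x@found)

#' @describeIn SaturationFit-class fitted parameters as a named vector.
#' @param object a fit object.
#' @param ... ignored.
#' @export
setMethod("coef", "SaturationFit",
          function(object, ...) c(I0 = object@I0, Imax = object@Imax,
                                  k = object@k))

#' @describeIn StainTimeModel-class fitted parameters as a named vector.
#' @param object a fit object.
#' @param ... ignored.
#' @export
setMethod("coef", "StainTimeModel",
          function(object, ...) c(A = object@A, c = object@c))

#' @describeIn FrontModel-class fitted parameters as a named vector.
#' @param object a fit object.
#' @param ... ignored.
#' @export
setMethod("coef", "FrontModel",
          function(object, ...) c(C = object@C, K = object@K))

#' @describeIn SaturationFit-class linearised 95\% confidence limits
#'   (parameters x c(lower, upper)), or NULL when unavailable.
#' @param parm,level ignored (intervals are stored at 95\%).
#' @export
setMethod("confint", "SaturationFit",
          function(object, parm, level = 0.95, ...) object@ci)

#' @describeIn FrontModel-class linearised 95\% confidence limits.
#' @param parm,level ignored (intervals are stored at 95\%).
#' @export
setMethod("confint", "FrontModel",
          function(object, parm, level = 0.95, ...) object@ci)

setMethod("show", "SliceImage", function(object) {
  cat(sprintf("SliceImage %s [%s, day %d]: %d x %d px @ %.4g mm/px\n",
              object@sampleId, object@stain, object@day,
              nrow(object@pixels), ncol(object@pixels), object@pixelSize))
})

setMethod("show", "LineProfile", function(object) {
  cat(sprintf(
    "LineProfile %s [%s, day %d]: %d points over %.2f mm, width %d px%s\n",
    object@sampleId, object@stain, object@day, length(object@positions),
    diff(range(object@positions)), object@widthPx,
    if (object@normalised) ", normalised" else ""))
})

setMethod("show", "EdgePair", function(object) {
  cat(sprintf("EdgePair: left %.3f mm, right %.3f mm (width %.3f mm)\n",
              object@leftMm, object@rightMm, object@rightMm - object@leftMm))
})

setMethod("show", "FrontLocation", function(object) {
  if (object@found)
    cat(sprintf("FrontLocation: %.3f mm from %s edge\n", object@depthMm,
                object@side))
  else cat(sprintf("FrontLocation: no front found (%s side)\n", object@side))
})

setMethod("show", "SaturationFit", function(object) {
  cat(sprintf(
    "SaturationFit [%s%s]: I0 = %.4g, Imax = %.4g, k = %.4g /day (n = %s)\n",
    object@stain,
    if (!is.na(object@depthMm)) sprintf(", %.1f mm", object@depthMm) else "",
    object@I0, object@Imax, object@k,
    ifelse(is.na(object@n), "?", object@n)))
})

setMethod("show", "StainTimeModel", function(object) {
  cat(sprintf(
    "StainTimeModel (%.0f%% saturation): t = %.4g * exp(%.4g x) days\n",
    100 * object@level, object@A, object@c))
})

setMethod("show", "FrontModel", function(object) {
  cat(sprintf(
    "FrontModel [%s]: x(t) = %.4g (1 - exp(-%.4g t)) mm (n = %s)\n",
    object@stain, object@C, object@K, ifelse(is.na(object@n), "?", object@n)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec [%s mode, %s]: R0 = %.3g mm @ %.4g mm/px, days %s\n",
    object@mode, object@stain, object@radius0, object@pixelSize,
    paste(object@timepoints, collapse = ", ")))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth at t = %.3g d: R = %.4g mm%s\n", object@t,
              object@radiusMm,
              if (!is.na(object@frontDepthMm))
                sprintf(", front depth = %.4g mm", object@frontDepthMm)
              else ""))
})
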