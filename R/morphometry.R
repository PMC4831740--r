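# Cross-section segmentation by thresholding and shrinkage tracking.

# Otsu's threshold on a 256-bin histogram between the image min and max.
# Returns a value strictly between two histogram bin centres.
.otsuThreshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) stop("cannot threshold a constant image")
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE),
                           nbins))
  w <- cumsum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  m <- cumsum(h * mids)
  total <- w[nbins]
  mTot <- m[nbins]
  between <- (mTot * w - m * total)^2 / (w * (total - w))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Segment the sample cross-section in a slice
#'
#' Thresholds the slice (Otsu's method by default, or a fixed threshold),
#' keeps the largest 4-connected foreground component and fills its
#' interior holes. Hole filling matters because front-stained samples have
#' a bright rim and a dim unstained core that naive thresholding hollows
#' out.
#'
#' @param slice a [SliceImage-class].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold required when `method = "fixed"`: pixels strictly above
#'   it are foreground.
#' @return A logical mask matrix, same dimensions as the slice.
#' @export
segmentCrossSection <- function(slice, method = c("otsu", "fixed"),
                                threshold = NULL) {
  stopifnot(is(slice, "SliceImage"))
  method <- match.arg(method)
  px <- pixels(slice)
  thr <- switch(method,
    otsu = .otsuThreshold(as.vector(px)),
    fixed = {
      if (is.null(threshold)) stop("fixed method requires a threshold")
      threshold
    })
  fg <- px > thr
  if (!any(fg)) stop("segmentation failed: empty foreground at threshold ",
                     signif(thr, 4))
  lab <- .ccLabel(fg)
  keep <- which.max(tabulate(lab[lab > 0L]))
  mask <- lab == keep
  # fill holes: background components not connected to the image border
  bgLab <- .ccLabel(!mask)
  borderLabs <- unique(c(bgLab[1L, ], bgLab[nrow(bgLab), ],
                         bgLab[, 1L], bgLab[, ncol(bgLab)]))
  borderLabs <- borderLabs[borderLabs > 0L]
  mask | (bgLab > 0L & !(bgLab %in% borderLabs))
}

#' Cross-sectional area of a mask
#'
#' @param mask logical matrix from [segmentCrossSection()].
#' @param pixelSizeMm pixel size in mm.
#' @return area in mm^2 (pixel count times pixel area).
#' @examples
#' crossSectionalArea(matrix(TRUE, 10, 10), 0.0075)  # 100 px
#' @export
crossSectionalArea <- function(mask, pixelSizeMm) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("empty mask has no area")
  if (pixelSizeMm <= 0) stop("pixelSizeMm must be positive")
  sum(mask) * pixelSizeMm^2
}

#' Normalise a cross-sectional area series to its unstained baseline
#'
#' Divides each day's area by the day-0 (unstained) area, giving the
#' shrinkage trajectory plotted against staining time.
#'
#' @param days staining days (must include 0).
#' @param areasMm2 areas in mm^2, parallel to `days`.
#' @param sampleId,stain metadata carried into the result.
#' @return data.frame `sample`, `stain`, `day`, `area_mm2`,
#'   `normalized_area` (exactly 1 at day 0), ordered by day.
#' @export
normaliseAreaSeries <- function(days, areasMm2, sampleId = "sample",
                                stain = "other") {
  stopifnot(length(days) == length(areasMm2))
  if (!0 %in% days) stop("day 0 (unstained baseline) is required")
  if (anyDuplicated(days)) stop("duplicate days in area series")
  if (any(!is.finite(areasMm2)) || any(areasMm2 <= 0))
    stop("areas must be positive")
  o <- order(days)
  days <- days[o]; areasMm2 <- areasMm2[o]
  a0 <- areasMm2[days == 0]
  data.frame(sample = sampleId, stain = stain, day = days,
             area_mm2 = areasMm2, normalized_area = areasMm2 / a0)
}

#' Measure the shrinkage trajectory of a slice series
#'
#' Convenience wrapper: segments every slice, measures its area and
#' normalises to day 0.
#'
#' @param slices list of [SliceImage-class] for one sample across days.
#' @param method,threshold passed to [segmentCrossSection()].
#' @return As [normaliseAreaSeries()].
#' @export
areaSeries <- function(slices, method = "otsu", threshold = NULL) {
  stopifnot(length(slices) > 0L,
            all(vapply(slices, is, TRUE, "SliceImage")))
  areas <- vapply(slices, function(s) {
    crossSectionalArea(segmentCrossSection(s, method, threshold),
                       pixelSize(s))
  }, 0)
  normaliseAreaSeries(vapply(slices, stainDay, 0L), areas,
                      sampleId = sampleId(slices[[1L]]),
                      stain = stain(slices[[1L]]))
}
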