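# Line-profile extraction, cohort normalisation and the gradient-threshold
# detectors for sample edges and stain fronts.

#' Extract a width-averaged line profile from a slice
#'
#' Averages a horizontal band of `widthPx` rows centred on `row` (default:
#' the image centre row) and returns intensity against position in mm from
#' the image's left edge. A 10-pixel band suppresses single-row noise while
#' staying narrow against fascicle-scale structure.
#'
#' @param slice a [SliceImage-class].
#' @param row centre row index, or `"centre"`.
#' @param widthPx band width in pixels (>= 1).
#' @return A raw (un-normalised) [LineProfile-class].
#' @export
extractLineProfile <- function(slice, row = "centre", widthPx = 10L) {
  stopifnot(is(slice, "SliceImage"))
  px <- pixels(slice)
  widthPx <- as.integer(widthPx)
  if (widthPx < 1L) stop("widthPx must be >= 1")
  if (identical(row, "centre")) row <- (nrow(px) + 1L) %/% 2L
  row <- as.integer(row)
  rows <- seq.int(row - (widthPx - 1L) %/% 2L, length.out = widthPx)
  if (rows[1L] < 1L || rows[widthPx] > nrow(px))
    stop("averaging band [", rows[1L], ", ", rows[widthPx],
         "] exceeds image bounds (", nrow(px), " rows)")
  vals <- if (widthPx == 1L) px[rows, ] else colMeans(px[rows, , drop = FALSE])
  LineProfile(positions = (seq_len(ncol(px)) - 1L) * pixelSize(slice),
              values = vals, widthPx = widthPx, sampleId = sampleId(slice),
              stain = stain(slice), day = stainDay(slice),
              normalised = FALSE)
}

#' Normalise a cohort of line profiles by their single global maximum
#'
#' Every intensity in every profile is divided by the one maximum recorded
#' across the whole collection, so that exactly one point in the cohort
#' equals 1.0 and all values are comparable across samples, stains and
#' days. Normalising per profile instead would erase the between-day
#' intensity growth the kinetics fits rely on.
#'
#' @param profiles a list of raw [LineProfile-class] objects (a single
#'   profile is accepted).
#' @return A list of normalised profiles (same order).
#' @export
normaliseCohort <- function(profiles) {
  if (is(profiles, "LineProfile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("empty profile collection")
  stopifnot(all(vapply(profiles, is, TRUE, "LineProfile")))
  gmax <- max(vapply(profiles, function(p) max(intensities(p)), 0))
  if (!is.finite(gmax) || gmax <= 0)
    stop("cannot normalise: global maximum intensity is not positive")
  lapply(profiles, function(p) {
    initialize(p, values = intensities(p) / gmax, normalised = TRUE)
  })
}

# Gaussian kernel truncated at 4 sigma, renormalised to sum 1.
.gaussKernel <- function(sigmaPx) {
  r <- ceiling(4 * sigmaPx)
  k <- dnorm(seq.int(-r, r), sd = sigmaPx)
  k / sum(k)
}

#' Smooth a profile with a Gaussian kernel
#'
#' Discrete convolution with a Gaussian of standard deviation `sigmaPx`
#' pixels, truncated at 4 sigma and renormalised to sum 1. Boundaries are
#' handled by edge replication, so a constant profile passes through
#' unchanged.
#'
#' @param p a [LineProfile-class].
#' @param sigmaPx kernel standard deviation in pixels (default 4, i.e.
#'   0.03 mm at 7.5 um/pixel).
#' @return The smoothed profile.
#' @export
smoothProfile <- function(p, sigmaPx = 4) {
  stopifnot(is(p, "LineProfile"))
  if (!is.numeric(sigmaPx) || sigmaPx <= 0) stop("sigmaPx must be positive")
  k <- .gaussKernel(sigmaPx)
  r <- (length(k) - 1L) %/% 2L
  v <- intensities(p)
  if (length(v) < length(k))
    stop("profile (", length(v), " points) shorter than kernel support (",
         length(k), ")")
  padded <- c(rep(v[1L], r), v, rep(v[length(v)], r))
  sm <- stats::filter(padded, k, sides = 2)
  initialize(p, values = as.numeric(sm[(r + 1L):(r + length(v))]))
}

#' Intensity gradient of a profile, per mm
#'
#' Central differences in the interior, one-sided differences at the two
#' ends, divided by the (uniform) spacing in mm.
#'
#' @param p a [LineProfile-class] with at least 3 points.
#' @return Numeric vector of gradients (intensity units per mm), one per
#'   profile point.
#' @export
gradientPerMm <- function(p) {
  stopifnot(is(p, "LineProfile"))
  v <- intensities(p)
  n <- length(v)
  if (n < 3L) stop("gradient needs at least 3 points")
  h <- pixelSize(p)
  g <- numeric(n)
  g[1L] <- (v[2L] - v[1L]) / h
  g[n] <- (v[n] - v[n - 1L]) / h
  g[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * h)
  g
}

# Walk along gradient values from `from` (exclusive) to `to` and return the
# first index where the gradient is approximately zero: |g| < tol, or the
# gradient changes sign between consecutive samples (the sample nearer zero
# is taken). The sign-change clause matters on noise-free data, where the
# filtered gradient can step across the whole ±tol band between samples.
.walkToZero <- function(g, from, to, tol) {
  if (from == to) return(NA_integer_)
  step <- if (to > from) 1L else -1L
  prev <- from
  for (j in seq(from + step, to, by = step)) {
    if (abs(g[j]) < tol) return(j)
    if (g[j] * g[prev] < 0)
      return(if (abs(g[j]) < abs(g[prev])) j else prev)
    prev <- j
  }
  NA_integer_
}

#' Detect the two sample edges on a line profile
#'
#' Three-stage gradient rule on the Gaussian-filtered profile:
#' \enumerate{
#'   \item smooth with `sigmaPx` ([smoothProfile()]);
#'   \item locate the global maximum of the gradient (the rising flank where
#'     the profile climbs from background into the sample) and walk toward
#'     the sample centre to the first point where |gradient| < `zeroTol` —
#'     the left edge;
#'   \item locate the global minimum of the gradient and walk from it toward
#'     the centre to the first near-zero-gradient point — the right edge
#'     (the mirror rule: the last near-zero point before the minimum when
#'     read from the centre outward).
#' }
#' Thresholds apply to the gradient of the normalised profile per mm.
#' "Approximately zero" also accepts a sign change of the gradient between
#' consecutive samples (the sample nearer zero is taken): on clean data the
#' filtered gradient can step across the whole tolerance band at once.
#'
#' @param p a normalised [LineProfile-class] covering
#'   background-sample-background.
#' @param zeroTol near-zero gradient threshold (normalised intensity / mm).
#' @param sigmaPx Gaussian filter width in pixels.
#' @return An [EdgePair-class].
#' @export
detectSampleEdges <- function(p, zeroTol = 0.01, sigmaPx = 4) {
  stopifnot(is(p, "LineProfile"))
  g <- gradientPerMm(smoothProfile(p, sigmaPx))
  pos <- positions(p)
  imax <- which.max(g)
  imin <- which.min(g)
  if (g[imax] <= zeroTol || g[imin] >= -zeroTol)
    stop("no edge: profile gradient never exceeds the zero tolerance")
  if (imax >= imin)
    stop("edge detection failed: rising flank not left of falling flank")
  ileft <- .walkToZero(g, imax, imin, zeroTol)
  iright <- .walkToZero(g, imin, imax, zeroTol)
  if (is.na(ileft) || is.na(iright))
    stop("edge detection failed: gradient never settles below zeroTol")
  if (ileft >= iright)
    stop("edge detection failed: detected edges cross")
  EdgePair(pos[ileft], pos[iright])
}

#' Local neighbourhood average of a profile
#'
#' Replaces each point by the mean intensity within a centred window of
#' `windowMm`, truncated at the profile ends — removing short-length-scale
#' sample variability before depth-resolved intensities are read off. A
#' window narrower than the pixel spacing leaves the profile unchanged.
#'
#' @param p a [LineProfile-class].
#' @param windowMm full window width in mm (default 0.1).
#' @return The locally averaged profile.
#' @export
neighbourhoodAverage <- function(p, windowMm = 0.1) {
  stopifnot(is(p, "LineProfile"))
  if (windowMm < 0) stop("windowMm must be >= 0")
  v <- intensities(p)
  n <- length(v)
  h <- pixelSize(p)
  hw <- floor(windowMm / 2 / h + 1e-9)
  if (hw < 1L) return(p)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  initialize(p, values = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Detect the stain-front edge inward of a sample edge
#'
#' Moving from the given sample edge toward the sample centre along the
#' Gaussian-filtered profile (gradient taken along the inward direction),
#' the first point whose gradient is below `-dropTol` marks the descent
#' into the unstained core; the next point inward where |gradient| <
#' `zeroTol` is the front edge. `found = FALSE` is returned when no point
#' passes the drop threshold — a bulk-stained (or unstained) sample has no
#' steep front — or when the descent never settles before the sample
#' centre (front at or beyond the centre: effectively fully stained).
#'
#' @param p a normalised [LineProfile-class].
#' @param edges the [EdgePair-class] from [detectSampleEdges()].
#' @param side `"left"` or `"right"`: which edge to walk inward from.
#' @param dropTol gradient drop threshold (default 0.2, normalised
#'   intensity / mm).
#' @param zeroTol near-zero gradient threshold.
#' @param sigmaPx Gaussian filter width in pixels.
#' @return A [FrontLocation-class]; `frontDepth()` is the distance from the
#'   sample edge in mm.
#' @export
detectStainFront <- function(p, edges, side = c("left", "right"),
                             dropTol = 0.2, zeroTol = 0.01, sigmaPx = 4) {
  stopifnot(is(p, "LineProfile"), is(edges, "EdgePair"))
  side <- match.arg(side)
  pos <- positions(p)
  if (leftEdge(edges) < pos[1L] || rightEdge(edges) > pos[length(pos)])
    stop("edges lie outside the profile extent")
  g <- gradientPerMm(smoothProfile(p, sigmaPx))
  centreMm <- (leftEdge(edges) + rightEdge(edges)) / 2
  if (side == "left") {
    idx <- which(pos >= leftEdge(edges) & pos <= centreMm)
    ginward <- g[idx]
    edgeMm <- leftEdge(edges)
    depth <- pos[idx] - edgeMm
  } else {
    idx <- rev(which(pos <= rightEdge(edges) & pos >= centreMm))
    ginward <- -g[idx]
    edgeMm <- rightEdge(edges)
    depth <- edgeMm - pos[idx]
  }
  drop <- which(ginward < -dropTol)[1L]
  if (is.na(drop)) return(FrontLocation(NA_real_, side, found = FALSE))
  settle <- .walkToZero(ginward, drop, length(ginward), zeroTol)
  if (is.na(settle)) return(FrontLocation(NA_real_, side, found = FALSE))
  FrontLocation(depth[settle], side, found = TRUE)
}

#' Depth-resolved intensity series across staining days
#'
#' For one sample scanned on several days, reads the neighbourhood-averaged
#' intensity at fixed depth increments inward from each detected edge and
#' averages the two sides, producing the intensity(depth, day) table the
#' per-depth saturation fits consume. Depths beyond a day's half-width are
#' recorded as `NA` (the sample may have shrunk).
#'
#' @param profiles list of normalised [LineProfile-class], one per day.
#' @param edges list of [EdgePair-class], parallel to `profiles`.
#' @param incrementMm depth step in mm (default 0.1).
#' @param maxDepthMm deepest increment; default: the largest half-width
#'   across days, rounded down to the increment.
#' @param windowMm neighbourhood-averaging window ([neighbourhoodAverage()]).
#' @return A data.frame with columns `sample`, `stain`, `day`, `depth_mm`,
#'   `intensity` (side-averaged), `intensity_left`, `intensity_right`.
#' @export
toDepthSeries <- function(profiles, edges, incrementMm = 0.1,
                          maxDepthMm = NULL, windowMm = 0.1) {
  stopifnot(length(profiles) >= 1L, length(profiles) == length(edges),
            all(vapply(profiles, is, TRUE, "LineProfile")),
            all(vapply(edges, is, TRUE, "EdgePair")))
  ids <- unique(vapply(profiles, sampleId, ""))
  if (length(ids) != 1L)
    stop("profiles come from different samples: ",
         paste(ids, collapse = ", "))
  if (is.null(maxDepthMm)) {
    hw <- vapply(edges, function(e) sampleWidth(e) / 2, 0)
    maxDepthMm <- floor(max(hw) / incrementMm) * incrementMm
  }
  depths <- seq(0, maxDepthMm, by = incrementMm)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- neighbourhoodAverage(profiles[[i]], windowMm)
    e <- edges[[i]]
    halfw <- sampleWidth(e) / 2
    readAt <- function(x) {
      out <- approx(positions(p), intensities(p), xout = x, rule = 1)$y
      out[depths > halfw + 1e-9] <- NA_real_
      out
    }
    left <- readAt(leftEdge(e) + depths)
    right <- readAt(rightEdge(e) - depths)
    data.frame(sample = sampleId(p), stain = stain(p), day = stainDay(p),
               depth_mm = depths,
               intensity = rowMeans(cbind(left, right), na.rm = FALSE),
               intensity_left = left, intensity_right = right)
  })
  do.call(rbind, rows)
}
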