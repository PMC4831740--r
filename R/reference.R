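#' Reference fitted constants for porcine ligament/tendon staining
#'
#' Model constants reported for 10\% w/v I2KI, PTA and PMA staining of
#' porcine knee ligaments and tendons imaged by laboratory micro-CT at
#' 7.5 um/voxel, shipped with the package so staining-time and feasibility
#' predictions can be made without refitting:
#' \describe{
#'   \item{saturation}{[SaturationFit-class] per stain — intensity at 1 mm
#'     depth against staining time (I2KI: I0 = 0.065, Imax = 0.357,
#'     k = 1.108/day; PTA: 0.068, 0.648, 0.489; PMA: 0.073, 0.401, 0.920).}
#'   \item{stainTime}{[StainTimeModel-class] per saturation level for
#'     I2KI-type bulk staining (90\%: A = 1.007 d, c = 0.313/mm; 95\%:
#'     1.336, 0.315; 99\%: 2.100, 0.317).}
#'   \item{front}{[FrontModel-class] per front-forming stain (PTA:
#'     C = 3.094 mm, K = 0.367/day; PMA: C = 2.056 mm, K = 0.607/day).}
#' }
#' The constants are also available as plain text in
#' `system.file("extdata", "reference_fits.csv", package = "StainKinetics")`.
#'
#' @return A list with elements `saturation`, `stainTime` and `front`, each
#'   a named list of model objects.
#' @examples
#' ref <- referenceFits()
#' saturationFraction(ref$saturation$I2KI, 4)      # ~0.99 of Imax by day 4
#' predictStainingTime(ref$stainTime$`90`, 1.5)    # ~1.6 days
#' maxPenetrationDepth(ref$front$PMA)              # ~2.1 mm radius limit
#' @export
referenceFits <- function() {
  path <- system.file("extdata", "reference_fits.csv",
                      package = "StainKinetics")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  sat <- tab[tab$model == "saturation", ]
  stt <- tab[tab$model == "staining_time", ]
  fro <- tab[tab$model == "front", ]
  list(
    saturation = setNames(lapply(seq_len(nrow(sat)), function(i)
      SaturationFit(I0 = sat$p1[i], Imax = sat$p2[i], k = sat$p3[i],
                    depthMm = 1, stain = sat$label[i])), sat$label),
    stainTime = setNames(lapply(seq_len(nrow(stt)), function(i)
      StainTimeModel(A = stt$p1[i], c = stt$p2[i],
                     level = stt$p3[i])), stt$label),
    front = setNames(lapply(seq_len(nrow(fro)), function(i)
      FrontModel(C = fro$p1[i], K = fro$p2[i], stain = fro$label[i])),
      fro$label))
}
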