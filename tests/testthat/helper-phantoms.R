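# Small, fast phantom specs used across the suite. Tests that exercise the
# acceptance-scale geometry (3 mm radius at 7.5 um/px) construct their own.

smallSaturating <- function(...) {
  args <- utils::modifyList(
    list(mode = "saturating", radius0 = 1, noiseSigma = 0, seed = 101L,
         sampleId = "sat1", stain = "I2KI"), list(...))
  do.call(PhantomSpec, args)
}

smallFront <- function(...) {
  args <- utils::modifyList(
    list(mode = "front", radius0 = 1, C = 0.8, K = 0.5, frontWidth = 0.15,
         noiseSigma = 0, seed = 102L, sampleId = "fr1", stain = "PTA"),
    list(...))
  do.call(PhantomSpec, args)
}

# normalised centre profile of one generated phantom slice
phantomProfile <- function(spec, t, widthPx = 10L) {
  sl <- generatePhantomSlice(spec, t)$slice
  normaliseCohort(list(extractLineProfile(sl, widthPx = widthPx)))[[1L]]
}

randomProfile <- function(n = 80L, seed = 1L) {
  set.seed(seed)
  LineProfile(positions = (0:(n - 1L)) * 0.0075, values = runif(n))
}
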