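# Plain-text (P2) NetPBM grayscale I/O. The toolchain here has no TIFF/PNG
# reader, and PGM is the simplest standard grayscale interchange format that
# stays text-only; 16-bit depth matches the dynamic range of the detectors
# this pipeline targets.

#' Write a slice as a plain (ASCII) 16-bit PGM image
#'
#' Intensities are clipped to [0, 1] and quantised to `maxval` levels.
#' Metadata (sample, stain, day, pixel size) is stored in comment lines so a
#' cohort round-trips through disk without a side table.
#'
#' @param slice a [SliceImage-class] with values in [0, 1].
#' @param path output file path (conventionally `.pgm`).
#' @param maxval maximum gray value (default 65535, i.e. 16-bit).
#' @return `path`, invisibly.
#' @seealso [readPGM()]
#' @export
writePGM <- function(slice, path, maxval = 65535L) {
  stopifnot(is(slice, "SliceImage"))
  px <- pmin(pmax(pixels(slice), 0), 1)
  q <- round(px * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "P2",
    sprintf("# sample=%s stain=%s day=%d pixel_size_mm=%.10g",
            sampleId(slice), stain(slice), stainDay(slice),
            pixelSize(slice)),
    sprintf("%d %d", ncol(q), nrow(q)),
    sprintf("%d", maxval)), con)
  # one image row per line; PGM allows arbitrary whitespace
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain (ASCII) PGM image written by [writePGM()]
#'
#' Values are rescaled to [0, 1] by dividing by the file's maxval. Metadata
#' comments written by [writePGM()] are restored; absent metadata falls back
#' to the arguments.
#'
#' @param path file path.
#' @param pixelSize fallback pixel size in mm when the file has no metadata.
#' @param sampleId,stain,day fallback metadata.
#' @return A [SliceImage-class].
#' @export
readPGM <- function(path, pixelSize = 0.0075, sampleId = "sample",
                    stain = "other", day = 0L) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "P2")
    stop("not a plain (P2) PGM file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  for (m in meta) {
    kv <- regmatches(m, gregexpr("[a-z_]+=[^ ]+", m))[[1L]]
    for (pair in kv) {
      key <- sub("=.*", "", pair)
      val <- sub("^[a-z_]+=", "", pair)
      switch(key,
             sample = sampleId <- val,
             stain = stain <- val,
             day = day <- as.integer(val),
             pixel_size_mm = pixelSize <- as.numeric(val))
    }
  }
  body <- lines[!grepl("^#", lines)][-1L]  # drop magic, keep header + data
  tokens <- scan(text = paste(body, collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  nc <- as.integer(tokens[1L]); nr <- as.integer(tokens[2L])
  maxval <- tokens[3L]
  vals <- tokens[-(1:3)]
  if (length(vals) != nr * nc)
    stop("corrupt PGM (expected ", nr * nc, " pixels, got ", length(vals),
         "): ", path)
  mat <- matrix(vals / maxval, nrow = nr, ncol = nc, byrow = TRUE)
  SliceImage(mat, pixelSize = pixelSize, sampleId = sampleId, stain = stain,
             day = day)
}
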