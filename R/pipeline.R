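# End-to-end pipeline: cohort on disk -> profiles -> detectors -> kinetics
# fits -> morphometry -> statistics, with every stage's output written as
# CSV/JSON and every detector decision logged.

#' Default pipeline configuration
#'
#' Detector and fit parameters with the defaults the detectors were
#' designed around: a 10-pixel profile band, sigma = 4 px Gaussian filter,
#' near-zero gradient tolerance 0.01 /mm, front drop threshold 0.2 /mm,
#' 0.1 mm neighbourhood window and 0.1 mm depth increments, saturation
#' levels 90/95/99\%.
#'
#' @param ... named overrides of any field.
#' @return A named list (the pipeline config).
#' @export
pipelineConfig <- function(...) {
  cfg <- list(widthPx = 10L, sigmaPx = 4, zeroTol = 0.01, dropTol = 0.2,
              windowMm = 0.1, incrementMm = 0.1,
              levels = c(0.90, 0.95, 0.99), segMethod = "otsu",
              segThreshold = NULL, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a config list as from [pipelineConfig()].
#' @return `cfg`, invisibly; stops with a message listing every violated
#'   field otherwise.
#' @export
validatePipelineConfig <- function(cfg) {
  bad <- character()
  chkPos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad <<- c(bad, paste0(field, " must be a single positive number"))
  }
  for (f in c("widthPx", "sigmaPx", "zeroTol", "dropTol", "windowMm",
              "incrementMm")) chkPos(f)
  lv <- cfg$levels
  if (!is.numeric(lv) || length(lv) == 0L || any(lv <= 0 | lv >= 1) ||
      is.unsorted(lv, strictly = TRUE))
    bad <- c(bad, "levels must be strictly increasing fractions in (0, 1)")
  if (!cfg$segMethod %in% c("otsu", "fixed"))
    bad <- c(bad, "segMethod must be 'otsu' or 'fixed'")
  if (length(bad))
    stop("invalid pipeline config:\n  ", paste(bad, collapse = "\n  "))
  invisible(cfg)
}

#' Simulate a phantom cohort on disk
#'
#' Thin logged wrapper over [generateCohort()]: validates the specs, writes
#' the slices and manifest, and reports what was written.
#'
#' @param specs a [PhantomSpec-class] or list of them.
#' @param outDir output directory.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly.
#' @export
simulateCohort <- function(specs, outDir, quiet = FALSE) {
  manifest <- generateCohort(specs, outDir)
  if (!quiet)
    message("wrote ", length(manifest$files), " slice(s) + manifest to ",
            outDir)
  invisible(manifest)
}

.logLine <- function(log, ...) c(log, paste0(...))

#' Run the full staining-kinetics pipeline on a cohort directory
#'
#' Reads every slice named in the cohort manifest, then:
#' \enumerate{
#'   \item extracts width-averaged centre line profiles and normalises the
#'     whole cohort by its single global maximum intensity;
#'   \item detects sample edges and (per side) stain fronts on every
#'     profile, logging each decision;
#'   \item builds the depth-resolved intensity series per sample, fits the
#'     saturation model at each depth, derives staining times per level and
#'     fits the staining-time-against-depth model (bulk-staining samples);
#'   \item fits the front-propagation model per sample from the detected
#'     front depths (front-forming samples);
#'   \item segments each slice and tracks normalised cross-sectional area;
#'   \item when >= 2 stains are present, runs the two-way day x stain ANOVA
#'     on the intensity 1 mm into each sample and on normalised areas, plus
#'     Tukey comparisons between stains.
#' }
#' Detection failures never abort the run: downstream stages receive
#' flagged missing values.
#'
#' @param cohortDir directory holding slices and `manifest.json`.
#' @param outDir output directory for result files.
#' @param config a [pipelineConfig()] list.
#' @param quiet suppress progress messages.
#' @return A result bundle (list): `profiles`, `depthSeries`,
#'   `depthFits`, `stainTimes`, `stainTimeModels`, `frontTable`,
#'   `frontModels`, `areas`, `stats`, `log`, plus `files` naming every
#'   file written.
#' @export
runPipeline <- function(cohortDir, outDir, config = pipelineConfig(),
                        quiet = FALSE) {
  validatePipelineConfig(config)
  manifest <- readCohortManifest(cohortDir)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  log <- character()

  # stage 1: profiles, cohort-wide normalisation
  slices <- list(); raw <- list()
  for (s in manifest$samples) {
    for (tp in s$timepoints) {
      path <- file.path(cohortDir, tp$file)
      if (!file.exists(path)) stop("slice listed in manifest missing: ", path)
      sl <- readPGM(path)
      key <- paste0(s$sample, "_day", stainDay(sl))
      slices[[key]] <- sl
      raw[[key]] <- extractLineProfile(sl, widthPx = config$widthPx)
    }
  }
  profiles <- normaliseCohort(raw)
  names(profiles) <- names(raw)
  log <- .logLine(log, "normalised ", length(profiles),
                  " profiles by cohort-wide maximum")

  profTab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample = sampleId(p), stain = stain(p), day = stainDay(p),
               position_mm = positions(p), intensity = intensities(p))))

  # stage 2: edges and fronts
  edgeRows <- list(); frontRows <- list()
  edges <- list()
  for (key in names(profiles)) {
    p <- profiles[[key]]
    e <- tryCatch(detectSampleEdges(p, zeroTol = config$zeroTol,
                                    sigmaPx = config$sigmaPx),
                  error = function(err) err)
    if (inherits(e, "error")) {
      log <- .logLine(log, key, ": edge detection failed: ",
                      conditionMessage(e))
      next
    }
    edges[[key]] <- e
    log <- .logLine(log, key, sprintf(": edges %.3f / %.3f mm",
                                      leftEdge(e), rightEdge(e)))
    edgeRows[[key]] <- data.frame(sample = sampleId(p), stain = stain(p),
                                  day = stainDay(p),
                                  left_mm = leftEdge(e),
                                  right_mm = rightEdge(e))
    fr <- lapply(c("left", "right"), function(side) {
      f <- detectStainFront(p, e, side, dropTol = config$dropTol,
                            zeroTol = config$zeroTol,
                            sigmaPx = config$sigmaPx)
      log <<- .logLine(log, key, " ", side, ": ",
                       if (frontFound(f))
                         sprintf("front at %.3f mm", frontDepth(f))
                       else "no front")
      data.frame(sample = sampleId(p), stain = stain(p), day = stainDay(p),
                 side = side, found = frontFound(f),
                 depth_mm = frontDepth(f))
    })
    frontRows[[key]] <- do.call(rbind, fr)
  }
  edgeTab <- if (length(edgeRows))
    do.call(rbind, c(edgeRows, list(make.row.names = FALSE))) else NULL
  frontTab <- if (length(frontRows))
    do.call(rbind, c(frontRows, list(make.row.names = FALSE))) else NULL

  # stage 3: depth series, per-depth saturation fits, staining-time models
  sampleIds <- vapply(manifest$samples, function(s) s$sample, "")
  depthSeries <- list(); depthFits <- list(); stainTimes <- list()
  stainTimeModels <- list()
  for (sid in sampleIds) {
    keys <- names(profiles)[vapply(profiles, sampleId, "") == sid]
    keys <- keys[keys %in% names(edges)]
    if (length(keys) < 2L) {
      log <- .logLine(log, sid, ": < 2 days with detected edges, ",
                      "skipping depth series")
      next
    }
    ds <- toDepthSeries(profiles[keys], edges[keys],
                        incrementMm = config$incrementMm,
                        windowMm = config$windowMm)
    depthSeries[[sid]] <- ds
    fits <- tryCatch(fitDepthProfile(ds), error = function(e) NULL)
    if (is.null(fits)) {
      log <- .logLine(log, sid, ": saturation fits failed at every depth")
      next
    }
    depthFits[[sid]] <- fits
    if (length(attr(fits, "failed")))
      log <- .logLine(log, sid, ": no saturation fit at depths ",
                      paste(attr(fits, "failed"), collapse = ", "), " mm")
    st <- stainingTimeTable(fits, config$levels)
    st$sample <- sid
    stainTimes[[sid]] <- st
    stainTimeModels[[sid]] <- lapply(setNames(config$levels,
                                              paste0("t", round(100 * config$levels))),
      function(f) {
        col <- paste0("t", round(100 * f))
        tryCatch(fitStainingTimeModel(st$depth_mm, st[[col]], level = f),
                 error = function(e) {
                   log <<- .logLine(log, sid, ": staining-time model (",
                                    col, ") failed: ", conditionMessage(e))
                   NULL
                 })
      })
  }

  # stage 4: front models per sample (average of the two sides per day)
  frontModels <- list()
  if (!is.null(frontTab) && nrow(frontTab)) {
    for (sid in sampleIds) {
      sub <- frontTab[frontTab$sample == sid, ]
      if (!nrow(sub)) next
      byDay <- split(sub, sub$day)
      days <- as.numeric(names(byDay))
      depth <- vapply(byDay, function(d) {
        v <- d$depth_mm[d$found]
        if (length(v)) mean(v) else NA_real_
      }, 0)
      fm <- tryCatch(fitFrontModel(days, depth, stain = sub$stain[1L]),
                     error = function(e) {
                       log <<- .logLine(log, sid, ": front model skipped: ",
                                        conditionMessage(e))
                       NULL
                     })
      if (!is.null(fm)) frontModels[[sid]] <- fm
    }
  }

  # stage 5: morphometry
  areaRows <- lapply(sampleIds, function(sid) {
    keys <- names(slices)[vapply(slices, sampleId, "") == sid]
    tryCatch(areaSeries(slices[keys], method = config$segMethod,
                        threshold = config$segThreshold),
             error = function(e) {
               log <<- .logLine(log, sid, ": morphometry failed: ",
                                conditionMessage(e))
               NULL
             })
  })
  areaTab <- do.call(rbind, areaRows)

  # stage 6: statistics across stains
  statsTab <- NULL
  depthAll <- if (length(depthSeries)) do.call(rbind, depthSeries) else NULL
  if (!is.null(depthAll)) {
    at1 <- depthAll[abs(depthAll$depth_mm - 1) < 1e-9 &
                      is.finite(depthAll$intensity), ]
    statsTab <- rbind(
      .anovaRows(at1, "intensity_1mm", at1$intensity),
      .anovaRows(areaTab, "normalized_area", areaTab$normalized_area))
  }
  if (is.null(statsTab) || !nrow(statsTab))
    log <- .logLine(log, "statistics skipped (needs >= 2 stains and days)")

  # write everything
  files <- c(profiles = "profiles.csv", depth = "depth_series.csv",
             edges = "edges.csv", fronts = "front_table.csv",
             stainTimes = "staining_times.csv", areas = "areas.csv",
             stats = "stats.csv", fits = "fits.json", log = "log.txt")
  wr <- function(df, f) if (!is.null(df) && nrow(df))
    write.csv(df, file.path(outDir, f), row.names = FALSE)
  wr(profTab, files["profiles"])
  wr(depthAll, files["depth"])
  wr(edgeTab, files["edges"])
  wr(frontTab, files["fronts"])
  if (length(stainTimes)) wr(do.call(rbind, stainTimes), files["stainTimes"])
  wr(areaTab, files["areas"])
  wr(statsTab, files["stats"])
  writeFitsJson(list(stainTimeModels = stainTimeModels,
                     frontModels = frontModels, depthFits = depthFits),
                file.path(outDir, files["fits"]))
  writeLines(log, file.path(outDir, files["log"]))
  if (!quiet) message("pipeline wrote ", length(files), " files to ", outDir)

  invisible(list(profiles = profiles, depthSeries = depthAll,
                 depthFits = depthFits,
                 stainTimes = if (length(stainTimes))
                   do.call(rbind, stainTimes) else NULL,
                 stainTimeModels = stainTimeModels,
                 frontTable = frontTab, frontModels = frontModels,
                 areas = areaTab, stats = statsTab, log = log,
                 files = file.path(outDir, files)))
}

.anovaRows <- function(df, what, values) {
  if (is.null(df) || !nrow(df)) return(NULL)
  if (length(unique(df$stain)) < 2L || length(unique(df$day)) < 2L)
    return(NULL)
  av <- tryCatch(twoWayAnova(values, df$day, df$stain),
                 error = function(e) NULL)
  if (is.null(av)) return(NULL)
  av$response <- what
  av
}

#' Serialise fitted models to JSON
#'
#' Writes saturation, staining-time and front models as records of
#' `{model, parameters, ci, residual_norm, n, provenance}` that
#' [readFitsJson()] restores losslessly.
#'
#' @param fits a (possibly nested) list of [SaturationFit-class],
#'   [StainTimeModel-class] and [FrontModel-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFitsJson <- function(fits, path) {
  enc <- function(x) {
    if (is(x, "SaturationFit"))
      list(model = "saturation", parameters = as.list(coef(x)),
           se = x@se, ci = x@ci, residual_norm = x@residualNorm, n = x@n,
           provenance = list(depth_mm = x@depthMm, stain = x@stain))
    else if (is(x, "StainTimeModel"))
      list(model = "staining_time", parameters = as.list(coef(x)),
           level = x@level)
    else if (is(x, "FrontModel"))
      list(model = "front", parameters = as.list(coef(x)), se = x@se,
           ci = x@ci, residual_norm = x@residualNorm, n = x@n,
           provenance = list(stain = x@stain))
    else if (is.list(x)) lapply(x, enc)
    else x
  }
  jsonlite::write_json(enc(fits), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Restore fitted models written by [writeFitsJson()]
#'
#' @param path JSON file.
#' @return The nested list of model objects.
#' @export
readFitsJson <- function(path) {
  num <- function(v, len = length(v)) {   # JSON null -> NA
    if (is.null(v) || len == 0L) return(NA_real_)
    vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e), 0)
  }
  dec <- function(x) {
    if (is.list(x) && !is.null(x$model)) {
      pr <- x$parameters
      ci <- if (!is.null(x$ci))  # serialised row-wise
        matrix(unlist(x$ci), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("lower", "upper")))
      switch(x$model,
        saturation = SaturationFit(pr$I0, pr$Imax, pr$k,
          se = num(x$se), ci = ci, residualNorm = num(x$residual_norm, 1L),
          n = if (is.null(x$n)) NA_integer_ else x$n,
          depthMm = num(x$provenance$depth_mm, 1L),
          stain = x$provenance$stain),
        staining_time = StainTimeModel(pr$A, pr$c, level = x$level),
        front = FrontModel(pr$C, pr$K, se = num(x$se), ci = ci,
          residualNorm = num(x$residual_norm, 1L),
          n = if (is.null(x$n)) NA_integer_ else x$n,
          stain = x$provenance$stain),
        stop("unknown model type: ", x$model))
    } else if (is.list(x)) lapply(x, dec)
    else x
  }
  dec(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Staining-time and feasibility report
#'
#' For each staining-time model, the predicted time to reach its saturation
#' level at `depthMm`; for each front model, whether a sample of radius
#' `radiusMm` can ever be fully penetrated (radius vs the asymptotic
#' maximum depth `C`).
#'
#' @param fits a list with elements `stainTime` (list of
#'   [StainTimeModel-class]) and/or `front` (list of [FrontModel-class]) —
#'   e.g. [referenceFits()] — or a path to a [writeFitsJson()] file.
#' @param depthMm target depth in mm (>= 0) for staining-time predictions.
#' @param radiusMm sample radius in mm for front feasibility verdicts
#'   (defaults to `depthMm`).
#' @return data.frame `model`, `label`, `level`, `depth_mm`,
#'   `predicted_days`, `max_depth_mm`, `feasible`.
#' @examples
#' predictStainingReport(referenceFits(), depthMm = 1.5)
#' @export
predictStainingReport <- function(fits, depthMm, radiusMm = depthMm) {
  if (is.character(fits)) fits <- readFitsJson(fits)
  if (!is.numeric(depthMm) || depthMm < 0) stop("depthMm must be >= 0")
  rows <- list()
  for (nm in names(fits$stainTime)) {
    m <- fits$stainTime[[nm]]
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      model = "staining_time", label = nm, level = m@level,
      depth_mm = depthMm, predicted_days = predictStainingTime(m, depthMm),
      max_depth_mm = NA_real_, feasible = NA)
  }
  for (nm in names(fits$front)) {
    m <- fits$front[[nm]]
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      model = "front", label = nm, level = NA_real_, depth_mm = radiusMm,
      predicted_days = NA_real_, max_depth_mm = maxPenetrationDepth(m),
      feasible = radiusMm <= maxPenetrationDepth(m))
  }
  if (!length(rows)) stop("no models found in fits")
  do.call(rbind, rows)
}
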