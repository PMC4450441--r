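## End-to-end orchestration: mask -> segment -> link -> measure ->
## depth-filter -> classify -> (optional) validate.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Unknown keys are
#' rejected so config typos fail loudly. The configuration is a plain
#' named list and serialises to/from JSON via [writeConfig()] /
#' [readConfig()].
#'
#' @param ... overrides of the defaults, by name: segmentation (`gaussSd`,
#'   `thresholdRadius`, `thresholdOffset`, `minRegionArea`,
#'   `closingRadius`), linking (`maxCentroidDist`, `maxAreaChange`,
#'   `maxZExtentPlanes`, `minPlanes`), depth filter (`depthMethod`,
#'   `depthTol`, `dCut`), classification (`fallbackThreshold`,
#'   `minSeparation`, `minFold`), and `seed`.
#' @return named list of parameters.
#' @examples
#' cfg <- pipelineConfig(thresholdRadius = 30)
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    gaussSd = 2, thresholdRadius = 40, thresholdOffset = 0.02,
    minRegionArea = 50, closingRadius = 5,
    maxCentroidDist = 20, maxAreaChange = 0.5, maxZExtentPlanes = 6,
    minPlanes = 2,
    depthMethod = "plateau", depthTol = 0.15, dCut = NULL,
    fallbackThreshold = 10, minSeparation = 1, minFold = 2,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("config overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    for (k in names(over)) cfg[k] <- list(over[[k]])
  }
  cfg
}

#' @rdname pipelineConfig
#' @param config a configuration list.
#' @param path JSON file path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full quantification pipeline on one stack
#'
#' Executes mask, segment, link, measure, depth-filter and classify on a
#' stack, and (when ground truth is supplied) the validation audit. The
#' per-stage counts mirror a per-run statistics table: planes, 2D
#' regions, reconstructed 3D cells, measured cells, depth-included cells.
#'
#' @param stack an [ImageStack].
#' @param config list from [pipelineConfig()].
#' @param truth optional [GroundTruth] for validation.
#' @param rootId identifier stored in the cell table.
#' @param classify fit ON/OFF states per reporter channel (requires >= 20
#'   eligible cells; skipped with a message otherwise).
#' @param outDir optional directory; when given, the per-cell CSV, the
#'   depth-profile CSV, a JSON run log of all parameters, and one PNG heat
#'   map per plane are written there.
#' @return list with `cellTable` (one row per reconstructed cell:
#'   measurements, `included`, and `state_<channel>` calls for included
#'   non-border cells), `profile`, `dCut`, `report` (named stage counts),
#'   `segs`, `cells` (the [CellSet]), and when `truth` is given `pairing`
#'   and `validation`.
#' @export
runPipeline <- function(stack, config = pipelineConfig(), truth = NULL,
                        rootId = 1L, classify = TRUE, outDir = NULL) {
  stopifnot(is(stack, "ImageStack"))
  segs <- .stage("segment", suppressWarnings(segmentStack(
    stack, gaussSd = config$gaussSd,
    thresholdRadius = config$thresholdRadius,
    thresholdOffset = config$thresholdOffset,
    minRegionArea = config$minRegionArea,
    closingRadius = config$closingRadius)))
  criteria <- LinkCriteria(config$maxCentroidDist, config$maxAreaChange,
                           config$maxZExtentPlanes, config$minPlanes)
  cells <- .stage("link", linkPlanes(segs, criteria, stack@zStepUm))
  meas <- .stage("measure", measureCells(cells, segs, stack,
                                         rootId = rootId))
  if (nrow(meas) > 0) {
    df <- .stage("depth-filter", suppressWarnings(depthFilter(
      meas, method = config$depthMethod, tol = config$depthTol,
      dCut = config$dCut)))
    meas <- df$measurements
    profile <- df$profile
    dCut <- df$dCut
  } else {
    profile <- data.frame(depthUm = numeric(), meanIntensity = numeric(),
                          nCells = integer(), accepted = logical())
    dCut <- NA_real_
  }

  chans <- grep("^reporter_", channelNames(stack), value = TRUE)
  if (classify && nrow(meas) > 0) {
    eligible <- meas$included & !meas$border
    for (ch in chans) {
      col <- paste0("state_", ch)
      meas[[col]] <- NA_character_
      if (sum(eligible) >= 20L) {
        cls <- .stage("classify", classifyStates(
          meas[[paste0("mean_", ch)]][eligible],
          fallbackThreshold = config$fallbackThreshold,
          minSeparation = config$minSeparation,
          minFold = config$minFold))
        meas[[col]][eligible] <- cls$state
      } else {
        message("fewer than 20 eligible cells; skipping state calls for ",
                ch)
      }
    }
  }

  report <- c(nPlanes = nPlanes(stack),
              nRegions2D = sum(vapply(segs, function(s) nrow(segTable(s)), 1L)),
              nCells3D = nrow(cells@cells),
              nMeasured = nrow(meas),
              nIncluded = if (nrow(meas)) sum(meas$included) else 0L)
  out <- list(cellTable = meas, profile = profile, dCut = dCut,
              report = report, segs = segs, cells = cells)
  if (!is.null(truth)) {
    out$pairing <- .stage("validate", matchCells(cells, segs, truth))
    if (nrow(meas) > 0)
      out$validation <- .stage("validate", suppressWarnings(accuracyAudit(
        out$pairing, meas[meas$included, , drop = FALSE], truth,
        seed = config$seed)))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCellTable(meas, file.path(outDir, "cells.csv"))
    write.csv(profile, file.path(outDir, "depth_profile.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = config, report = as.list(report), dCut = dCut),
      file.path(outDir, "run_log.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    if (nrow(meas) > 0)
      for (p in seq_len(nPlanes(stack)))
        writeHeatmapPng(renderHeatmap(segs, cells, meas, p),
                        file.path(outDir, sprintf("heatmap_plane%02d.png", p)))
  }
  out
}

## integer translation with zero fill
.translate <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  srcR <- max(1, 1 - dr):min(nrow(m), nrow(m) - dr)
  srcC <- max(1, 1 - dc):min(ncol(m), ncol(m) - dc)
  if (length(srcR) < 1 || length(srcC) < 1) return(out)
  out[srcR + dr, srcC + dc] <- m[srcR, srcC]
  out
}

## phase-correlation drift of plane b relative to plane a (row, col).
## The correlation peak search is restricted to |shift| <= maxShift:
## periodic structures (regular cell grids) have secondary peaks at
## lattice multiples that an unrestricted argmax can latch onto.
.phaseShift <- function(a, b, maxShift = 20L) {
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fa * Conj(Fb)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  sr <- c(0:min(maxShift, nr - 1), seq(nr - 1, max(nr - maxShift, 1))) %% nr
  sc <- c(0:min(maxShift, nc - 1), seq(nc - 1, max(nc - maxShift, 1))) %% nc
  sub <- r[unique(sr) + 1, unique(sc) + 1, drop = FALSE]
  k <- which.max(sub)
  i <- unique(sr)[(k - 1) %% nrow(sub) + 1]
  j <- unique(sc)[(k - 1) %/% nrow(sub) + 1]
  if (i > nr / 2) i <- i - nr
  if (j > nc / 2) j <- j - nc
  c(i, j)
}

#' Register a stack by per-plane translation
#'
#' Estimates the integer translation of each wall-channel plane relative
#' to the previous plane by phase correlation, accumulates the shifts
#' relative to the first plane, and applies the inverse shift identically
#' to all channels. Synthetic stacks are pre-aligned, so this is off by
#' default in the pipeline.
#'
#' @param stack an [ImageStack] (>= 2 planes for any effect).
#' @return list with `stack` (registered) and `shifts` (planes x 2 matrix
#'   of the estimated drift of each plane, rows then columns).
#' @export
alignStack <- function(stack) {
  nz <- nPlanes(stack)
  shifts <- matrix(0L, nz, 2, dimnames = list(NULL, c("row", "col")))
  if (nz < 2L) return(list(stack = stack, shifts = shifts))
  wall <- getChannel(stack, "wall")
  for (p in 2:nz) {
    d <- .phaseShift(wall[, , p - 1], wall[, , p])
    shifts[p, ] <- shifts[p - 1, ] - as.integer(d)
  }
  voxels <- stack@voxels
  for (ch in names(voxels))
    for (p in 2:nz)
      if (any(shifts[p, ] != 0L))
        voxels[[ch]][, , p] <- .translate(voxels[[ch]][, , p],
                                          -shifts[p, 1], -shifts[p, 2])
  list(stack = ImageStack(voxels, stack@pxPerUm, stack@zStepUm),
       shifts = shifts)
}
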