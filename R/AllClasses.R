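#' Geometry of a synthetic root meristem
#'
#' Describes the idealised meristem the synthetic generator renders: a slab
#' of `zPlanes/cellDepthPlanes` cell layers, each a rectangular grid of
#' `nFiles` longitudinal files times `cellsPerFile` cells. Physical
#' calibration follows the imaging setup this package targets: 0.249 um per
#' pixel in-plane (2048 px = 510 um) and a 3-um z-step.
#'
#' @slot nFiles integer, lateral cell files per layer.
#' @slot cellsPerFile integer, cells along the root axis per file.
#' @slot cellLengthPx,cellWidthPx integer, cell extents in pixels (axis,
#'   lateral).
#' @slot wallWidthPx integer, rendered cell-wall thickness in pixels.
#' @slot nucleusRadiusUm numeric, nuclear radius in micrometres. The
#'   default (3.5) makes each nucleus intersect 2-3 consecutive planes at
#'   the default 3-um z-step.
#' @slot zPlanes integer, number of confocal planes; must be a multiple of
#'   `cellDepthPlanes`.
#' @slot cellDepthPlanes integer, z-extent of one cell layer in planes.
#' @slot zStepUm numeric, z spacing in micrometres.
#' @slot pxPerUm numeric, in-plane pixels per micrometre.
#' @slot marginPx integer, background margin around the tissue.
#' @aliases RootGeometry
#' @exportClass RootGeometry
setClass("RootGeometry", representation(
  nFiles = "integer", cellsPerFile = "integer",
  cellLengthPx = "integer", cellWidthPx = "integer", wallWidthPx = "integer",
  nucleusRadiusUm = "numeric", zPlanes = "integer", cellDepthPlanes = "integer",
  zStepUm = "numeric", pxPerUm = "numeric", marginPx = "integer"
))

setValidity("RootGeometry", function(object) {
  msg <- character()
  cnt <- c(nFiles = object@nFiles, cellsPerFile = object@cellsPerFile,
           cellLengthPx = object@cellLengthPx, cellWidthPx = object@cellWidthPx,
           zPlanes = object@zPlanes, cellDepthPlanes = object@cellDepthPlanes)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@zStepUm <= 0 || object@pxPerUm <= 0)
    msg <- c(msg, "zStepUm and pxPerUm must be positive")
  if (object@zPlanes %% object@cellDepthPlanes != 0L)
    msg <- c(msg, "zPlanes must be a multiple of cellDepthPlanes")
  dPx <- 2 * object@nucleusRadiusUm * object@pxPerUm
  inner <- min(object@cellLengthPx, object@cellWidthPx) - 2 * object@wallWidthPx
  if (dPx >= inner)
    msg <- c(msg, sprintf(
      "nucleus (diameter %.1f px) does not fit inside the cell cross-section (%d px)",
      dPx, inner))
  if (2 * object@nucleusRadiusUm >= object@cellDepthPlanes * object@zStepUm)
    msg <- c(msg, "nucleus does not fit inside the cell depth")
  if (length(msg)) msg else TRUE
})

#' @param nFiles,cellsPerFile,cellLengthPx,cellWidthPx,wallWidthPx,nucleusRadiusUm,zPlanes,cellDepthPlanes,zStepUm,pxPerUm,marginPx see slots.
#' @return A `RootGeometry` object.
#' @examples
#' RootGeometry(nFiles = 3, cellsPerFile = 6)
#' @rdname RootGeometry-class
#' @export
RootGeometry <- function(nFiles = 4, cellsPerFile = 12, cellLengthPx = 50,
                         cellWidthPx = 40, wallWidthPx = 2,
                         nucleusRadiusUm = 3.5, zPlanes = 12,
                         cellDepthPlanes = 4, zStepUm = 3.0,
                         pxPerUm = 1 / 0.249, marginPx = 40) {
  new("RootGeometry", nFiles = as.integer(nFiles),
      cellsPerFile = as.integer(cellsPerFile),
      cellLengthPx = as.integer(cellLengthPx),
      cellWidthPx = as.integer(cellWidthPx),
      wallWidthPx = as.integer(wallWidthPx),
      nucleusRadiusUm = nucleusRadiusUm, zPlanes = as.integer(zPlanes),
      cellDepthPlanes = as.integer(cellDepthPlanes), zStepUm = zStepUm,
      pxPerUm = pxPerUm, marginPx = as.integer(marginPx))
}

#' Expression model for the synthetic generator
#'
#' Holds the stochastic model of reporter expression: the probability that
#' a clonal cell file is ON, whether the two reporters share one heritable
#' state per file (`trans`) or draw states independently (`cis`), reporter
#' intensities, detector noise, per-plane photobleaching and per-cell
#' biological intensity variability.
#'
#' @slot pOn numeric in `[0, 1]`, probability a cell file is in the ON state.
#' @slot memoryMode `"cis"` or `"trans"`.
#' @slot nReporters 1 or 2 nuclear reporter channels.
#' @slot onIntensity,offIntensity nuclear fluorescence (a.u.) of ON and OFF
#'   cells; `onIntensity > offIntensity >= 0`.
#' @slot noiseSd additive Gaussian detector noise sd (a.u.), clipped at 0.
#' @slot bleachRate fractional intensity loss per plane of depth
#'   (acquisition order).
#' @slot intensityCv lognormal coefficient of variation of per-cell
#'   intensity, truncated to `[0.5, 2]` times the state intensity so ON and
#'   OFF populations never overlap in the ground truth.
#' @slot switchNoise probability a single cell flips away from its file
#'   state (default 0; exposed for robustness testing).
#' @slot wallIntensity,tissueIntensity rendered wall-channel levels (a.u.).
#' @slot baselineIntensity tissue autofluorescence baseline (a.u.) rendered
#'   into the reporter channels over the whole tissue; keeps low-signal
#'   pixels away from the detector's zero clip, as in real acquisitions.
#' @aliases ExpressionModel
#' @exportClass ExpressionModel
setClass("ExpressionModel", representation(
  pOn = "numeric", memoryMode = "character", nReporters = "integer",
  onIntensity = "numeric", offIntensity = "numeric", noiseSd = "numeric",
  bleachRate = "numeric", intensityCv = "numeric", switchNoise = "numeric",
  wallIntensity = "numeric", tissueIntensity = "numeric",
  baselineIntensity = "numeric"
))

setValidity("ExpressionModel", function(object) {
  msg <- character()
  if (object@pOn < 0 || object@pOn > 1) msg <- c(msg, "pOn must be in [0, 1]")
  if (!object@memoryMode %in% c("cis", "trans"))
    msg <- c(msg, "memoryMode must be 'cis' or 'trans'")
  if (!object@nReporters %in% 1:2) msg <- c(msg, "nReporters must be 1 or 2")
  if (object@offIntensity < 0) msg <- c(msg, "offIntensity must be >= 0")
  if (object@onIntensity <= object@offIntensity)
    msg <- c(msg, "onIntensity must exceed offIntensity")
  if (object@bleachRate < 0 || object@bleachRate >= 1)
    msg <- c(msg, "bleachRate must be in [0, 1)")
  if (object@switchNoise < 0 || object@switchNoise > 1)
    msg <- c(msg, "switchNoise must be in [0, 1]")
  if (object@noiseSd < 0 || object@intensityCv < 0 ||
      object@baselineIntensity < 0)
    msg <- c(msg, "noiseSd, intensityCv and baselineIntensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param pOn,memoryMode,nReporters,onIntensity,offIntensity,noiseSd,bleachRate,intensityCv,switchNoise,wallIntensity,tissueIntensity,baselineIntensity see slots.
#' @return An `ExpressionModel` object.
#' @examples
#' ExpressionModel(pOn = 0.5, memoryMode = "cis", nReporters = 2)
#' @rdname ExpressionModel-class
#' @export
ExpressionModel <- function(pOn = 0.5, memoryMode = c("cis", "trans"),
                            nReporters = 1, onIntensity = 100,
                            offIntensity = 10, noiseSd = 5,
                            bleachRate = 0.01, intensityCv = 0.2,
                            switchNoise = 0, wallIntensity = 200,
                            tissueIntensity = 30, baselineIntensity = 5) {
  new("ExpressionModel", pOn = pOn, memoryMode = match.arg(memoryMode),
      nReporters = as.integer(nReporters), onIntensity = onIntensity,
      offIntensity = offIntensity, noiseSd = noiseSd, bleachRate = bleachRate,
      intensityCv = intensityCv, switchNoise = switchNoise,
      wallIntensity = wallIntensity, tissueIntensity = tissueIntensity,
      baselineIntensity = baselineIntensity)
}

#' Multi-channel confocal image stack
#'
#' A named list of 3D voxel arrays (row, column, plane), one per channel,
#' with physical calibration. Plane 1 is the top (first-acquired) focal
#' plane. The wall channel is named `"wall"`; reporters are
#' `"reporter_1"` (and `"reporter_2"`).
#'
#' @slot voxels named list of numeric 3D arrays sharing dimensions.
#' @slot pxPerUm in-plane pixels per micrometre.
#' @slot zStepUm z spacing in micrometres.
#' @aliases ImageStack
#' @exportClass ImageStack
setClass("ImageStack", representation(
  voxels = "list", pxPerUm = "numeric", zStepUm = "numeric"
))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(object@voxels) == 0L) return("stack has no channels")
  if (is.null(names(object@voxels)) || any(names(object@voxels) == ""))
    msg <- c(msg, "channels must be named")
  dims <- lapply(object@voxels, dim)
  if (!all(vapply(dims, length, 1L) == 3L))
    msg <- c(msg, "each channel must be a 3D array")
  else if (length(unique(lapply(dims, as.integer))) != 1L)
    msg <- c(msg, "all channels must share dimensions")
  if (object@zStepUm <= 0) msg <- c(msg, "zStepUm must be positive")
  if (length(msg)) msg else TRUE
})

#' @param voxels,pxPerUm,zStepUm see slots.
#' @return An `ImageStack` object.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(voxels, pxPerUm = 1 / 0.249, zStepUm = 3.0) {
  new("ImageStack", voxels = voxels, pxPerUm = pxPerUm, zStepUm = zStepUm)
}

#' Ground truth for a synthetic root
#'
#' Pairs every true cell with its geometry, clonal file membership, plane
#' span, true ON/OFF state per reporter and true (noise- and bleach-free)
#' mean intensity, plus a voxel-level label array of true cell ids.
#'
#' @slot cells data.frame, one row per true cell.
#' @slot labels integer 3D array (row, column, plane) of true cell ids
#'   (0 = no cell: background, walls).
#' @slot geometry the [RootGeometry] used.
#' @slot layout list with per-layer tissue rectangles and axial offsets.
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  cells = "data.frame", labels = "array", geometry = "RootGeometry",
  layout = "list"
))

#' Segmentation of one z-plane into candidate 2D cell regions
#'
#' @slot planeIndex 1-based plane index.
#' @slot labels integer matrix; 0 = background/wall, k >= 1 = region k.
#' @slot table data.frame with per-label `label`, `area` (px^2),
#'   `crow`, `ccol` (centroid, px) and `border` flag.
#' @aliases PlaneSegmentation
#' @exportClass PlaneSegmentation
setClass("PlaneSegmentation", representation(
  planeIndex = "integer", labels = "matrix", table = "data.frame"
))

setValidity("PlaneSegmentation", function(object) {
  tab <- object@table
  need <- c("label", "area", "crow", "ccol", "border")
  if (!all(need %in% names(tab))) return("table lacks required columns")
  TRUE
})

#' Criteria for linking 2D regions across neighbouring planes
#'
#' Two regions in adjacent planes belong to the same 3D cell when their
#' centroids are within `maxCentroidDist` pixels and their relative area
#' difference `|a1 - a2| / max(a1, a2)` does not exceed `maxAreaChange`;
#' chains are limited to `maxZExtentPlanes` planes (18 um at a 3-um step).
#' Chains shorter than `minPlanes` planes are discarded as segmentation
#' noise (nuclei span 2-3 planes, so a bona fide cell is corroborated by
#' at least one neighbouring plane).
#'
#' @slot maxCentroidDist numeric, pixels (default 20).
#' @slot maxAreaChange numeric, fraction (default 0.5).
#' @slot maxZExtentPlanes integer (default 6).
#' @slot minPlanes integer (default 2; set 1 to keep single-plane cells).
#' @aliases LinkCriteria
#' @exportClass LinkCriteria
setClass("LinkCriteria", representation(
  maxCentroidDist = "numeric", maxAreaChange = "numeric",
  maxZExtentPlanes = "integer", minPlanes = "integer"
))

setValidity("LinkCriteria", function(object) {
  if (object@maxCentroidDist <= 0 || object@maxAreaChange <= 0 ||
      object@maxZExtentPlanes < 1L || object@minPlanes < 1L)
    "all criteria must be positive" else TRUE
})

#' @param maxCentroidDist,maxAreaChange,maxZExtentPlanes,minPlanes see slots.
#' @return A `LinkCriteria` object.
#' @examples
#' LinkCriteria()
#' @rdname LinkCriteria-class
#' @export
LinkCriteria <- function(maxCentroidDist = 20, maxAreaChange = 0.5,
                         maxZExtentPlanes = 6, minPlanes = 2) {
  new("LinkCriteria", maxCentroidDist = maxCentroidDist,
      maxAreaChange = maxAreaChange,
      maxZExtentPlanes = as.integer(maxZExtentPlanes),
      minPlanes = as.integer(minPlanes))
}

#' Set of reconstructed 3D cells
#'
#' @slot cells data.frame, one row per reconstructed cell: `cellId`,
#'   `nPlanes`, `planeLo`, `planeHi`, `totalAreaPx` (the volume proxy),
#'   `depthUm` (mean distance from the top focal plane), `crow`, `ccol`,
#'   `border` flag.
#' @slot regions data.frame mapping each cell to its member 2D regions:
#'   `cellId`, `plane`, `label`, `area`, `crow`, `ccol`.
#' @slot criteria the [LinkCriteria] used.
#' @aliases CellSet
#' @exportClass CellSet
setClass("CellSet", representation(
  cells = "data.frame", regions = "data.frame", criteria = "LinkCriteria"
))

#' Result of the two-reporter cis-vs-trans memory test
#'
#' @slot counts named integer vector of file-level joint states
#'   (`on_on`, `on_off`, `off_on`, `off_off`).
#' @slot statistic observed fraction of mixed-state (ON/OFF or OFF/ON) files.
#' @slot pValue parametric-bootstrap p-value under the trans null.
#' @slot pSymmetry exact two-sided binomial p-value for the symmetry of the
#'   ON/OFF vs OFF/ON counts.
#' @slot errorRate estimated per-cell call-error rate (within-file discordance).
#' @slot pOn estimated probability a file is ON under the null.
#' @slot nFiles number of files tested.
#' @slot nBoot bootstrap replicates.
#' @aliases CisTransResult
#' @exportClass CisTransResult
setClass("CisTransResult", representation(
  counts = "integer", statistic = "numeric", pValue = "numeric",
  pSymmetry = "numeric", errorRate = "numeric", pOn = "numeric",
  nFiles = "integer", nBoot = "integer"
))

#' Accuracy audit of the automated pipeline against reference measurements
#'
#' @slot nChecked number of sampled cells.
#' @slot nAccurate number within tolerance of the reference.
#' @slot accuracy fraction accurate.
#' @slot tolerance relative-error tolerance used.
#' @slot errors data.frame with per-sampled-cell automated and reference
#'   means and relative error (NA for unpaired, i.e. missegmented, cells).
#' @aliases ValidationReport
#' @exportClass ValidationReport
setClass("ValidationReport", representation(
  nChecked = "integer", nAccurate = "integer", accuracy = "numeric",
  tolerance = "numeric", errors = "data.frame"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "RootGeometry", function(object) {
  nl <- object@zPlanes %/% object@cellDepthPlanes
  cat("RootGeometry:", object@nFiles, "files/layer x", object@cellsPerFile,
      "cells x", nl, "layers =", object@nFiles * nl * object@cellsPerFile,
      "cells\n")
  cat(sprintf("  cell %d x %d px, wall %d px, nucleus r = %.1f um\n",
              object@cellLengthPx, object@cellWidthPx, object@wallWidthPx,
              object@nucleusRadiusUm))
  cat(sprintf("  %d planes, z-step %.1f um, %.3f px/um\n", object@zPlanes,
              object@zStepUm, object@pxPerUm))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels[[1]])
  cat(sprintf("ImageStack: %d x %d px, %d planes, channels: %s\n",
              d[1], d[2], d[3], paste(names(object@voxels), collapse = ", ")))
  cat(sprintf("  %.3f px/um, z-step %.1f um\n", object@pxPerUm, object@zStepUm))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@cells), "cells in",
      length(unique(object@cells$fileId)), "files\n")
})

setMethod("show", "PlaneSegmentation", function(object) {
  cat("PlaneSegmentation: plane", object@planeIndex, "with",
      nrow(object@table), "regions\n")
})

setMethod("show", "CellSet", function(object) {
  cat("CellSet:", nrow(object@cells), "reconstructed cells from",
      nrow(object@regions), "2D regions\n")
})

setMethod("show", "CisTransResult", function(object) {
  cat("Two-reporter cis/trans memory test\n")
  cat("  files:", object@nFiles, " counts:",
      paste(names(object@counts), object@counts, collapse = ", "), "\n")
  cat(sprintf("  mixed-state fraction = %.3f, bootstrap p = %.4g (trans null, B = %d)\n",
              object@statistic, object@pValue, object@nBoot))
  cat(sprintf("  ON/OFF vs OFF/ON symmetry: binomial p = %.4g\n",
              object@pSymmetry))
  cat(sprintf("  estimated call error = %.3f, P(file ON) = %.3f\n",
              object@errorRate, object@pOn))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf(
    "ValidationReport: %d/%d cells accurate (%.1f%%) at %.0f%% relative-error tolerance\n",
    object@nAccurate, object@nChecked, 100 * object@accuracy,
    100 * object@tolerance))
})
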