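## Synthetic root-meristem generator.
##
## The meristem is idealised as a slab of cell layers stacked in z; each
## layer is a rectangular grid of rounded cell files (nFiles across,
## cellsPerFile along the axis). Alternate layers are offset axially by
## half a cell length so that cells in different layers are never mistaken
## for one another by the centroid-based 3D linking. Clonal files share an
## ON/OFF expression state per reporter; nuclei are spheres rendered into
## the reporter channels; walls are bright ridges in the wall channel.

#' ON probability as a function of cold exposure
#'
#' Maps weeks of cold to the probability that a clonal cell file keeps the
#' reporter in the ON state. A logistic decay reproduces the qualitative
#' series seen in vernalization experiments: essentially all files ON
#' without cold, a bimodal ON/OFF population around 6-8 weeks and nearly
#' complete silencing by 10 weeks.
#'
#' @param weeks numeric, weeks of cold exposure (>= 0).
#' @param halfWeeks cold duration at which half the files are silenced.
#' @param slopeWeeks logistic slope (weeks).
#' @return numeric vector of ON probabilities, monotone decreasing in
#'   `weeks`.
#' @examples
#' pOnFromColdWeeks(c(0, 2, 4, 6, 8, 10))
#' @export
pOnFromColdWeeks <- function(weeks, halfWeeks = 6, slopeWeeks = 1.3) {
  stopifnot(all(weeks >= 0), slopeWeeks > 0)
  stats::plogis(-(weeks - halfWeeks) / slopeWeeks)
}

#' Draw heritable file states under a cis or trans memory model
#'
#' Under `trans` memory the expression state is stored in diffusible
#' factors, so both reporter copies in a file share one Bernoulli(pOn)
#' draw; under `cis` memory each reporter copy draws its state
#' independently, allowing mixed ON/OFF files.
#'
#' @param nFiles number of clonal files.
#' @param pOn probability a file (or file-reporter copy) is ON.
#' @param memoryMode `"cis"` or `"trans"`.
#' @param nReporters 1 or 2.
#' @param seed optional integer seed.
#' @return logical matrix `nFiles x nReporters`; `TRUE` = ON.
#' @examples
#' drawFileStates(5, 0.5, "trans", 2, seed = 1)
#' @export
drawFileStates <- function(nFiles, pOn, memoryMode = c("cis", "trans"),
                           nReporters = 1, seed = NULL) {
  memoryMode <- match.arg(memoryMode)
  stopifnot(nFiles >= 1, pOn >= 0, pOn <= 1, nReporters %in% 1:2)
  if (!is.null(seed)) set.seed(seed)
  if (memoryMode == "trans") {
    s <- runif(nFiles) < pOn
    matrix(s, nFiles, nReporters)
  } else {
    matrix(runif(nFiles * nReporters) < pOn, nFiles, nReporters)
  }
}

## per-cell lognormal intensity factor, truncated to [0.5, 2] so that the
## ON and OFF ground-truth populations can never overlap (ON:OFF >= 10:1
## by default, and 10 * 0.5 > 1 * 2).
.intensityFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  f <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  pmin(pmax(f, 0.5), 2)
}

## static layout of the cell grid: per-layer rectangle, axial offsets,
## per-layer wall mask and true cell-label image
.rootLayout <- function(geometry) {
  g <- geometry
  nLayers <- g@zPlanes %/% g@cellDepthPlanes
  axOff <- ((seq_len(nLayers) - 1L) %% 2L) * (g@cellLengthPx %/% 2L)
  gridRows <- g@cellsPerFile * g@cellLengthPx
  gridCols <- g@nFiles * g@cellWidthPx
  nrow <- 2L * g@marginPx + gridRows + max(axOff)
  ncol <- 2L * g@marginPx + gridCols
  w <- g@wallWidthPx

  layers <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    r0 <- g@marginPx + axOff[l]          # 0-based top row of the grid
    c0 <- g@marginPx
    rowRel <- seq_len(nrow) - 1L - r0    # 0-based position within the grid
    colRel <- seq_len(ncol) - 1L - c0
    inR <- rowRel >= 0L & rowRel < gridRows
    inC <- colRel >= 0L & colRel < gridCols
    # wall bands: w/2 px on each side of every cell boundary
    bandR <- inR & (rowRel %% g@cellLengthPx < ceiling(w / 2) |
                    rowRel %% g@cellLengthPx >= g@cellLengthPx - floor(w / 2))
    bandC <- inC & (colRel %% g@cellWidthPx < ceiling(w / 2) |
                    colRel %% g@cellWidthPx >= g@cellWidthPx - floor(w / 2))
    tissue <- outer(inR, inC, "&")
    wall <- tissue & (outer(bandR, inC, "&") | outer(inR, bandC, "&"))
    # cell index per pixel (0 outside tissue)
    cIdx <- ifelse(inR, rowRel %/% g@cellLengthPx + 1L, 0L)
    fIdx <- ifelse(inC, colRel %/% g@cellWidthPx + 1L, 0L)
    lab <- outer(cIdx, fIdx, function(a, b)
      ifelse(a > 0L & b > 0L, (b - 1L) * g@cellsPerFile + a, 0L))
    lab[wall | !tissue] <- 0L
    layers[[l]] <- list(tissue = tissue, wall = wall, labels = lab,
                        rowOffset = r0, colOffset = c0)
  }
  list(nrow = nrow, ncol = ncol, nLayers = nLayers, axOff = axOff,
       layers = layers)
}

#' Generate a synthetic root-meristem z-stack with ground truth
#'
#' Renders a two- or three-channel confocal stack (cell-wall channel plus
#' one channel per reporter) of an idealised root meristem, together with
#' voxel-level ground truth: per-cell file membership, plane span, true
#' ON/OFF state and true mean intensity per reporter. All randomness is
#' governed by `seed`, split into independent sub-streams for expression
#' states, geometric jitter, and detector noise, so states are
#' reproducible independently of noise.
#'
#' True mean intensities are defined on the noise-free, bleach-free
#' rendering; photobleaching (`bleachRate`) and detector noise act on the
#' rendered stack only, exactly as they corrupt a real acquisition.
#'
#' @param geometry a [RootGeometry].
#' @param expression an [ExpressionModel].
#' @param seed integer master seed.
#' @return list with elements `stack` (an [ImageStack]) and `truth`
#'   (a [GroundTruth]).
#' @examples
#' r <- generateRoot(RootGeometry(nFiles = 2, cellsPerFile = 3, zPlanes = 4,
#'                                cellDepthPlanes = 4),
#'                   ExpressionModel(pOn = 1), seed = 1)
#' r$stack
#' head(truthCells(r$truth))
#' @export
generateRoot <- function(geometry = RootGeometry(),
                         expression = ExpressionModel(), seed = 1L) {
  validObject(geometry); validObject(expression)
  g <- geometry; e <- expression
  set.seed(seed)
  subs <- sample.int(.Machine$integer.max - 1L, 3L)

  lay <- .rootLayout(g)
  nLayers <- lay$nLayers
  nCellsLayer <- g@nFiles * g@cellsPerFile
  nCells <- nCellsLayer * nLayers
  nFilesTotal <- g@nFiles * nLayers
  rPx <- g@nucleusRadiusUm * g@pxPerUm
  layerDepthUm <- g@cellDepthPlanes * g@zStepUm

  ## --- expression states (sub-stream 1) ---------------------------------
  set.seed(subs[1])
  fileOn <- drawFileStates(nFilesTotal, e@pOn, e@memoryMode, e@nReporters)
  cellLayer <- rep(seq_len(nLayers), each = nCellsLayer)
  cellWithin <- rep(seq_len(nCellsLayer), nLayers)          # layer-local id
  cellFileLateral <- (cellWithin - 1L) %/% g@cellsPerFile + 1L
  cellFile <- (cellLayer - 1L) * g@nFiles + cellFileLateral  # global file id
  cellOn <- fileOn[cellFile, , drop = FALSE]
  if (e@switchNoise > 0) {
    flip <- matrix(runif(nCells * e@nReporters) < e@switchNoise,
                   nCells, e@nReporters)
    cellOn <- xor(cellOn, flip)
  }
  fac <- matrix(.intensityFactors(nCells * e@nReporters, e@intensityCv),
                nCells, e@nReporters)
  nucInt <- ifelse(cellOn, e@onIntensity, e@offIntensity) * fac

  ## --- geometric jitter (sub-stream 2) ----------------------------------
  set.seed(subs[2])
  cellRow0 <- lay$layers[[1]]$rowOffset  # recomputed per layer below
  cellCtrRow <- cellCtrCol <- zCtr <- numeric(nCells)
  maxJit <- max(0, min(g@cellWidthPx, g@cellLengthPx) / 2 - g@wallWidthPx -
                  rPx - 1)
  jit <- min(2, maxJit)
  for (i in seq_len(nCells)) {
    l <- cellLayer[i]
    cw <- (cellWithin[i] - 1L) %% g@cellsPerFile  # 0-based cell along axis
    f <- cellFileLateral[i] - 1L
    cellCtrRow[i] <- lay$layers[[l]]$rowOffset + cw * g@cellLengthPx +
      g@cellLengthPx / 2 + runif(1, -jit, jit)
    cellCtrCol[i] <- lay$layers[[l]]$colOffset + f * g@cellWidthPx +
      g@cellWidthPx / 2 + runif(1, -jit, jit)
    z0 <- (l - 1L) * layerDepthUm
    zCtr[i] <- z0 + runif(1, g@nucleusRadiusUm,
                          layerDepthUm - g@nucleusRadiusUm)
  }

  ## --- render (deterministic given the above) ---------------------------
  labels3d <- array(0L, c(lay$nrow, lay$ncol, g@zPlanes))
  wallCh <- array(0, c(lay$nrow, lay$ncol, g@zPlanes))
  repCh <- replicate(e@nReporters,
                     array(0, c(lay$nrow, lay$ncol, g@zPlanes)),
                     simplify = FALSE)
  planeLayer <- (seq_len(g@zPlanes) - 1L) %/% g@cellDepthPlanes + 1L
  zOfPlane <- (seq_len(g@zPlanes) - 1L) * g@zStepUm
  for (p in seq_len(g@zPlanes)) {
    L <- lay$layers[[planeLayer[p]]]
    pw <- matrix(0, lay$nrow, lay$ncol)
    pw[L$tissue] <- e@tissueIntensity
    pw[L$wall] <- e@wallIntensity
    wallCh[, , p] <- pw
    if (e@baselineIntensity > 0)
      for (k in seq_len(e@nReporters)) {
        pr <- repCh[[k]][, , p]
        pr[L$tissue] <- pr[L$tissue] + e@baselineIntensity
        repCh[[k]][, , p] <- pr
      }
    lab <- L$labels + 0L
    lab[lab > 0L] <- lab[lab > 0L] + (planeLayer[p] - 1L) * nCellsLayer
    labels3d[, , p] <- lab
  }

  nucVox <- integer(nCells)
  nucPlanes <- integer(nCells)
  for (i in seq_len(nCells)) {
    l <- cellLayer[i]
    planes <- which(planeLayer == l)
    for (p in planes) {
      dz <- abs(zOfPlane[p] - zCtr[i])
      if (dz >= g@nucleusRadiusUm) next
      rad <- sqrt(g@nucleusRadiusUm^2 - dz^2) * g@pxPerUm
      rr <- max(1L, floor(cellCtrRow[i] - rad)):min(lay$nrow, ceiling(cellCtrRow[i] + rad))
      cc <- max(1L, floor(cellCtrCol[i] - rad)):min(lay$ncol, ceiling(cellCtrCol[i] + rad))
      disk <- outer((rr - cellCtrRow[i])^2, (cc - cellCtrCol[i])^2, "+") <= rad^2
      if (!any(disk)) next
      nucPlanes[i] <- nucPlanes[i] + 1L
      nucVox[i] <- nucVox[i] + sum(disk)
      for (k in seq_len(e@nReporters)) {
        sub <- repCh[[k]][rr, cc, p]
        sub[disk] <- sub[disk] + nucInt[i, k]
        repCh[[k]][rr, cc, p] <- sub
      }
    }
  }

  ## per-cell truth means on the clean (noise- and bleach-free) rendering:
  ## autofluorescence baseline plus the nuclear signal diluted over the
  ## reconstructed cell volume
  cellVox <- tabulate(labels3d[labels3d > 0L], nbins = nCells)
  trueMean <- e@baselineIntensity + nucInt * (nucVox / cellVox)

  ## --- bleach + noise (sub-stream 3) ------------------------------------
  bleach <- (1 - e@bleachRate)^(seq_len(g@zPlanes) - 1L)
  for (k in seq_len(e@nReporters))
    for (p in seq_len(g@zPlanes))
      repCh[[k]][, , p] <- repCh[[k]][, , p] * bleach[p]
  set.seed(subs[3])
  addNoise <- function(a) {
    if (e@noiseSd > 0) a <- a + rnorm(length(a), 0, e@noiseSd)
    a[a < 0] <- 0
    a
  }
  wallCh <- addNoise(wallCh)
  repCh <- lapply(repCh, addNoise)

  voxels <- c(list(wall = wallCh),
              stats::setNames(repCh, paste0("reporter_", seq_len(e@nReporters))))
  stack <- ImageStack(voxels, pxPerUm = g@pxPerUm, zStepUm = g@zStepUm)

  planeLo <- (cellLayer - 1L) * g@cellDepthPlanes + 1L
  planeHi <- cellLayer * g@cellDepthPlanes
  cells <- data.frame(
    cellId = seq_len(nCells), fileId = cellFile, layer = cellLayer,
    planeLo = planeLo, planeHi = planeHi,
    vox = cellVox, nucPlanes = nucPlanes,
    crow = cellCtrRow, ccol = cellCtrCol,
    depthUm = (planeLo + planeHi - 2) / 2 * g@zStepUm
  )
  for (k in seq_len(e@nReporters)) {
    cells[[paste0("state_reporter_", k)]] <-
      ifelse(cellOn[, k], "ON", "OFF")
    cells[[paste0("trueMean_reporter_", k)]] <- trueMean[, k]
  }
  truth <- new("GroundTruth", cells = cells, labels = labels3d,
               geometry = g, layout = lay)
  list(stack = stack, truth = truth)
}

#' True tissue footprint of a synthetic plane
#'
#' @param truth a [GroundTruth].
#' @param plane 1-based plane index.
#' @return logical matrix; `TRUE` on true tissue pixels (walls included).
#' @export
tissueFootprint <- function(truth, plane) {
  g <- truth@geometry
  l <- (plane - 1L) %/% g@cellDepthPlanes + 1L
  truth@layout$layers[[l]]$tissue
}

#' Per-cell state table from ground truth
#'
#' Flattens a [GroundTruth] into the per-cell table used by downstream
#' expression analysis: one row per true cell with its clonal file id and
#' the ON/OFF state (and true mean intensity) of each reporter.
#'
#' @param truth a [GroundTruth].
#' @return data.frame with columns `cellId`, `fileId`,
#'   `state_reporter_k` and `trueMean_reporter_k` for each reporter.
#' @export
truthStateTable <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  keep <- c("cellId", "fileId",
            grep("^(state|trueMean)_reporter_", names(truth@cells),
                 value = TRUE))
  truth@cells[, keep]
}
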