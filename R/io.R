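## Standard-format I/O: multi-page TIFF stacks with a JSON calibration
## sidecar, CSV cell tables, 16-bit label TIFFs and PNG heat maps.

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered plane-major (all channels of plane 1, then plane 2,
#' ...). Intensities are stored as 32-bit floats scaled into `[0, 1]`; the
#' scale factor, channel names and physical calibration go to a JSON
#' sidecar so [readStack()] restores the stack exactly.
#'
#' @param stack an [ImageStack].
#' @param dir output directory (created if needed).
#' @param name basename for `<name>.tif` and `<name>.json`.
#' @return invisibly, the TIFF path.
#' @export
writeStack <- function(stack, dir, name = "root") {
  stopifnot(is(stack, "ImageStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- channelNames(stack)
  nz <- nPlanes(stack)
  scale <- max(1, vapply(stack@voxels, max, 1.0))
  pages <- list()
  for (p in seq_len(nz))
    for (ch in chans)
      pages[[length(pages) + 1L]] <- stack@voxels[[ch]][, , p] / scale
  tifPath <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 32L)
  meta <- list(channels = chans, zPlanes = nz, pxPerUm = stack@pxPerUm,
               zStepUm = stack@zStepUm, scale = scale,
               pageOrder = "plane-major")
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tifPath)
}

#' Read an image stack written by [writeStack()]
#'
#' @param dir directory holding `<name>.tif` and `<name>.json`.
#' @param name stack basename.
#' @return an [ImageStack].
#' @export
readStack <- function(dir, name = "root") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  chans <- meta$channels
  nz <- as.integer(meta$zPlanes)
  meta$scale <- as.numeric(meta$scale)
  d <- dim(pages[[1]])
  voxels <- lapply(seq_along(chans), function(k) {
    a <- array(0, c(d[1], d[2], nz))
    for (p in seq_len(nz))
      a[, , p] <- pages[[(p - 1L) * length(chans) + k]] * meta$scale
    a
  })
  names(voxels) <- chans
  ImageStack(voxels, pxPerUm = as.numeric(meta$pxPerUm),
             zStepUm = as.numeric(meta$zStepUm))
}

#' Write ground truth as CSV plus a 16-bit label TIFF
#'
#' @param truth a [GroundTruth].
#' @param dir output directory.
#' @param name basename for `<name>_truth.csv` / `<name>_labels.tif`.
#' @return invisibly, the CSV path.
#' @export
writeTruth <- function(truth, dir, name = "root") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  write.csv(truthCells(truth), csv, row.names = FALSE)
  tl <- truthLabels(truth)
  pages <- lapply(seq_len(dim(tl)[3]), function(p) tl[, , p] / 65535)
  tiff::writeTIFF(pages, file.path(dir, paste0(name, "_labels.tif")),
                  bits.per.sample = 16L)
  invisible(csv)
}

#' Write a per-cell table as CSV
#'
#' @param cellTable data.frame (e.g. from [runPipeline()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeCellTable <- function(cellTable, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(cellTable, path, row.names = FALSE)
  invisible(path)
}

#' Write a heat-map matrix as PNG
#'
#' Maps intensity through a black-red-yellow-white ramp; zero pixels
#' (unreconstructed) stay black.
#'
#' @param mat numeric matrix from [renderHeatmap()].
#' @param path output PNG path.
#' @param maxValue intensity mapped to the top of the ramp (default the
#'   matrix maximum).
#' @return invisibly, `path`.
#' @export
writeHeatmapPng <- function(mat, path, maxValue = NULL) {
  if (is.null(maxValue) || maxValue <= 0) maxValue <- max(mat, 1e-12)
  v <- pmin(mat / maxValue, 1)
  ramp <- grDevices::colorRamp(c("black", "darkred", "orange", "yellow",
                                 "white"))
  rgb <- ramp(as.vector(v)) / 255
  img <- array(rgb, c(nrow(mat), ncol(mat), 3))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(img, path)
  invisible(path)
}
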