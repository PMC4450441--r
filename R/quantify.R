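## Per-cell reporter quantification over reconstructed 3D volumes and the
## depth-based exclusion for photobleaching.

#' Measure mean reporter intensity per reconstructed cell
#'
#' For every reconstructed cell, reporter intensity is summed over the
#' exact labelled pixels of its member 2D regions across planes and
#' divided by the total reconstructed area (the volume proxy). No
#' background subtraction or flat-field correction is applied; means are
#' raw fluorescence.
#'
#' @param cellset a [CellSet] from [linkPlanes()].
#' @param segs the list of [PlaneSegmentation] the cells were built from.
#' @param stack the [ImageStack] the segmentations came from.
#' @param channels character vector of channel names to quantify; default
#'   all reporter channels.
#' @param rootId identifier recorded in the output (for multi-root tables).
#' @return data.frame, one row per cell: `cellId`, `rootId`,
#'   `totalAreaPx`, `nPlanes`, `depthUm`, `border`, `included` (all `TRUE`
#'   until a depth filter runs) and one `mean_<channel>` column per
#'   channel.
#' @export
measureCells <- function(cellset, segs, stack, channels = NULL,
                         rootId = 1L) {
  stopifnot(is(cellset, "CellSet"), is(stack, "ImageStack"))
  if (is.null(channels))
    channels <- grep("^reporter_", channelNames(stack), value = TRUE)
  for (ch in channels)
    if (!ch %in% channelNames(stack)) stop("no such channel: '", ch, "'")
  reg <- cellset@regions
  cells <- cellset@cells
  if (nrow(cells) == 0L) {
    out <- data.frame(cellId = integer(), rootId = integer(),
                      totalAreaPx = numeric(), nPlanes = integer(),
                      depthUm = numeric(), border = logical(),
                      included = logical())
    for (ch in channels) out[[paste0("mean_", ch)]] <- numeric(0)
    return(out)
  }
  out <- data.frame(cellId = cells$cellId,
                    rootId = rep_len(rootId, nrow(cells)),
                    totalAreaPx = cells$totalAreaPx,
                    nPlanes = cells$nPlanes, depthUm = cells$depthUm,
                    border = cells$border, included = TRUE)
  zmax <- nPlanes(stack)
  if (any(reg$plane < 1L | reg$plane > zmax))
    stop("cell references a plane outside the stack")
  segPlane <- vapply(segs, function(s) s@planeIndex, 1L)

  for (ch in channels) {
    vox <- getChannel(stack, ch)
    # per-(plane, label) intensity sums
    sums <- numeric(nrow(reg))
    for (p in unique(reg$plane)) {
      s <- segs[[match(p, segPlane)]]
      lab <- segLabels(s)
      vals <- vox[, , p]
      sel <- lab > 0L
      if (!any(sel)) next
      persum <- rowsum(vals[sel], lab[sel])
      rows <- which(reg$plane == p)
      sums[rows] <- persum[match(reg$label[rows], as.integer(rownames(persum)))]
    }
    tot <- rowsum(sums, reg$cellId)
    out[[paste0("mean_", ch)]] <-
      tot[match(cells$cellId, as.integer(rownames(tot))), 1] /
      cells$totalAreaPx
  }
  out
}

#' Depth-based exclusion of photobleached cells
#'
#' Mean fluorescence per cell decreases with depth in the stack because
#' deeper planes are acquired later (photobleaching). The analysis is
#' restricted to depths where the intensity is approximately constant:
#' with `method = "plateau"`, the per-depth mean of cell means is
#' computed, and the cut depth is the deepest depth at which the running
#' (cumulative) mean still reaches `(1 - tol)` of the shallow-plateau
#' mean. With `method = "manual"`, the caller supplies `dCut` directly.
#'
#' @param measurements data.frame from [measureCells()].
#' @param method `"plateau"` or `"manual"`.
#' @param tol plateau tolerance (default 0.15).
#' @param dCut manual cut depth in micrometres (required for
#'   `method = "manual"`).
#' @param channel mean column used for the profile; default the first
#'   `mean_` column.
#' @return list with `profile` (data.frame of depth, mean intensity, cell
#'   count, accepted flag), `dCut` (um) and `measurements` (the input with
#'   `included` updated: cells deeper than `dCut` are excluded).
#' @export
depthFilter <- function(measurements, method = c("plateau", "manual"),
                        tol = 0.15, dCut = NULL, channel = NULL) {
  method <- match.arg(method)
  m <- measurements
  if (is.null(channel)) {
    channel <- grep("^mean_", names(m), value = TRUE)[1]
    if (is.na(channel)) stop("no mean_<channel> column found")
  }
  depth <- round(m$depthUm, 6)
  ud <- sort(unique(depth))
  prof <- data.frame(
    depthUm = ud,
    meanIntensity = vapply(ud, function(d) mean(m[[channel]][depth == d]), 1.0),
    nCells = vapply(ud, function(d) sum(depth == d), 1L))
  if (method == "manual") {
    if (is.null(dCut)) stop("manual method requires dCut")
  } else {
    if (length(ud) < 3L) {
      warning("fewer than 3 distinct depths; no depth filtering applied")
      dCut <- max(ud)
    } else {
      # cell-count-weighted running mean, so sparse depth bins (single
      # stray cells) cannot dominate the plateau decision
      run <- cumsum(prof$meanIntensity * prof$nCells) / cumsum(prof$nCells)
      ok <- run >= (1 - tol) * prof$meanIntensity[1]
      dCut <- max(prof$depthUm[ok])
    }
  }
  prof$accepted <- prof$depthUm <= dCut
  m$included <- m$included & depth <= dCut
  list(profile = prof, dCut = dCut, measurements = m)
}

#' Render a per-cell mean-intensity heat map for one plane
#'
#' Recolours the label image of one plane by the mean intensity of the
#' reconstructed cell owning each region. Pixels not belonging to any
#' successfully reconstructed (and measured) cell are 0 (black).
#'
#' @param segs list of [PlaneSegmentation].
#' @param cellset the [CellSet].
#' @param measurements data.frame from [measureCells()].
#' @param planeIndex 1-based plane to render.
#' @param channel mean column to paint; default the first `mean_` column.
#' @param includedOnly drop cells excluded by the depth filter.
#' @return numeric matrix of per-pixel cell mean intensity.
#' @export
renderHeatmap <- function(segs, cellset, measurements, planeIndex,
                          channel = NULL, includedOnly = FALSE) {
  if (is.null(channel))
    channel <- grep("^mean_", names(measurements), value = TRUE)[1]
  segPlane <- vapply(segs, function(s) s@planeIndex, 1L)
  s <- segs[[match(planeIndex, segPlane)]]
  lab <- segLabels(s)
  out <- matrix(0, nrow(lab), ncol(lab))
  reg <- cellset@regions
  reg <- reg[reg$plane == planeIndex, , drop = FALSE]
  if (nrow(reg) == 0L) return(out)
  meas <- measurements
  if (includedOnly) meas <- meas[meas$included, , drop = FALSE]
  val <- meas[[channel]][match(reg$cellId, meas$cellId)]
  for (k in seq_len(nrow(reg))) {
    if (is.na(val[k])) next
    out[lab == reg$label[k]] <- val[k]
  }
  out
}
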