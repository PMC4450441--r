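## Per-plane tissue masking and cell-wall segmentation.

.asMat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Mask root tissue in a cell-wall image
#'
#' Produces a single filled connected component covering the
#' high-intensity wall region and its interior: Gaussian smoothing, global
#' Otsu thresholding, morphological closing with a disc, retention of the
#' largest connected component, and hole filling. Pixels outside the mask
#' are excluded from all downstream steps.
#'
#' @param wallPlane numeric matrix, one z-plane of the wall channel.
#' @param gaussSd Gaussian smoothing sd in pixels.
#' @param closingRadius disc radius (px) for morphological closing.
#' @return logical matrix; `TRUE` on tissue.
#' @examples
#' m <- maskTissue(matrix(c(rep(0, 200), rep(10, 200)), 20, 20))
#' @export
maskTissue <- function(wallPlane, gaussSd = 2, closingRadius = 5) {
  stopifnot(is.matrix(wallPlane))
  if (length(wallPlane) == 0L || !all(is.finite(wallPlane)))
    stop("wallPlane must be a non-empty finite matrix")
  out <- matrix(FALSE, nrow(wallPlane), ncol(wallPlane))
  if (max(wallPlane) <= 0) {
    warning("all-zero wall image; returning an empty mask")
    return(out)
  }
  sm <- .asMat(EBImage::gblur(wallPlane, sigma = gaussSd))
  rng <- range(sm)
  if (diff(rng) == 0) return(!out)  # constant positive image: all tissue
  nm <- (sm - rng[1]) / diff(rng)
  bin <- nm > EBImage::otsu(nm, range = c(0, 1))
  brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
  bin <- .asMat(EBImage::closing(bin, brush)) > 0
  lab <- .asMat(EBImage::bwlabel(bin))
  if (max(lab) == 0) {
    warning("no tissue found; returning an empty mask")
    return(out)
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  comp <- lab == keep
  .asMat(EBImage::fillHull(comp)) > 0
}

#' Segment one wall plane into candidate 2D cell regions
#'
#' The segmentation chain is: Gaussian smoothing (`gaussSd`), median-based
#' local thresholding (a pixel is wall when it exceeds the local median
#' within `thresholdRadius` by more than `thresholdOffset` of the dynamic
#' range), skeletonization of the wall to 1-px ridges, and flood-fill
#' labelling of the non-wall space inside the mask (4-connected components
#' of the skeleton complement, so ridges always separate neighbouring
#' cells). Skeleton pixels belong to no cell. Regions smaller than
#' `minRegionArea` are dropped; regions touching the image border are kept
#' but flagged.
#'
#' @param wallPlane numeric matrix, one z-plane of the wall channel.
#' @param mask logical matrix from [maskTissue()].
#' @param gaussSd Gaussian smoothing sd in pixels (default 2).
#' @param thresholdRadius local-median radius in pixels (default 40).
#' @param thresholdOffset threshold offset as a fraction of the image
#'   dynamic range (default 0.02). The median rule alone marks half of any
#'   flat region as wall; the offset suppresses that.
#' @param minRegionArea minimum region area in px^2 (default 50).
#' @param planeIndex 1-based plane index recorded in the result.
#' @return a [PlaneSegmentation].
#' @export
segmentPlane <- function(wallPlane, mask, gaussSd = 2, thresholdRadius = 40,
                         thresholdOffset = 0.02, minRegionArea = 50,
                         planeIndex = 1L) {
  stopifnot(is.matrix(wallPlane), is.logical(mask),
            all(dim(mask) == dim(wallPlane)),
            gaussSd > 0, thresholdRadius > 0)
  empty <- function() new("PlaneSegmentation",
                          planeIndex = as.integer(planeIndex),
                          labels = matrix(0L, nrow(wallPlane), ncol(wallPlane)),
                          table = data.frame(label = integer(), area = integer(),
                                             crow = numeric(), ccol = numeric(),
                                             border = logical()))
  if (!any(mask)) return(empty())

  sm <- .asMat(EBImage::gblur(wallPlane, sigma = gaussSd))
  rng <- range(sm)
  if (diff(rng) > 0) {
    nm <- (sm - rng[1]) / diff(rng)
    r <- min(as.integer(thresholdRadius),
             (min(dim(nm)) - 1L) %/% 2L)  # median window must fit the image
    med <- .asMat(EBImage::medianFilter(nm, r))
    wallBin <- nm > med + thresholdOffset
  } else {
    wallBin <- matrix(FALSE, nrow(sm), ncol(sm))
  }
  wallBin <- wallBin & mask
  skel <- .thin_zhang_suen(matrix(as.integer(wallBin), nrow(wallBin))) > 0

  lab <- .asMat(EBImage::bwlabel(mask & !skel))
  storage.mode(lab) <- "integer"
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas < minRegionArea)
    if (length(small)) lab[lab %in% small] <- 0L
    # relabel 1..K in first-occurrence (column-major) order
    old <- sort(unique(lab[lab > 0L]))
    if (length(old)) lab[lab > 0L] <- match(lab[lab > 0L], old)
  }
  if (max(lab) == 0L) {
    seg <- empty()
    seg@labels <- lab
    return(seg)
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(lv)
  crow <- rowsum(rows, lv)[, 1] / area
  ccol <- rowsum(cols, lv)[, 1] / area
  onBorder <- rows == 1L | rows == nrow(lab) | cols == 1L | cols == ncol(lab)
  border <- as.logical(rowsum(as.integer(onBorder), lv)[, 1] > 0)
  new("PlaneSegmentation", planeIndex = as.integer(planeIndex),
      labels = lab,
      table = data.frame(label = seq_along(area), area = area,
                         crow = as.numeric(crow), ccol = as.numeric(ccol),
                         border = border))
}

#' Segment every plane of a stack
#'
#' Convenience wrapper running [maskTissue()] and [segmentPlane()] on each
#' z-plane of the wall channel.
#'
#' @param stack an [ImageStack].
#' @param gaussSd,thresholdRadius,thresholdOffset,minRegionArea,closingRadius
#'   passed to [maskTissue()] / [segmentPlane()].
#' @return list of [PlaneSegmentation], one per plane.
#' @export
segmentStack <- function(stack, gaussSd = 2, thresholdRadius = 40,
                         thresholdOffset = 0.02, minRegionArea = 50,
                         closingRadius = 5) {
  wall <- getChannel(stack, "wall")
  lapply(seq_len(dim(wall)[3]), function(p) {
    plane <- wall[, , p]
    m <- maskTissue(plane, gaussSd = gaussSd, closingRadius = closingRadius)
    segmentPlane(plane, m, gaussSd = gaussSd,
                 thresholdRadius = thresholdRadius,
                 thresholdOffset = thresholdOffset,
                 minRegionArea = minRegionArea, planeIndex = p)
  })
}
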