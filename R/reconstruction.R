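## Linking of 2D regions across neighbouring z-planes into 3D cells.

#' Relative area difference of two regions
#'
#' `|a1 - a2| / max(a1, a2)`: the symmetric relative difference used by
#' the linking criterion "relative areas do not vary by more than 50%".
#'
#' @param a1,a2 positive areas (px^2); vectorised.
#' @return fraction in `[0, 1)`.
#' @examples
#' relativeAreaDiff(100, 140)  # 0.2857...
#' @export
relativeAreaDiff <- function(a1, a2) {
  if (any(a1 <= 0) || any(a2 <= 0)) stop("areas must be positive")
  abs(a1 - a2) / pmax(a1, a2)
}

## Optimal one-to-one matching between the regions of two adjacent planes.
## Only pairs satisfying both criteria are admissible; among admissible
## matchings the assignment maximises the number of links and minimises
## total centroid distance (ties broken by smaller area difference, then
## lower labels, via tiny lexicographic cost perturbations).
.matchAdjacent <- function(tabA, tabB, criteria) {
  nA <- nrow(tabA); nB <- nrow(tabB)
  none <- data.frame(i = integer(), j = integer())
  if (nA == 0L || nB == 0L) return(none)
  d <- sqrt(outer(tabA$crow, tabB$crow, "-")^2 +
            outer(tabA$ccol, tabB$ccol, "-")^2)
  rad <- relativeAreaDiff(outer(tabA$area, rep(1, nB)),
                          outer(rep(1, nA), tabB$area))
  adm <- d <= criteria@maxCentroidDist & rad <= criteria@maxAreaChange
  if (!any(adm)) return(none)
  BIG <- 1e9; DUMMY <- 1e5
  n <- nA + nB
  cost <- matrix(0, n, n)
  real <- d + 1e-5 * rad +
    1e-8 * outer(tabA$label, rep(1, nB)) +
    1e-10 * outer(rep(1, nA), tabB$label)
  real[!adm] <- BIG
  cost[seq_len(nA), seq_len(nB)] <- real
  cost[seq_len(nA), nB + seq_len(nA)] <- DUMMY       # A unmatched
  cost[nA + seq_len(nB), seq_len(nB)] <- DUMMY       # B unmatched
  asg <- .hungarian_square(cost)
  i <- seq_len(nA)
  j <- asg[i]
  keep <- j >= 1L & j <= nB
  keep[keep] <- adm[cbind(i[keep], j[keep])]
  data.frame(i = i[keep], j = j[keep])
}

#' Link per-plane 2D regions into 3D cells
#'
#' For every pair of neighbouring z-planes, regions are matched one-to-one
#' when their centroids lie within `maxCentroidDist` pixels and their
#' relative areas differ by at most `maxAreaChange` (the matching is the
#' minimum-total-centroid-distance optimal assignment over admissible
#' pairs, never a greedy scan). Matched chains form 3D cells; chains are
#' cut after `maxZExtentPlanes` planes (18 um at the default 3-um step)
#' and chains spanning fewer than `minPlanes` planes are discarded.
#' Linking is strictly between adjacent planes; no plane skipping.
#'
#' @param segs list of [PlaneSegmentation], one per plane.
#' @param criteria a [LinkCriteria].
#' @param zStepUm z spacing in micrometres (for depth bookkeeping).
#' @return a [CellSet]. Cell depth is the mean distance of the cell's
#'   member planes from the top focal plane.
#' @export
linkPlanes <- function(segs, criteria = LinkCriteria(), zStepUm = 3.0) {
  validObject(criteria)
  emptySet <- function() new("CellSet",
    cells = data.frame(cellId = integer(), nPlanes = integer(),
                       planeLo = integer(), planeHi = integer(),
                       totalAreaPx = numeric(), depthUm = numeric(),
                       crow = numeric(), ccol = numeric(),
                       border = logical()),
    regions = data.frame(cellId = integer(), plane = integer(),
                         label = integer(), area = numeric(),
                         crow = numeric(), ccol = numeric()),
    criteria = criteria)
  if (length(segs) == 0L) return(emptySet())
  stopifnot(all(vapply(segs, is, TRUE, "PlaneSegmentation")))
  segs <- segs[order(vapply(segs, function(s) s@planeIndex, 1L))]
  pIdx <- vapply(segs, function(s) s@planeIndex, 1L)
  if (anyDuplicated(pIdx)) stop("duplicate plane indices")

  tabs <- lapply(segs, segTable)
  nreg <- vapply(tabs, nrow, 1L)
  if (sum(nreg) == 0L) return(emptySet())
  offs <- cumsum(c(0L, head(nreg, -1L)))  # global region index offsets

  nxt <- rep(NA_integer_, sum(nreg))
  for (k in seq_len(length(segs) - 1L)) {
    if (pIdx[k + 1L] != pIdx[k] + 1L) next  # not neighbouring planes
    m <- .matchAdjacent(tabs[[k]], tabs[[k + 1L]], criteria)
    if (nrow(m)) nxt[offs[k] + m$i] <- offs[k + 1L] + m$j
  }

  hasPrev <- logical(sum(nreg))
  hasPrev[nxt[!is.na(nxt)]] <- TRUE
  starts <- which(!hasPrev)

  glob <- do.call(rbind, lapply(seq_along(tabs), function(k) {
    t <- tabs[[k]]
    if (nrow(t) == 0L) return(NULL)
    data.frame(plane = pIdx[k], label = t$label, area = t$area,
               crow = t$crow, ccol = t$ccol, border = t$border)
  }))

  chains <- list()
  for (s in starts) {
    chain <- s
    cur <- s
    while (!is.na(nxt[cur])) { cur <- nxt[cur]; chain <- c(chain, cur) }
    # cut after every maxZExtentPlanes planes
    cuts <- split(chain, (seq_along(chain) - 1L) %/% criteria@maxZExtentPlanes)
    chains <- c(chains, unname(cuts))
  }
  chains <- chains[vapply(chains, length, 1L) >= criteria@minPlanes]
  if (length(chains) == 0L) return(emptySet())

  # deterministic cell ids: order by (first plane, first label)
  ord <- order(vapply(chains, function(ch) glob$plane[ch[1]], 1L),
               vapply(chains, function(ch) glob$label[ch[1]], 1L))
  chains <- chains[ord]

  regions <- do.call(rbind, lapply(seq_along(chains), function(id) {
    ch <- chains[[id]]
    data.frame(cellId = id, plane = glob$plane[ch], label = glob$label[ch],
               area = glob$area[ch], crow = glob$crow[ch],
               ccol = glob$ccol[ch])
  }))
  cells <- do.call(rbind, lapply(seq_along(chains), function(id) {
    ch <- chains[[id]]
    a <- glob$area[ch]
    data.frame(cellId = id, nPlanes = length(ch),
               planeLo = min(glob$plane[ch]), planeHi = max(glob$plane[ch]),
               totalAreaPx = sum(a),
               depthUm = mean(glob$plane[ch] - 1) * zStepUm,
               crow = sum(glob$crow[ch] * a) / sum(a),
               ccol = sum(glob$ccol[ch] * a) / sum(a),
               border = any(glob$border[ch]))
  }))
  new("CellSet", cells = cells, regions = regions, criteria = criteria)
}

#' Audit every reconstructed cell against the linking criteria
#'
#' Post-hoc check, independent of the matching code path: every adjacent
#' region pair inside every cell must satisfy the centroid-distance and
#' relative-area criteria, plane indices must be strictly consecutive, and
#' no cell may exceed the z-extent cap.
#'
#' @param cellset a [CellSet].
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
auditLinkCriteria <- function(cellset) {
  cr <- cellset@criteria
  reg <- cellset@regions
  for (id in unique(reg$cellId)) {
    r <- reg[reg$cellId == id, ]
    r <- r[order(r$plane), ]
    if (nrow(r) > cr@maxZExtentPlanes)
      stop("cell ", id, " exceeds the z-extent cap")
    if (nrow(r) > 1L) {
      if (any(diff(r$plane) != 1L))
        stop("cell ", id, " has non-consecutive planes")
      d <- sqrt(diff(r$crow)^2 + diff(r$ccol)^2)
      if (any(d > cr@maxCentroidDist))
        stop("cell ", id, " violates the centroid-distance criterion")
      rad <- relativeAreaDiff(head(r$area, -1), r$area[-1])
      if (any(rad > cr@maxAreaChange))
        stop("cell ", id, " violates the relative-area criterion")
    }
  }
  invisible(TRUE)
}
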