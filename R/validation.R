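## Scoring the automated pipeline against ground truth.

#' Pair reconstructed cells with ground-truth cells
#'
#' Each automated cell is paired with the true cell owning the majority of
#' its pixels (no pairing when the overlap is below half of the automated
#' cell's pixels). When several automated cells claim the same true cell,
#' the one with the largest pixel overlap wins and the others stay
#' unpaired ("incorrectly segmented").
#'
#' @param cellset a [CellSet] from [linkPlanes()].
#' @param segs the list of [PlaneSegmentation] used to build it.
#' @param truth the matching [GroundTruth].
#' @return data.frame with `cellId`, `trueId` (NA when unpaired) and
#'   `overlap` (fraction of the automated cell's pixels in the paired true
#'   cell).
#' @export
matchCells <- function(cellset, segs, truth) {
  stopifnot(is(cellset, "CellSet"), is(truth, "GroundTruth"))
  tl <- truthLabels(truth)
  reg <- cellset@regions
  cells <- cellset@cells
  if (nrow(cells) == 0L)
    return(data.frame(cellId = integer(), trueId = integer(),
                      overlap = numeric()))
  segPlane <- vapply(segs, function(s) s@planeIndex, 1L)
  auto <- array(0L, dim(tl))
  for (p in unique(reg$plane)) {
    s <- segs[[match(p, segPlane)]]
    lab <- segLabels(s)
    rows <- reg[reg$plane == p, ]
    map <- integer(max(lab))
    map[rows$label] <- rows$cellId
    pl <- lab
    pl[pl > 0L] <- map[pl[pl > 0L]]
    auto[, , p] <- pl
  }
  sel <- auto > 0L
  ov <- data.frame(auto = auto[sel], tru = tl[sel])
  agg <- stats::aggregate(cnt ~ auto + tru, cbind(ov, cnt = 1L), sum)
  total <- tapply(agg$cnt, agg$auto, sum)

  best <- do.call(rbind, lapply(split(agg, agg$auto), function(d) {
    d <- d[d$tru > 0L, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    d[which.max(d$cnt), ]
  }))
  pairing <- data.frame(cellId = cells$cellId, trueId = NA_integer_,
                        overlap = 0)
  if (!is.null(best)) {
    frac <- best$cnt / as.numeric(total[as.character(best$auto)])
    ok <- frac >= 0.5
    best <- best[ok, , drop = FALSE]; frac <- frac[ok]
    # at most one automated cell per true cell: largest overlap wins
    ord <- order(best$tru, -best$cnt, best$auto)
    best <- best[ord, , drop = FALSE]; frac <- frac[ord]
    keep <- !duplicated(best$tru)
    best <- best[keep, , drop = FALSE]; frac <- frac[keep]
    k <- match(best$auto, pairing$cellId)
    pairing$trueId[k] <- best$tru
    pairing$overlap[k] <- frac
  }
  pairing
}

#' Accuracy audit of automated per-cell intensities
#'
#' Draws a random (seeded) sample of reconstructed cells and scores each
#' as accurate when its automated mean intensity is within `tolerance`
#' relative error of the reference (ground-truth) value. Automated cells
#' with no ground-truth partner are incorrectly segmented and always count
#' as inaccurate; they are sampled in proportion to their abundance.
#'
#' @param pairing data.frame from [matchCells()].
#' @param measurements data.frame from [measureCells()] (restrict to
#'   depth-included cells before calling if the audit should mirror the
#'   analysed population).
#' @param truth the [GroundTruth].
#' @param channel reporter channel audited (default `"reporter_1"`).
#' @param tolerance relative-error tolerance for "accurate" (default 0.2).
#' @param sampleN number of cells to check (default 50).
#' @param seed seed for the random sample.
#' @return a [ValidationReport].
#' @export
accuracyAudit <- function(pairing, measurements, truth,
                          channel = "reporter_1", tolerance = 0.2,
                          sampleN = 50, seed = 1L) {
  stopifnot(tolerance > 0)
  tcol <- paste0("trueMean_", channel)
  mcol <- paste0("mean_", channel)
  if (!tcol %in% names(truthCells(truth))) stop("no such truth channel")
  if (!mcol %in% names(measurements)) stop("no such measured channel")
  m <- measurements
  if (nrow(m) == 0L) stop("no measurements to audit")
  set.seed(seed)
  n <- min(sampleN, nrow(m))
  if (n < sampleN)
    warning("fewer cells than sampleN available; auditing all ", n)
  pick <- sample(nrow(m), n)
  auto <- m[[mcol]][pick]
  trueId <- pairing$trueId[match(m$cellId[pick], pairing$cellId)]
  ref <- truthCells(truth)[[tcol]][match(trueId, truthCells(truth)$cellId)]
  relErr <- ifelse(is.na(ref), NA_real_, abs(auto - ref) / ref)
  accurate <- !is.na(relErr) & relErr <= tolerance
  new("ValidationReport", nChecked = as.integer(n),
      nAccurate = as.integer(sum(accurate)),
      accuracy = sum(accurate) / n, tolerance = tolerance,
      errors = data.frame(cellId = m$cellId[pick], trueId = trueId,
                          auto = auto, reference = ref, relError = relErr,
                          accurate = accurate))
}

#' Reference per-cell measurement over ground-truth masks
#'
#' Measures mean reporter intensity over the exact ground-truth voxel
#' masks of a synthetic root (the same summed-intensity / total-volume
#' formula as [measureCells()], with a perfect segmentation). Useful as
#' the segmentation-free reference when isolating downstream operations
#' (state classification, depth filtering) from segmentation error.
#'
#' @param truth a [GroundTruth].
#' @param stack the matching [ImageStack].
#' @param channels channel names; default all reporters.
#' @param rootId identifier stored in the output.
#' @return data.frame shaped like [measureCells()] output.
#' @export
measureTruthCells <- function(truth, stack, channels = NULL, rootId = 1L) {
  stopifnot(is(truth, "GroundTruth"), is(stack, "ImageStack"))
  if (is.null(channels))
    channels <- grep("^reporter_", channelNames(stack), value = TRUE)
  tc <- truthCells(truth)
  tl <- truthLabels(truth)
  sel <- tl > 0L
  ids <- tl[sel]
  out <- data.frame(cellId = tc$cellId, rootId = rootId,
                    totalAreaPx = tc$vox,
                    nPlanes = tc$planeHi - tc$planeLo + 1L,
                    depthUm = tc$depthUm, border = FALSE, included = TRUE)
  for (ch in channels) {
    v <- getChannel(stack, ch)
    sums <- rowsum(v[sel], ids)
    out[[paste0("mean_", ch)]] <-
      sums[match(tc$cellId, as.integer(rownames(sums))), 1] / tc$vox
  }
  out
}

#' Full-pipeline accuracy audit on a batch of synthetic roots
#'
#' Generates `nRoots` synthetic roots, runs the complete
#' segmentation-reconstruction-quantification pipeline (including the
#' depth filter) on each, pools the depth-included reconstructed cells
#' across roots, and audits a seeded random sample of them against the
#' ground truth, mirroring a manual validation of cells drawn from many
#' roots. Reconstructed cells without a ground-truth partner count as
#' inaccurate.
#'
#' @param nRoots number of synthetic roots.
#' @param geometry a [RootGeometry] shared by all roots.
#' @param expression an [ExpressionModel] shared by all roots.
#' @param seed master seed (per-root seeds and the audit sample derive
#'   from it).
#' @param config [pipelineConfig()] for the pipeline stages.
#' @param channel audited reporter channel.
#' @param tolerance relative-error tolerance for "accurate".
#' @param sampleN cells to sample across the pooled batch.
#' @return list with `report` (a [ValidationReport]), `pool` (per-cell
#'   automated and reference means for every included cell) and `stats`
#'   (named counts: roots, true cells, reconstructed cells, included
#'   cells, paired cells).
#' @export
syntheticBatchAudit <- function(nRoots = 8, geometry = RootGeometry(),
                                expression = ExpressionModel(),
                                seed = 1L, config = pipelineConfig(),
                                channel = "reporter_1", tolerance = 0.2,
                                sampleN = 50) {
  set.seed(seed)
  rootSeeds <- sample.int(.Machine$integer.max - 1L, nRoots)
  pool <- vector("list", nRoots)
  nTrue <- nRecon <- nIncl <- 0L
  for (i in seq_len(nRoots)) {
    r <- generateRoot(geometry, expression, seed = rootSeeds[i])
    out <- runPipeline(r$stack, config = config, truth = r$truth,
                       rootId = i, classify = FALSE)
    m <- out$cellTable[out$cellTable$included, , drop = FALSE]
    tc <- truthCells(r$truth)
    tid <- out$pairing$trueId[match(m$cellId, out$pairing$cellId)]
    pool[[i]] <- data.frame(
      rootId = i, cellId = m$cellId, trueId = tid,
      auto = m[[paste0("mean_", channel)]],
      reference = tc[[paste0("trueMean_", channel)]][match(tid, tc$cellId)])
    nTrue <- nTrue + nrow(tc)
    nRecon <- nRecon + out$report[["nCells3D"]]
    nIncl <- nIncl + nrow(m)
  }
  pool <- do.call(rbind, pool)
  set.seed(seed)
  n <- min(sampleN, nrow(pool))
  pick <- sample(nrow(pool), n)
  err <- pool[pick, ]
  err$relError <- ifelse(is.na(err$reference), NA_real_,
                         abs(err$auto - err$reference) / err$reference)
  err$accurate <- !is.na(err$relError) & err$relError <= tolerance
  report <- new("ValidationReport", nChecked = as.integer(n),
                nAccurate = as.integer(sum(err$accurate)),
                accuracy = sum(err$accurate) / n, tolerance = tolerance,
                errors = err)
  list(report = report, pool = pool,
       stats = c(nRoots = nRoots, nTrueCells = nTrue,
                 nReconstructed = nRecon, nIncluded = nIncl,
                 nPaired = sum(!is.na(pool$trueId))))
}
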