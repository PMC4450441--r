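# Independent brute-force oracle for 3D linking: exhaustive enumeration of
# admissible one-to-one matchings per adjacent plane pair, maximising the
# number of links and then minimising the same composite cost convention as
# the package (centroid distance, then area difference, then labels), with
# chains cut at the z-extent cap. Shares no code with linkPlanes().

oracleComposite <- function(d, rad, labA, labB)
  d + 1e-5 * rad + 1e-8 * labA + 1e-10 * labB

oracleMatchPair <- function(tabA, tabB, cr) {
  nA <- nrow(tabA); nB <- nrow(tabB)
  if (nA == 0 || nB == 0) return(data.frame(i = integer(), j = integer()))
  opts <- vector("list", nA)
  for (i in seq_len(nA)) {
    d <- sqrt((tabA$crow[i] - tabB$crow)^2 + (tabA$ccol[i] - tabB$ccol)^2)
    rad <- abs(tabA$area[i] - tabB$area) / pmax(tabA$area[i], tabB$area)
    j <- which(d <= cr@maxCentroidDist & rad <= cr@maxAreaChange)
    opts[[i]] <- list(j = j,
                      cost = oracleComposite(d[j], rad[j],
                                             tabA$label[i], tabB$label[j]))
  }
  best <- NULL
  rec <- function(i, used, pairsI, pairsJ, cost) {
    if (i > nA) {
      cand <- list(n = length(pairsI), cost = cost, i = pairsI, j = pairsJ)
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && cand$cost < best$cost - 1e-12))
        best <<- cand
      return(invisible())
    }
    o <- opts[[i]]
    for (k in seq_along(o$j)) {
      j <- o$j[k]
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, c(pairsI, i), c(pairsJ, j), cost + o$cost[k])
        used[j] <- FALSE
      }
    }
    rec(i + 1L, used, pairsI, pairsJ, cost)  # leave region i unmatched
  }
  rec(1L, logical(nB), integer(0), integer(0), 0)
  data.frame(i = best$i, j = best$j)
}

oracleLink <- function(segs, cr) {
  segs <- segs[order(vapply(segs, function(s) s@planeIndex, 1L))]
  pIdx <- vapply(segs, function(s) s@planeIndex, 1L)
  tabs <- lapply(segs, segTable)
  key <- function(k, i) paste(pIdx[k], tabs[[k]]$label[i])
  nxt <- new.env()
  prev <- new.env()
  for (k in seq_len(length(segs) - 1L)) {
    if (pIdx[k + 1L] != pIdx[k] + 1L) next
    m <- oracleMatchPair(tabs[[k]], tabs[[k + 1L]], cr)
    for (r in seq_len(nrow(m))) {
      assign(key(k, m$i[r]), key(k + 1L, m$j[r]), envir = nxt)
      assign(key(k + 1L, m$j[r]), TRUE, envir = prev)
    }
  }
  chains <- list()
  for (k in seq_along(segs)) for (i in seq_len(nrow(tabs[[k]]))) {
    kk <- key(k, i)
    if (!is.null(prev[[kk]])) next
    chain <- kk
    while (!is.null(nxt[[kk]])) { kk <- nxt[[kk]]; chain <- c(chain, kk) }
    cuts <- split(chain, (seq_along(chain) - 1L) %/% cr@maxZExtentPlanes)
    chains <- c(chains, unname(cuts))
  }
  chains <- chains[lengths(chains) >= cr@minPlanes]
  sort(vapply(chains, paste, "", collapse = "|"))
}

# canonical chain strings from a CellSet, comparable with oracleLink output
cellSetChains <- function(cs) {
  reg <- cellRegions(cs)
  reg <- reg[order(reg$cellId, reg$plane), ]
  sp <- split(reg[, c("plane", "label")], reg$cellId)
  unname(sort(vapply(sp, function(d)
    paste(paste(d$plane, d$label), collapse = "|"), "")))
}

# random sparse linking instance: jittered grid sites so that admissibility
# is exercised near the 20-px and 50% boundaries without blowing up the
# oracle's enumeration
randomLinkInstance <- function(seed) {
  set.seed(seed)
  nP <- sample(2:5, 1)
  spacing <- sample(c(30, 42, 60), 1)
  sites <- expand.grid(r = spacing * (1:3), c = spacing * (1:2))
  segs <- vector("list", nP)
  for (p in seq_len(nP)) {
    k <- sample(2:6, 1)
    pick <- sample(nrow(sites), k)
    segs[[p]] <- makeSeg(
      plane = p, label = seq_len(k),
      area = runif(k, 60, 320),
      crow = sites$r[pick] + runif(k, -11, 11),
      ccol = sites$c[pick] + runif(k, -11, 11))
  }
  segs
}
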