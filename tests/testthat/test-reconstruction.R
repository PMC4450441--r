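test_that("relative area difference follows the symmetric formula", {
  expect_identical(relativeAreaDiff(100, 100), 0)
  expect_identical(relativeAreaDiff(100, 200), 0.5)
  expect_equal(relativeAreaDiff(140, 100), 2 / 7)
  expect_identical(relativeAreaDiff(140, 100), relativeAreaDiff(100, 140))
  expect_error(relativeAreaDiff(0, 10), "positive")
  expect_error(relativeAreaDiff(10, -1), "positive")
})

test_that("pairwise linking honours both printed criteria and boundaries", {
  cr <- LinkCriteria(minPlanes = 1)
  link2 <- function(d, a1, a2) {
    segs <- list(makeSeg(1, 1, a1, 100, 100),
                 makeSeg(2, 1, a2, 100, 100 + d))
    nrow(cellTable(linkPlanes(segs, cr)))  # 1 if linked, 2 if not
  }
  expect_identical(link2(19, 100, 140), 1L)   # 19 px, rel diff 0.286: linked
  expect_identical(link2(21, 100, 140), 2L)   # violates the 20-px criterion
  expect_identical(link2(0, 100, 250), 2L)    # rel diff 0.6 > 0.5
  expect_identical(link2(20, 100, 200), 1L)   # both criteria at the boundary
})

test_that("chains longer than six planes are split at the cap", {
  segs <- lapply(1:8, function(p) makeSeg(p, 1, 100, 50, 50))
  cs <- linkPlanes(segs, LinkCriteria(minPlanes = 1))
  tab <- cellTable(cs)
  expect_identical(nrow(tab), 2L)
  expect_identical(sort(tab$nPlanes), c(2L, 6L))
  expect_lte(max(tab$nPlanes), 6L)
  auditLinkCriteria(cs)
})

test_that("single-plane fragments are dropped under the default min-planes rule", {
  segs <- list(makeSeg(1, 1:2, c(100, 100), c(50, 200), c(50, 50)),
               makeSeg(2, 1, 100, 50, 50))
  cs <- linkPlanes(segs, LinkCriteria())
  expect_identical(nrow(cellTable(cs)), 1L)        # the linked pair survives
  cs1 <- linkPlanes(segs, LinkCriteria(minPlanes = 1))
  expect_identical(nrow(cellTable(cs1)), 2L)       # configurable to keep
  expect_identical(nrow(linkPlanes(list(), LinkCriteria())@cells), 0L)
})

test_that("linking equals the brute-force optimal-assignment oracle", {
  cr <- LinkCriteria(minPlanes = 1)
  for (seed in 1:60) {
    segs <- randomLinkInstance(seed)
    got <- cellSetChains(linkPlanes(segs, cr))
    want <- oracleLink(segs, cr)
    expect_identical(got, want, info = paste("instance seed", seed))
  }
})

test_that("optimal assignment beats greedy nearest-first on a crafted tie", {
  # region A1 is nearest to B1, but matching A1-B1 leaves A2 unmatchable;
  # the optimal assignment links both
  segs <- list(
    makeSeg(1, 1:2, c(100, 100), c(50, 50), c(100, 118)),
    makeSeg(2, 1:2, c(100, 100), c(50, 50), c(110, 128)))
  cs <- linkPlanes(segs, LinkCriteria(minPlanes = 1))
  expect_identical(nrow(cellTable(cs)), 2L)
  expect_true(all(cellTable(cs)$nPlanes == 2L))
})

test_that("reconstructed cells on a synthetic root satisfy the audit and partition", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 8)
  segs <- segmentStack(r$stack)
  cs <- linkPlanes(segs, LinkCriteria(), r$stack@zStepUm)
  expect_true(auditLinkCriteria(cs))
  reg <- cellRegions(cs)
  expect_false(anyDuplicated(reg[, c("plane", "label")]) > 0)
  # physical extent cap: 6 planes at 3 um
  expect_lte(max(cellTable(cs)$nPlanes), 6L)

  # >= 80% of true cells recovered one-to-one
  pair <- matchCells(cs, segs, r$truth)
  expect_gte(sum(!is.na(pair$trueId)) / nrow(truthCells(r$truth)), 0.8)
})
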