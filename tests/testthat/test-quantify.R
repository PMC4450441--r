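a2 <- function(m) array(m, c(dim(m), 1))

# two-plane toy: one region of 10 px per plane, intensity sums 100 and 300
toyStackSegs <- function() {
  lab <- matrix(0L, 10, 10); lab[1:2, 1:5] <- 1L
  v <- array(0, c(10, 10, 2))
  p1 <- matrix(0, 10, 10); p1[1:2, 1:5] <- 10   # sum 100
  p2 <- matrix(0, 10, 10); p2[1:2, 1:5] <- 30   # sum 300
  v[, , 1] <- p1; v[, , 2] <- p2
  stack <- ImageStack(list(wall = array(0, c(10, 10, 2)), reporter_1 = v))
  segs <- lapply(1:2, function(p) new("PlaneSegmentation",
    planeIndex = p, labels = lab,
    table = data.frame(label = 1L, area = 10, crow = 1.5, ccol = 3,
                       border = FALSE)))
  list(stack = stack, segs = segs)
}

test_that("mean intensity is summed intensity over summed area", {
  ts <- toyStackSegs()
  cs <- linkPlanes(ts$segs, LinkCriteria())
  m <- measureCells(cs, ts$segs, ts$stack)
  expect_identical(nrow(m), 1L)
  expect_identical(m$mean_reporter_1, 400 / 20)   # (100 + 300) / (10 + 10)
  expect_identical(m$totalAreaPx, 20)
  expect_error(measureCells(cs, ts$segs, ts$stack, channels = "nope"),
               "no such channel")
})

test_that("a uniform channel yields exactly that constant for every cell", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 1), seed = 2)
  segs <- segmentStack(r$stack)
  cs <- linkPlanes(segs, LinkCriteria(), 3)
  vox <- r$stack@voxels
  vox$reporter_1[] <- 4.25
  flat <- ImageStack(vox)
  m <- measureCells(cs, segs, flat)
  expect_equal(m$mean_reporter_1, rep(4.25, nrow(m)), tolerance = 1e-12)
})

test_that("total intensity is conserved across per-cell means", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 3)
  segs <- segmentStack(r$stack)
  cs <- linkPlanes(segs, LinkCriteria(), 3)
  m <- measureCells(cs, segs, r$stack)
  v <- getChannel(r$stack, "reporter_1")
  reg <- cellRegions(cs)
  total <- 0
  for (p in unique(reg$plane)) {
    lab <- segLabels(segs[[p]])
    total <- total + sum(v[, , p][lab %in% reg$label[reg$plane == p]])
  }
  expect_equal(sum(m$mean_reporter_1 * m$totalAreaPx), total,
               tolerance = 1e-6)
})

test_that("automated means track ground truth on clean stacks", {
  r <- generateRoot(smallGeom(),
                    ExpressionModel(pOn = 0.5, noiseSd = 0, bleachRate = 0),
                    seed = 5)
  segs <- segmentStack(r$stack)
  cs <- linkPlanes(segs, LinkCriteria(), 3)
  m <- measureCells(cs, segs, r$stack)
  pair <- matchCells(cs, segs, r$truth)
  tc <- truthCells(r$truth)
  ref <- tc$trueMean_reporter_1[match(pair$trueId, tc$cellId)]
  err <- abs(m$mean_reporter_1 - ref) / ref
  expect_gte(mean(err <= 0.1, na.rm = TRUE), 0.8)
})

test_that("depth filter plateau, manual and degenerate paths behave", {
  m <- data.frame(cellId = 1:30, depthUm = rep(c(0, 3, 6), each = 10),
                  included = TRUE,
                  mean_reporter_1 = rep(c(10, 9.8, 3), each = 10))
  out <- depthFilter(m)
  expect_identical(out$dCut, 3)             # 3rd depth drags the mean down
  expect_identical(out$measurements$included, m$depthUm <= 3)
  expect_identical(out$profile$accepted, c(TRUE, TRUE, FALSE))

  # idempotence: filtering the filtered table changes nothing
  again <- depthFilter(out$measurements)
  expect_identical(again$measurements$included, out$measurements$included)

  # manual cut keeps only the top depth bin
  man <- depthFilter(m, method = "manual", dCut = 0)
  expect_identical(sum(man$measurements$included), 10L)

  expect_warning(depthFilter(m[m$depthUm < 6, ]), "fewer than 3")
  expect_error(depthFilter(m, method = "manual"), "requires dCut")
})

test_that("no bleaching means no depth exclusion; more bleaching never deepens the cut", {
  deepGeom <- smallGeom(zPlanes = 12)   # three cell layers, three depths
  r0 <- generateRoot(deepGeom, ExpressionModel(pOn = 1, bleachRate = 0),
                     seed = 4)
  m0 <- depthFilter(measureTruthCells(r0$truth, r0$stack))
  expect_identical(m0$dCut, max(truthCells(r0$truth)$depthUm))
  expect_true(all(m0$measurements$included))

  pool <- function(bleach) do.call(rbind, lapply(1:3, function(s) {
    r <- generateRoot(deepGeom,
                      ExpressionModel(pOn = 1, bleachRate = bleach),
                      seed = s)
    measureTruthCells(r$truth, r$stack)
  }))
  dLow <- depthFilter(pool(0.02))$dCut
  dHigh <- depthFilter(pool(0.12))$dCut
  expect_lte(dHigh, dLow)
})

test_that("heat maps paint exactly the reconstructed pixels", {
  ts <- toyStackSegs()
  cs <- linkPlanes(ts$segs, LinkCriteria())
  m <- measureCells(cs, ts$segs, ts$stack)
  hm <- renderHeatmap(ts$segs, cs, m, 1)
  lab <- segLabels(ts$segs[[1]])
  expect_true(all(hm[lab == 1L] == 20))
  expect_true(all(hm[lab == 0L] == 0))

  # a plane with no reconstructed cells is all black
  segsE <- list(ts$segs[[1]],
                new("PlaneSegmentation", planeIndex = 2L,
                    labels = matrix(0L, 10, 10),
                    table = data.frame(label = integer(), area = numeric(),
                                       crow = numeric(), ccol = numeric(),
                                       border = logical())))
  csE <- linkPlanes(segsE, LinkCriteria())
  expect_true(all(renderHeatmap(segsE, csE, m[0, ], 2) == 0))
})
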