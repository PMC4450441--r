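test_that("mask handles degenerate images", {
  expect_warning(m <- maskTissue(matrix(0, 32, 32)), "all-zero")
  expect_false(any(m))
  # constant positive image: everything is tissue
  expect_true(all(maskTissue(matrix(7, 32, 32))))
})

test_that("mask covers the tissue and little background on synthetic planes", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 2)
  wall <- getChannel(r$stack, "wall")
  for (p in c(1, 5)) {
    m <- maskTissue(wall[, , p])
    fp <- tissueFootprint(r$truth, p)
    expect_gte(mean(m[fp]), 0.99)
    expect_lte(mean(m[!fp]), 0.05)
  }
})

test_that("a bright 2-px wall yields exactly two separated regions", {
  img <- twoCellImage()
  mask <- matrix(TRUE, nrow(img), ncol(img))
  seg <- segmentPlane(img, mask, minRegionArea = 20)
  tab <- segTable(seg)
  expect_identical(nrow(tab), 2L)
  lab <- segLabels(seg)
  # the two regions lie on opposite sides of the wall and no region
  # crosses it: all pixels of region 1 above, all of region 2 below
  rows1 <- range(which(lab == 1, arr.ind = TRUE)[, 1])
  rows2 <- range(which(lab == 2, arr.ind = TRUE)[, 1])
  expect_true(rows1[2] < min(32, rows2[1]) || rows2[2] < min(32, rows1[1]))
  # skeleton (label 0 inside the mask between the regions) separates them:
  # no pair of 4-adjacent pixels belongs to two different regions
  expect_false(any(lab[-1, ] > 0 & lab[-nrow(lab), ] > 0 &
                   lab[-1, ] != lab[-nrow(lab), ]))
  expect_false(any(lab[, -1] > 0 & lab[, -ncol(lab)] > 0 &
                   lab[, -1] != lab[, -ncol(lab)]))
})

test_that("a uniform plane under a full mask gives one region covering it", {
  img <- matrix(5, 48, 48)
  mask <- matrix(TRUE, 48, 48)
  seg <- segmentPlane(img, mask)
  expect_identical(nrow(segTable(seg)), 1L)
  expect_identical(sum(segLabels(seg) == 1L), 48L * 48L)
})

test_that("empty mask gives an empty segmentation", {
  seg <- segmentPlane(matrix(1, 32, 32), matrix(FALSE, 32, 32))
  expect_identical(nrow(segTable(seg)), 0L)
})

test_that("segmentation recovers the true cell grid", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 4)
  wall <- getChannel(r$stack, "wall")[, , 2]
  m <- maskTissue(wall)
  seg <- segmentPlane(wall, m, planeIndex = 2)
  tab <- segTable(seg)
  G <- smallGeom()@nFiles * smallGeom()@cellsPerFile  # cells per layer
  expect_lte(abs(nrow(tab) - G) / G, 0.1)

  # labels live inside the mask
  lab <- segLabels(seg)
  expect_true(all(m[lab > 0]))

  # >= 80% of regions match one true cell with IoU >= 0.5
  tl <- truthLabels(r$truth)[, , 2]
  iou <- vapply(tab$label, function(l) {
    px <- lab == l
    tid <- as.integer(names(which.max(table(tl[px & tl > 0]))))
    if (length(tid) == 0) return(0)
    tpx <- tl == tid
    sum(px & tpx) / sum(px | tpx)
  }, 1.0)
  expect_gte(mean(iou >= 0.5), 0.8)
})

test_that("determinism and min-area monotonicity hold", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 1), seed = 6)
  wall <- getChannel(r$stack, "wall")[, , 1]
  m <- maskTissue(wall)
  s1 <- segmentPlane(wall, m)
  s2 <- segmentPlane(wall, m)
  expect_identical(segLabels(s1), segLabels(s2))

  counts <- vapply(c(10, 50, 400), function(a)
    nrow(segTable(segmentPlane(wall, m, minRegionArea = a))), 1L)
  expect_true(all(diff(counts) <= 0))
})
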