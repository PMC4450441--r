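test_that("generation is deterministic and respects forced expression states", {
  g <- smallGeom()
  r1 <- generateRoot(g, ExpressionModel(pOn = 1), seed = 7)
  r2 <- generateRoot(g, ExpressionModel(pOn = 1), seed = 7)
  expect_identical(r1$stack@voxels, r2$stack@voxels)
  expect_identical(truthCells(r1$truth), truthCells(r2$truth))

  tc <- truthCells(r1$truth)
  expect_true(all(tc$state_reporter_1 == "ON"))

  r0 <- generateRoot(g, ExpressionModel(pOn = 0), seed = 7)
  tc0 <- truthCells(r0$truth)
  expect_true(all(tc0$state_reporter_1 == "OFF"))
  # OFF reporter channel is close to baseline + off signal everywhere
  rep1 <- getChannel(r0$stack, "reporter_1")
  e <- ExpressionModel(pOn = 0)
  expect_lt(max(rep1), e@baselineIntensity + e@offIntensity * 2 + 6 * e@noiseSd)
})

test_that("nuclei span 2-3 consecutive planes at the 3-um step", {
  # a 7-um-diameter sphere sampled every 3 um intersects floor(7/3)=2 or 3
  # planes whatever the offset; the rendered truth must agree
  spans <- unlist(lapply(1:3, function(s) {
    truthCells(generateRoot(RootGeometry(), ExpressionModel(), seed = s)$truth)$nucPlanes
  }))
  expect_true(all(spans %in% 2:3))
  expect_gte(mean(spans %in% 2:3), 0.95)
})

test_that("oversized nuclei are rejected with a geometry error", {
  expect_error(RootGeometry(nucleusRadiusUm = 6), "does not fit")
  expect_error(RootGeometry(cellWidthPx = 20, nucleusRadiusUm = 3.5),
               "does not fit")
})

test_that("files are perfectly state-coherent and ON truth means dominate OFF", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 11)
  tc <- truthCells(r$truth)
  perFile <- tapply(tc$state_reporter_1, tc$fileId,
                    function(s) length(unique(s)))
  expect_true(all(perFile == 1L))
  on <- tc$trueMean_reporter_1[tc$state_reporter_1 == "ON"]
  off <- tc$trueMean_reporter_1[tc$state_reporter_1 == "OFF"]
  expect_gt(min(on), max(off))
})

test_that("bleaching attenuates each plane by a non-increasing factor", {
  g <- smallGeom()
  planeMeans <- function(bleach) {
    r <- generateRoot(g, ExpressionModel(pOn = 1, bleachRate = bleach,
                                         noiseSd = 0), seed = 3)
    tl <- truthLabels(r$truth)
    v <- getChannel(r$stack, "reporter_1")
    vapply(seq_len(dim(tl)[3]), function(p) mean(v[, , p][tl[, , p] > 0]),
           1.0)
  }
  ratio <- planeMeans(0.1) / planeMeans(0)
  expect_equal(ratio, 0.9^(seq_along(ratio) - 1), tolerance = 1e-8)
  expect_true(all(diff(ratio) < 0))
})

test_that("truth state table reflects the memory model", {
  # trans: mixed two-reporter files are impossible by construction
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5,
                                                 memoryMode = "trans",
                                                 nReporters = 2), seed = 5)
  tab <- truthStateTable(r$truth)
  expect_true(all(c("state_reporter_1", "state_reporter_2") %in% names(tab)))
  expect_identical(sum(tab$state_reporter_1 != tab$state_reporter_2), 0L)

  # one reporter: exactly one state column
  r1 <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 5)
  expect_identical(grep("^state_", names(truthStateTable(r1$truth))), 3L)

  # cis with many files: mixed-file fraction matches 2 p (1 - p)
  st <- drawFileStates(400, 0.5, "cis", 2, seed = 9)
  mixedFrac <- mean(st[, 1] != st[, 2])
  expect_lt(abs(mixedFrac - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("state sub-stream is reproducible independently of noise level", {
  g <- smallGeom()
  a <- generateRoot(g, ExpressionModel(pOn = 0.5, noiseSd = 0), seed = 13)
  b <- generateRoot(g, ExpressionModel(pOn = 0.5, noiseSd = 20), seed = 13)
  expect_identical(truthCells(a$truth)$state_reporter_1,
                   truthCells(b$truth)$state_reporter_1)
})

test_that("pOnFromColdWeeks is monotone decreasing and spans the series", {
  w <- c(0, 2, 4, 6, 8, 10)
  p <- pOnFromColdWeeks(w)
  expect_true(all(diff(p) < 0))
  expect_gt(p[1], 0.95)
  expect_lt(p[6], 0.1)
})
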