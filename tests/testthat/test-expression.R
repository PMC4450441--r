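# closed-form expectation of the majority-agreement fraction for i.i.d.
# ON states with probability p in files of length n
expectedAgreement <- function(n, p) {
  k <- 0:n
  sum(dbinom(k, n, p) * pmax(k, n - k) / n)
}

test_that("mixture classification recovers true states from bimodal data", {
  r <- generateRoot(RootGeometry(), ExpressionModel(pOn = 0.5), seed = 21)
  m <- measureTruthCells(r$truth, r$stack)
  cls <- classifyStates(m$mean_reporter_1)
  expect_true(attr(cls, "bimodal"))
  tru <- truthCells(r$truth)$state_reporter_1
  expect_gte(mean(cls$state == tru), 0.95)
  expect_true(all(cls$posterior >= 0 & cls$posterior <= 1))
})

test_that("uniform populations take the unimodal fallback path", {
  for (p in c(0, 1)) {
    r <- generateRoot(RootGeometry(), ExpressionModel(pOn = p), seed = 22)
    m <- measureTruthCells(r$truth, r$stack)
    cls <- classifyStates(m$mean_reporter_1)
    expect_false(attr(cls, "bimodal"))
    expect_true(all(cls$state == if (p == 1) "ON" else "OFF"))
  }
  # all-identical intensities are degenerate but must not crash
  cls <- classifyStates(rep(3, 25))
  expect_false(attr(cls, "bimodal"))
  expect_true(all(cls$state == "OFF"))
  expect_error(classifyStates(rep(1, 5)), "at least 20")
})

test_that("state calls are invariant under monotone affine rescaling", {
  r <- generateRoot(RootGeometry(), ExpressionModel(pOn = 0.4), seed = 23)
  x <- measureTruthCells(r$truth, r$stack)$mean_reporter_1
  a <- classifyStates(x)
  b <- classifyStates(3 * x + 10)
  expect_identical(a$state, b$state)
})

test_that("histogram summary flags bimodality and tracks cold duration", {
  r <- generateRoot(RootGeometry(), ExpressionModel(pOn = 0.5), seed = 24)
  m <- measureTruthCells(r$truth, r$stack)
  hs <- histogramSummary(m$mean_reporter_1)
  expect_true(hs$bimodal)
  expect_identical(sum(hs$counts), nrow(m))

  r1 <- generateRoot(RootGeometry(), ExpressionModel(pOn = 1), seed = 24)
  hs1 <- histogramSummary(measureTruthCells(r1$truth, r1$stack)$mean_reporter_1)
  expect_false(hs1$bimodal)
  expect_identical(hs1$onFraction, 1)

  # longer cold -> lower ON fraction (generator + classification)
  onFrac <- vapply(c(2, 6, 10), function(w) {
    r <- generateRoot(RootGeometry(),
                      ExpressionModel(pOn = pOnFromColdWeeks(w)), seed = 25)
    histogramSummary(measureTruthCells(r$truth, r$stack)$mean_reporter_1)$onFraction
  }, 1.0)
  expect_true(all(diff(onFrac) < 0))
})

test_that("coherence is 1 for perfect clonal calls and matches closed forms otherwise", {
  r <- generateRoot(smallGeom(), ExpressionModel(pOn = 0.5), seed = 26)
  tab <- truthStateTable(r$truth)
  fc <- fileCoherence(tab$state_reporter_1, tab$fileId)
  expect_identical(fc$coherence, 1)
  expect_true(all(vapply(fc$runs, sum, 1L) == fc$files$length))

  # permutation control: i.i.d. states give the binomial closed form
  set.seed(1)
  n <- 12; p <- 0.7; files <- rep(1:300, each = n)
  iid <- ifelse(rbinom(length(files), 1, p) == 1, "ON", "OFF")
  fcIid <- fileCoherence(iid, files)
  expect_lt(abs(fcIid$coherence - expectedAgreement(n, p)), 0.02)

  # injected 5% call error on coherent files
  e <- 0.05
  truth <- rep(ifelse(rbinom(300, 1, 0.5) == 1, "ON", "OFF"), each = n)
  flip <- rbinom(length(truth), 1, e) == 1
  noisy <- ifelse(flip, ifelse(truth == "ON", "OFF", "ON"), truth)
  fcE <- fileCoherence(noisy, files)
  expect_lt(abs(fcE$coherence - expectedAgreement(n, 1 - e)), 0.02)

  # invariance to file relabelling / order
  perm <- sample(length(files))
  expect_equal(fileCoherence(noisy[perm], files[perm])$coherence,
               fcE$coherence)
  expect_error(fileCoherence("ON", 1), "length >= 2")
})

test_that("cis/trans test keeps the trans null and rejects it on cis data", {
  mkCalls <- function(states, cellsPerFile = 10) {
    list(s1 = rep(ifelse(states[, 1], "ON", "OFF"), each = cellsPerFile),
         s2 = rep(ifelse(states[, 2], "ON", "OFF"), each = cellsPerFile),
         f = rep(seq_len(nrow(states)), each = cellsPerFile))
  }
  tr <- mkCalls(drawFileStates(60, 0.5, "trans", 2, seed = 31))
  resT <- cisTransTest(tr$s1, tr$s2, tr$f, B = 499, seed = 1)
  expect_identical(resT@statistic, 0)
  expect_gte(resT@pValue, 0.05)
  expect_identical(sum(resT@counts), 60L)
  expect_identical(resT@counts[["on_off"]] + resT@counts[["off_on"]], 0L)

  ci <- mkCalls(drawFileStates(100, 0.5, "cis", 2, seed = 32))
  resC <- cisTransTest(ci$s1, ci$s2, ci$f, B = 499, seed = 1)
  expect_lt(resC@pValue, 0.05)
  expect_gt(resC@statistic, 0.3)
  expect_true(resC@pSymmetry >= 0 && resC@pSymmetry <= 1)

  expect_error(cisTransTest(tr$s1, NULL, tr$f), "two reporters")
  expect_error(cisTransTest(tr$s1[1:20], tr$s2[1:20], rep(1:2, each = 10)),
               "at least 10 files")
})
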