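test_that("reference-base probability arrays impute and flag correctly", {
  allA <- GenomeSequence("a", strrep("A", 20))
  m <- fitCentralModel(allA, k = 1)
  rp <- referenceBaseProbabilities(m, allA)
  expect_equal(length(rp), 20L)
  expect_equal(refProbValues(rp)[2:19], rep(1, 18))   # perfect model
  expect_equal(refProbValues(rp)[c(1, 20)], c(0.25, 0.25))
  expect_equal(which(disqualified(rp)), c(1L, 20L))

  ## self-fit on the printed toy sequence: interior values are the training
  ## frequencies (all contexts deterministic here, so 1.0)
  g <- GenomeSequence("t", "ACGTACGT")
  mt <- fitCentralModel(g, k = 1)
  rpt <- referenceBaseProbabilities(mt, g)
  expect_equal(refProbValues(rpt)[2:7], rep(1, 6))

  ## unseen contexts score the uniform fallback
  other <- GenomeSequence("o", strrep("T", 10))
  rpo <- referenceBaseProbabilities(mt, other)
  expect_equal(refProbValues(rpo)[2:9], rep(0.25, 8))

  ## TSV + sidecar round trip
  path <- tempfile(fileext = ".tsv")
  writeRefProbArray(rpt, path)
  back <- readRefProbArray(path)
  expect_equal(refProbValues(back), refProbValues(rpt))
  expect_equal(disqualified(back), disqualified(rpt))
})

test_that("accuracy is exact on deterministic fixtures", {
  allA <- GenomeSequence("a", strrep("A", 20))
  expect_equal(overallAccuracy(accuracyReport(fitCentralModel(allA, 1), allA)),
               1.0)
  g <- GenomeSequence("t", "ACGTACGT")
  rep1 <- accuracyReport(fitCentralModel(g, 1), g)
  expect_equal(overallAccuracy(rep1), 1.0)
  expect_equal(rep1@nOverall, 6)
})

test_that("accuracy on iid uniform data is 0.25 within binomial error", {
  gen <- generateGenome(syntheticGenomeSpec(1e5, order = 0, seed = 17))
  rep0 <- accuracyReport(gen$model, gen$genome)
  expect_equal(overallAccuracy(rep0), 0.25, tolerance = 0.01)
})

test_that("overall accuracy is the position-weighted per-chromosome mean", {
  g1 <- generateGenome(syntheticGenomeSpec(4000, order = 1,
                                           transitionTable = toyChain1()@probs,
                                           seed = 3, name = "c1"))$genome
  g2 <- generateGenome(syntheticGenomeSpec(9000, order = 1,
                                           transitionTable = toyChain1()@probs,
                                           seed = 4, name = "c2"))$genome
  m <- fitMarkovModel(list(g1, g2), 1)
  repAB <- accuracyReport(m, list(g1, g2))
  pc <- perChromosomeAccuracy(repAB)
  expect_equal(nrow(pc), 2L)
  expect_equal(overallAccuracy(repAB),
               sum(pc$accuracy * pc$n) / sum(pc$n))
})

test_that("annotation strata report accuracy only where they have positions", {
  g <- GenomeSequence("chrZ", paste0(strrep("A", 50), strrep("C", 50)))
  m <- fitCentralModel(g, 1)
  ann <- GenomicRanges::GRanges(c("chrZ", "chrZ"),
                                IRanges::IRanges(start = c(1, 200),
                                                 end = c(30, 250)))
  S4Vectors::mcols(ann)$label <- c("inA", "offEnd")
  expect_warning(repA <- accuracyReport(m, g, annotations = ann), "clip")
  pa <- perAnnotationAccuracy(repA)
  expect_equal(pa$label, "inA")          # empty stratum absent, not zero
  expect_equal(pa$n, 29)                 # positions 1..29 qualified
})

test_that("density grids bin pairs on a fixed [0,1] grid", {
  ## identical arrays populate only the diagonal
  v <- c(0.01, 0.2, 0.5, 0.77, 0.99)
  gSame <- densityGrid(v, v, positions = seq_along(v) - 1L)
  cm <- gridCounts(gSame)
  expect_equal(sum(cm), 5)
  expect_equal(sum(diag(cm)), 5)

  ## two corner points land in opposite corner bins
  gCorner <- densityGrid(c(0.01, 0.99), c(0.99, 0.01), positions = 0:1)
  cc <- gridCounts(gCorner)
  expect_equal(cc[1, 50], 1L)
  expect_equal(cc[50, 1], 1L)
  expect_equal(sum(cc), 2L)

  ## 1.0 falls in the right-closed last bin
  gOne <- densityGrid(1, 1, positions = 0L)
  expect_equal(gridCounts(gOne)[50, 50], 1L)

  expect_error(densityGrid(1:3 / 4, 1:2 / 4), "lengths differ")

  ## RefProbArray input: defaults to positions qualified in both
  allA <- GenomeSequence("a", strrep("A", 20))
  m <- fitCentralModel(allA, 1)
  rp <- referenceBaseProbabilities(m, allA)
  gRp <- densityGrid(rp, rp)
  expect_equal(sum(gridCounts(gRp)), 18L)
})

test_that("the Vuong z statistic matches a direct formula oracle", {
  set.seed(99)
  d <- rnorm(1000, mean = 0.1, sd = 1)
  vt <- vuongTest(d, rep(0, 1000))
  ## independent brute-force computation
  n <- 1000
  mOracle <- sum(d) / n
  sOracle <- sqrt(sum((d - mOracle)^2) / (n - 1))
  zOracle <- sqrt(n) * mOracle / sOracle
  expect_equal(vuongZ(vt), zOracle, tolerance = 1e-9)
  expect_equal(vuongP(vt), 2 * pnorm(-abs(zOracle)), tolerance = 1e-9)

  ## identical models are degenerate
  expect_error(vuongTest(rep(-1.2, 50), rep(-1.2, 50)), "degenerate")
  ## perfectly symmetric differences: z = 0, p = 1
  vt0 <- vuongTest(c(rep(0.3, 50), rep(-0.3, 50)), rep(0, 100))
  expect_equal(vuongZ(vt0), 0)
  expect_equal(vuongP(vt0), 1)
})

test_that("aggregation pools sufficient statistics exactly", {
  set.seed(5)
  la <- rnorm(400, -1); lb <- rnorm(400, -1.05)
  single <- aggregateVuong(list(vuongStats(la, lb)))
  direct <- vuongTest(la, lb)
  expect_equal(vuongZ(single), vuongZ(direct), tolerance = 1e-12)
  expect_equal(single@n, direct@n)

  ## two identical chromosomes: same mean, doubled n, z scales by sqrt(2)
  twice <- aggregateVuong(list(vuongStats(la, lb), vuongStats(la, lb)))
  expect_equal(twice@meanLR, direct@meanLR, tolerance = 1e-12)
  expect_equal(twice@n, 2 * direct@n)
  ## pooled sd shrinks slightly (n-1 denominator), so compare via variance
  expect_equal(vuongZ(twice), sqrt(2 * 400) * twice@meanLR / twice@sdLR)

  ## equal-and-opposite chromosomes cancel
  opp <- aggregateVuong(list(vuongStats(la, lb), vuongStats(lb, la)))
  expect_equal(opp@meanLR, 0, tolerance = 1e-12)
  expect_equal(vuongZ(opp), 0, tolerance = 1e-12)

  expect_error(aggregateVuong(list()), "no per-chromosome")
})

test_that("test-position sampling is seeded and respects the mask", {
  g <- GenomeSequence("g", randomBases(1004, seed = 2))
  mask <- buildPositionMask(g, 2)     # 1000 qualified positions
  pos <- sampleTestPositions(g, mask, fraction = 0.10, seed = 3)
  expect_length(pos, 100L)
  expect_identical(pos, sampleTestPositions(g, mask, fraction = 0.10, seed = 3))
  expect_false(any(disqualified(mask)[pos + 1L]))
  expect_length(sampleTestPositions(g, mask, fraction = 1, seed = 1), 1000L)
})

test_that("log-likelihoods are floored and finite", {
  g <- GenomeSequence("t", "ACGTACGT")
  m <- fitCentralModel(g, k = 1)
  other <- GenomeSequence("o", "AGGGGGGA")
  ll <- positionLogLikelihoods(m, other, 1:6)
  expect_true(all(is.finite(ll)))
  expect_true(all(ll >= log(1e-12)))
})
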