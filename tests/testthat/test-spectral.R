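test_that("segmentation drops the remainder and applies the 10% rule", {
  expect_equal(segmentCount(segmentChromosome(64444167)), 64L)
  expect_equal(segmentCount(segmentChromosome(999999)), 0L)
  expect_equal(segmentCount(segmentChromosome(2e6 + 5)), 2L)

  ## exactly 10% disqualified is included; strictly more is excluded
  disqA <- rep(FALSE, 1e4); disqA[1:1000] <- TRUE
  segA <- segmentChromosome(1e4, disqA, segmentLength = 1e4)
  expect_true(segmentTable(segA)$included)
  disqB <- rep(FALSE, 1e4); disqB[1:1001] <- TRUE
  segB <- segmentChromosome(1e4, disqB, segmentLength = 1e4)
  expect_false(segmentTable(segB)$included)
  expect_equal(segmentTable(segB)$disqualifiedFraction, 0.1001)
})

test_that("GC indicator encodes G/C as 1, A/T/N as 0", {
  expect_equal(gcIndicator(GenomeSequence("x", "ACGT")), c(0, 1, 1, 0))
  expect_equal(gcIndicator(GenomeSequence("x", "GGCC")), c(1, 1, 1, 1))
  g <- GenomeSequence("x", "ATNTA")
  expect_equal(gcIndicator(g), rep(0, 5))
  expect_true(disqualified(buildPositionMask(g, 1))[3])
  ## 0-based half-open slice [2,5) of ACGTAC is GTA
  expect_equal(gcIndicator(GenomeSequence("x", "ACGTAC"), 2, 5), c(1, 0, 0))
})

test_that("FFT magnitudes match closed forms and a brute-force DFT", {
  ## constant array: DC only
  m <- fourierMagnitudes(rep(3, 64))
  expect_equal(unname(m[1]), 3 * 64)
  expect_equal(max(m[-1]), 0, tolerance = 1e-9)

  ## planted cosine: magnitude L/2 at its frequency, ~0 elsewhere
  L <- 1e4
  v <- cos(2 * pi * 50 * (0:(L - 1)) / L)
  mv <- fourierMagnitudes(v)
  expect_equal(unname(mv["50"]), L / 2, tolerance = 1e-6)
  expect_lt(max(mv[-51]), 1e-6)

  ## random array vs the O(L^2) oracle
  set.seed(1)
  x <- rnorm(64)
  expect_equal(unname(fourierMagnitudes(x)), bruteDftMagnitudes(x),
               tolerance = 1e-8)

  expect_error(fourierMagnitudes(c(1, NA, 3)), "non-finite")
})

test_that("Parseval's identity holds for the one-sided magnitudes", {
  for (seed in 1:3) {
    set.seed(seed)
    L <- c(64, 100, 257)[seed]          # even, even, odd lengths
    x <- rnorm(L)
    m <- fourierMagnitudes(x)
    w <- rep(2, length(m)); w[1] <- 1
    if (L %% 2 == 0) w[length(m)] <- 1  # Nyquist bin is unique for even L
    expect_equal(sum(w * m^2), L * sum(x^2), tolerance = 1e-6)
  }
})

test_that("windowed norms follow the Euclidean-norm definition", {
  L <- 1e4
  v <- cos(2 * pi * 500 * (0:(L - 1)) / L)
  sp <- windowedNormSpectrum(fourierMagnitudes(v), window = 100, step = 10)
  tab <- spectrumTable(sp)
  inWin <- tab$fStart <= 500 & tab$fStart + 100 > 500
  expect_equal(tab$norm[inWin], rep(L / 2, sum(inWin)), tolerance = 1e-6)
  expect_equal(max(tab$norm[!inWin]), 0, tolerance = 1e-6)
  expect_true(all(peakWindow(sp)$fStart <= 500 &
                    peakWindow(sp)$fStart + 100 > 500))

  ## all-zero magnitudes give all-zero norms
  sp0 <- windowedNormSpectrum(rep(0, 500), window = 50, step = 10)
  expect_equal(sp0@norms, rep(0, length(sp0@norms)))

  ## two equal coefficients in one window: norm m*sqrt(2)
  mags <- rep(0, 201); mags[11] <- 5; mags[12] <- 5  # frequencies 10 and 11
  sp2 <- windowedNormSpectrum(mags, window = 50, step = 100)
  expect_equal(sp2@norms[1], 5 * sqrt(2))

  ## power flag returns the summed power
  spP <- windowedNormSpectrum(mags, window = 50, step = 100, power = TRUE)
  expect_equal(spP@norms[1], 50)

  ## oversized window truncates with a warning
  expect_warning(spT <- windowedNormSpectrum(mags, window = 1000), "truncated")
  expect_length(spT@norms, 1L)

  ## DC exclusion: adding a constant to the input leaves the spectrum alone;
  ## sign flips too
  set.seed(7)
  x <- rnorm(512)
  s1 <- windowedNormSpectrum(fourierMagnitudes(x), window = 50, step = 25)
  s2 <- windowedNormSpectrum(fourierMagnitudes(x + 100), window = 50, step = 25)
  s3 <- windowedNormSpectrum(fourierMagnitudes(-x), window = 50, step = 25)
  expect_equal(s1@norms, s2@norms, tolerance = 1e-6)
  expect_equal(s1@norms, s3@norms, tolerance = 1e-9)
})

test_that("frequency windows convert to the published period windows", {
  p <- frequencyWindowToPeriods(4000, 1000, 1e6)
  expect_equal(p$periodLow, 200)
  expect_equal(p$periodHigh, 250)
  expect_equal(p$periodMid, 222)
  expect_equal(frequencyWindowToPeriods(7500, 1000, 1e6)$periodMid, 125)
  expect_equal(frequencyWindowToPeriods(11000, 1000, 1e6)$periodMid, 87)
  expect_equal(frequencyWindowToPeriods(18000, 1000, 1e6)$periodLow, 53)
  expect_equal(frequencyWindowToPeriods(18000, 1000, 1e6)$periodHigh, 56)
  p0 <- frequencyWindowToPeriods(100, 0, 1000)
  expect_equal(p0$periodLow, 10)
  expect_equal(p0$periodMid, 10)
  expect_equal(p0$periodHigh, 10)
})

test_that("shuffling destroys a planted peak but keeps the values", {
  ## the 5% bound scales as sqrt(2 * window / L): at the published scale
  ## (1 Mb, window 1000) it is ~0.045, matched here by L = 800 * window
  L <- 2^18
  v <- cos(2 * pi * 1000 * (0:(L - 1)) / L)
  peak0 <- max(windowedNormSpectrum(fourierMagnitudes(v), window = 200,
                                    step = 50)@norms)
  sh <- shuffleControl(v, seed = 3)
  expect_equal(sort(sh), sort(v))
  expect_identical(sh, shuffleControl(v, seed = 3))
  ## 10-seed average of the post-shuffle maximum stays below 5% of the peak
  ratios <- vapply(1:10, function(s) {
    vs <- shuffleControl(v, seed = s)
    max(windowedNormSpectrum(fourierMagnitudes(vs), window = 200,
                             step = 50)@norms) / peak0
  }, numeric(1))
  expect_lt(mean(ratios), 0.05)
})

test_that("randomizing half the positions halves the coherent amplitude", {
  L <- 2^15
  v <- 0.5 + 0.5 * cos(2 * pi * 1000 * (0:(L - 1)) / L)
  win <- function(x) {
    sp <- windowedNormSpectrum(fourierMagnitudes(x), window = 200, step = 50)
    tab <- spectrumTable(sp)
    max(tab$norm[tab$fStart <= 1000 & tab$fStart + 200 > 1000])
  }
  peak0 <- win(v)
  expect_identical(randomizeControl(v, integer(0)), v)   # empty subset
  full <- randomizeControl(v, 0:(L - 1), seed = 1)
  expect_true(all(full >= 0 & full <= 1))
  ratios <- vapply(1:10, function(s) {
    set.seed(s + 100)
    half <- sample(0:(L - 1), L / 2)
    win(randomizeControl(v, half, seed = s)) / peak0
  }, numeric(1))
  expect_gt(mean(ratios), 0.25)
})

test_that("segment spectra exclude bad segments and keep good ones", {
  set.seed(12)
  L <- 3e4
  v <- 0.4 + 0.1 * cos(2 * pi * (0:(L - 1)) / 200) + rnorm(L, sd = 0.02)
  disq <- rep(FALSE, L)
  disq[10001 + 0:1500] <- TRUE     # second segment 15% disqualified
  res <- segmentSpectra(v, disq, segmentLength = 1e4, window = 20, step = 5)
  tab <- segmentTable(res$segments)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$included, c(TRUE, FALSE, TRUE))
  expect_equal(names(res$spectra), c("1", "3"))
  ## the planted 200 bp period sits at frequency 50 of a 10 kb segment
  pk <- peakWindow(res$spectra[["1"]])
  expect_true(pk$fStart <= 50 && pk$fStart + 20 > 50)
})
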