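test_that("architecture validation enforces the word-encoding kernels", {
  expect_error(architectureSpec(5, convFilters = 8, kernelSizes = 5),
               "3 or 4")
  expect_error(architectureSpec(5, convFilters = c(8, 8), kernelSizes = 3),
               "same length")
  expect_error(architectureSpec(1, convFilters = c(8, 8),
                                kernelSizes = c(3, 3)), "whole input")
  s <- architectureSpec(50, convFilters = 64, kernelSizes = 4,
                        lstmUnits = c(100, 100))
  expect_equal(s$flankSize, 50L)
})

test_that("parameter counts follow the standard LSTM formula", {
  ## a single bidirectional LSTM of H=8 on 4-dim input: 2*4*(8*(4+8)+8) = 832
  spec <- architectureSpec(3, convFilters = integer(0),
                           kernelSizes = integer(0), lstmUnits = 8)
  m <- buildModel(spec, seed = 1)
  lstmPars <- sum(vapply(unlist(m@weights$lstm, recursive = FALSE),
                         function(dir) sum(lengths(dir)), numeric(1)))
  expect_equal(lstmPars, 832)
  ## plus the 4-way softmax head on the 16-dim summary: 16*4 + 4
  expect_equal(parameterCount(m), 832 + 68)

  ## doubling the flank leaves the count unchanged (recurrent weight sharing)
  m2 <- buildModel(architectureSpec(6, convFilters = integer(0),
                                    kernelSizes = integer(0), lstmUnits = 8),
                   seed = 1)
  expect_equal(parameterCount(m2), parameterCount(m))

  ## conv layer contributes kernel*inDim*filters + filters
  m3 <- buildModel(architectureSpec(5, convFilters = 16, kernelSizes = 3,
                                    lstmUnits = 8), seed = 1)
  expect_equal(parameterCount(m3),
               (3 * 4 * 16 + 16) + 2 * 4 * (8 * (16 + 8) + 8) + 68)
})

test_that("prediction emits distributions, deterministically", {
  m <- buildModel(architectureSpec(4, convFilters = 8, kernelSizes = 3,
                                   lstmUnits = 6), seed = 2)
  g <- GenomeSequence("g", randomBases(200, seed = 5))
  p <- predictPositions(m, g, 10:30)
  expect_equal(rowSums(p), rep(1, 21), tolerance = 1e-9)
  expect_true(all(p > 0))
  ## duplicated contexts give identical outputs
  cw <- extractContext(g, 20, 4)
  pb <- predictBatch(m, list(cw, cw))
  expect_equal(pb[1, ], pb[2, ])
  expect_equal(rowSums(pb), c(1, 1), tolerance = 1e-9)
  ## flank mismatch is a contract error
  cw3 <- extractContext(g, 20, 3)
  expect_error(predictBatch(m, list(cw3)), "flank size")
  ## bidirectional output is still a distribution
  pbd <- predictPositions(m, g, 10:20, bidirectional = TRUE)
  expect_equal(rowSums(pbd), rep(1, 11), tolerance = 1e-9)
})

test_that("training-position sampling is uniform, seeded and masked", {
  g <- GenomeSequence("g", randomBases(1004, seed = 2))
  mask <- buildPositionMask(g, 2)
  all <- sampleTrainingPositions(g, mask, fraction = 1, seed = 1)
  expect_equal(all, which(!disqualified(mask)) - 1L)
  half <- sampleTrainingPositions(g, mask, fraction = 0.5, seed = 9)
  expect_length(half, 500L)
  expect_false(any(disqualified(mask)[half + 1L]))
  expect_identical(half, sampleTrainingPositions(g, mask, 0.5, seed = 9))
  expect_false(identical(half, sampleTrainingPositions(g, mask, 0.5, seed = 10)))
})

test_that("training on a constant genome converges to certainty", {
  g <- GenomeSequence("a", strrep("A", 1500))
  m <- buildModel(architectureSpec(3, convFilters = 8, kernelSizes = 3,
                                   lstmUnits = 6), seed = 1)
  cfg <- trainingConfig(sampleFraction = 0.5, rounds = 3,
                        batchesPerRound = 25, batchSize = 64,
                        validationSize = 100, seed = 2)
  mt <- trainModel(m, g, cfg)
  log <- trainingLog(mt)
  expect_equal(nrow(log), 3L)
  expect_equal(log$valAccuracy[3], 1.0)
  expect_equal(argmaxBase(predictPositions(mt, g, 100)), "A")
  ## identical seeds reproduce the log exactly
  mt2 <- trainModel(m, g, cfg)
  expect_equal(trainingLog(mt2), log, tolerance = 1e-12)
})

test_that("validation loss falls toward the chain's conditional entropy", {
  chain <- toyChain1()
  gen <- generateGenome(syntheticGenomeSpec(1.2e5, order = 1,
                                            transitionTable = chain@probs,
                                            seed = 6))
  m <- buildModel(architectureSpec(3, convFilters = 12, kernelSizes = 3,
                                   lstmUnits = 12), seed = 4)
  cfg <- trainingConfig(sampleFraction = 0.3, rounds = 4,
                        batchesPerRound = 80, batchSize = 128,
                        validationSize = 2000, seed = 5,
                        learningRate = 0.01, learningRateDecay = 0.85)
  mt <- trainModel(m, gen$genome, cfg)
  log <- trainingLog(mt)
  expect_equal(nrow(log), 4L)
  ## improvement over the first rounds
  expect_lt(log$valLoss[2], log$valLoss[1])
  expect_lt(log$valLoss[4], log$valLoss[1])
  ## approaches the left-conditional entropy rate from above (the
  ## bidirectional floor is even lower)
  Hl <- conditionalEntropy(chain, "left")
  expect_lt(log$valLoss[4], Hl + 0.1)
  expect_gt(log$valLoss[4], conditionalEntropy(chain, "central", k = 1) - 0.02)
})

test_that("chromosome-split training keeps train and validation disjoint", {
  gA <- generateGenome(syntheticGenomeSpec(8000, order = 0, seed = 1,
                                           name = "chrA"))$genome
  gB <- generateGenome(syntheticGenomeSpec(8000, order = 0, seed = 2,
                                           name = "chrB"))$genome
  m <- buildModel(architectureSpec(2, convFilters = integer(0),
                                   kernelSizes = integer(0), lstmUnits = 4),
                  seed = 3)
  cfg <- trainingConfig(sampleFraction = 1, rounds = 1, batchesPerRound = 5,
                        batchSize = 32, validationSize = 500, seed = 4,
                        trainChromosomes = "chrA", testChromosomes = "chrB")
  mt <- trainModel(m, list(gA, gB), cfg)
  expect_equal(nrow(trainingLog(mt)), 1L)
  ## with sampleFraction 1 on chrA, validation could only come from chrB:
  ## training on chrA alone must still leave validation positions available
  expect_true(is.finite(trainingLog(mt)$valLoss))
})

test_that("divergent training aborts with a diagnostic", {
  g <- GenomeSequence("a", strrep("A", 600))
  m <- buildModel(architectureSpec(2, convFilters = integer(0),
                                   kernelSizes = integer(0), lstmUnits = 4),
                  seed = 1)
  cfg <- trainingConfig(sampleFraction = 0.5, rounds = 1,
                        batchesPerRound = 10, batchSize = 32,
                        validationSize = 50, seed = 2, learningRate = Inf)
  expect_error(trainModel(m, g, cfg), "non-finite|aborted")
})
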