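#' @include count-models.R
NULL

## ---------------------------------------------------------------------------
## A small convolutional + bidirectional-LSTM context model, written directly
## in base R matrix code (no deep-learning framework is assumed). Sequences
## are represented as lists of per-timestep B x D matrices; training is
## mini-batch Adam on the categorical cross-entropy of the 4-way softmax
## output. Sized for desk-scale experiments on synthetic genomes, not for
## GPU-scale training of mammalian genomes.
## ---------------------------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Architecture of the neural context model
#'
#' One or two valid (unpadded) convolution layers perform the "word
#' encoding" of tri- or quadro-nucleotides (kernel length 3 or 4, ReLU),
#' followed by one or more bidirectional LSTM layers; the final forward and
#' backward hidden states feed an optional ReLU dense layer and a fixed
#' 4-way softmax. The focus base is excluded from the input window: the
#' model sees `2 * flankSize` one-hot encoded bases (left flank then right
#' flank, 5' to 3').
#'
#' @param flankSize context size F on each side of the focus.
#' @param convFilters integer vector of filter counts, one per conv layer
#'   (empty for none).
#' @param kernelSizes kernel length per conv layer, each 3 or 4.
#' @param lstmUnits hidden units per bidirectional LSTM layer (>= 1 layer).
#' @param denseUnits optional ReLU dense layer size before the softmax.
#' @return a validated list with class attribute kept plain (it is stored
#'   inside [NeuralModel-class]).
#' @export
architectureSpec <- function(flankSize, convFilters = 16L, kernelSizes = 3L,
                             lstmUnits = 16L, denseUnits = NULL) {
  flankSize <- as.integer(flankSize)
  convFilters <- as.integer(convFilters)
  kernelSizes <- as.integer(kernelSizes)
  lstmUnits <- as.integer(lstmUnits)
  stopifnot(flankSize >= 1L, length(lstmUnits) >= 1L, all(lstmUnits >= 1L))
  if (length(convFilters) != length(kernelSizes))
    stop("convFilters and kernelSizes must have the same length")
  if (length(kernelSizes) && !all(kernelSizes %in% c(3L, 4L)))
    stop("kernel lengths must be 3 or 4 (tri-/quadro-nucleotide encoding)")
  T0 <- 2L * flankSize
  if (sum(kernelSizes - 1L) >= T0)
    stop("convolutions consume the whole input window")
  list(flankSize = flankSize, convFilters = convFilters,
       kernelSizes = kernelSizes, lstmUnits = lstmUnits,
       denseUnits = if (is.null(denseUnits)) integer(0)
                    else as.integer(denseUnits))
}

.glorot <- function(nin, nout, nr, nc) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained neural context model
#'
#' Weights are Glorot-uniform initialized (LSTM forget-gate biases at 1),
#' deterministically for a given seed.
#'
#' @param spec an [architectureSpec()].
#' @param seed integer seed for the initialization.
#' @return a [NeuralModel-class]; [parameterCount()] gives its exact
#'   trainable-weight count.
#' @export
buildModel <- function(spec, seed = 1L) {
  set.seed(seed)
  weights <- list(conv = list(), lstm = list(), dense = NULL, out = NULL)
  D <- 4L
  for (l in seq_along(spec$convFilters)) {
    K <- spec$kernelSizes[l]; Fl <- spec$convFilters[l]
    weights$conv[[l]] <- list(W = .glorot(K * D, Fl, K * D, Fl),
                              b = numeric(Fl))
    D <- Fl
  }
  for (l in seq_along(spec$lstmUnits)) {
    H <- spec$lstmUnits[l]
    mk <- function() {
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget gate bias
      list(Wx = .glorot(D + H, 4L * H, D, 4L * H),
           Wh = .glorot(D + H, 4L * H, H, 4L * H), b = b)
    }
    weights$lstm[[l]] <- list(fwd = mk(), bwd = mk())
    D <- 2L * H
  }
  if (length(spec$denseUnits)) {
    weights$dense <- list(W = .glorot(D, spec$denseUnits, D, spec$denseUnits),
                          b = numeric(spec$denseUnits))
    D <- spec$denseUnits
  }
  weights$out <- list(W = .glorot(D, 4L, D, 4L), b = numeric(4L))
  new("NeuralModel", spec = spec, weights = weights,
      trainingLog = data.frame(round = integer(0), trainLoss = numeric(0),
                               valLoss = numeric(0), valAccuracy = numeric(0)),
      trained = FALSE)
}

#' @rdname modelFlankSize
#' @export
setMethod("modelFlankSize", "NeuralModel", function(model)
  model@spec$flankSize)

#' @describeIn parameterCount exact trainable-weight count of a neural model.
#' @export
setMethod("parameterCount", "NeuralModel", function(x, k) {
  tot <- 0
  walk <- function(w) {
    if (is.list(w)) for (e in w) walk(e)
    else if (is.numeric(w)) tot <<- tot + length(w)
  }
  walk(x@weights)
  tot
})

setMethod("show", "NeuralModel", function(object) {
  s <- object@spec
  cat("NeuralModel: flank", s$flankSize,
      if (length(s$convFilters))
        paste0("| conv ", paste0(s$convFilters, "x", s$kernelSizes,
                                 collapse = ", ")) else "| no conv",
      "| biLSTM", paste(s$lstmUnits, collapse = "+"),
      if (length(s$denseUnits)) paste("| dense", s$denseUnits) else "",
      "|", parameterCount(object), "parameters,",
      if (object@trained) paste0("trained (", nrow(object@trainingLog),
                                 " rounds)") else "untrained", "\n")
})

#' @rdname NeuralModel-class
#' @param model a NeuralModel.
#' @return data.frame with one row per completed training round (round,
#'   trainLoss, valLoss, valAccuracy).
#' @export
trainingLog <- function(model) model@trainingLog

## ---- forward / backward ---------------------------------------------------

## seqs: list over time of B x D matrices. Returns list(probs, cache).
.nnForward <- function(weights, spec, seqs, needCache = FALSE) {
  cache <- list(conv = list(), lstm = list())
  for (l in seq_along(weights$conv)) {
    cv <- weights$conv[[l]]
    K <- spec$kernelSizes[l]
    Tin <- length(seqs)
    Tout <- Tin - K + 1L
    out <- vector("list", Tout)
    pre <- if (needCache) vector("list", Tout) else NULL
    uns <- if (needCache) vector("list", Tout) else NULL
    for (t in seq_len(Tout)) {
      U <- do.call(cbind, seqs[t:(t + K - 1L)])
      Z <- sweep(U %*% cv$W, 2L, cv$b, "+")
      A <- Z * (Z > 0)
      out[[t]] <- A
      if (needCache) { pre[[t]] <- Z; uns[[t]] <- U }
    }
    if (needCache)
      cache$conv[[l]] <- list(input = seqs, pre = pre, U = uns)
    seqs <- out
  }
  for (l in seq_along(weights$lstm)) {
    lw <- weights$lstm[[l]]
    Tn <- length(seqs)
    B <- nrow(seqs[[1L]])
    H <- spec$lstmUnits[l]
    runDir <- function(par, order) {
      h <- matrix(0, B, H); c0 <- matrix(0, B, H)
      hs <- vector("list", Tn)
      cc <- if (needCache) vector("list", Tn) else NULL
      for (t in order) {
        G <- seqs[[t]] %*% par$Wx + h %*% par$Wh
        G <- sweep(G, 2L, par$b, "+")
        i <- .sigmoid(G[, 1:H, drop = FALSE])
        f <- .sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
        g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
        o <- .sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
        cNew <- f * c0 + i * g
        tc <- tanh(cNew)
        hNew <- o * tc
        if (needCache)
          cc[[t]] <- list(i = i, f = f, g = g, o = o, cPrev = c0,
                          c = cNew, tc = tc, hPrev = h)
        hs[[t]] <- hNew
        h <- hNew; c0 <- cNew
      }
      list(hs = hs, cache = cc)
    }
    fw <- runDir(lw$fwd, seq_len(Tn))
    bw <- runDir(lw$bwd, rev(seq_len(Tn)))
    if (needCache)
      cache$lstm[[l]] <- list(input = seqs, fwd = fw$cache, bwd = bw$cache)
    seqs <- lapply(seq_len(Tn),
                   function(t) cbind(fw$hs[[t]], bw$hs[[t]]))
  }
  Tn <- length(seqs)
  H <- spec$lstmUnits[length(spec$lstmUnits)]
  feat <- cbind(seqs[[Tn]][, 1:H, drop = FALSE],
                seqs[[1L]][, (H + 1):(2 * H), drop = FALSE])
  if (!is.null(weights$dense)) {
    Zd <- sweep(feat %*% weights$dense$W, 2L, weights$dense$b, "+")
    Ad <- Zd * (Zd > 0)
    if (needCache) cache$dense <- list(input = feat, pre = Zd)
    feat <- Ad
  }
  logits <- sweep(feat %*% weights$out$W, 2L, weights$out$b, "+")
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  colnames(probs) <- .BASES
  if (needCache) {
    cache$outInput <- feat
    cache$Tn <- Tn
    cache$B <- nrow(probs)
  }
  list(probs = probs, cache = cache)
}

## Gradients of the mean cross-entropy wrt all weights. y: integer 1..4.
.nnBackward <- function(weights, spec, cache, probs, y) {
  B <- cache$B
  grads <- list(conv = list(), lstm = list(), dense = NULL, out = NULL)
  dLogits <- probs
  dLogits[cbind(seq_len(B), y)] <- dLogits[cbind(seq_len(B), y)] - 1
  dLogits <- dLogits / B
  grads$out <- list(W = crossprod(cache$outInput, dLogits),
                    b = colSums(dLogits))
  dFeat <- tcrossprod(dLogits, weights$out$W)
  if (!is.null(weights$dense)) {
    dZd <- dFeat * (cache$dense$pre > 0)
    grads$dense <- list(W = crossprod(cache$dense$input, dZd),
                        b = colSums(dZd))
    dFeat <- tcrossprod(dZd, weights$dense$W)
  }
  nL <- length(weights$lstm)
  H <- spec$lstmUnits[nL]
  Tn <- cache$Tn
  ## upstream gradient on the last LSTM layer's output sequence
  dSeq <- lapply(seq_len(Tn), function(t) matrix(0, B, 2L * H))
  dSeq[[Tn]][, 1:H] <- dFeat[, 1:H, drop = FALSE]
  dSeq[[1L]][, (H + 1):(2 * H)] <- dFeat[, (H + 1):(2 * H), drop = FALSE]
  for (l in rev(seq_len(nL))) {
    lc <- cache$lstm[[l]]
    Hl <- spec$lstmUnits[l]
    inSeq <- lc$input
    Din <- ncol(inSeq[[1L]])
    dIn <- lapply(seq_len(Tn), function(t) matrix(0, B, Din))
    backDir <- function(par, cc, order, cols) {
      dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
      dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
      db <- numeric(length(par$b))
      dhNext <- matrix(0, B, Hl)
      dcNext <- matrix(0, B, Hl)
      for (t in rev(order)) {
        s <- cc[[t]]
        dh <- dSeq[[t]][, cols, drop = FALSE] + dhNext
        dc <- dh * s$o * (1 - s$tc^2) + dcNext
        di <- dc * s$g * s$i * (1 - s$i)
        df <- dc * s$cPrev * s$f * (1 - s$f)
        dg <- dc * s$i * (1 - s$g^2)
        do <- dh * s$tc * s$o * (1 - s$o)
        dG <- cbind(di, df, dg, do)
        dWx <- dWx + crossprod(inSeq[[t]], dG)
        dWh <- dWh + crossprod(s$hPrev, dG)
        db <- db + colSums(dG)
        dIn[[t]] <<- dIn[[t]] + tcrossprod(dG, par$Wx)
        dhNext <- tcrossprod(dG, par$Wh)
        dcNext <- dc * s$f
      }
      list(Wx = dWx, Wh = dWh, b = db)
    }
    gFwd <- backDir(weights$lstm[[l]]$fwd, lc$fwd, seq_len(Tn), 1:Hl)
    gBwd <- backDir(weights$lstm[[l]]$bwd, lc$bwd, rev(seq_len(Tn)),
                    (Hl + 1):(2 * Hl))
    grads$lstm[[l]] <- list(fwd = gFwd, bwd = gBwd)
    dSeq <- dIn
  }
  for (l in rev(seq_along(weights$conv))) {
    cc <- cache$conv[[l]]
    K <- spec$kernelSizes[l]
    cv <- weights$conv[[l]]
    Tout <- length(cc$pre)
    Din <- ncol(cc$input[[1L]])
    dW <- matrix(0, nrow(cv$W), ncol(cv$W))
    db <- numeric(length(cv$b))
    dInput <- lapply(seq_along(cc$input), function(t) matrix(0, B, Din))
    for (t in seq_len(Tout)) {
      dZ <- dSeq[[t]] * (cc$pre[[t]] > 0)
      dW <- dW + crossprod(cc$U[[t]], dZ)
      db <- db + colSums(dZ)
      dU <- tcrossprod(dZ, cv$W)
      for (o in seq_len(K)) {
        colsU <- ((o - 1L) * Din + 1L):(o * Din)
        dInput[[t + o - 1L]] <- dInput[[t + o - 1L]] + dU[, colsU, drop = FALSE]
      }
    }
    grads$conv[[l]] <- list(W = dW, b = db)
    dSeq <- dInput
  }
  grads
}

## ---- Adam over nested weight lists ---------------------------------------

.zerosLike <- function(w) {
  if (is.list(w)) lapply(w, .zerosLike)
  else if (is.numeric(w)) w * 0
  else w
}

.adamStep <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  step <- function(w, g, m, v) {
    if (is.null(w) || is.null(g)) return(list(w = w, m = m, v = v))
    if (is.list(w)) {
      out <- lapply(seq_along(w),
                    function(i) step(w[[i]], g[[i]], m[[i]], v[[i]]))
      return(list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- step(w, g, state$m, state$v)
  ## restore the list names lost by lapply-over-indices
  relabel <- function(src, tmpl) {
    if (is.list(tmpl)) {
      names(src) <- names(tmpl)
      for (i in seq_along(src))
        if (is.list(tmpl[[i]])) src[[i]] <- relabel(src[[i]], tmpl[[i]])
    }
    src
  }
  list(w = relabel(res$w, w),
       state = list(m = relabel(res$m, w), v = relabel(res$v, w)))
}

## ---- input construction ---------------------------------------------------

## One-hot input sequence (list over 2F timesteps of B x 4 matrices) for
## 0-based focus positions; reverse = TRUE builds the reverse-strand window.
.neuralInput <- function(codes, positions, F, reverse = FALSE) {
  idx <- as.integer(positions) + 1L
  offs <- c(-(F:1), 1:F)
  if (reverse) offs <- rev(offs)
  B <- length(idx)
  lapply(offs, function(off) {
    cd <- codes[idx + off]
    if (reverse) cd <- 5L - cd
    m <- matrix(0, B, 4L)
    m[cbind(seq_len(B), cd)] <- 1
    m
  })
}

## ---- training -------------------------------------------------------------

#' Training configuration for the neural model
#'
#' @param sampleFraction fraction of qualified positions sampled (without
#'   replacement) as the training pool; about one third is a sizeable
#'   fraction appropriate for large genomes.
#' @param rounds number of training rounds, each ended by a validation pass.
#' @param batchesPerRound,batchSize mini-batches per round and their size.
#' @param validationSize positions held out for validation (disjoint from the
#'   training pool).
#' @param seed integer seed controlling sampling, initialization order and
#'   batch composition (identical seeds + single-threaded BLAS reproduce the
#'   log exactly).
#' @param learningRate Adam learning rate.
#' @param learningRateDecay multiplicative decay of the learning rate after
#'   each round (1 = constant).
#' @param trainChromosomes,testChromosomes optional sequence-name lists for a
#'   true train/test split by chromosome.
#' @return a validated list.
#' @export
trainingConfig <- function(sampleFraction = 1 / 3, rounds = 5L,
                           batchesPerRound = 200L, batchSize = 128L,
                           validationSize = 5000L, seed = 1L,
                           learningRate = 0.005, learningRateDecay = 1,
                           trainChromosomes = NULL,
                           testChromosomes = NULL) {
  stopifnot(sampleFraction > 0, sampleFraction <= 1, rounds >= 1,
            batchesPerRound >= 1, batchSize >= 1, validationSize >= 1)
  list(sampleFraction = sampleFraction, rounds = as.integer(rounds),
       batchesPerRound = as.integer(batchesPerRound),
       batchSize = as.integer(batchSize),
       validationSize = as.integer(validationSize), seed = as.integer(seed),
       learningRate = learningRate,
       learningRateDecay = learningRateDecay,
       trainChromosomes = trainChromosomes,
       testChromosomes = testChromosomes)
}

#' Seeded sample of qualified training positions
#'
#' Uniform sample without replacement of `round(fraction * n)` qualified
#' positions; deterministic given the seed.
#'
#' @param genome a [GenomeSequence-class].
#' @param mask a [PositionMask-class].
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return sorted 0-based positions, all qualified.
#' @export
sampleTrainingPositions <- function(genome, mask, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  qual <- which(!disqualified(mask)) - 1L
  if (length(qual) == 0L)
    stop("no qualified positions to sample from")
  nTake <- max(1L, round(fraction * length(qual)))
  if (nTake >= length(qual)) return(qual)
  set.seed(seed)
  sort(sample(qual, nTake))
}

#' Train a neural context model
#'
#' Mini-batch Adam on the categorical cross-entropy of the softmax output
#' (single strand). Training is divided into rounds, each ended by a
#' validation pass on held-out positions; the returned model carries the
#' per-round log. Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an untrained (or previously trained) [NeuralModel-class].
#' @param genomes a [GenomeSequence-class] or list of them.
#' @param config a [trainingConfig()].
#' @return the trained model with its [trainingLog()] populated.
#' @export
trainModel <- function(model, genomes, config = trainingConfig()) {
  stopifnot(is(model, "NeuralModel"))
  if (is(genomes, "GenomeSequence")) genomes <- list(genomes)
  F <- model@spec$flankSize
  names(genomes) <- vapply(genomes, seqName, character(1))
  codesList <- lapply(genomes, baseCodes)
  qualList <- lapply(genomes, function(g)
    which(!disqualified(buildPositionMask(g, F))) - 1L)

  trainNames <- if (is.null(config$trainChromosomes)) names(genomes)
                else intersect(names(genomes), config$trainChromosomes)
  valNames <- if (is.null(config$testChromosomes)) trainNames
              else intersect(names(genomes), config$testChromosomes)
  if (length(trainNames) == 0L) stop("no training chromosomes selected")

  set.seed(config$seed)
  trainTab <- do.call(rbind, lapply(trainNames, function(nm) {
    q <- qualList[[nm]]
    nTake <- max(1L, round(config$sampleFraction * length(q)))
    cbind(match(nm, names(genomes)),
          if (nTake >= length(q)) q else sort(sample(q, nTake)))
  }))
  ## validation positions: disjoint from the training pool
  valTab <- do.call(rbind, lapply(valNames, function(nm) {
    gi <- match(nm, names(genomes))
    avail <- qualList[[nm]]
    if (is.null(config$testChromosomes) || nm %in% trainNames)
      avail <- setdiff(avail, trainTab[trainTab[, 1L] == gi, 2L])
    cbind(gi, avail)
  }))
  if (is.null(valTab) || nrow(valTab) == 0L)
    stop("no validation positions available (training pool covers everything)")
  vSel <- if (nrow(valTab) > config$validationSize)
    valTab[sort(sample.int(nrow(valTab), config$validationSize)), , drop = FALSE]
  else valTab
  if (nrow(trainTab) == 0L) stop("empty training sample")

  weights <- model@weights
  adam <- list(m = .zerosLike(weights), v = .zerosLike(weights))
  tGlobal <- 0L
  log <- model@trainingLog
  pool <- sample.int(nrow(trainTab))
  poolAt <- 1L

  evalBatchedLoss <- function(tab) {
    tot <- 0; hits <- 0
    bs <- 2048L
    for (s in seq(1L, nrow(tab), by = bs)) {
      rows <- s:min(s + bs - 1L, nrow(tab))
      for (gi in unique(tab[rows, 1L])) {
        sel <- rows[tab[rows, 1L] == gi]
        codes <- codesList[[gi]]
        x <- .neuralInput(codes, tab[sel, 2L], F)
        y <- codes[tab[sel, 2L] + 1L]
        pr <- .nnForward(weights, model@spec, x)$probs
        pv <- pmax(pr[cbind(seq_along(sel), y)], .LOGP_FLOOR)
        tot <- tot - sum(log(pv))
        hits <- hits + sum(max.col(pr, ties.method = "first") == y)
      }
    }
    c(loss = tot / nrow(tab), acc = hits / nrow(tab))
  }

  lr <- config$learningRate
  decay <- if (is.null(config$learningRateDecay)) 1 else config$learningRateDecay
  for (r in seq_len(config$rounds)) {
    batchLoss <- numeric(config$batchesPerRound)
    for (bIdx in seq_len(config$batchesPerRound)) {
      if (poolAt + config$batchSize - 1L > length(pool)) {
        pool <- sample.int(nrow(trainTab))
        poolAt <- 1L
      }
      take <- pool[poolAt:(poolAt + config$batchSize - 1L)]
      poolAt <- poolAt + config$batchSize
      ## one forward/backward per genome represented in the batch
      gTotal <- NULL
      lossSum <- 0
      nTot <- length(take)
      for (gi in unique(trainTab[take, 1L])) {
        sel <- take[trainTab[take, 1L] == gi]
        codes <- codesList[[gi]]
        x <- .neuralInput(codes, trainTab[sel, 2L], F)
        y <- codes[trainTab[sel, 2L] + 1L]
        fw <- .nnForward(weights, model@spec, x, needCache = TRUE)
        pv <- pmax(fw$probs[cbind(seq_along(sel), y)], .LOGP_FLOOR)
        lossSum <- lossSum - sum(log(pv))
        g <- .nnBackward(weights, model@spec, fw$cache, fw$probs, y)
        wgt <- length(sel) / nTot
        gTotal <- if (is.null(gTotal)) .scaleGrads(g, wgt)
                  else .addGrads(gTotal, .scaleGrads(g, wgt))
      }
      batchLoss[bIdx] <- lossSum / nTot
      if (!is.finite(batchLoss[bIdx]))
        stop("training aborted: non-finite loss in round ", r, ", batch ",
             bIdx)
      tGlobal <- tGlobal + 1L
      upd <- .adamStep(weights, gTotal, adam, lr, tGlobal)
      weights <- upd$w
      adam <- upd$state
    }
    lr <- lr * decay
    val <- evalBatchedLoss(vSel)
    log <- rbind(log, data.frame(round = r, trainLoss = mean(batchLoss),
                                 valLoss = unname(val["loss"]),
                                 valAccuracy = unname(val["acc"])))
  }
  initialize(model, weights = weights, trainingLog = log, trained = TRUE)
}

.scaleGrads <- function(g, s) {
  if (is.list(g)) lapply(g, .scaleGrads, s = s)
  else if (is.numeric(g)) g * s else g
}

.addGrads <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .addGrads(a[[i]], b[[i]])
    a
  } else if (is.numeric(a)) a + b else a
}

#' @rdname predictPositions
#' @export
setMethod("predictPositions", "NeuralModel",
  function(model, genome, positions, bidirectional = FALSE) {
    codes <- baseCodes(genome)
    F <- model@spec$flankSize
    idx <- .checkQualified(codes, positions, F, "central")
    B <- length(idx)
    out <- matrix(NA_real_, B, 4L, dimnames = list(NULL, .BASES))
    bs <- 2048L
    for (s in seq(1L, B, by = bs)) {
      rows <- s:min(s + bs - 1L, B)
      x <- .neuralInput(codes, idx[rows] - 1L, F)
      p <- .nnForward(model@weights, model@spec, x)$probs
      if (bidirectional) {
        xr <- .neuralInput(codes, idx[rows] - 1L, F, reverse = TRUE)
        pr <- .nnForward(model@weights, model@spec, xr)$probs
        p <- (p + pr[, 4:1, drop = FALSE]) / 2
      }
      out[rows, ] <- p
    }
    out
  })

#' Predict probabilities for a batch of context windows
#'
#' @param model a trained [NeuralModel-class].
#' @param contexts list of [ContextWindow-class] objects, all with the
#'   model's flank size.
#' @return numeric matrix (one row per context, columns A,C,G,T), batch order
#'   preserved; every row sums to 1.
#' @export
predictBatch <- function(model, contexts) {
  stopifnot(is(model, "NeuralModel"))
  if (is(contexts, "ContextWindow")) contexts <- list(contexts)
  F <- model@spec$flankSize
  ok <- vapply(contexts, function(cw) cw@flankSize == F, logical(1))
  if (!all(ok))
    stop("context flank size does not match the model's flank size ", F)
  strs <- vapply(contexts, function(cw) paste0(cw@left, cw@right),
                 character(1))
  codes <- lapply(strs, baseCodes)
  if (any(vapply(codes, function(cd) any(cd == .N_CODE), logical(1))))
    stop("contexts containing N are disqualified")
  B <- length(contexts)
  x <- lapply(seq_len(2L * F), function(t) {
    m <- matrix(0, B, 4L)
    m[cbind(seq_len(B), vapply(codes, `[[`, integer(1), t))] <- 1
    m
  })
  .nnForward(model@weights, model@spec, x)$probs
}
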