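#' @include count-models.R
NULL

#' Describe a synthetic genome with known structure
#'
#' A fully specified generative model for test genomes: an order-k Markov
#' chain, optional planted periodic GC modulation (the probability of drawing
#' G or C at position i is `gcBaseline + gcAmplitude * cos(2*pi*i/gcPeriod)`,
#' applied as a classwise reweighting of the chain's emissions), optional
#' soft-masked repeat copies, and N blocks overwritten last. Everything is
#' deterministic given `seed`.
#'
#' @param length genome length in bases.
#' @param order Markov order of the generating chain (0-3).
#' @param transitionTable 4^order x 4 row-stochastic matrix (rows ordered by
#'   left k-mer code, A...A first); default is the uniform table.
#' @param gcPeriod planted GC period in bases, or NA for none.
#' @param gcAmplitude,gcBaseline cosine amplitude and mean of the G+C
#'   probability; `gcBaseline +/- gcAmplitude` must stay inside (0,1).
#' @param repeatMotif base string inserted (soft-masked) as repeat copies, or
#'   NA.
#' @param repeatCopies number of non-overlapping copies to insert.
#' @param nBlocks integer matrix (n x 2) of 0-based half-open N blocks, or
#'   NULL.
#' @param seed integer seed.
#' @param name sequence name.
#' @return a [SyntheticGenomeSpec-class].
#' @export
syntheticGenomeSpec <- function(length, order = 0L, transitionTable = NULL,
                                gcPeriod = NA_real_, gcAmplitude = 0,
                                gcBaseline = 0.5, repeatMotif = NA_character_,
                                repeatCopies = 0L, nBlocks = NULL, seed = 1L,
                                name = "synthetic") {
  order <- as.integer(order)
  if (is.null(transitionTable))
    transitionTable <- matrix(0.25, nrow = 4^order, ncol = 4L)
  tt <- unname(as.matrix(transitionTable))
  if (is.null(nBlocks)) nBlocks <- matrix(integer(0), ncol = 2L)
  new("SyntheticGenomeSpec", length = as.numeric(length), order = order,
      transitionTable = tt, gcPeriod = as.numeric(gcPeriod),
      gcAmplitude = as.numeric(gcAmplitude),
      gcBaseline = as.numeric(gcBaseline),
      repeatMotif = as.character(repeatMotif),
      repeatCopies = as.integer(repeatCopies),
      nBlocks = matrix(as.integer(nBlocks), ncol = 2L),
      seed = as.integer(seed), name = as.character(name))
}

setMethod("show", "SyntheticGenomeSpec", function(object) {
  cat("SyntheticGenomeSpec:", format(object@length, big.mark = ","),
      "bases, order", object@order,
      if (!is.na(object@gcPeriod))
        paste0(", GC period ", object@gcPeriod, " (amp ", object@gcAmplitude,
               ", base ", object@gcBaseline, ")") else "",
      if (object@repeatCopies > 0)
        paste0(", ", object@repeatCopies, " repeat copies") else "",
      ", seed ", object@seed, "\n", sep = "")
})

#' A random row-stochastic transition table
#'
#' Rows are independent draws from a symmetric Dirichlet, handy for building
#' non-trivial generating chains in tests.
#'
#' @param order Markov order.
#' @param seed integer seed.
#' @param alpha Dirichlet concentration (smaller = more deterministic rows).
#' @return a 4^order x 4 matrix with k-mer rownames.
#' @export
randomTransitionTable <- function(order, seed = 1L, alpha = 1) {
  set.seed(seed)
  n <- 4^order
  g <- matrix(stats::rgamma(n * 4L, shape = alpha), nrow = n)
  tt <- g / rowSums(g)
  rownames(tt) <- if (order > 0) .decodeContext(0:(n - 1), order) else "-"
  colnames(tt) <- .BASES
  tt
}

#' The default "small" test world
#'
#' 2 Mb, order-2 chain, planted 200 bp GC period (amplitude 0.1, baseline
#' 0.4), 50 soft-masked copies of a 300-base motif — sized so the full
#' pipeline runs in minutes on one CPU.
#'
#' @param seed integer seed.
#' @param length override the 2 Mb default (the 50 repeat copies scale
#'   proportionally so short test genomes stay packable).
#' @return a [SyntheticGenomeSpec-class].
#' @export
smallSyntheticSpec <- function(seed = 1L, length = 2e6) {
  set.seed(seed + 7L)
  motif <- paste0(sample(.BASES, 300L, replace = TRUE), collapse = "")
  copies <- max(1L, as.integer(round(50 * length / 2e6)))
  syntheticGenomeSpec(length = length, order = 2L,
                      transitionTable = randomTransitionTable(2L, seed = seed,
                                                              alpha = 0.8),
                      gcPeriod = 200, gcAmplitude = 0.1, gcBaseline = 0.4,
                      repeatMotif = motif, repeatCopies = copies, seed = seed,
                      name = "synth_small")
}

#' Generate a genome from a synthetic spec
#'
#' Samples the base sequence from the chain (with optional position-dependent
#' GC reweighting), inserts non-overlapping soft-masked repeat copies at
#' seeded positions, then overwrites N blocks. Identical seeds give
#' byte-identical genomes.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @return list with elements `genome` (a [GenomeSequence-class]) and `model`
#'   (the generating chain as a [MarkovModel-class] handle usable with
#'   [predictPositions()] and the oracle functions).
#' @export
generateGenome <- function(spec) {
  stopifnot(is(spec, "SyntheticGenomeSpec"))
  validObject(spec)
  L <- as.integer(spec@length)
  set.seed(spec@seed)
  u <- stats::runif(L)
  gcProb <- if (!is.na(spec@gcPeriod)) {
    spec@gcBaseline +
      spec@gcAmplitude * cos(2 * pi * (seq_len(L) - 1) / spec@gcPeriod)
  } else numeric(0)
  codes <- sample_chain_cpp(spec@transitionTable, spec@order, u, gcProb)
  flags <- logical(L)
  if (spec@repeatCopies > 0L && !is.na(spec@repeatMotif)) {
    ml <- nchar(spec@repeatMotif)
    if (ml * spec@repeatCopies > L / 2)
      stop("repeat copies would cover more than half the genome")
    starts <- NULL
    for (try in 1:1000) {
      cand <- sort(sample.int(L - ml + 1L, spec@repeatCopies)) - 1L
      if (spec@repeatCopies < 2L || all(diff(cand) >= ml)) {
        starts <- cand
        break
      }
    }
    if (is.null(starts))
      stop("could not place ", spec@repeatCopies,
           " non-overlapping repeat copies")
    mcodes <- baseCodes(toupper(spec@repeatMotif))
    for (s in starts) {
      codes[(s + 1L):(s + ml)] <- mcodes
      flags[(s + 1L):(s + ml)] <- TRUE
    }
  }
  if (nrow(spec@nBlocks) > 0L)
    for (r in seq_len(nrow(spec@nBlocks)))
      codes[(spec@nBlocks[r, 1L] + 1L):spec@nBlocks[r, 2L]] <- .N_CODE
  genome <- new("GenomeSequence", name = spec@name,
                bases = .codesToString(codes), repeatFlags = flags)
  list(genome = genome,
       model = markovModelFromTable(spec@transitionTable, spec@order))
}

#' Write a synthetic genome plus its truth sidecar
#'
#' Produces a soft-masked FASTA and a JSON sidecar holding the full spec
#' (including the transition table), so oracle quantities can be recomputed.
#'
#' @param spec a [SyntheticGenomeSpec-class].
#' @param fastaPath output FASTA path.
#' @param sidecarPath output JSON path (default: fastaPath + ".json").
#' @return the generated genome, invisibly.
#' @export
writeSyntheticGenome <- function(spec, fastaPath,
                                 sidecarPath = paste0(fastaPath, ".json")) {
  gen <- generateGenome(spec)
  writeGenomeFasta(gen$genome, fastaPath)
  side <- list(length = spec@length, order = spec@order,
               transitionTable = spec@transitionTable,
               gcPeriod = if (is.na(spec@gcPeriod)) NULL else spec@gcPeriod,
               gcAmplitude = spec@gcAmplitude,
               gcBaseline = spec@gcBaseline,
               repeatMotif = if (is.na(spec@repeatMotif)) NULL
                             else spec@repeatMotif,
               repeatCopies = spec@repeatCopies, nBlocks = spec@nBlocks,
               seed = spec@seed, name = spec@name)
  jsonlite::write_json(side, sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(gen$genome)
}

#' Read a truth sidecar back into a spec
#' @param sidecarPath JSON path written by [writeSyntheticGenome()].
#' @return a [SyntheticGenomeSpec-class].
#' @export
readSyntheticSpec <- function(sidecarPath) {
  s <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  orElse <- function(x, na) if (is.null(x) || length(x) == 0L) na else x
  syntheticGenomeSpec(length = s$length, order = s$order,
                      transitionTable = matrix(unlist(s$transitionTable),
                                               ncol = 4L),
                      gcPeriod = orElse(s$gcPeriod, NA_real_),
                      gcAmplitude = s$gcAmplitude, gcBaseline = s$gcBaseline,
                      repeatMotif = orElse(s$repeatMotif, NA_character_),
                      repeatCopies = s$repeatCopies,
                      nBlocks = if (length(s$nBlocks)) matrix(unlist(s$nBlocks),
                                                             ncol = 2L)
                                else NULL,
                      seed = s$seed, name = s$name)
}

## Stationary distribution over left m-mers of an order-m chain, by power
## iteration on the m-mer transition operator.
.stationaryKmer <- function(tt, order) {
  n <- 4^order
  if (order == 0L) return(1)
  pi0 <- rep(1 / n, n)
  ## next state of m-mer s on emitting base b: (s*4 + b) mod 4^m
  nextState <- outer(0:(n - 1), 0:3, function(s, b) (s * 4 + b) %% n) + 1L
  for (it in 1:20000) {
    pi1 <- numeric(n)
    for (b in 1:4) {
      agg <- rowsum(pi0 * tt[, b], nextState[, b])
      at <- as.integer(rownames(agg))
      pi1[at] <- pi1[at] + agg[, 1L]
    }
    if (max(abs(pi1 - pi0)) < 1e-15) return(pi1)
    pi0 <- pi1
  }
  pi0
}

## Joint distribution of all (2k+1)-mers under the chain, as a list with the
## context key (both flanks, central coding) and center base of each word.
.wordDistribution <- function(tt, order, k) {
  m <- as.integer(order)
  stopifnot(k >= m, k <= 3L)
  W <- 2L * k + 1L
  nw <- 4^W
  w <- 0:(nw - 1)
  piM <- .stationaryKmer(tt, m)
  ## probability of the first m digits = stationary m-mer probability
  firstM <- if (m > 0) w %/% 4^(W - m) else rep(0L, nw)
  p <- if (m > 0) piM[firstM + 1L] else rep(1, nw)
  for (j in (m + 1L):W) {
    d <- (w %/% 4^(W - j)) %% 4          # j-th digit
    ctx <- if (m > 0) (w %/% 4^(W - j + 1L)) %% 4^m else rep(0L, nw)
    p <- p * tt[cbind(ctx + 1L, d + 1L)]
  }
  low <- w %% 4^k                         # right flank
  center <- (w %/% 4^k) %% 4
  high <- w %/% 4^(k + 1L)                # left flank
  list(ctxKey = high * 4^k + low, center = center, p = p)
}

#' Bayes accuracy of the optimal k-context predictor
#'
#' The accuracy ceiling for any model that sees k bases on each side of the
#' focus: `sum over contexts of pi(context) * max_x p(x | context)`, computed
#' by exact enumeration of all (2k+1)-mers under the generating chain
#' (stationary initial distribution). Refused when k is below the generating
#' order, since the result would not be the Bayes bound.
#'
#' @param model generating chain as a [MarkovModel-class] handle (e.g. from
#'   [generateGenome()]).
#' @param k context size of the predictor (order <= k <= 3).
#' @return the Bayes accuracy (a probability).
#' @examples
#' chain <- markovModelFromTable(matrix(0.25, 1, 4), 0)
#' bayesAccuracy(chain, 1)   # 0.25 for iid uniform
#' @export
bayesAccuracy <- function(model, k = model@k) {
  stopifnot(is(model, "MarkovModel"))
  if (k < model@k)
    stop("k = ", k, " below the generating order ", model@k,
         ": result would not be the Bayes bound")
  wd <- .wordDistribution(model@probs, model@k, as.integer(k))
  ## each (context, center) pair occurs exactly once in the enumeration
  jm <- matrix(0, nrow = 4^(2 * k), ncol = 4L)
  jm[cbind(wd$ctxKey + 1L, wd$center + 1L)] <- wd$p
  sum(pmax(jm[, 1], jm[, 2], jm[, 3], jm[, 4]))
}

#' Conditional entropy of the generating chain (nats per base)
#'
#' `context = "left"` (default) gives the chain's entropy rate
#' `sum_s pi(s) H(p(. | s))` over left k-mers — the cross-entropy floor for a
#' left-context (Markov) predictor. `context = "central"` conditions on both
#' flanks of size `k`, the floor for a bidirectional predictor.
#'
#' @param model generating chain ([MarkovModel-class]).
#' @param context `"left"` or `"central"`.
#' @param k flank size for the central variant (order <= k <= 3).
#' @return entropy in nats per base.
#' @examples
#' chain <- markovModelFromTable(matrix(0.25, 1, 4), 0)
#' conditionalEntropy(chain)   # log(4)
#' @export
conditionalEntropy <- function(model, context = c("left", "central"),
                               k = model@k) {
  stopifnot(is(model, "MarkovModel"))
  context <- match.arg(context)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (context == "left") {
    piM <- .stationaryKmer(model@probs, model@k)
    sum(piM * apply(model@probs, 1L, H))
  } else {
    wd <- .wordDistribution(model@probs, model@k, as.integer(k))
    jm <- matrix(0, nrow = 4^(2 * k), ncol = 4L)
    jm[cbind(wd$ctxKey + 1L, wd$center + 1L)] <- wd$p
    rs <- rowSums(jm)
    keep <- rs > 0
    cond <- jm[keep, , drop = FALSE] / rs[keep]
    sum(rs[keep] * apply(cond, 1L, H))
  }
}
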