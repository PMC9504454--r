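#' @include sequence-io.R
NULL

## Largest context table whose codes stay exact in a double (2^53).
.MAX_EXACT_CONTEXTS <- 2^53

## Context codes for a set of focus indices (1-based, all qualified).
## Digits are read 5'->3', left flank then right flank, most significant
## first; each digit is base code - 1. Central uses both flanks, Markov the
## left flank only. `reverse = TRUE` gives the code of the reverse-strand
## context (complemented bases, mirrored order) used by bidirectional
## averaging.
.contextCodes <- function(codes, idx, k, type = c("central", "markov"),
                          reverse = FALSE) {
  type <- match.arg(type)
  if (k == 0L) return(numeric(length(idx)))
  offs <- switch(type, central = c(-(k:1), 1L:k), markov = -(k:1))
  if (reverse) {
    offs <- switch(type, central = c(k:1, -(1L:k)), markov = k:1)
    codes <- 5L - codes  # complement: A<->T, C<->G (N never reaches here)
  }
  pw <- 4^(rev(seq_along(offs)) - 1)
  key <- numeric(length(idx))
  for (j in seq_along(offs))
    key <- key + (codes[idx + offs[j]] - 1) * pw[j]
  key
}

## Decode a context code back into its base string (length m digits).
.decodeContext <- function(key, m) {
  vapply(key, function(kk) {
    d <- integer(m)
    for (j in m:1) { d[j] <- kk %% 4; kk <- kk %/% 4 }
    paste0(.BASES[d + 1L], collapse = "")
  }, character(1))
}

## Qualified focus indices (1-based) for fitting. Central needs both flanks
## free of N; Markov needs k non-N left bases and a non-N focus.
.qualifiedIndices <- function(codes, k, type) {
  n <- length(codes)
  isN <- codes == .N_CODE
  if (type == "central") {
    if (n <= 2L * k) return(integer(0))
    cs <- c(0, cumsum(isN))
    i <- (k + 1L):(n - k)
    i[cs[i + k + 1L] - cs[i - k] == 0]
  } else {
    if (n <= k) return(integer(0))
    cs <- c(0, cumsum(isN))
    i <- (k + 1L):n
    i[cs[i + 1L] - cs[i - k] == 0]  # covers k = 0: focus non-N
  }
}

.fitCountModel <- function(genomes, k, type, positions = NULL,
                           pseudocount = 0) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  m <- if (type == "central") 2L * k else k
  if (4^m >= .MAX_EXACT_CONTEXTS)
    stop("context table for k = ", k, " (", type, ") would need 4^", m,
         " contexts, beyond the exact-integer budget of 2^53")
  if (is(genomes, "GenomeSequence")) genomes <- list(genomes)
  pieces <- vector("list", length(genomes))
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    codes <- baseCodes(g)
    idx <- .qualifiedIndices(codes, k, type)
    if (!is.null(positions)) {
      want <- if (is.list(positions)) positions[[gi]] else positions
      idx <- intersect(idx, as.integer(want) + 1L)
    }
    if (length(idx) == 0L) next
    key <- .contextCodes(codes, idx, k, type)
    pieces[[gi]] <- data.table::data.table(ck = key * 4 + (codes[idx] - 1))
  }
  dt <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(dt) || nrow(dt) == 0L)
    stop("no qualified positions to fit a ", type, " model with k = ", k)
  ck <- NULL  # appease R CMD check
  agg <- dt[, .N, by = ck][order(ck)]
  keyAll <- agg$ck %/% 4
  base <- agg$ck %% 4 + 1
  keys <- unique(keyAll)
  counts <- matrix(0, nrow = length(keys), ncol = 4L,
                   dimnames = list(NULL, .BASES))
  counts[cbind(match(keyAll, keys), base)] <- agg$N
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  new(if (type == "central") "CentralModel" else "MarkovModel",
      k = k, keys = keys, counts = counts, probs = probs,
      pseudocount = pseudocount)
}

#' Fit a central model by counting
#'
#' For every context of k bases on each side of a position, counts how often
#' each of the four bases occurs in the central position over all qualified
#' positions (forward strand only); the per-context frequencies are the
#' conditional probabilities. Contexts are stored sparsely (observed ones
#' only); [parameterCount()] still reports the dense count `3 * 4^(2k)`.
#'
#' @param genomes a [GenomeSequence-class] or list of them.
#' @param k flank size (>= 1).
#' @param positions optional 0-based position subset (or list per genome);
#'   intersected with the qualified positions.
#' @param pseudocount additive smoothing alpha (default 0: frequencies are
#'   exact; unseen contexts fall back to uniform at prediction time).
#' @return a [CentralModel-class].
#' @examples
#' g <- GenomeSequence("toy", "ACGTACGT")
#' m <- fitCentralModel(g, k = 1)
#' predictPositions(m, g, 2)    # context A.T around position 2
#' @export
fitCentralModel <- function(genomes, k, positions = NULL, pseudocount = 0)
  .fitCountModel(genomes, k, "central", positions, pseudocount)

#' Fit an order-k Markov model on left flanks
#'
#' Counts the base following every observed left k-mer over qualified
#' positions (>= k non-N left bases and a non-N focus).
#'
#' @inheritParams fitCentralModel
#' @param k Markov order (left-context length).
#' @return a [MarkovModel-class].
#' @export
fitMarkovModel <- function(genomes, k, positions = NULL, pseudocount = 0)
  .fitCountModel(genomes, k, "markov", positions, pseudocount)

#' Build a Markov model directly from a transition table
#'
#' Used for generating-chain handles from the synthetic-data module; the
#' model has no counts, only probabilities.
#'
#' @param transitionTable 4^k x 4 matrix of conditional distributions, rows
#'   ordered by left k-mer code (A...A first).
#' @param k the order.
#' @return a [MarkovModel-class].
#' @export
markovModelFromTable <- function(transitionTable, k) {
  k <- as.integer(k)
  stopifnot(nrow(transitionTable) == 4^max(k, 0), ncol(transitionTable) == 4L)
  new("MarkovModel", k = k, keys = as.numeric(seq_len(nrow(transitionTable)) - 1),
      counts = matrix(0, 0, 4), probs = unname(as.matrix(transitionTable)),
      pseudocount = 0)
}

.modelType <- function(model)
  if (is(model, "CentralModel")) "central" else "markov"

#' @rdname modelFlankSize
#' @export
setMethod("modelFlankSize", "CountModel", function(model) model@k)

#' @describeIn parameterCount dense free-parameter count by kind and k.
#' @export
setMethod("parameterCount", "character", function(x, k) {
  x <- match.arg(x, c("central", "markov"))
  stopifnot(k >= 0)
  if (x == "central") 3 * 4^(2 * k) else 3 * 4^k
})

#' @describeIn parameterCount dense count for a fitted central model.
#' @export
setMethod("parameterCount", "CentralModel", function(x, k)
  3 * 4^(2 * x@k))

#' @describeIn parameterCount dense count for a fitted Markov model.
#' @export
setMethod("parameterCount", "MarkovModel", function(x, k) 3 * 4^x@k)

setMethod("show", "CountModel", function(object) {
  cat(class(object), "k =", object@k, "-", length(object@keys),
      "observed contexts of", format(4^(if (is(object, "CentralModel"))
        2 * object@k else object@k), big.mark = ","), "possible;",
      format(parameterCount(object), big.mark = ","),
      "dense parameters\n")
})

## Shared prediction engine for count models. `idx` are 1-based qualified
## focus indices.
.countModelProbs <- function(model, codes, idx, reverse = FALSE) {
  type <- .modelType(model)
  key <- .contextCodes(codes, idx, model@k, type, reverse = reverse)
  row <- match(key, model@keys)
  p <- matrix(0.25, nrow = length(idx), ncol = 4L,
              dimnames = list(NULL, .BASES))
  seen <- !is.na(row)
  if (any(seen)) p[seen, ] <- model@probs[row[seen], , drop = FALSE]
  p
}

.checkQualified <- function(codes, positions, k, type) {
  n <- length(codes)
  if (any(positions < 0 | positions >= n))
    stop("positions out of range [0, ", n, ")")
  idx <- as.integer(positions) + 1L
  ok <- idx %in% .qualifiedIndices(codes, k, type)
  if (!all(ok))
    stop("disqualified position(s): ",
         paste(positions[!ok][seq_len(min(5, sum(!ok)))], collapse = ", "),
         " (context contains N or touches a sequence end)")
  idx
}

#' @rdname predictPositions
#' @export
setMethod("predictPositions", "CountModel",
  function(model, genome, positions, bidirectional = FALSE) {
    codes <- baseCodes(genome)
    type <- .modelType(model)
    ## bidirectional application needs both flanks even for a Markov model
    qtype <- if (bidirectional) "central" else type
    idx <- .checkQualified(codes, positions, model@k, qtype)
    p <- .countModelProbs(model, codes, idx)
    if (bidirectional) {
      pr <- .countModelProbs(model, codes, idx, reverse = TRUE)
      ## reverse-strand probability of the complement base: column order
      ## T,G,C,A maps back to A,C,G,T
      p <- (p + pr[, 4:1, drop = FALSE]) / 2
      colnames(p) <- .BASES
    }
    p
  })

#' Most probable base of a probability vector
#'
#' Ties are broken by the fixed order A < C < G < T for determinism.
#'
#' @param p numeric vector of 4 probabilities (A,C,G,T), or a matrix with 4
#'   columns (one row per position).
#' @return single base character, or character vector for matrix input.
#' @examples
#' argmaxBase(c(0.1, 0.6, 0.2, 0.1))        # "C"
#' argmaxBase(c(0.25, 0.25, 0.25, 0.25))    # "A" (tie-break)
#' @export
argmaxBase <- function(p) {
  if (is.matrix(p)) .BASES[max.col(p, ties.method = "first")]
  else .BASES[which.max(p)]
}

#' Bidirectional (two-strand) average prediction at one position
#'
#' Averages the model's forward-strand distribution with its reverse-strand
#' distribution mapped back through base complementation:
#' `q(x) = (p_fwd(x | context) + p_rev(comp(x) | revcomp context)) / 2`.
#'
#' @param model a context model.
#' @param genome a [GenomeSequence-class].
#' @param pos 0-based position, qualified on both strands.
#' @return named numeric vector of 4 probabilities summing to 1.
#' @export
bidirectionalAverage <- function(model, genome, pos) {
  p <- predictPositions(model, genome, pos, bidirectional = TRUE)
  structure(p[1L, ], names = .BASES)
}

#' Serialize / restore a fitted model
#'
#' Models are stored in R's native binary container together with their kind
#' and context size; see [exportProbabilitiesTSV()] for a plain-text view.
#'
#' @param model a fitted model.
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
writeContextModel <- function(model, path) {
  stopifnot(is(model, "ContextModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname writeContextModel
#' @export
readContextModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "ContextModel")) stop("'", path, "' is not a context model")
  model
}

#' Export per-context probabilities as TSV
#'
#' One row per observed context: the context string, its four conditional
#' probabilities and the training count total. Intended for small k.
#'
#' @param model a [CentralModel-class] or [MarkovModel-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportProbabilitiesTSV <- function(model, path) {
  m <- if (is(model, "CentralModel")) 2L * model@k else model@k
  ctx <- .decodeContext(model@keys, m)
  total <- if (nrow(model@counts)) rowSums(model@counts) else
    rep(NA_real_, length(model@keys))
  df <- data.frame(context = ctx, pA = model@probs[, 1], pC = model@probs[, 2],
                   pG = model@probs[, 3], pT = model@probs[, 4], n = total)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
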