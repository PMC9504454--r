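#' @useDynLib dnacontext, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Integer encoding used throughout: A=1, C=2, G=3, T=4, N=5.
.BASES <- c("A", "C", "G", "T")
.N_CODE <- 5L

## grouped counting goes through data.table's `[` dispatch
.datatable.aware <- TRUE

#' GenomeSequence: a chromosome-like sequence with soft-mask flags
#'
#' Holds one named sequence over the alphabet \{A,C,G,T,N\} together with a
#' per-base logical repeat flag (TRUE where the source FASTA letter was
#' lowercase, i.e. soft-masked repeat). Any input letter outside A/C/G/T
#' (after upper-casing) is coerced to N at construction.
#'
#' @slot name single character label.
#' @slot bases single character string, upper case, over A/C/G/T/N.
#' @slot repeatFlags logical vector, one entry per base.
#' @export
setClass("GenomeSequence",
  representation(name = "character", bases = "character",
                 repeatFlags = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
    if (length(object@bases) != 1L) msg <- c(msg, "'bases' must be a single string")
    n <- nchar(object@bases)
    if (length(object@repeatFlags) != n)
      msg <- c(msg, "repeatFlags length must equal the number of bases")
    if (n > 0L && grepl("[^ACGTN]", object@bases))
      msg <- c(msg, "bases must be over {A,C,G,T,N}")
    if (length(msg)) msg else TRUE
  })

#' PositionMask: disqualified positions for a flank size
#'
#' A position is disqualified iff its context of flank size F contains at
#' least one N, its own base is N, or it lies within F bases of either
#' sequence end.
#'
#' @slot disqualified logical vector, one entry per genome position.
#' @slot flankSize integer flank size F used to compute the mask.
#' @export
setClass("PositionMask",
  representation(disqualified = "logical", flankSize = "integer"),
  validity = function(object) {
    if (length(object@flankSize) != 1L || object@flankSize < 0L)
      "flankSize must be a single non-negative integer" else TRUE
  })

#' ContextWindow: the flanking context of one genomic position
#'
#' @slot left character string of length-F left flank (5' to 3').
#' @slot right character string of length-F right flank.
#' @slot focusPosition 0-based position of the (excluded) focus base.
#' @slot flankSize integer F.
#' @export
setClass("ContextWindow",
  representation(left = "character", right = "character",
                 focusPosition = "integer", flankSize = "integer"),
  validity = function(object) {
    F <- object@flankSize
    if (nchar(object@left) != F || nchar(object@right) != F)
      "both flanks must have length exactly flankSize" else TRUE
  })

#' Virtual parent of all context models
#'
#' A ContextModel maps the flanking context of a position to a probability
#' distribution over the four bases; see [predictPositions()].
#' @export
setClass("ContextModel", representation("VIRTUAL"))

#' Count-based models (virtual): sparse context count/probability tables
#'
#' @slot k integer context size (flank size for central, order for Markov).
#' @slot keys numeric vector of observed context codes (sorted).
#' @slot counts numeric matrix (length(keys) x 4) of focus-base counts, or a
#'   0-row matrix for models built directly from probabilities.
#' @slot probs numeric matrix (length(keys) x 4), rows summing to 1.
#' @slot pseudocount additive smoothing alpha (default 0).
#' @export
setClass("CountModel", contains = c("ContextModel", "VIRTUAL"),
  representation(k = "integer", keys = "numeric", counts = "matrix",
                 probs = "matrix", pseudocount = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@probs) != length(object@keys))
      msg <- c(msg, "probs must have one row per key")
    if (nrow(object@probs) > 0L) {
      if (ncol(object@probs) != 4L) msg <- c(msg, "probs must have 4 columns")
      s <- rowSums(object@probs)
      if (any(abs(s - 1) > 1e-9)) msg <- c(msg, "probability rows must sum to 1")
    }
    if (is.unsorted(object@keys)) msg <- c(msg, "keys must be sorted")
    if (length(msg)) msg else TRUE
  })

#' Central model: focus-base distribution given both flanks of size k
#' @export
setClass("CentralModel", contains = "CountModel")

#' Markov model: base distribution given the k left neighbours
#' @export
setClass("MarkovModel", contains = "CountModel")

#' Neural context model (convolution + bidirectional LSTM + softmax)
#'
#' @slot spec architecture list from [architectureSpec()].
#' @slot weights named list of parameter matrices/vectors.
#' @slot trainingLog data.frame with one row per completed training round.
#' @slot trained logical.
#' @export
setClass("NeuralModel", contains = "ContextModel",
  representation(spec = "list", weights = "list",
                 trainingLog = "data.frame", trained = "logical"))

#' RefProbArray: per-position probability of the reference base
#'
#' @slot values numeric vector in `[0,1]`; disqualified positions hold exactly
#'   the imputed constant.
#' @slot disqualified logical vector of the same length.
#' @slot imputedValue constant stored at disqualified positions (default 0.25).
#' @slot genomeName label of the scored sequence.
#' @export
setClass("RefProbArray",
  representation(values = "numeric", disqualified = "logical",
                 imputedValue = "numeric", genomeName = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != length(object@disqualified))
      msg <- c(msg, "values and disqualified must have equal length")
    q <- object@values[!object@disqualified]
    if (length(q) && (min(q) < 0 || max(q) > 1))
      msg <- c(msg, "qualified values must lie in [0,1]")
    d <- object@values[object@disqualified]
    if (length(d) && any(d != object@imputedValue))
      msg <- c(msg, "disqualified positions must hold the imputed constant")
    if (length(msg)) msg else TRUE
  })

#' AccuracyReport: prediction accuracy overall and per stratum
#'
#' @slot overall fraction of qualified positions predicted correctly.
#' @slot nOverall number of qualified positions scored.
#' @slot perChromosome data.frame (chrom, accuracy, n).
#' @slot perAnnotation data.frame (label, accuracy, n); empty strata absent.
#' @export
setClass("AccuracyReport",
  representation(overall = "numeric", nOverall = "numeric",
                 perChromosome = "data.frame", perAnnotation = "data.frame"))

#' DensityGrid: 2-D histogram of two reference-base probability arrays
#'
#' Axis ranges are fixed to `[0,1]` with `bins` equal bins per axis; the last
#' bin is right-closed.
#'
#' @slot counts integer matrix (bins x bins); rows index the first array.
#' @slot bins number of bins per axis (50 in the standard analysis).
#' @export
setClass("DensityGrid",
  representation(counts = "matrix", bins = "integer"),
  validity = function(object) {
    if (!all(dim(object@counts) == object@bins))
      "counts must be bins x bins" else TRUE
  })

#' VuongResult: non-nested likelihood-ratio z-test
#'
#' @slot n sample size.
#' @slot meanLR mean per-position log-likelihood difference (numerator minus
#'   denominator model).
#' @slot sdLR its sample standard deviation.
#' @slot z test statistic sqrt(n) * meanLR / sdLR.
#' @slot p two-sided normal p-value.
#' @export
setClass("VuongResult",
  representation(n = "numeric", meanLR = "numeric", sdLR = "numeric",
                 z = "numeric", p = "numeric"))

#' SegmentSet: adjacent fixed-length segments of one chromosome
#'
#' @slot segmentLength segment size in bases (default 1e6).
#' @slot segments data.frame with columns start, end (0-based half-open),
#'   disqualifiedFraction, included.
#' @export
setClass("SegmentSet",
  representation(segmentLength = "numeric", segments = "data.frame"))

#' WindowedSpectrum: running-window norms of Fourier magnitudes
#'
#' @slot window number of consecutive frequencies per window.
#' @slot step window start spacing, in frequencies.
#' @slot startFrequencies first frequency (cycles per segment) of each window;
#'   frequency 0 is never included.
#' @slot norms Euclidean norm (or summed power, see `power` flag of
#'   [windowedNormSpectrum()]) of the coefficient magnitudes in each window.
#' @slot segmentLength length of the transformed array (bases).
#' @export
setClass("WindowedSpectrum",
  representation(window = "numeric", step = "numeric",
                 startFrequencies = "numeric", norms = "numeric",
                 segmentLength = "numeric"))

#' SyntheticGenomeSpec: full description of a generated genome
#'
#' @slot length genome length in bases.
#' @slot order Markov order of the generating chain (0-3).
#' @slot transitionTable numeric matrix 4^order x 4; row i gives the
#'   conditional distribution of the next base given the left k-mer whose
#'   code is i (rownames are the k-mers; a 1 x 4 matrix for order 0).
#' @slot gcPeriod planted GC modulation period in bases (NA for none).
#' @slot gcAmplitude cosine amplitude of the G+C probability.
#' @slot gcBaseline mean G+C probability under modulation.
#' @slot repeatMotif base sequence inserted (lower case) as repeat copies, or
#'   NA.
#' @slot repeatCopies number of inserted copies.
#' @slot nBlocks integer matrix (n x 2) of 0-based half-open `[start,end)` N
#'   blocks.
#' @slot seed integer seed making generation deterministic.
#' @slot name sequence name of the generated genome.
#' @export
setClass("SyntheticGenomeSpec",
  representation(length = "numeric", order = "integer",
                 transitionTable = "matrix", gcPeriod = "numeric",
                 gcAmplitude = "numeric", gcBaseline = "numeric",
                 repeatMotif = "character", repeatCopies = "integer",
                 nBlocks = "matrix", seed = "integer", name = "character"),
  validity = function(object) {
    msg <- character()
    if (object@order < 0L || object@order > 3L)
      msg <- c(msg, "order must be between 0 and 3")
    tt <- object@transitionTable
    if (nrow(tt) != 4L^object@order || ncol(tt) != 4L)
      msg <- c(msg, "transitionTable must be 4^order x 4")
    else if (any(abs(rowSums(tt) - 1) > 1e-9) || any(tt < 0))
      msg <- c(msg, "transitionTable rows must be distributions")
    if (!is.na(object@gcPeriod)) {
      lo <- object@gcBaseline - object@gcAmplitude
      hi <- object@gcBaseline + object@gcAmplitude
      if (lo <= 0 || hi >= 1)
        msg <- c(msg, "gcBaseline +/- gcAmplitude must stay inside (0,1)")
      if (object@gcAmplitude < 0 || object@gcAmplitude >= 0.5)
        msg <- c(msg, "gcAmplitude must lie in [0, 0.5)")
    }
    if (nrow(object@nBlocks) > 0L) {
      if (any(object@nBlocks[, 1L] < 0) ||
          any(object@nBlocks[, 2L] > object@length) ||
          any(object@nBlocks[, 1L] >= object@nBlocks[, 2L]))
        msg <- c(msg, "nBlocks must be 0 <= start < end <= length")
    }
    if (length(msg)) msg else TRUE
  })
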