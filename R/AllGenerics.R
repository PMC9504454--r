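#' @include AllClasses.R
NULL

#' Predict base probabilities at genomic positions
#'
#' The common prediction contract shared by all context models: for each
#' requested position, return the model's probability distribution over
#' (A, C, G, T) for the base at that position given its flanking context.
#' With `bidirectional = TRUE` the model is applied on both strands and the
#' two distributions are averaged (probabilities of complementary bases are
#' matched across strands).
#'
#' @param model a [CentralModel-class], [MarkovModel-class] or
#'   [NeuralModel-class].
#' @param genome a [GenomeSequence-class].
#' @param positions 0-based positions; all must be qualified for the model's
#'   flank size (no N in context, not within flank of an end).
#' @param bidirectional average forward- and reverse-strand predictions.
#' @return numeric matrix `length(positions) x 4` with columns A, C, G, T;
#'   every row sums to 1.
#' @export
setGeneric("predictPositions", function(model, genome, positions,
                                        bidirectional = FALSE)
  standardGeneric("predictPositions"))

#' Flank size of a context model
#' @param model a context model.
#' @return integer number of bases the model uses on each side of the focus.
#' @export
setGeneric("modelFlankSize", function(model) standardGeneric("modelFlankSize"))

#' Number of model parameters
#'
#' For count models the free-parameter count of the dense table: a central
#' model with flank k has `3 * 4^(2k)` free parameters and an order-k Markov
#' model `3 * 4^k` (each context contributes a 4-way distribution with 3 free
#' entries). For a neural model, the exact number of trainable weights.
#'
#' @param x a fitted model, or a character kind `"central"`/`"markov"`.
#' @param k context size, used with the character form.
#' @return a numeric count (exact; may exceed integer range for large k).
#' @examples
#' parameterCount("central", 3)   # 12288, reported as ~12,000
#' parameterCount("markov", 14)   # 805306368, reported as ~0.8 billion
#' @export
setGeneric("parameterCount", function(x, k) standardGeneric("parameterCount"))

#' @rdname GenomeSequence-class
#' @param x a GenomeSequence.
#' @export
setGeneric("seqName", function(x) standardGeneric("seqName"))

#' @rdname GenomeSequence-class
#' @export
setGeneric("repeatFlags", function(x) standardGeneric("repeatFlags"))

#' @rdname PositionMask-class
#' @param x a PositionMask (or object carrying one).
#' @export
setGeneric("disqualified", function(x) standardGeneric("disqualified"))
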