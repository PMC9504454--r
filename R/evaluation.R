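#' @include count-models.R
NULL

.LOGP_FLOOR <- 1e-12  # zero probabilities are floored before logging

#' Reference-base probability array of a model on a genome
#'
#' At every position, the probability the model assigns to the base actually
#' present in the reference sequence. Disqualified positions (context with N,
#' or within flank of an end) are flagged and imputed with a constant so the
#' array is gap-free for downstream spectral analysis.
#'
#' @param model a context model.
#' @param genome a [GenomeSequence-class].
#' @param bidirectional use the two-strand averaged predictor.
#' @param imputedValue constant stored at disqualified positions.
#' @return a [RefProbArray-class] of the genome's length.
#' @export
referenceBaseProbabilities <- function(model, genome, bidirectional = FALSE,
                                       imputedValue = 0.25) {
  F <- modelFlankSize(model)
  mask <- buildPositionMask(genome, F)
  disq <- disqualified(mask)
  values <- rep(imputedValue, length(genome))
  pos <- which(!disq) - 1L
  if (length(pos)) {
    p <- predictPositions(model, genome, pos, bidirectional = bidirectional)
    ref <- baseCodes(genome)[pos + 1L]
    values[pos + 1L] <- p[cbind(seq_along(pos), ref)]
  }
  new("RefProbArray", values = values, disqualified = disq,
      imputedValue = imputedValue, genomeName = seqName(genome))
}

#' @rdname RefProbArray-class
#' @param x a RefProbArray.
#' @export
setMethod("disqualified", "RefProbArray", function(x) x@disqualified)

#' @rdname RefProbArray-class
#' @export
refProbValues <- function(x) x@values

#' @rdname RefProbArray-class
#' @aliases length,RefProbArray-method
#' @export
setMethod("length", "RefProbArray", function(x) length(x@values))

setMethod("show", "RefProbArray", function(object) {
  q <- !object@disqualified
  cat("RefProbArray on", object@genomeName, ":", length(object@values),
      "positions,", sum(!q), "disqualified (imputed",
      object@imputedValue, ")\n")
  if (any(q))
    cat("  mean qualified probability:",
        round(mean(object@values[q]), 4), "\n")
})

#' Write / read a RefProbArray as TSV plus JSON sidecar
#'
#' One value per line; the sidecar records the genome name, imputed constant
#' and disqualified run-length encoding so the array round-trips exactly.
#'
#' @param x a [RefProbArray-class].
#' @param path TSV path; the sidecar is `path` + ".json".
#' @return `path` (write) or the restored array (read).
#' @export
writeRefProbArray <- function(x, path) {
  data.table::fwrite(data.table::data.table(value = x@values), path,
                     sep = "\t", col.names = FALSE)
  r <- rle(x@disqualified)
  jsonlite::write_json(list(genome = x@genomeName,
                            imputedValue = x@imputedValue,
                            disqualifiedRleLengths = r$lengths,
                            disqualifiedRleValues = r$values),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRefProbArray
#' @export
readRefProbArray <- function(path) {
  values <- data.table::fread(path, header = FALSE)[[1L]]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  disq <- inverse.rle(structure(list(lengths = side$disqualifiedRleLengths,
                                     values = side$disqualifiedRleValues),
                                class = "rle"))
  new("RefProbArray", values = as.numeric(values), disqualified = disq,
      imputedValue = side$imputedValue, genomeName = side$genome)
}

#' Prediction accuracy, overall and stratified
#'
#' Fraction of qualified positions where the model's argmax prediction (ties
#' broken A<C<G<T) equals the reference base, reported overall, per
#' chromosome, and per annotation label. Empty strata are absent from the
#' report, not zero.
#'
#' @param model a context model.
#' @param genomes a [GenomeSequence-class] or list of them.
#' @param annotations optional `GRanges` with a `label` column (see
#'   [readAnnotations()]); accuracy is additionally reported within each
#'   label.
#' @param includeRepeats add a `"repeat"` stratum from the soft-mask flags.
#' @param bidirectional use the two-strand averaged predictor.
#' @return an [AccuracyReport-class].
#' @export
accuracyReport <- function(model, genomes, annotations = NULL,
                           includeRepeats = FALSE, bidirectional = FALSE) {
  if (is(genomes, "GenomeSequence")) genomes <- list(genomes)
  F <- modelFlankSize(model)
  labels <- if (!is.null(annotations))
    unique(S4Vectors::mcols(annotations)$label) else character(0)
  if (includeRepeats) labels <- c(labels, "repeat")
  chromRows <- list()
  stratHit <- stats::setNames(numeric(length(labels)), labels)
  stratN <- stats::setNames(numeric(length(labels)), labels)
  for (g in genomes) {
    mask <- buildPositionMask(g, F)
    pos <- which(!disqualified(mask)) - 1L
    if (length(pos) == 0L) next
    p <- predictPositions(model, g, pos, bidirectional = bidirectional)
    pred <- max.col(p, ties.method = "first")
    ref <- baseCodes(g)[pos + 1L]
    hit <- pred == ref
    chromRows[[seqName(g)]] <-
      data.frame(chrom = seqName(g), accuracy = mean(hit), n = length(hit))
    for (lab in labels) {
      inLab <- if (lab == "repeat" && includeRepeats) repeatFlags(g)
               else annotationToMask(annotations, seqName(g), length(g), lab)
      sel <- inLab[pos + 1L]
      stratHit[lab] <- stratHit[lab] + sum(hit[sel])
      stratN[lab] <- stratN[lab] + sum(sel)
    }
  }
  if (length(chromRows) == 0L) stop("no qualified positions in any genome")
  perChrom <- do.call(rbind, c(chromRows, list(make.row.names = FALSE)))
  keep <- stratN > 0
  perAnn <- data.frame(label = labels[keep],
                       accuracy = stratHit[keep] / stratN[keep],
                       n = stratN[keep], row.names = NULL)
  nTot <- sum(perChrom$n)
  new("AccuracyReport",
      overall = sum(perChrom$accuracy * perChrom$n) / nTot, nOverall = nTot,
      perChromosome = perChrom, perAnnotation = perAnn)
}

setMethod("show", "AccuracyReport", function(object) {
  cat("AccuracyReport: overall", sprintf("%.4f", object@overall),
      "over", object@nOverall, "positions\n")
  if (nrow(object@perChromosome) > 1L) {
    cat("  per chromosome:\n")
    print(object@perChromosome, row.names = FALSE)
  }
  if (nrow(object@perAnnotation)) {
    cat("  per annotation:\n")
    print(object@perAnnotation, row.names = FALSE)
  }
})

#' Accessors for AccuracyReport
#' @param x an [AccuracyReport-class].
#' @return `overallAccuracy`: the genome-wide fraction; the others the
#'   per-stratum data.frames.
#' @export
overallAccuracy <- function(x) x@overall

#' @rdname overallAccuracy
#' @export
perChromosomeAccuracy <- function(x) x@perChromosome

#' @rdname overallAccuracy
#' @export
perAnnotationAccuracy <- function(x) x@perAnnotation

#' Model-vs-model density grid of reference-base probabilities
#'
#' 2-D histogram of paired probabilities on a grid of `bins` equally sized
#' bins per axis over `[0,1]` (bin edges i/bins; the last bin is right-closed).
#'
#' @param a,b [RefProbArray-class] objects covering the same genome, or bare
#'   numeric vectors in `[0,1]`.
#' @param positions optional 0-based positions to score; default: positions
#'   qualified in both arrays.
#' @param bins bins per axis (50 in the standard analysis).
#' @return a [DensityGrid-class]; `gridCounts()` extracts the matrix.
#' @export
densityGrid <- function(a, b, positions = NULL, bins = 50L) {
  va <- if (is(a, "RefProbArray")) a@values else a
  vb <- if (is(b, "RefProbArray")) b@values else b
  if (length(va) != length(vb))
    stop("the two arrays must cover the same positions (lengths differ)")
  if (is.null(positions)) {
    ok <- rep(TRUE, length(va))
    if (is(a, "RefProbArray")) ok <- ok & !a@disqualified
    if (is(b, "RefProbArray")) ok <- ok & !b@disqualified
    idx <- which(ok)
  } else idx <- as.integer(positions) + 1L
  bins <- as.integer(bins)
  bi <- function(v) pmin(floor(v * bins) + 1L, bins)
  counts <- matrix(0L, bins, bins)
  if (length(idx)) {
    tab <- table(factor(bi(va[idx]), levels = 1:bins),
                 factor(bi(vb[idx]), levels = 1:bins))
    counts <- matrix(as.integer(tab), bins, bins)
  }
  new("DensityGrid", counts = counts, bins = bins)
}

#' @rdname densityGrid
#' @param x a DensityGrid.
#' @export
gridCounts <- function(x) x@counts

setMethod("show", "DensityGrid", function(object) {
  cat("DensityGrid:", object@bins, "x", object@bins, "bins,",
      sum(object@counts), "positions\n")
})

#' Per-position reference-base log-likelihoods
#'
#' Natural-log probability assigned to the reference base at each requested
#' position; probabilities are floored at 1e-12 to keep downstream tests
#' finite.
#'
#' @param model a context model.
#' @param genome a [GenomeSequence-class].
#' @param positions 0-based qualified positions.
#' @param bidirectional use the averaged predictor.
#' @return numeric vector of log-likelihoods.
#' @export
positionLogLikelihoods <- function(model, genome, positions,
                                   bidirectional = FALSE) {
  p <- predictPositions(model, genome, positions,
                        bidirectional = bidirectional)
  ref <- baseCodes(genome)[as.integer(positions) + 1L]
  log(pmax(p[cbind(seq_along(positions), ref)], .LOGP_FLOOR))
}

#' Vuong likelihood-ratio test for non-nested models
#'
#' Tests the null of equally performing models from paired per-position
#' log-likelihoods: with `d_i = logpA_i - logpB_i`,
#' `z = sqrt(n) * mean(d) / sd(d)` and a two-sided normal p-value. Positive z
#' favours model a (the "numerator").
#'
#' @param logpA,logpB finite log-likelihood vectors over the same positions.
#' @return a [VuongResult-class].
#' @export
vuongTest <- function(logpA, logpB) {
  stopifnot(length(logpA) == length(logpB))
  if (!all(is.finite(logpA)) || !all(is.finite(logpB)))
    stop("log-likelihoods must be finite")
  d <- logpA - logpB
  n <- length(d)
  s <- stats::sd(d)
  if (n < 2L || s == 0)
    stop("degenerate test: the models are identical on this sample")
  m <- mean(d)
  z <- sqrt(n) * m / s
  new("VuongResult", n = n, meanLR = m, sdLR = s, z = z,
      p = 2 * stats::pnorm(-abs(z)))
}

#' Sufficient statistics of a log-likelihood difference sample
#'
#' @param logpA,logpB as in [vuongTest()].
#' @return list with `sumD`, `sumD2`, `n` — poolable across chromosomes via
#'   [aggregateVuong()].
#' @export
vuongStats <- function(logpA, logpB) {
  d <- logpA - logpB
  list(sumD = sum(d), sumD2 = sum(d^2), n = length(d))
}

#' Aggregate per-chromosome Vuong statistics into a genome-level test
#'
#' Pools the sufficient statistics (sums, sums of squares, counts), which is
#' equivalent to running the test on the union of the per-chromosome samples.
#'
#' @param perChromosome list of lists with `sumD`, `sumD2`, `n` (see
#'   [vuongStats()]).
#' @return a [VuongResult-class].
#' @export
aggregateVuong <- function(perChromosome) {
  if (length(perChromosome) == 0L) stop("no per-chromosome statistics given")
  n <- sum(vapply(perChromosome, `[[`, numeric(1), "n"))
  sumD <- sum(vapply(perChromosome, `[[`, numeric(1), "sumD"))
  sumD2 <- sum(vapply(perChromosome, `[[`, numeric(1), "sumD2"))
  if (n < 2L) stop("need at least 2 pooled observations")
  m <- sumD / n
  v <- (sumD2 - n * m^2) / (n - 1)
  if (v <= 0)
    stop("degenerate test: the models are identical on this sample")
  s <- sqrt(v)
  z <- sqrt(n) * m / s
  new("VuongResult", n = n, meanLR = m, sdLR = s, z = z,
      p = 2 * stats::pnorm(-abs(z)))
}

setMethod("show", "VuongResult", function(object) {
  cat(sprintf("Vuong non-nested LR test: n = %d, mean LR = %.6g, z = %.3f, p = %.3g\n",
              as.integer(object@n), object@meanLR, object@z, object@p))
})

#' @rdname vuongTest
#' @param x a [VuongResult-class].
#' @export
vuongZ <- function(x) x@z

#' @rdname vuongTest
#' @export
vuongP <- function(x) x@p

#' Seeded sample of qualified test positions
#'
#' Uniform sample without replacement of `round(fraction * n)` qualified
#' positions (the comparison protocol uses 10% per chromosome).
#'
#' @param genome a [GenomeSequence-class].
#' @param mask a [PositionMask-class] for the model's flank size.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return sorted 0-based positions.
#' @export
sampleTestPositions <- function(genome, mask, fraction = 0.10, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  qual <- which(!disqualified(mask)) - 1L
  if (length(qual) == 0L) stop("no qualified positions to sample from")
  nTake <- max(1L, round(fraction * length(qual)))
  if (nTake >= length(qual)) return(qual)
  set.seed(seed)
  sort(sample(qual, nTake))
}
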