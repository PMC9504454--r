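#' @include sequence-io.R
NULL

#' Segment a chromosome into adjacent fixed-length pieces
#'
#' Segments start at position 0, are exactly `segmentLength` long, and the
#' trailing remainder is dropped. A segment is excluded when strictly more
#' than `maxDisqualified` of its positions are disqualified (exactly 10% is
#' still included).
#'
#' @param length chromosome length L in bases.
#' @param mask a [PositionMask-class] or logical disqualified vector of
#'   length L; NULL means no disqualified positions.
#' @param segmentLength segment size (default 1 Mb).
#' @param maxDisqualified exclusion threshold on the disqualified fraction.
#' @return a [SegmentSet-class].
#' @examples
#' segmentCount(segmentChromosome(64444167))   # 64 segments of 1 Mb
#' @export
segmentChromosome <- function(length, mask = NULL, segmentLength = 1e6,
                              maxDisqualified = 0.10) {
  length <- as.numeric(length)
  stopifnot(length >= 0)
  nseg <- floor(length / segmentLength)
  if (nseg == 0)
    return(new("SegmentSet", segmentLength = segmentLength,
               segments = data.frame(start = numeric(0), end = numeric(0),
                                     disqualifiedFraction = numeric(0),
                                     included = logical(0))))
  starts <- (seq_len(nseg) - 1) * segmentLength
  disq <- if (is.null(mask)) NULL
          else if (is(mask, "PositionMask")) disqualified(mask) else mask
  frac <- if (is.null(disq)) rep(0, nseg) else {
    cs <- c(0, cumsum(as.numeric(disq)))
    (cs[starts + segmentLength + 1] - cs[starts + 1]) / segmentLength
  }
  new("SegmentSet", segmentLength = segmentLength,
      segments = data.frame(start = starts, end = starts + segmentLength,
                            disqualifiedFraction = frac,
                            included = frac <= maxDisqualified))
}

#' @rdname segmentChromosome
#' @param x a [SegmentSet-class].
#' @param includedOnly count only included segments.
#' @export
segmentCount <- function(x, includedOnly = FALSE) {
  if (includedOnly) sum(x@segments$included) else nrow(x@segments)
}

#' @rdname segmentChromosome
#' @export
segmentTable <- function(x) x@segments

setMethod("show", "SegmentSet", function(object) {
  cat("SegmentSet:", nrow(object@segments), "segments of",
      format(object@segmentLength, big.mark = ","), "bases;",
      sum(object@segments$included), "included\n")
})

#' GC indicator array of a genome slice
#'
#' 1 at G or C positions, 0 at A or T; N positions emit 0 (their weight in a
#' segment is already controlled by the disqualified-fraction rule).
#'
#' @param genome a [GenomeSequence-class].
#' @param start,end 0-based half-open slice; defaults to the whole sequence.
#' @return numeric 0/1 vector of length `end - start`.
#' @examples
#' gcIndicator(GenomeSequence("x", "ACGT"))   # 0 1 1 0
#' @export
gcIndicator <- function(genome, start = 0, end = length(genome)) {
  stopifnot(start >= 0, end <= length(genome), start <= end)
  codes <- baseCodes(genome)[(start + 1):end]
  as.numeric(codes == 2L | codes == 3L)
}

#' One-sided discrete-Fourier magnitudes
#'
#' Raw (unnormalized) DFT magnitudes at integer frequencies 0..floor(L/2)
#' cycles per segment.
#'
#' @param values finite numeric array of length L >= 2.
#' @return numeric vector of magnitudes, names giving the frequency.
#' @export
fourierMagnitudes <- function(values) {
  L <- length(values)
  stopifnot(L >= 2L)
  if (!all(is.finite(values))) stop("input contains non-finite values")
  m <- Mod(stats::fft(values))[1:(floor(L / 2) + 1L)]
  names(m) <- 0:floor(L / 2)
  m
}

#' Running-window norm of Fourier coefficient magnitudes
#'
#' For each window start f0 = 1, 1+step, 1+2*step, ... the Euclidean norm
#' `sqrt(sum over f in [f0, f0+window) of magnitude(f)^2)` — the square root
#' of the windowed power ("cumulative power spectrum in a running window").
#' Frequency 0 (the segment mean) is always excluded.
#'
#' @param magnitudes output of [fourierMagnitudes()] (frequency 0 first).
#' @param window number of consecutive frequencies per window (default
#'   1,000).
#' @param step spacing of window starts (default 100).
#' @param power return the summed power instead of its square root.
#' @param segmentLength length of the transformed array, used for period
#'   annotation; default `2 * (length(magnitudes) - 1)` (exact for even L).
#' @return a [WindowedSpectrum-class].
#' @export
windowedNormSpectrum <- function(magnitudes, window = 1000L, step = 100L,
                                 power = FALSE, segmentLength = NULL) {
  stopifnot(window >= 1L, step >= 1L)
  fmax <- length(magnitudes) - 1L
  if (is.null(segmentLength)) segmentLength <- 2 * fmax
  if (fmax < 1L) stop("no nonzero frequencies available")
  if (window > fmax) {
    warning("window (", window, ") exceeds available frequencies (", fmax,
            "); returning a single truncated window")
    starts <- 1L
    window <- fmax
  } else {
    starts <- seq.int(1L, fmax - window + 1L, by = step)
  }
  cs <- c(0, cumsum(magnitudes[-1L]^2))  # cs[f+1] = sum over 1..f
  pw <- cs[starts + window] - cs[starts]
  new("WindowedSpectrum", window = as.numeric(window), step = as.numeric(step),
      startFrequencies = as.numeric(starts),
      norms = if (power) pw else sqrt(pw),
      segmentLength = as.numeric(segmentLength))
}

#' Convert a frequency window into a window of periods
#'
#' For a segment of length L, a frequency window `[f_start, f_start + width]`
#' corresponds to periods between `L/(f_start+width)` and `L/f_start`; a peak
#' assigned to the window's mid frequency has period `L/(f_start+width/2)`.
#' All periods are rounded to the nearest integer base pair.
#'
#' @param fStart window start frequency (cycles per segment), >= 1.
#' @param width window width in frequencies (0 gives a single frequency).
#' @param segmentLength L in bases.
#' @return data.frame with fStart, width, periodLow, periodMid, periodHigh.
#' @examples
#' frequencyWindowToPeriods(4000, 1000, 1e6)   # periods (200, 250), mid 222
#' @export
frequencyWindowToPeriods <- function(fStart, width, segmentLength) {
  stopifnot(all(fStart >= 1))
  data.frame(fStart = fStart, width = width,
             periodLow = round(segmentLength / (fStart + width)),
             periodMid = round(segmentLength / (fStart + width / 2)),
             periodHigh = round(segmentLength / fStart))
}

#' @rdname windowedNormSpectrum
#' @param x a [WindowedSpectrum-class].
#' @export
spectrumTable <- function(x) {
  cbind(frequencyWindowToPeriods(x@startFrequencies, x@window,
                                 x@segmentLength)[
          , c("fStart", "periodLow", "periodMid", "periodHigh")],
        norm = x@norms)
}

#' @rdname windowedNormSpectrum
#' @export
peakWindow <- function(x) {
  tab <- spectrumTable(x)
  tab[which.max(tab$norm), , drop = FALSE]
}

setMethod("show", "WindowedSpectrum", function(object) {
  cat("WindowedSpectrum:", length(object@norms), "windows of",
      object@window, "frequencies (step", object@step, ") on a segment of",
      format(object@segmentLength, big.mark = ","), "bases\n")
  pk <- peakWindow(object)
  cat("  peak window at frequency", pk$fStart, "- periods", pk$periodLow,
      "-", pk$periodHigh, "bp (mid", pk$periodMid, "bp)\n")
})

#' Shuffle control: destroy phase coherence, keep the value multiset
#'
#' @param values numeric array.
#' @param seed integer seed.
#' @return a seeded uniform random permutation of `values`.
#' @export
shuffleControl <- function(values, seed = 1L) {
  set.seed(seed)
  values[sample.int(length(values))]
}

#' Randomization control: replace a subset by uniform noise
#'
#' Entries at the chosen positions are replaced by independent uniform draws
#' on `[0,1]`; all other entries are untouched.
#'
#' @param values numeric array.
#' @param positions 0-based positions to randomize.
#' @param seed integer seed.
#' @return the modified array.
#' @export
randomizeControl <- function(values, positions, seed = 1L) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(values)
  stopifnot(min(positions) >= 0L, max(positions) < length(values))
  set.seed(seed)
  values[positions + 1L] <- stats::runif(length(positions))
  values
}

#' Windowed spectra for every included segment of an array
#'
#' Runs the full per-chromosome pipeline: segment, apply the disqualified
#' exclusion rule, Fourier transform each included segment and compute its
#' running-window norm spectrum.
#'
#' @param values per-base numeric array (reference-base probabilities or
#'   GC indicator) for one chromosome.
#' @param mask optional [PositionMask-class] / logical disqualified vector.
#' @param segmentLength,window,step,power as in [segmentChromosome()] and
#'   [windowedNormSpectrum()].
#' @param maxDisqualified segment exclusion threshold.
#' @return list with `segments` (a [SegmentSet-class]) and `spectra` (a list
#'   of [WindowedSpectrum-class], one per included segment, named by 1-based
#'   segment number).
#' @export
segmentSpectra <- function(values, mask = NULL, segmentLength = 1e6,
                           window = 1000L, step = 100L, power = FALSE,
                           maxDisqualified = 0.10) {
  segs <- segmentChromosome(length(values), mask, segmentLength,
                            maxDisqualified)
  tab <- segmentTable(segs)
  spectra <- list()
  for (i in seq_len(nrow(tab))) {
    if (!tab$included[i]) next
    seg <- values[(tab$start[i] + 1):tab$end[i]]
    spectra[[as.character(i)]] <-
      windowedNormSpectrum(fourierMagnitudes(seg), window = window,
                           step = step, power = power,
                           segmentLength = segmentLength)
  }
  list(segments = segs, spectra = spectra)
}
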