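#' @include AllGenerics.R
NULL

## ASCII lookup: A=1, C=2, G=3, T=4, N=5 (upper case only; sequences are
## normalized at construction).
.CODE_LUT <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  lut
})

## Integer codes (A=1..T=4, N=5) for a GenomeSequence or a plain string.
baseCodes <- function(x) {
  s <- if (is(x, "GenomeSequence")) x@bases else x
  if (nchar(s) == 0L) return(integer(0))
  .CODE_LUT[utf8ToInt(s)]
}

.codesToString <- function(codes) {
  if (length(codes) == 0L) return("")
  intToUtf8(utf8ToInt("ACGTN")[codes])
}

#' Construct a GenomeSequence
#'
#' Normalizes the input: lower-case letters are upper-cased and flagged as
#' soft-masked repeat; any letter outside A/C/G/T is coerced to N. When
#' `repeatFlags` is supplied it overrides the case-derived flags.
#'
#' @param name sequence label.
#' @param bases a single character string (any case, IUPAC codes allowed and
#'   coerced to N).
#' @param repeatFlags optional logical vector, one per base.
#' @return a [GenomeSequence-class].
#' @examples
#' g <- GenomeSequence("chr1", "acgtNACGT")
#' repeatFlags(g)[1:4]   # soft-masked prefix
#' @export
GenomeSequence <- function(name, bases, repeatFlags = NULL) {
  stopifnot(is.character(bases), length(bases) == 1L)
  n <- nchar(bases)
  flags <- if (is.null(repeatFlags)) {
    if (n == 0L) logical(0) else {
      ch <- utf8ToInt(bases)
      ch >= utf8ToInt("a") & ch <= utf8ToInt("z")
    }
  } else repeatFlags
  up <- toupper(bases)
  up <- chartr("BDEFHIJKLMOPQRSUVWXYZ", strrep("N", 21L), up)
  new("GenomeSequence", name = as.character(name), bases = up,
      repeatFlags = as.logical(flags))
}

#' @rdname GenomeSequence-class
#' @aliases length,GenomeSequence-method
#' @export
setMethod("length", "GenomeSequence", function(x) nchar(x@bases))

#' @rdname GenomeSequence-class
#' @export
setMethod("seqName", "GenomeSequence", function(x) x@name)

#' @rdname GenomeSequence-class
#' @export
setMethod("repeatFlags", "GenomeSequence", function(x) x@repeatFlags)

#' @rdname GenomeSequence-class
#' @export
setMethod("as.character", "GenomeSequence", function(x) x@bases)

setMethod("show", "GenomeSequence", function(object) {
  n <- length(object)
  cat("GenomeSequence", object@name, ":", n, "bases,",
      sum(object@repeatFlags), "soft-masked,",
      sum(baseCodes(object) == .N_CODE), "N\n")
  if (n > 0L)
    cat("  ", substr(object@bases, 1L, min(n, 60L)),
        if (n > 60L) "..." else "", "\n", sep = "")
})

#' Read genome sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines; soft-masking (lower case) is
#' significant and recorded in the repeat flags. Letters outside A/C/G/T are
#' coerced to N. Record order is preserved.
#'
#' @param path FASTA file path.
#' @return a list of [GenomeSequence-class] objects, named by record.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set),
                function(i) GenomeSequence(nm[i], as.character(set[[i]])))
  names(out) <- nm
  out
}

#' Write genome sequences as soft-masked FASTA
#'
#' Repeat-flagged positions are written lower case, so reading the file back
#' reproduces both the bases and the repeat flags.
#'
#' @param genomes a GenomeSequence or list of them.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path, width = 70L) {
  if (is(genomes, "GenomeSequence")) genomes <- list(genomes)
  strs <- vapply(genomes, function(g) {
    s <- strsplit(g@bases, "")[[1L]]
    s[g@repeatFlags] <- tolower(s[g@repeatFlags])
    paste0(s, collapse = "")
  }, character(1))
  set <- Biostrings::BStringSet(strs)
  names(set) <- vapply(genomes, seqName, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' One-hot encode a base sequence
#'
#' @param bases a character string or character vector of single bases over
#'   A/C/G/T (N is not allowed: callers must mask disqualified positions
#'   first).
#' @return numeric matrix `length x 4`; row for A is (1,0,0,0), C (0,1,0,0),
#'   G (0,0,1,0), T (0,0,0,1).
#' @examples
#' oneHotEncode("ACGT")   # the 4 x 4 identity matrix
#' @export
oneHotEncode <- function(bases) {
  if (length(bases) > 1L) bases <- paste0(bases, collapse = "")
  codes <- baseCodes(toupper(bases))
  if (any(is.na(codes)) || any(codes == .N_CODE))
    stop("one-hot encoding is defined for A/C/G/T only")
  m <- matrix(0, nrow = length(codes), ncol = 4L,
              dimnames = list(NULL, .BASES))
  m[cbind(seq_along(codes), codes)] <- 1
  m
}

#' Build the disqualified-position mask for a flank size
#'
#' A position is disqualified iff its context of flank size F contains at
#' least one N, its own base is N, or it lies within F bases of either end.
#'
#' @param genome a [GenomeSequence-class].
#' @param flank flank size F (>= 1).
#' @return a [PositionMask-class].
#' @export
buildPositionMask <- function(genome, flank) {
  flank <- as.integer(flank)
  stopifnot(flank >= 0L)  # 0 arises for order-0 generating chains: N only
  n <- length(genome)
  if (n == 0L)
    return(new("PositionMask", disqualified = logical(0), flankSize = flank))
  isN <- baseCodes(genome) == .N_CODE
  disq <- rep(TRUE, n)
  if (n > 2L * flank) {
    ## windowed N count via cumulative sums over [i-F, i+F]
    cs <- c(0, cumsum(isN))
    i <- (flank + 1L):(n - flank)
    nInWindow <- cs[i + flank + 1L] - cs[i - flank]
    disq[i] <- nInWindow > 0
  }
  new("PositionMask", disqualified = disq, flankSize = flank)
}

#' @rdname PositionMask-class
#' @export
setMethod("disqualified", "PositionMask", function(x) x@disqualified)

setMethod("show", "PositionMask", function(object) {
  cat("PositionMask: flank", object@flankSize, "-",
      sum(object@disqualified), "of", length(object@disqualified),
      "positions disqualified\n")
})

#' Extract the flanking context of a position
#'
#' @param genome a [GenomeSequence-class].
#' @param pos 0-based position, `0 <= pos < length(genome)`.
#' @param flank flank size F.
#' @return a [ContextWindow-class], or `NULL` when the position is
#'   disqualified (context touches an end or contains an N, or the focus base
#'   is N).
#' @export
extractContext <- function(genome, pos, flank) {
  flank <- as.integer(flank)
  n <- length(genome)
  if (pos < 0 || pos >= n) stop("position ", pos, " out of range [0, ", n, ")")
  i <- pos + 1L
  if (i - flank < 1L || i + flank > n) return(NULL)
  win <- substr(genome@bases, i - flank, i + flank)
  if (grepl("N", win, fixed = TRUE)) return(NULL)
  new("ContextWindow",
      left = substr(win, 1L, flank),
      right = substr(win, flank + 2L, 2L * flank + 1L),
      focusPosition = as.integer(pos), flankSize = flank)
}

setMethod("show", "ContextWindow", function(object) {
  cat("ContextWindow @", object@focusPosition, ":", object@left, ".",
      object@right, "\n")
})

#' Reverse complement of a plain character sequence
#'
#' A<->T, C<->G, N->N, order reversed; an involution. Extends the familiar
#' Biostrings generic to bare character vectors as used throughout this
#' package.
#'
#' @param x character vector of sequences over A/C/G/T/N (any case).
#' @param ... ignored.
#' @return character vector of reverse complements (upper case preserved
#'   as given).
#' @importFrom Biostrings reverseComplement
#' @exportMethod reverseComplement
setMethod("reverseComplement", "character", function(x, ...) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    intToUtf8(rev(utf8ToInt(comp)))
  }, character(1), USE.NAMES = FALSE)
})

#' Read annotation intervals from a BED file
#'
#' 3+ column BED (0-based half-open); the name column (4th) is used as the
#' annotation label.
#'
#' @param path BED file path.
#' @param label fallback label applied when the BED has no name column.
#' @return a [GenomicRanges::GRanges] with a `label` metadata column.
#' @export
readAnnotations <- function(path, label = "region") {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name) && !all(is.na(gr$name))) gr$name
         else rep(label, length(gr))
  S4Vectors::mcols(gr)$label <- lab
  gr
}

#' Annotation coverage mask for one chromosome
#'
#' @param annotations a `GRanges` with a `label` metadata column (see
#'   [readAnnotations()]), or any `GRanges` when `label` is `NULL`.
#' @param chrom chromosome name to restrict to.
#' @param length chromosome length L.
#' @param label annotation label to select; `NULL` selects all intervals.
#' @return logical vector of length L, TRUE exactly at positions covered by
#'   at least one matching interval (overlaps do not double count). Intervals
#'   extending past L are clipped with a warning.
#' @export
annotationToMask <- function(annotations, chrom, length, label = NULL) {
  length <- as.integer(length)
  gr <- annotations[as.character(GenomicRanges::seqnames(annotations)) == chrom]
  if (!is.null(label)) {
    labs <- S4Vectors::mcols(gr)$label
    if (is.null(labs)) stop("annotations carry no 'label' column")
    gr <- gr[labs == label]
  }
  mask <- logical(length)
  if (length(gr) == 0L) return(mask)
  st <- GenomicRanges::start(gr)      # 1-based inclusive
  en <- GenomicRanges::end(gr)
  if (any(en > length)) {
    warning("clipping ", sum(en > length), " interval(s) extending past ",
            length, " on ", chrom)
    en <- pmin(en, length)
  }
  keep <- st <= en & st <= length
  cov <- IRanges::coverage(IRanges::IRanges(st[keep], en[keep]), width = length)
  as.logical(cov > 0L)
}
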