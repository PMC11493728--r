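#' Construct a reference amplicon
#'
#' @param sequence amplicon sequence: a [Biostrings::DNAString], a character
#'   string, or a single-sequence FASTA file path.
#' @param frameOffset 0-based index of the first in-frame coding base
#'   (default 0: the amplicon starts in frame).
#' @param targetedPositions 1-based protein positions (amplicon-local
#'   reading frame) targeted by saturation mutagenesis, e.g. `c(403, 404)`
#'   when the amplicon frame is numbered to match the full-length protein.
#'
#' @return An [AmpliconReference-class] object.
#' @examples
#' ref <- AmpliconReference("ATGCTGGATTTTAAACTG", frameOffset = 0,
#'                          targetedPositions = c(2, 3))
#' codonWindows(ref)
#' @export
AmpliconReference <- function(sequence, frameOffset = 0L,
                              targetedPositions = integer()) {
  if (is.character(sequence) && length(sequence) == 1L &&
      file.exists(sequence)) {
    ss <- Biostrings::readDNAStringSet(sequence)
    if (length(ss) != 1L)
      stop("reference FASTA must contain exactly one sequence")
    sequence <- ss[[1L]]
  }
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("AmpliconReference",
      sequence = sequence,
      frameOffset = as.integer(frameOffset),
      targetedPositions = as.integer(targetedPositions))
}

#' @rdname AmpliconReference-class
#' @export
setMethod("refSequence", "AmpliconReference", function(x) x@sequence)

#' @rdname AmpliconReference-class
#' @export
setMethod("frameOffset", "AmpliconReference", function(x) x@frameOffset)

#' @rdname AmpliconReference-class
#' @export
setMethod("targetedPositions", "AmpliconReference",
          function(x) x@targetedPositions)

#' @describeIn AmpliconReference-class 1-based [IRanges::IRanges] of the
#'   targeted codon windows on the amplicon (each of width 3).
#' @export
setMethod("codonWindows", "AmpliconReference", function(x) {
  IRanges::IRanges(start = x@frameOffset + 3L * (x@targetedPositions - 1L) + 1L,
                   width = 3L,
                   names = as.character(x@targetedPositions))
})

setMethod("show", "AmpliconReference", function(object) {
  cat("AmpliconReference of", length(object@sequence), "bp\n")
  cat("  frame offset:", object@frameOffset, "(0-based)\n")
  cat("  targeted positions:",
      if (length(object@targetedPositions))
        paste(object@targetedPositions, collapse = ", ") else "none", "\n")
  if (length(object@targetedPositions)) {
    cat("  wild-type residues:",
        paste0(wtAminoAcids(object), object@targetedPositions,
               collapse = ", "), "\n")
  }
})

#' Wild-type codons and residues at the targeted positions
#'
#' @param x an [AmpliconReference-class].
#' @return `wtCodons()`: character vector of codons; `wtAminoAcids()`:
#'   character vector of one-letter residues.
#' @export
wtCodons <- function(x) {
  stopifnot(is(x, "AmpliconReference"))
  w <- codonWindows(x)
  vapply(seq_along(w), function(i) {
    as.character(Biostrings::subseq(x@sequence, IRanges::start(w)[i],
                                    IRanges::end(w)[i]))
  }, character(1))
}

#' @rdname wtCodons
#' @export
wtAminoAcids <- function(x) .translateCodons(wtCodons(x))

#' Generate a synthetic amplicon sequence
#'
#' Draws a random amplicon whose coding region is free of stop codons, for
#' use as a stand-in wild-type reference in simulations. The default length
#' matches a typical CSR selection amplicon (664 bp).
#'
#' @param length amplicon length in bp.
#' @param frameOffset 0-based first coding base.
#' @param seed optional integer seed.
#' @return An [AmpliconReference-class] without targeted positions (add
#'   them via [AmpliconReference()] on `refSequence()` if needed).
#' @export
syntheticAmplicon <- function(length = 664L, frameOffset = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  lead <- if (frameOffset > 0) sample(bases, frameOffset, replace = TRUE)
          else character()
  nCodon <- (length - frameOffset) %/% 3L
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  codons <- sample(sense, nCodon, replace = TRUE)
  tailLen <- length - frameOffset - 3L * nCodon
  tail <- if (tailLen > 0) sample(bases, tailLen, replace = TRUE)
          else character()
  AmpliconReference(paste(c(lead, codons, tail), collapse = ""),
                    frameOffset = frameOffset)
}
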