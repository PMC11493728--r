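#' Load amplicon reads from a FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] preserving file
#' order; plain and gzip-compressed files are handled transparently.
#'
#' @param path FASTQ file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
loadReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path, format = "fastq")
}

.REJECTION_LEVELS <- c("indel-in-window", "ambiguous-base", "stop-codon",
                       "alignment-fail")

#' Call variant genotypes at the targeted codons
#'
#' Globally aligns each read to the reference amplicon (match +1, mismatch
#' -1, gap open -2, gap extend -1), extracts the read bases over each
#' targeted codon window, translates them, and reports the deviations from
#' wild type as a genotype label (`"L-403-P; R-406-S"`; `"WT"` when all
#' targeted codons are wild type). Reads are rejected — rejection is data,
#' not an error — when an indel overlaps a window (`indel-in-window`), a
#' window contains a non-ACGT base (`ambiguous-base`), a targeted codon
#' translates to a stop (`stop-codon`), or alignment identity falls below
#' `minIdentity` (`alignment-fail`). Coding changes outside the targeted
#' windows do not affect the call; they are accounted for by the fidelity
#' profiling instead.
#'
#' Window extraction happens after alignment, so indels upstream of a
#' window do not shift it. Because errors elsewhere on the read are
#' tallied during the same alignment, the returned object also carries the
#' per-read error tallies consumed by [aggregateProfile()] and friends.
#'
#' @param reads a [Biostrings::DNAStringSet], character vector, or FASTQ
#'   path.
#' @param ref an [AmpliconReference-class] with targeted positions.
#' @param minIdentity minimum aligned identity for a callable read
#'   (default 0.7).
#' @param revcompRetry retry reads failing `minIdentity` as reverse
#'   complements (default TRUE; reads are otherwise assumed to be in
#'   amplicon orientation).
#'
#' @return A [S4Vectors::DataFrame] with one row per read: `genotype`
#'   (label or `NA`), `rejected`, `reason` (factor), alignment `score`,
#'   `identity`, and the error tallies `nSub`, `delBases`, `insBases`,
#'   `basesAnalyzed` (targeted windows excluded), `frameshift`, plus a
#'   16-column `subMatrix` matrix column (reference base x read base,
#'   ACGT order).
#' @export
callGenotypes <- function(reads, ref, minIdentity = 0.7,
                          revcompRetry = TRUE) {
  stopifnot(is(ref, "AmpliconReference"))
  if (length(targetedPositions(ref)) == 0L)
    stop("reference has no targeted positions")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- loadReads(reads)
  readChar <- as.character(reads)
  if (length(readChar) == 0L)
    return(S4Vectors::DataFrame(genotype = character(),
                                rejected = logical(),
                                reason = factor(character(),
                                                levels = .REJECTION_LEVELS)))
  if (any(nchar(readChar) == 0L)) stop("empty read sequence")

  w <- codonWindows(ref)
  refChar <- as.character(refSequence(ref))
  ana <- cs_analyze_reads(readChar, refChar,
                          IRanges::start(w) - 1L, IRanges::end(w),
                          frameOffset(ref))

  if (revcompRetry && any(ana$identity < minIdentity)) {
    idx <- which(ana$identity < minIdentity)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(readChar[idx])))
    ana2 <- cs_analyze_reads(rc, refChar,
                             IRanges::start(w) - 1L, IRanges::end(w),
                             frameOffset(ref))
    better <- ana2$identity > ana$identity[idx]
    if (any(better)) {
      for (f in setdiff(names(ana), "subMat"))
        ana[[f]][idx[better]] <- ana2[[f]][better]
      ana$subMat[idx[better], ] <- ana2$subMat[better, , drop = FALSE]
    }
  }

  k <- length(targetedPositions(ref))
  wtAA <- wtAminoAcids(ref)
  pos <- targetedPositions(ref)

  codMat <- matrix("", nrow = length(readChar), ncol = k)
  for (j in seq_len(k))
    codMat[, j] <- substr(ana$windowSeq, 3L * (j - 1L) + 1L, 3L * j)

  ambiguous <- grepl("[^ACGT]", ana$windowSeq)
  aaMat <- matrix(.translateCodons(as.vector(codMat)), ncol = k)
  hasStop <- rowSums(aaMat == "*") > 0

  reason <- rep(NA_character_, length(readChar))
  reason[hasStop] <- "stop-codon"
  reason[ambiguous] <- "ambiguous-base"
  reason[ana$indelInWindow] <- "indel-in-window"
  reason[ana$identity < minIdentity] <- "alignment-fail"
  rejected <- !is.na(reason)

  genotype <- rep(NA_character_, length(readChar))
  ok <- !rejected
  if (any(ok))
    genotype[ok] <- .genotypeLabels(wtAA, pos,
                                    aaMat[ok, , drop = FALSE])

  subMat <- ana$subMat
  colnames(subMat) <- paste0(rep(c("A", "C", "G", "T"), each = 4), ">",
                             rep(c("A", "C", "G", "T"), times = 4))
  S4Vectors::DataFrame(
    genotype = genotype, rejected = rejected,
    reason = factor(reason, levels = .REJECTION_LEVELS),
    score = ana$score, identity = ana$identity,
    nSub = ana$nSub, delBases = ana$delBases, insBases = ana$insBases,
    basesAnalyzed = ana$basesAnalyzed, frameshift = ana$frameshift,
    subMatrix = I(subMat)
  )
}

#' Build a pre/post-selection variant count table
#'
#' Counts callable reads per genotype for both rounds; genotypes absent in
#' one round get count 0. Frequencies are counts over callable reads per
#' round, so each round's frequencies sum to 1.
#'
#' @param callsR0,callsR1 genotype call tables from [callGenotypes()].
#' @return A [VariantCounts-class].
#' @export
buildCountTable <- function(callsR0, callsR1) {
  g0 <- callsR0$genotype[!callsR0$rejected]
  g1 <- callsR1$genotype[!callsR1$rejected]
  if (length(g0) == 0L) stop("no callable reads in round r0")
  if (length(g1) == 0L) stop("no callable reads in round r1")
  labels <- sort(unique(c(g0, g1)))
  m <- cbind(r0 = as.integer(table(factor(g0, levels = labels))),
             r1 = as.integer(table(factor(g1, levels = labels))))
  rownames(m) <- labels
  VariantCounts(m)
}

#' @rdname VariantCounts-class
#' @param counts integer matrix with columns `r0` and `r1`, rows named by
#'   genotype label.
#' @export
VariantCounts <- function(counts) {
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(round = c("r0", "r1"),
                                   row.names = c("r0", "r1")))
  new("VariantCounts", se)
}

#' @describeIn VariantCounts-class the count matrix.
#' @export
setMethod("counts", "VariantCounts",
          function(object, ...) SummarizedExperiment::assay(object, "counts"))

#' @describeIn VariantCounts-class callable reads per round (column sums).
#' @export
setMethod("roundTotals", "VariantCounts",
          function(x) colSums(counts(x)))

#' @describeIn VariantCounts-class per-round frequency matrix
#'   (columns sum to 1).
#' @export
setMethod("variantFrequencies", "VariantCounts", function(x) {
  m <- counts(x)
  sweep(m, 2L, colSums(m), "/")
})

setMethod("show", "VariantCounts", function(object) {
  m <- counts(object)
  cat("VariantCounts:", nrow(m), "genotypes\n")
  tot <- colSums(m)
  cat("  callable reads: r0 =", tot[["r0"]], ", r1 =", tot[["r1"]], "\n")
  top <- head(m[order(-m[, "r1"]), , drop = FALSE], 5L)
  print(top)
})
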