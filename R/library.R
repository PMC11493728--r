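.genotypeLabels <- function(wtAA, positions, aaTable) {
  if (length(positions) == 0L) return(rep("WT", nrow(aaTable)))
  apply(aaTable, 1L, function(aa) {
    i <- which(aa != wtAA)
    if (!length(i)) "WT"
    else paste(paste0(wtAA[i], "-", positions[i], "-", aa[i]),
               collapse = "; ")
  })
}

# codons available to a scheme, and the canonical (first, alphabetical)
# codon used when emitting reads for a given amino acid
.schemeCodons <- function(codonScheme) {
  all <- names(.GENETIC_CODE)
  switch(codonScheme,
    "NNK" = all[substr(all, 3, 3) %in% c("G", "T")],
    "NNN" = all,
    "exhaustive-AA" = {
      aa <- .GENETIC_CODE
      all[!duplicated(aa)]
    },
    stop("unknown codon scheme: ", codonScheme))
}

.canonicalCodon <- function(aa, codonScheme) {
  cods <- sort(.schemeCodons(codonScheme))
  map <- vapply(aa, function(a) cods[.GENETIC_CODE[cods] == a][1L],
                character(1))
  if (anyNA(map))
    stop("codon scheme cannot encode residue(s): ",
         paste(unique(aa[is.na(map)]), collapse = ", "))
  map
}

#' Build a saturation-mutagenesis protein variant library
#'
#' Enumerates every protein variant obtainable at the targeted codons of a
#' reference amplicon, excluding variants containing a stop codon, so a
#' `k`-position library holds `20^k` protein variants (400 for `k = 2`,
#' 3.2e6 for `k = 5`). Genotypes are tracked at the protein level; the DNA
#' codon scheme (default NNK) only governs how reads are emitted by the
#' simulator.
#'
#' @param reference an [AmpliconReference-class] with targeted positions.
#' @param codonScheme `"NNK"` (default), `"NNN"` or `"exhaustive-AA"`.
#' @param enumerate materialise the variant list? Defaults to `TRUE` for
#'   libraries of at most `2e5` variants; larger libraries record only the
#'   theoretical size unless forced.
#'
#' @return A [VariantLibrary-class].
#' @examples
#' ref <- AmpliconReference(refSequence(syntheticAmplicon(90, seed = 1)),
#'                          targetedPositions = c(10, 11))
#' lib <- buildLibrary(ref)
#' theoreticalSize(lib)  # 400
#' @export
buildLibrary <- function(reference, codonScheme = c("NNK", "NNN",
                                                    "exhaustive-AA"),
                         enumerate = NULL) {
  stopifnot(is(reference, "AmpliconReference"))
  codonScheme <- match.arg(codonScheme)
  validObject(reference) # position / frame errors surface here
  k <- length(targetedPositions(reference))
  size <- 20^k
  if (is.null(enumerate)) enumerate <- size <= 2e5

  if (enumerate) {
    if (k == 0L) {
      aaTable <- matrix(character(), nrow = 1L, ncol = 0L)
      labels <- "WT"
    } else {
      grid <- do.call(expand.grid,
                      c(rep(list(.AA20), k),
                        list(KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)))
      aaTable <- as.matrix(grid)
      dimnames(aaTable) <- list(NULL, as.character(
        targetedPositions(reference)))
      labels <- .genotypeLabels(wtAminoAcids(reference),
                                targetedPositions(reference), aaTable)
    }
  } else {
    aaTable <- matrix(character(), nrow = 0L, ncol = k)
    labels <- character()
  }

  new("VariantLibrary", reference = reference, aaTable = aaTable,
      labels = labels, codonScheme = codonScheme, theoreticalSize = size)
}

#' @rdname VariantLibrary-class
#' @export
setMethod("variantLabels", "VariantLibrary", function(x) x@labels)

#' @rdname VariantLibrary-class
#' @export
setMethod("theoreticalSize", "VariantLibrary", function(x) x@theoreticalSize)

#' @describeIn VariantLibrary-class the underlying reference amplicon.
#' @export
libraryReference <- function(x) {
  stopifnot(is(x, "VariantLibrary"))
  x@reference
}

setMethod("show", "VariantLibrary", function(object) {
  k <- length(targetedPositions(object@reference))
  cat("VariantLibrary:", k, "targeted position(s),",
      format(object@theoreticalSize, big.mark = ","),
      "protein variants (stops excluded)\n")
  cat("  codon scheme:", object@codonScheme, "\n")
  cat("  enumerated:", if (nrow(object@aaTable) || k == 0L) "yes" else "no",
      "\n")
  if (length(object@labels))
    cat("  e.g.", paste(head(object@labels, 3), collapse = " | "), "\n")
})

# full-length DNA sequence of each enumerated variant, canonical codons
.variantSequences <- function(lib) {
  ref <- lib@reference
  refChar <- as.character(ref@sequence)
  if (!nrow(lib@aaTable)) stop("library is not enumerated")
  k <- ncol(lib@aaTable)
  if (k == 0L) return(stats::setNames(refChar, "WT"))
  w <- codonWindows(ref)
  seqs <- rep(refChar, nrow(lib@aaTable))
  for (j in seq_len(k)) {
    cod <- .canonicalCodon(lib@aaTable[, j], lib@codonScheme)
    substr(seqs, IRanges::start(w)[j], IRanges::end(w)[j]) <- cod
  }
  stats::setNames(seqs, lib@labels)
}
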