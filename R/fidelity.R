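#' Global pairwise alignment of a read against the reference
#'
#' Needleman-Wunsch alignment with affine gaps under the package's fixed
#' scoring (match +1, mismatch -1, gap open -2, gap extend -1) and
#' deterministic tie-breaks: a mismatch is preferred over opening a gap, a
#' gap in the read (deletion) over a gap in the reference (insertion), and
#' gaps are closed as early as possible during traceback.
#'
#' @param read,ref sequences (character or [Biostrings::DNAString];
#'   `ref` may be an [AmpliconReference-class]).
#' @return A list with gapped strings `ref` and `read` (equal length,
#'   `"-"` marking gaps) and the alignment `score`.
#' @export
alignToReference <- function(read, ref) {
  if (is(ref, "AmpliconReference")) ref <- refSequence(ref)
  read <- as.character(read); ref <- as.character(ref)
  if (nchar(read) == 0L || nchar(ref) == 0L) stop("empty sequence")
  cs_pair_align(read, ref)
}

#' Tally alignment errors by type
#'
#' Walks a gapped alignment and counts substitutions (recorded in a 4x4
#' reference-base x read-base matrix), deleted bases (gap in read) and
#' inserted bases (gap in reference). A k-bp gap counts k bases: rates are
#' per base. The read is flagged as a frameshift when the summed indel
#' lengths inside the coding region are not a multiple of 3.
#'
#' @param alignment a list as returned by [alignToReference()].
#' @param frameOffset 0-based first coding base on the reference
#'   (default 0).
#' @param windows optional [IRanges::IRanges] of targeted codon windows
#'   (1-based reference coordinates) excluded from error counting and from
#'   the bases analysed.
#' @return A list: `substitutions`, `deletions`, `insertions`,
#'   `basesAnalyzed`, `frameshift`, `subMatrix`.
#' @examples
#' aln <- alignToReference("ACGTACGTT", "ACGTACGTA")
#' tallyErrors(aln)$substitutions  # 1
#' @export
tallyErrors <- function(alignment, frameOffset = 0L, windows = NULL) {
  ra <- strsplit(alignment$ref, "")[[1]]
  rd <- strsplit(alignment$read, "")[[1]]
  stopifnot(length(ra) == length(rd))
  refPos <- cumsum(ra != "-")          # 1-based ref coordinate per column
  n <- max(refPos)
  codingEnd <- frameOffset + 3L * ((n - frameOffset) %/% 3L) # 0-based excl
  inWin <- rep(FALSE, n)
  if (!is.null(windows))
    for (i in seq_along(windows))
      inWin[IRanges::start(windows)[i]:IRanges::end(windows)[i]] <- TRUE

  bases <- c("A", "C", "G", "T")
  subMat <- matrix(0L, 4, 4, dimnames = list(ref = bases, read = bases))
  subs <- dels <- ins <- codingIndel <- 0L
  for (i in seq_along(ra)) {
    p <- refPos[i]
    coding <- p > frameOffset && p <= codingEnd
    if (ra[i] == "-") {                 # insertion (consumes read only)
      ins <- ins + 1L
      # boundary lies strictly inside the coding region?
      if (p >= frameOffset + 1L && p < codingEnd) codingIndel <- codingIndel + 1L
    } else if (rd[i] == "-") {          # deletion
      dels <- dels + 1L
      if (coding) codingIndel <- codingIndel + 1L
    } else if (ra[i] != rd[i] && !inWin[p]) {
      if (ra[i] %in% bases && rd[i] %in% bases) {
        subs <- subs + 1L
        subMat[ra[i], rd[i]] <- subMat[ra[i], rd[i]] + 1L
      }
    }
  }
  list(substitutions = subs, deletions = dels, insertions = ins,
       basesAnalyzed = n - sum(inWin),
       frameshift = codingIndel > 0L && codingIndel %% 3L != 0L,
       subMatrix = subMat)
}

.BASES <- c("A", "C", "G", "T")
.TS_PAIRS <- c("A>G", "G>A", "C>T", "T>C")

.emptySubMat <- function() {
  matrix(0, 4, 4, dimnames = list(ref = .BASES, read = .BASES))
}

.foldSubMat <- function(v) {
  m <- matrix(as.numeric(v), 4, 4, byrow = TRUE,
              dimnames = list(ref = .BASES, read = .BASES))
  m
}

#' Aggregate per-read error tallies into an error profile
#'
#' Sums per-read tallies from [callGenotypes()] into per-base deletion,
#' insertion and substitution rates (errors divided by reference bases
#' analysed, targeted codon windows excluded). Reads carrying
#' frame-shifting indels are excluded from the rate aggregation but
#' counted in the frameshift frequency (frameshifted reads over all reads
#' analysed). With a baseline profile (typically the pre-selection round,
#' capturing shared PCR/sequencing noise), the corrected total rate
#' (total minus baseline total) and the fold over baseline (total over
#' baseline total, rounded to the nearest integer) are filled in.
#'
#' @param tallies a [callGenotypes()] result (or any subset of its rows).
#' @param baseline optional [ErrorProfile-class] to correct against.
#' @return An [ErrorProfile-class].
#' @export
aggregateProfile <- function(tallies, baseline = NULL) {
  n <- nrow(tallies)
  if (n == 0L) stop("no reads to aggregate")
  fs <- tallies$frameshift
  keep <- !fs
  totalBases <- sum(tallies$basesAnalyzed[keep])
  if (totalBases == 0) stop("zero bases analysed")
  subs <- sum(tallies$nSub[keep])
  dels <- sum(tallies$delBases[keep])
  inss <- sum(tallies$insBases[keep])
  subMat <- .foldSubMat(colSums(tallies$subMatrix[keep, , drop = FALSE]))
  rateSub <- subs / totalBases
  rateDel <- dels / totalBases
  rateIns <- inss / totalBases
  rateTotal <- rateSub + rateDel + rateIns
  tsCount <- sum(subMat[cbind(c("A", "G", "C", "T"),
                              c("G", "A", "T", "C"))])
  tvCount <- sum(subMat) - tsCount
  corrected <- NA_real_
  fold <- NA_real_
  if (!is.null(baseline)) {
    stopifnot(is(baseline, "ErrorProfile"))
    corrected <- rateTotal - baseline@rateTotal
    fold <- round(rateTotal / baseline@rateTotal)
  }
  new("ErrorProfile",
      nReads = n, totalBases = totalBases,
      rateDel = rateDel, rateIns = rateIns, rateSub = rateSub,
      rateTotal = rateTotal, correctedTotal = corrected, fold = fold,
      frameshiftFreq = sum(fs) / n,
      subMatrix = subMat,
      tsRate = tsCount / totalBases, tvRate = tvCount / totalBases)
}

#' Baseline correction of printed or precomputed error rates
#'
#' Arithmetic helper for working directly with reported totals: corrected
#' rate = `total - baselineTotal`; fold = `round(total / baselineTotal)`.
#'
#' @param total,baselineTotal per-base total error rates.
#' @return A list with `corrected` and `fold`.
#' @export
correctErrorRate <- function(total, baselineTotal) {
  list(corrected = total - baselineTotal,
       fold = round(total / baselineTotal))
}

#' Per-genotype error profiles
#'
#' Splits the per-read tallies by called genotype and aggregates an
#' [ErrorProfile-class] for each. The targeted codons never contribute:
#' the variant's defining codons are not errors, so their windows are
#' excluded from error counting for every read (library-level rates are
#' therefore the read-count-weighted average of the per-genotype rates).
#' Rejected reads are not assigned to any genotype.
#'
#' @param calls a [callGenotypes()] result.
#' @param baseline optional [ErrorProfile-class] passed through to
#'   [aggregateProfile()].
#' @return Named list of [ErrorProfile-class] objects.
#' @export
mutantErrorRates <- function(calls, baseline = NULL) {
  ok <- !calls$rejected
  if (!any(ok)) stop("no callable reads")
  idx <- split(which(ok), calls$genotype[ok])
  lapply(idx, function(i) aggregateProfile(calls[i, ], baseline = baseline))
}

#' Substitution spectrum and transition/transversion rates
#'
#' Aggregates the 4x4 substitution counts of a read set (frameshifted
#' reads excluded, consistent with [aggregateProfile()]) and normalises
#' each cell by its reference-base opportunity (occurrences of the
#' reference base among analysed positions times reads analysed).
#' Transitions are `A<->G` and `C<->T`; everything else is a
#' transversion.
#'
#' @param tallies a [callGenotypes()] result.
#' @param ref the [AmpliconReference-class] the reads were called against.
#' @return A list: `counts` (4x4), `rates` (4x4, per opportunity),
#'   `tsRate`, `tvRate` (events per analysed base), `tsTvRatio`.
#' @export
substitutionSpectrum <- function(tallies, ref) {
  stopifnot(is(ref, "AmpliconReference"))
  keep <- !tallies$frameshift
  if (!any(keep)) stop("no non-frameshifted reads")
  cnt <- .foldSubMat(colSums(tallies$subMatrix[keep, , drop = FALSE]))
  if (sum(cnt) == 0) stop("no substitutions observed")

  w <- codonWindows(ref)
  refChars <- strsplit(as.character(refSequence(ref)), "")[[1]]
  inWin <- rep(FALSE, length(refChars))
  for (i in seq_along(w))
    inWin[IRanges::start(w)[i]:IRanges::end(w)[i]] <- TRUE
  oppPerRead <- table(factor(refChars[!inWin], levels = .BASES))
  nReads <- sum(keep)
  opp <- as.numeric(oppPerRead) * nReads
  rates <- sweep(cnt, 1L, ifelse(opp > 0, opp, NA), "/")

  totalBases <- sum(tallies$basesAnalyzed[keep])
  tsCount <- sum(cnt[cbind(c("A", "G", "C", "T"), c("G", "A", "T", "C"))])
  tvCount <- sum(cnt) - tsCount
  list(counts = cnt, rates = rates,
       tsRate = tsCount / totalBases, tvRate = tvCount / totalBases,
       tsTvRatio = if (tvCount > 0) tsCount / tvCount else Inf)
}

setMethod("show", "ErrorProfile", function(object) {
  fmt <- function(x) formatC(x, format = "e", digits = 2)
  cat("ErrorProfile over", object@nReads, "reads,",
      format(object@totalBases, big.mark = ","), "bases analysed\n")
  cat("  del:", fmt(object@rateDel), " ins:", fmt(object@rateIns),
      " sub:", fmt(object@rateSub), " total:", fmt(object@rateTotal),
      "errors/bp\n")
  if (!is.na(object@correctedTotal))
    cat("  corrected total:", fmt(object@correctedTotal),
        sprintf(" (%dx baseline)\n", as.integer(object@fold)))
  cat("  frameshift freq:", fmt(object@frameshiftFreq), "\n")
})

#' @describeIn ErrorProfile-class per-type rates as a named vector.
#' @param x an `ErrorProfile`.
#' @export
errorRates <- function(x) {
  stopifnot(is(x, "ErrorProfile"))
  c(deletion = x@rateDel, insertion = x@rateIns,
    substitution = x@rateSub, total = x@rateTotal,
    correctedTotal = x@correctedTotal, frameshiftFreq = x@frameshiftFreq)
}
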