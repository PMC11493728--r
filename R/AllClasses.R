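#' Reference amplicon with targeted codon positions
#'
#' Holds the wild-type amplicon sequence, the 0-based offset of the first
#' in-frame coding base, and the 1-based protein positions targeted by
#' saturation mutagenesis. The codon windows derived from these positions
#' must lie fully inside the amplicon.
#'
#' @slot sequence [Biostrings::DNAString] wild-type amplicon.
#' @slot frameOffset single integer, 0-based index of the first codon base.
#' @slot targetedPositions integer vector of 1-based protein positions,
#'   strictly increasing.
#'
#' @seealso [AmpliconReference()], [codonWindows()]
#' @name AmpliconReference-class
#' @rdname AmpliconReference-class
#' @exportClass AmpliconReference
setClass("AmpliconReference",
  slots = c(
    sequence = "DNAString",
    frameOffset = "integer",
    targetedPositions = "integer"
  )
)

setValidity("AmpliconReference", function(object) {
  msg <- NULL
  n <- length(object@sequence)
  off <- object@frameOffset
  pos <- object@targetedPositions
  if (length(off) != 1L || is.na(off) || off < 0L)
    msg <- c(msg, "frameOffset must be a single non-negative integer")
  else if (off >= n)
    msg <- c(msg, "frameOffset lies outside the amplicon")
  if (anyNA(pos) || any(pos < 1L))
    msg <- c(msg, "targeted positions must be positive integers")
  if (is.unsorted(pos, strictly = TRUE))
    msg <- c(msg, "targeted positions must be strictly increasing")
  if (is.null(msg) && length(pos)) {
    ends <- off + 3L * pos          # 0-based exclusive end of each codon
    if (any(ends > n))
      msg <- c(msg, "targeted codon windows extend beyond the amplicon")
  }
  if (is.null(msg)) TRUE else msg
})

#' Saturation-mutagenesis protein variant library
#'
#' The set of protein variants obtainable by saturating the targeted codons
#' of an [AmpliconReference-class]. Stop-codon variants are excluded, so the
#' theoretical size is `20^k` for `k` targeted positions. For very large
#' libraries the variant list need not be materialised; the theoretical
#' size is always recorded.
#'
#' @slot reference the [AmpliconReference-class] the library is built on.
#' @slot aaTable character matrix (variants x positions) of amino acids;
#'   may have zero rows when the library was not enumerated.
#' @slot labels character vector of genotype labels (`"L-403-P; R-406-S"`
#'   style, `"WT"` for the wild type); parallel to `aaTable` rows.
#' @slot codonScheme one of `"NNK"`, `"NNN"`, `"exhaustive-AA"`.
#' @slot theoreticalSize numeric, `20^k`.
#'
#' @name VariantLibrary-class
#' @rdname VariantLibrary-class
#' @exportClass VariantLibrary
setClass("VariantLibrary",
  slots = c(
    reference = "AmpliconReference",
    aaTable = "matrix",
    labels = "character",
    codonScheme = "character",
    theoreticalSize = "numeric"
  )
)

setValidity("VariantLibrary", function(object) {
  msg <- NULL
  k <- length(object@reference@targetedPositions)
  if (!identical(object@theoreticalSize, 20^k))
    msg <- c(msg, "theoreticalSize must equal 20^k (stops excluded)")
  if (nrow(object@aaTable) != length(object@labels))
    msg <- c(msg, "aaTable rows and labels differ in length")
  if (nrow(object@aaTable) && ncol(object@aaTable) != k)
    msg <- c(msg, "aaTable must have one column per targeted position")
  if (any(object@aaTable == "*"))
    msg <- c(msg, "stop-codon variants must be excluded")
  if (is.null(msg)) TRUE else msg
})

#' Pre-/post-selection variant count table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `counts` assay
#' whose two columns are the pre-selection (`r0`) and post-selection (`r1`)
#' rounds; rows are genotype labels. Totals are the callable reads per
#' round, so per-round frequencies sum to one.
#'
#' @name VariantCounts-class
#' @rdname VariantCounts-class
#' @exportClass VariantCounts
setClass("VariantCounts", contains = "SummarizedExperiment")

setValidity("VariantCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (!identical(colnames(m), c("r0", "r1")))
      msg <- c(msg, "count columns must be 'r0' and 'r1'")
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be non-negative integers")
    if (is.null(rownames(m)))
      msg <- c(msg, "rows must be named by genotype label")
  }
  if (is.null(msg)) TRUE else msg
})

#' Aggregated per-base error profile
#'
#' Per-base deletion, insertion and substitution rates over a read set,
#' with optional baseline correction: `correctedTotal` is the total rate
#' minus the baseline (pre-selection) total rate, and `fold` is the total
#' rate divided by the baseline total rate, rounded to the nearest integer.
#' Reads whose indels shift the coding frame are excluded from rate
#' aggregation but counted in `frameshiftFreq` (frameshifted reads divided
#' by all reads analysed).
#'
#' @slot nReads number of reads analysed (including frameshifted ones).
#' @slot totalBases reference bases analysed in the non-frameshifted reads
#'   (targeted codon windows excluded).
#' @slot rateDel,rateIns,rateSub,rateTotal per-base error rates (errors/bp).
#' @slot correctedTotal `rateTotal` minus the baseline total (`NA` without
#'   a baseline).
#' @slot fold total-rate fold over baseline, rounded to integer (`NA`
#'   without a baseline).
#' @slot frameshiftFreq fraction of reads carrying frame-shifting indels.
#' @slot subMatrix 4x4 substitution count matrix (reference base in rows,
#'   read base in columns, ACGT order).
#' @slot tsRate,tvRate transition / transversion rates (events/bp).
#'
#' @name ErrorProfile-class
#' @rdname ErrorProfile-class
#' @exportClass ErrorProfile
setClass("ErrorProfile",
  slots = c(
    nReads = "numeric",
    totalBases = "numeric",
    rateDel = "numeric",
    rateIns = "numeric",
    rateSub = "numeric",
    rateTotal = "numeric",
    correctedTotal = "numeric",
    fold = "numeric",
    frameshiftFreq = "numeric",
    subMatrix = "matrix",
    tsRate = "numeric",
    tvRate = "numeric"
  )
)

setValidity("ErrorProfile", function(object) {
  msg <- NULL
  if (object@totalBases < 0) msg <- c(msg, "totalBases must be >= 0")
  if (!is.na(object@frameshiftFreq) &&
      (object@frameshiftFreq < 0 || object@frameshiftFreq > 1))
    msg <- c(msg, "frameshiftFreq must lie in [0, 1]")
  if (!identical(dim(object@subMatrix), c(4L, 4L)))
    msg <- c(msg, "subMatrix must be 4x4")
  if (is.null(msg)) TRUE else msg
})

#' Subsampling detection trials at one coverage pair
#'
#' Binary detection outcomes for every genotype ever classified as
#' significantly enriched across `nTrials` seeded subsampling trials at a
#' fixed pre-/post-selection coverage pair.
#'
#' @slot coverageR0,coverageR1 coverage levels (reads / theoretical library
#'   size) for the pre- and post-selection rounds.
#' @slot detections logical matrix, genotypes x trials.
#' @slot nTrials number of trials.
#'
#' @name CoverageTrialSet-class
#' @rdname CoverageTrialSet-class
#' @exportClass CoverageTrialSet
setClass("CoverageTrialSet",
  slots = c(
    coverageR0 = "numeric",
    coverageR1 = "numeric",
    detections = "matrix",
    nTrials = "integer"
  )
)

setValidity("CoverageTrialSet", function(object) {
  msg <- NULL
  if (object@coverageR0 <= 0 || object@coverageR1 <= 0)
    msg <- c(msg, "coverage levels must be positive")
  if (ncol(object@detections) != object@nTrials)
    msg <- c(msg, "detections must have one column per trial")
  if (!is.logical(object@detections))
    msg <- c(msg, "detections must be logical")
  if (is.null(msg)) TRUE else msg
})
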