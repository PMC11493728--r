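## CSR selection and sequencing simulator.
##
## The selection model is deterministic exponential amplification: after c
## cycles a variant of relative fitness w contributes pre * (1 + w)^c to the
## pool, and reads are drawn multinomially from the renormalised pool.
## Compartment occupancy is not modelled; this is the simplest model that
## reproduces the log-linear enrichment the analysis assumes.

#' Default error model rates
#'
#' Baseline (sequencing + recovery PCR) per-base rates are anchored to the
#' pre-selection round of a deep-sequenced 2-codon CSR library
#' (substitution 5.60e-4, deletion 2.20e-4, insertion 9.69e-6 errors/bp,
#' total ~7.9e-4). Polymerase (per-variant, post-selection only) defaults
#' reflect corrected error rates typical of selected exonuclease-deficient
#' KOD variants (substitution ~7.4e-3).
#'
#' @return Named list of per-base rates.
#' @export
defaultErrorRates <- function() {
  list(
    seqSub = 5.60e-4, seqDel = 2.20e-4, seqIns = 9.69e-6,
    polSub = 7.4e-3, polDel = 2.0e-4, polIns = 8.0e-5
  )
}

#' Expected variant frequencies after selection
#'
#' @param preFreq named numeric vector of pre-selection frequencies
#'   (must sum to 1).
#' @param fitness named numeric vector of per-cycle amplification
#'   efficiencies `w >= 0`, aligned with `preFreq` (missing names get 0).
#' @param cycles number of selection PCR cycles (default 20).
#' @return Named numeric vector of expected post-selection frequencies
#'   (sums to 1).
#' @export
expectedPostFrequencies <- function(preFreq, fitness, cycles = 20L) {
  stopifnot(length(preFreq) > 0, !is.null(names(preFreq)))
  if (abs(sum(preFreq) - 1) > 1e-8)
    stop("pre-selection frequencies must sum to 1")
  w <- rep(0, length(preFreq))
  names(w) <- names(preFreq)
  if (!is.null(names(fitness))) {
    hit <- intersect(names(fitness), names(w))
    w[hit] <- fitness[hit]
  } else {
    stopifnot(length(fitness) == length(preFreq))
    w[] <- fitness
  }
  if (any(w < 0)) stop("fitness values must be non-negative")
  amp <- preFreq * (1 + w)^cycles
  amp / sum(amp)
}

#' True log enrichment under the exponential selection model
#'
#' `ln(expected post frequency / pre frequency)` per variant.
#' @inheritParams expectedPostFrequencies
#' @return Named numeric vector.
#' @export
trueEnrichment <- function(preFreq, fitness, cycles = 20L) {
  post <- expectedPostFrequencies(preFreq, fitness, cycles)
  log(post / preFreq)
}

#' Simulate one round of CSR selection
#'
#' Applies deterministic exponential amplification `(1 + w)^cycles` to the
#' pre-selection frequencies and samples read counts multinomially at the
#' requested depth.
#'
#' @inheritParams expectedPostFrequencies
#' @param depth number of reads to draw.
#' @param seed optional integer seed.
#' @return Named integer vector of post-selection counts summing exactly
#'   to `depth`.
#' @export
simulateSelection <- function(preFreq, fitness, cycles = 20L, depth,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(depth > 0)
  post <- expectedPostFrequencies(preFreq, fitness, cycles)
  counts <- as.integer(rmultinom(1L, size = depth, prob = post))
  names(counts) <- names(post)
  counts
}

#' Emit noisy amplicon reads for a set of variant counts
#'
#' Each read is the full-length amplicon of its source variant (targeted
#' codons set to the scheme's canonical codon for the variant residues),
#' mutated by a per-variant polymerase error model (post-selection reads)
#' plus a baseline sequencing/PCR error model (all reads). Substitutions
#' follow a transition:transversion weighting; indel event lengths are
#' drawn from configurable distributions. Reads whose indels shift the
#' coding frame are emitted, not suppressed.
#'
#' @param counts named integer vector (genotype label -> read count); names
#'   must be labels of `library`.
#' @param library an enumerated [VariantLibrary-class].
#' @param round `"r0"` (baseline errors only) or `"r1"` (polymerase +
#'   baseline errors).
#' @param polSub,polDel,polIns per-variant polymerase per-base rates:
#'   scalars or vectors named by genotype label. Ignored for `round =
#'   "r0"`.
#' @param seqSub,seqDel,seqIns baseline per-base rates applied to every
#'   read.
#' @param tsBias transition:transversion weight; a substitution is a
#'   transition with probability `tsBias / (1 + tsBias)` (default 2, i.e.
#'   a 2:1 transition:transversion rate ratio).
#' @param delLenProbs,insLenProbs named numeric vectors giving the indel
#'   event length distribution (names are lengths).
#' @param shuffle randomise read order (default TRUE).
#' @param seed optional integer seed.
#'
#' @return A list with `reads` ([Biostrings::DNAStringSet], names
#'   `read_1..read_n`) and `truth` (a [S4Vectors::DataFrame] with the
#'   source variant and the injected error counts per read).
#' @export
simulateReads <- function(counts, library, round = c("r1", "r0"),
                          polSub = defaultErrorRates()$polSub,
                          polDel = defaultErrorRates()$polDel,
                          polIns = defaultErrorRates()$polIns,
                          seqSub = defaultErrorRates()$seqSub,
                          seqDel = defaultErrorRates()$seqDel,
                          seqIns = defaultErrorRates()$seqIns,
                          tsBias = 2,
                          delLenProbs = c("1" = 1),
                          insLenProbs = c("1" = 1),
                          shuffle = TRUE, seed = NULL) {
  round <- match.arg(round)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(library, "VariantLibrary"))
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) == 0)
    stop("no reads requested")
  if (any(counts < 0)) stop("counts must be non-negative")
  rates <- c(polSub = 0, polDel = 0, polIns = 0,
             seqSub = seqSub, seqDel = seqDel, seqIns = seqIns)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")

  seqs <- .variantSequences(library)
  miss <- setdiff(names(counts), names(seqs))
  if (length(miss))
    stop("unknown genotype(s): ", paste(head(miss), collapse = ", "))

  variant <- rep(names(counts), counts)
  n <- length(variant)
  if (shuffle) variant <- variant[sample.int(n)]
  templates <- unname(seqs[variant])

  expandRate <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) rep(x, n)
    else if (!is.null(names(x))) {
      v <- x[variant]
      if (anyNA(v)) stop("missing ", what, " rate for some genotypes")
      unname(v)
    } else stop(what, " rates must be a scalar or a named vector")
  }
  if (round == "r1") {
    subR <- expandRate(polSub, "polymerase substitution") + seqSub
    delR <- expandRate(polDel, "polymerase deletion") + seqDel
    insR <- expandRate(polIns, "polymerase insertion") + seqIns
  } else {
    subR <- rep(seqSub, n); delR <- rep(seqDel, n); insR <- rep(seqIns, n)
  }
  if (any(c(subR, delR, insR) > 1)) stop("combined rates exceed 1")

  tsProb <- tsBias / (1 + tsBias)
  mut <- cs_mutate_reads(templates, subR, delR, insR, tsProb,
                         as.integer(names(delLenProbs)),
                         unname(delLenProbs / sum(delLenProbs)),
                         as.integer(names(insLenProbs)),
                         unname(insLenProbs / sum(insLenProbs)),
                         frameOffset(library@reference))

  reads <- Biostrings::DNAStringSet(mut$read)
  names(reads) <- paste0("read_", seq_len(n))
  truth <- S4Vectors::DataFrame(
    read = names(reads), variant = variant,
    nSub = mut$nSub, nDelBases = mut$nDelBases, nInsBases = mut$nInsBases,
    frameshift = mut$frameshift
  )
  list(reads = reads, truth = truth)
}

#' Write reads as FASTQ
#'
#' One record per read, Phred+33, constant quality `"I"` (the analysis does
#' not use quality scores). A `.gz` suffix triggers gzip compression.
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeSimFastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a complete CSR selection experiment
#'
#' Draws pre-selection counts from the library composition, applies one
#' round of exponential selection, emits noisy reads for both rounds, and
#' returns the full ground truth. With a fixed seed the outputs (including
#' any FASTQ files written) are byte-identical across runs.
#'
#' @param library an enumerated [VariantLibrary-class].
#' @param fitness named per-variant amplification efficiencies (variants
#'   not named get 0).
#' @param cycles selection PCR cycles (default 20).
#' @param preDepth,postDepth reads to emit per round.
#' @param preFreq optional named pre-selection frequencies (default
#'   uniform over the library).
#' @param seed integer seed (required for reproducibility).
#' @param outdir optional directory; when given, writes `r0.fastq`,
#'   `r1.fastq`, `variant_truth.tsv`, `read_truth_r0.tsv`,
#'   `read_truth_r1.tsv` and `config.json` there.
#' @param ... error-model arguments passed to [simulateReads()].
#'
#' @return A list with elements `preCounts`, `postCounts`, `readsR0`,
#'   `readsR1`, `truthR0`, `truthR1` (per-read provenance) and
#'   `variantTruth` (per-variant [S4Vectors::DataFrame]: `variant`,
#'   `preCount`, `postCount`, `w`, `preFreq`, `postFreq`, `eTrue`), plus
#'   `files` when `outdir` is given.
#' @export
simulateCsrRun <- function(library, fitness, cycles = 20L,
                           preDepth, postDepth, preFreq = NULL,
                           seed = 1L, outdir = NULL, ...) {
  stopifnot(is(library, "VariantLibrary"), preDepth > 0, postDepth > 0)
  labels <- variantLabels(library)
  if (length(labels) == 0L) stop("library must be enumerated")
  if (is.null(preFreq)) {
    preFreq <- rep(1 / length(labels), length(labels))
    names(preFreq) <- labels
  }
  set.seed(seed)
  preCounts <- as.integer(rmultinom(1L, preDepth, preFreq))
  names(preCounts) <- names(preFreq)
  postFreqExp <- expectedPostFrequencies(preFreq, fitness, cycles)
  postCounts <- as.integer(rmultinom(1L, postDepth, postFreqExp))
  names(postCounts) <- names(postFreqExp)

  r0 <- simulateReads(preCounts, library, round = "r0", ...)
  r1 <- simulateReads(postCounts, library, round = "r1", ...)

  w <- rep(0, length(labels)); names(w) <- labels
  hit <- intersect(names(fitness), labels)
  w[hit] <- fitness[hit]
  variantTruth <- S4Vectors::DataFrame(
    variant = labels,
    preCount = preCounts[labels],
    postCount = postCounts[labels],
    w = w,
    preFreq = preFreq[labels],
    postFreq = postFreqExp[labels],
    eTrue = log(postFreqExp[labels] / preFreq[labels])
  )

  out <- list(preCounts = preCounts, postCounts = postCounts,
              readsR0 = r0$reads, readsR1 = r1$reads,
              truthR0 = r0$truth, truthR1 = r1$truth,
              variantTruth = variantTruth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- list(
      r0 = file.path(outdir, "r0.fastq"),
      r1 = file.path(outdir, "r1.fastq"),
      variantTruth = file.path(outdir, "variant_truth.tsv"),
      truthR0 = file.path(outdir, "read_truth_r0.tsv"),
      truthR1 = file.path(outdir, "read_truth_r1.tsv"),
      config = file.path(outdir, "config.json")
    )
    writeSimFastq(r0$reads, f$r0)
    writeSimFastq(r1$reads, f$r1)
    write.table(as.data.frame(variantTruth), f$variantTruth, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(r0$truth), f$truthR0, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(r1$truth), f$truthR1, sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(cycles = cycles, preDepth = preDepth, postDepth = postDepth,
             seed = seed, codonScheme = library@codonScheme,
             targetedPositions = targetedPositions(library@reference)),
        f$config, auto_unbox = TRUE)
    }
    out$files <- f
  }
  out
}
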