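#' Reads required for a target sequencing coverage
#'
#' Coverage is defined as sequencing reads divided by the theoretical
#' protein library size (stop-codon variants excluded), so the read count
#' needed for coverage `C` is `ceiling(C * librarySize)` — e.g. 60x on a
#' 5-codon saturation library (3.2e6 variants) needs 1.92e8 reads.
#'
#' @param librarySize theoretical protein library size (or a
#'   [VariantLibrary-class]).
#' @param C coverage level(s), `> 0`.
#' @return Integer-valued numeric vector of read counts.
#' @export
readsForCoverage <- function(librarySize, C) {
  if (is(librarySize, "VariantLibrary"))
    librarySize <- theoreticalSize(librarySize)
  if (any(librarySize <= 0) || any(C <= 0))
    stop("library size and coverage must be positive")
  ceiling(C * librarySize)
}

#' Subsample reads to a target coverage
#'
#' Draws `readsForCoverage(librarySize, C)` reads, with replacement by
#' default (a without-replacement variant is available for sensitivity
#' checks and requires the draw not to exceed the input size).
#'
#' @param reads a [Biostrings::DNAStringSet] (or anything subsettable by
#'   integer index).
#' @param C coverage level.
#' @param librarySize theoretical protein library size.
#' @param seed optional integer seed.
#' @param replace sample with replacement (default TRUE).
#' @return The subsampled reads.
#' @export
subsampleReads <- function(reads, C, librarySize, seed = NULL,
                           replace = TRUE) {
  if (length(reads) == 0L) stop("no reads to subsample")
  if (!is.null(seed)) set.seed(seed)
  n <- readsForCoverage(librarySize, C)
  if (!replace && n > length(reads))
    stop("cannot draw ", n, " reads without replacement from ",
         length(reads))
  reads[sample.int(length(reads), n, replace = replace)]
}

#' Seeded subsampling detection trials over coverage pairs
#'
#' For each pre-/post-selection coverage pair, repeatedly subsamples the
#' two call sets, rebuilds the count table, reruns the enrichment
#' classification, and records which genotypes were detected as
#' significantly enriched in each trial. Genotype calls are computed once
#' on the full read sets and the trials subsample reads by index, which is
#' distribution-identical to re-calling the subsampled reads. Trial seeds
#' are derived from the master seed by a counter (`seed + trial index`),
#' so trials are independent and the whole grid is reproducible.
#'
#' @param callsR0,callsR1 full-coverage genotype call tables from
#'   [callGenotypes()].
#' @param librarySize theoretical protein library size.
#' @param coveragePairs data frame with columns `cr0` and `cr1`; balanced
#'   grids use `cr0 == cr1`, unbalanced grids enumerate a Cartesian
#'   product (see [coverageGrid()]).
#' @param nTrials trials per pair (default 10).
#' @param alpha significance level for the enrichment classification.
#' @param seed master integer seed.
#' @param replace sample reads with replacement (default TRUE).
#' @return A list of [CoverageTrialSet-class], one per coverage pair.
#' @export
detectionTrials <- function(callsR0, callsR1, librarySize, coveragePairs,
                            nTrials = 10L, alpha = 0.05, seed = 1L,
                            replace = TRUE) {
  stopifnot(all(c("cr0", "cr1") %in% names(coveragePairs)), nTrials >= 1)
  counter <- 0L
  lapply(seq_len(nrow(coveragePairs)), function(k) {
    cr0 <- coveragePairs$cr0[k]
    cr1 <- coveragePairs$cr1[k]
    n0 <- readsForCoverage(librarySize, cr0)
    n1 <- readsForCoverage(librarySize, cr1)
    detected <- vector("list", nTrials)
    for (i in seq_len(nTrials)) {
      counter <<- counter + 1L
      set.seed((seed + counter) %% .Machine$integer.max)
      i0 <- sample.int(nrow(callsR0), n0, replace = replace)
      i1 <- sample.int(nrow(callsR1), n1, replace = replace)
      tab <- tryCatch(
        buildCountTable(callsR0[i0, ], callsR1[i1, ]),
        error = function(e)
          stop("trial ", counter, " (pair ", k, "): ",
               conditionMessage(e)))
      detected[[i]] <- enrichedSet(tab, alpha = alpha)
    }
    genos <- sort(unique(unlist(detected)))
    det <- matrix(FALSE, nrow = length(genos), ncol = nTrials,
                  dimnames = list(genos, NULL))
    for (i in seq_len(nTrials)) det[detected[[i]], i] <- TRUE
    new("CoverageTrialSet", coverageR0 = cr0, coverageR1 = cr1,
        detections = det, nTrials = as.integer(nTrials))
  })
}

#' Balanced or full Cartesian coverage grids
#'
#' @param levels coverage levels (the conventional ladder is
#'   `c(0.1, 0.2, 0.5, 0.8, 1, 2, 5, 10, 20, 50, 60)`).
#' @param balanced if TRUE (default) pair each level with itself;
#'   otherwise enumerate the full `cr0` x `cr1` product.
#' @return A data frame with columns `cr0`, `cr1`.
#' @export
coverageGrid <- function(levels, balanced = TRUE) {
  if (balanced) data.frame(cr0 = levels, cr1 = levels)
  else expand.grid(cr0 = levels, cr1 = levels, KEEP.OUT.ATTRS = FALSE)
}

#' @describeIn CoverageTrialSet-class per-genotype detection probability
#'   `P = detections / trials` (exactly `k/N`).
#' @export
setMethod("detectionProbability", "CoverageTrialSet",
          function(x) rowMeans(x@detections))

setMethod("show", "CoverageTrialSet", function(object) {
  cat(sprintf("CoverageTrialSet: C_r0 = %g, C_r1 = %g, %d trials\n",
              object@coverageR0, object@coverageR1, object@nTrials))
  cat("  genotypes ever detected:", nrow(object@detections), "\n")
})

#' Detection and precision summary over coverage pairs
#'
#' For each trial set, the true-positive probability `TP` is the mean
#' detection probability over the truth-set genotypes (those significantly
#' enriched in the full-coverage analysis; undetected truth genotypes
#' contribute 0), the false-positive probability `FP` is the mean
#' detection probability over non-truth genotypes ever detected (0 when
#' none were), and precision is `TP / (TP + FP)` (`NA` when both are 0).
#'
#' @param trialSets list of [CoverageTrialSet-class] from
#'   [detectionTrials()].
#' @param truthSet character vector of genotypes enriched in the
#'   full-coverage analysis (see [enrichedSet()]).
#' @return A data frame: `cr0`, `cr1`, `TP`, `FP`, `precision`.
#' @export
precisionSummary <- function(trialSets, truthSet) {
  if (length(truthSet) == 0L) stop("truth set is empty")
  rows <- lapply(trialSets, function(ts) {
    P <- detectionProbability(ts)
    pv <- P[truthSet]
    pv[is.na(pv)] <- 0
    tp <- mean(pv)
    fpGenos <- setdiff(names(P), truthSet)
    fp <- if (length(fpGenos)) mean(P[fpGenos]) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    data.frame(cr0 = ts@coverageR0, cr1 = ts@coverageR1,
               TP = tp, FP = fp, precision = prec)
  })
  do.call(rbind, rows)
}
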