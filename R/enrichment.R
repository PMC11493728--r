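#' Per-variant enrichment score
#'
#' The natural-log ratio of a variant's post-selection to pre-selection
#' frequency, `E = ln((c1/N1) / (c0/N0))`. When either count is zero the
#' default policy adds 0.5 to both counts for the score only (raw counts
#' are kept for significance testing); a variant with both counts zero has
#' no defined score and is returned as `NA`.
#'
#' @param c0,c1 pre- and post-selection read counts.
#' @param N0,N1 total callable reads per round (positive).
#' @param zeroPolicy `"add-half"` (default) or `"none"` (zero counts give
#'   infinite scores).
#' @return Numeric vector of enrichment scores.
#' @examples
#' enrichmentScore(2, 100, 8, 100)  # log(4)
#' @export
enrichmentScore <- function(c0, N0, c1, N1,
                            zeroPolicy = c("add-half", "none")) {
  zeroPolicy <- match.arg(zeroPolicy)
  stopifnot(all(N0 > 0), all(N1 > 0))
  if (any(c0 < 0) || any(c1 < 0)) stop("counts must be non-negative")
  n <- max(length(c0), length(c1))
  c0 <- rep_len(c0, n); c1 <- rep_len(c1, n)
  N0 <- rep_len(N0, n); N1 <- rep_len(N1, n)
  a0 <- c0; a1 <- c1
  if (zeroPolicy == "add-half") {
    z <- (c0 == 0 | c1 == 0)
    a0[z] <- c0[z] + 0.5
    a1[z] <- c1[z] + 0.5
  }
  e <- log((a1 / N1) / (a0 / N0))
  e[c0 == 0 & c1 == 0] <- NA_real_
  e
}

#' Calibrate the total-read ratio from a reference record
#'
#' When only per-variant counts and one known enrichment score are
#' available (e.g. a published table row), the unknown total-read ratio
#' term `ln(N0/N1)` can be recovered from the reference record:
#' `offset = E_ref - ln(c1_ref/c0_ref)`. Any other variant's score in the
#' same selection is then `ln(c1/c0) + offset` (see
#' [calibratedEnrichment()]). The calibration is insensitive to whether
#' published totals counted rejected reads.
#'
#' @param c0Ref,c1Ref reference counts (positive).
#' @param eRef known enrichment score of the reference record.
#' @return The offset `ln(N0/N1)`.
#' @export
calibrateTotalRatio <- function(c0Ref, c1Ref, eRef) {
  stopifnot(c0Ref > 0, c1Ref > 0)
  eRef - log(c1Ref / c0Ref)
}

#' @rdname calibrateTotalRatio
#' @param c0,c1 counts of the variant(s) to score.
#' @param offset total-ratio offset from [calibrateTotalRatio()].
#' @export
calibratedEnrichment <- function(c0, c1, offset) {
  stopifnot(all(c0 > 0), all(c1 > 0))
  log(c1 / c0) + offset
}

# Core of the unconditional E-test for two Poisson means
# (Krishnamoorthy-Thomson style): the standardised difference of rates
# T = (c1/t1 - c0/t0) / sqrt(lambda_hat (1/t0 + 1/t1)), with lambda_hat
# the pooled rate (c0+c1)/(t0+t1), and p the probability under
# H0: rate0 = rate1 = lambda_hat of outcome pairs (y0, y1) at least as
# extreme as observed. The y1 tail is summed exactly via ppois; y0 is
# enumerated over mean +/- max(10*sqrt(mean), 50), leaving omitted tail
# mass below 1e-8.
.poissonETest1 <- function(c0, t0, c1, t1) {
  lam <- (c0 + c1) / (t0 + t1)
  if (lam == 0) return(1)
  se <- sqrt(lam * (1 / t0 + 1 / t1))
  tObs <- (c1 / t1 - c0 / t0) / se
  a <- abs(tObs)
  if (a < 1e-12) return(1)
  a <- a * (1 - 1e-10) # keep outcomes tied with the observed statistic
  m0 <- lam * t0
  m1 <- lam * t1
  half <- max(10 * sqrt(m0), 50)
  y0 <- seq.int(max(0, floor(m0 - half)), ceiling(m0 + half))
  w0 <- dpois(y0, m0)
  hi <- t1 * (y0 / t0 + a * se) # detect when T(y0, y1) >= |tObs|
  lo <- t1 * (y0 / t0 - a * se) # ... and when T(y0, y1) <= -|tObs|
  pHigh <- ppois(ceiling(hi) - 1, m1, lower.tail = FALSE)
  fl <- floor(lo)
  pLow <- ifelse(fl >= 0, ppois(fl, m1), 0)
  min(1, sum(w0 * pmin(pHigh + pLow, 1)))
}

#' E-test for the equality of two Poisson means
#'
#' Unconditional test of `H0: rate0 == rate1` for two Poisson counts with
#' exposures (here: per-variant read counts with total callable reads as
#' exposures). Two-sided; the null distribution is evaluated at the pooled
#' rate estimate and summed exactly over outcome pairs at least as extreme
#' as observed (tail truncation below 1e-8).
#'
#' @param c0,c1 observed counts (non-negative integers).
#' @param t0,t1 exposures (positive).
#' @return Two-sided p-value(s) in `(0, 1]`; vectorised over its
#'   arguments.
#' @examples
#' poissonETest(5, 100, 5, 100)   # 1
#' poissonETest(10, 1000, 20, 1000)
#' @export
poissonETest <- function(c0, t0, c1, t1) {
  if (any(t0 <= 0) || any(t1 <= 0)) stop("exposures must be positive")
  if (any(c0 < 0) || any(c1 < 0)) stop("counts must be non-negative")
  n <- max(length(c0), length(c1), length(t0), length(t1))
  c0 <- rep_len(c0, n); c1 <- rep_len(c1, n)
  t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
  vapply(seq_len(n),
         function(i) .poissonETest1(c0[i], t0[i], c1[i], t1[i]),
         numeric(1))
}

#' Classify variants as enriched, depleted or neutral
#'
#' Computes enrichment scores and E-test p-values for every genotype in a
#' count table and classifies each as `enriched` (`p < alpha`, `E > 0`),
#' `depleted` (`p < alpha`, `E < 0`) or `neutral`. Variants observed in
#' neither round are dropped. No multiple-testing correction is applied by
#' default; `bh = TRUE` adds Benjamini-Hochberg adjusted p-values and
#' classifies on those.
#'
#' @param x a [VariantCounts-class].
#' @param alpha two-sided significance level (default 0.05).
#' @param bh apply Benjamini-Hochberg correction (default FALSE).
#' @param minPostCount optional reporting filter: keep only variants with
#'   post-selection count above this value (applied after
#'   classification, never as part of it).
#' @param zeroPolicy passed to [enrichmentScore()].
#' @return A [S4Vectors::DataFrame] sorted by `E` descending (ties broken
#'   by post-selection count, then label) with columns `genotype`,
#'   `countR0`, `countR1`, `freqR0`, `freqR1`, `E`, `p` (and `padj` when
#'   `bh`), `class`.
#' @export
classifyVariants <- function(x, alpha = 0.05, bh = FALSE,
                             minPostCount = NULL,
                             zeroPolicy = c("add-half", "none")) {
  stopifnot(is(x, "VariantCounts"), alpha >= 0, alpha <= 1)
  m <- counts(x)
  tot <- roundTotals(x)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  e <- enrichmentScore(m[, "r0"], tot[["r0"]], m[, "r1"], tot[["r1"]],
                       zeroPolicy = match.arg(zeroPolicy))
  p <- poissonETest(m[, "r0"], tot[["r0"]], m[, "r1"], tot[["r1"]])
  pc <- if (bh) p.adjust(p, method = "BH") else p
  cls <- rep("neutral", nrow(m))
  cls[pc < alpha & e > 0] <- "enriched"
  cls[pc < alpha & e < 0] <- "depleted"
  res <- S4Vectors::DataFrame(
    genotype = rownames(m),
    countR0 = m[, "r0"], countR1 = m[, "r1"],
    freqR0 = m[, "r0"] / tot[["r0"]], freqR1 = m[, "r1"] / tot[["r1"]],
    E = e, p = p,
    class = factor(cls, levels = c("enriched", "depleted", "neutral")))
  if (bh) res$padj <- pc
  o <- order(-res$E, -res$countR1, res$genotype)
  res <- res[o, ]
  rownames(res) <- NULL
  if (!is.null(minPostCount)) res <- res[res$countR1 > minPostCount, ]
  res
}

#' Genotypes classified as significantly enriched
#'
#' @inheritParams classifyVariants
#' @param ... passed to [classifyVariants()].
#' @return Character vector of genotype labels.
#' @export
enrichedSet <- function(x, alpha = 0.05, ...) {
  res <- classifyVariants(x, alpha = alpha, ...)
  as.character(res$genotype[res$class == "enriched"])
}
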