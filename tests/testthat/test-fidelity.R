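test_that("global alignment handles identity and single indels", {
  a <- alignToReference("ACGTACGTA", "ACGTACGTA")
  expect_equal(a$score, 9)
  expect_false(grepl("-", a$ref) || grepl("-", a$read))

  # one internal base deleted: exactly one 1-bp deletion column
  a2 <- alignToReference("ACGTCGTA", "ACGTACGTA")
  t2 <- tallyErrors(a2)
  expect_equal(t2$deletions, 1)
  expect_equal(t2$substitutions, 0)
  expect_equal(t2$insertions, 0)
  expect_error(alignToReference("", "ACGT"), "empty")
})

test_that("alignment scores agree with an independent aligner", {
  # Biostrings::pairwiseAlignment with gapOpening 1 + gapExtension 1
  # reproduces this package's affine cost 2 + (g - 1) for a g-bp gap
  sub <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(sub) <- 1
  set.seed(11)
  ref <- as.character(refSequence(syntheticAmplicon(80, seed = 11)))
  for (i in 1:25) {
    rd <- randomMutate(ref, nSub = sample(0:6, 1), nDel = sample(0:2, 1),
                       nIns = sample(0:2, 1))
    ours <- alignToReference(rd, ref)$score
    pa <- Biostrings::pairwiseAlignment(rd, ref, type = "global",
                                        substitutionMatrix = sub,
                                        gapOpening = 1, gapExtension = 1)
    expect_equal(ours, Biostrings::score(pa))
  }
})

test_that("edit-operation tallies match the dynamic-programming oracle", {
  set.seed(23)
  ref <- as.character(refSequence(syntheticAmplicon(80, seed = 23)))
  for (i in 1:40) {
    rd <- randomMutate(ref, nSub = sample(0:5, 1), nDel = sample(0:2, 1),
                       nIns = sample(0:2, 1))
    aln <- alignToReference(rd, ref)
    tal <- tallyErrors(aln)
    orc <- oracleAlign(rd, ref)
    expect_equal(aln$score, orc$score)
    expect_equal(tal$substitutions, orc$nSub)
    expect_equal(tal$deletions, orc$delBases)
    expect_equal(tal$insertions, orc$insBases)
    # conservation: aligned ref columns = matches + subs + deletions
    expect_equal(tal$basesAnalyzed, nchar(ref))
  }
})

test_that("error tallies implement the per-base and frameshift definitions", {
  ref <- as.character(refSequence(syntheticAmplicon(102, seed = 2)))
  rd <- ref
  substr(rd, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(ref, 50, 50))[1]
  t1 <- tallyErrors(alignToReference(rd, ref))
  expect_equal(t1$substitutions / t1$basesAnalyzed, 1 / 102)
  expect_false(t1$frameshift)

  del2 <- paste0(substr(ref, 1, 30), substr(ref, 33, 102))
  t2 <- tallyErrors(alignToReference(del2, ref))
  expect_equal(t2$deletions, 2)
  expect_true(t2$frameshift)

  del3 <- paste0(substr(ref, 1, 30), substr(ref, 34, 102))
  t3 <- tallyErrors(alignToReference(del3, ref))
  expect_equal(t3$deletions, 3)
  expect_false(t3$frameshift)
})

test_that("profiles aggregate additively and self-correct to zero", {
  st <- studySimulation()
  prof0 <- aggregateProfile(st$calls0)
  expect_equal(prof0@rateTotal, prof0@rateDel + prof0@rateIns +
                 prof0@rateSub)
  self <- aggregateProfile(st$calls0, baseline = prof0)
  expect_equal(self@correctedTotal, 0)
  expect_equal(self@fold, 1)

  prof1 <- aggregateProfile(st$calls1, baseline = prof0)
  expect_gt(prof1@correctedTotal, 0)
  expect_equal(prof1@correctedTotal, prof1@rateTotal - prof0@rateTotal)
  expect_equal(prof1@fold, round(prof1@rateTotal / prof0@rateTotal))
  expect_true(prof1@frameshiftFreq >= 0 && prof1@frameshiftFreq <= 1)

  # frameshifted reads are excluded from rates but counted in the
  # frameshift frequency
  fs <- st$calls1$frameshift
  keep <- !fs
  expect_equal(prof1@totalBases, sum(st$calls1$basesAnalyzed[keep]))
  expect_equal(prof1@frameshiftFreq, mean(fs))
})

test_that("per-genotype error rates recover the simulator truth", {
  ref <- testReference(len = 150, positions = c(20L, 21L), seed = 5)
  lib <- buildLibrary(ref)
  labs <- variantLabels(lib)
  counts <- stats::setNames(c(500L, 500L), labs[c(3, 9)])
  out <- simulateReads(counts, lib, round = "r1",
                       polSub = c(stats::setNames(c(1e-3, 1e-2),
                                                  labs[c(3, 9)])),
                       polDel = 0, polIns = 0,
                       seqSub = 0, seqDel = 0, seqIns = 0, seed = 14)
  calls <- callGenotypes(out$reads, ref)
  rates <- mutantErrorRates(calls)
  for (k in c(1, 2)) {
    v <- labs[c(3, 9)][k]
    true <- c(1e-3, 1e-2)[k]
    bases <- rates[[v]]@totalBases
    se <- sqrt(true * (1 - true) / bases)
    expect_lt(abs(rates[[v]]@rateSub - true), 3 * se + true * 0.15)
  }
  # conservation: per-genotype bases sum to the library-level total
  # (over the same, callable, read set)
  tot <- aggregateProfile(calls[!calls$rejected, ])
  expect_equal(sum(vapply(rates, function(p) p@totalBases, numeric(1))),
               tot@totalBases)

  # all-WT, error-free reads give all-zero rates
  wtReads <- simulateReads(stats::setNames(50L, "WT"), lib, round = "r0",
                           seqSub = 0, seqDel = 0, seqIns = 0, seed = 3)
  wtCalls <- callGenotypes(wtReads$reads, ref)
  wtProf <- mutantErrorRates(wtCalls)[["WT"]]
  expect_equal(wtProf@rateTotal, 0)
})

test_that("substitution spectra recover the transition bias", {
  ref <- testReference(len = 150, positions = c(20L, 21L), seed = 5)
  lib <- buildLibrary(ref)
  # pure C->T events injected by hand: transversion rate must be zero
  wt <- csrseq:::.variantSequences(lib)[["WT"]]
  cpos <- which(strsplit(wt, "")[[1]] == "C")
  cpos <- setdiff(cpos, 58:63) # keep clear of the codon windows
  rd <- wt
  for (p in cpos[1:3]) substr(rd, p, p) <- "T"
  calls <- callGenotypes(rd, ref)
  spec <- substitutionSpectrum(calls, ref)
  expect_equal(spec$counts["C", "T"], 3)
  expect_equal(spec$tvRate, 0)
  expect_equal(sum(spec$counts), sum(calls$nSub))

  # simulator transition:transversion weight 2 is recovered
  counts <- stats::setNames(rep(10L, 400), variantLabels(lib))
  out <- simulateReads(counts, lib, round = "r0", seqSub = 0.02,
                       seqDel = 0, seqIns = 0, tsBias = 2, seed = 15)
  calls2 <- callGenotypes(out$reads, ref)
  spec2 <- substitutionSpectrum(calls2, ref)
  nEv <- sum(spec2$counts)
  pHat <- spec2$tsRate / (spec2$tsRate + spec2$tvRate)
  se <- sqrt(pHat * (1 - pHat) / nEv)
  expect_lt(abs(pHat - 2 / 3), 3 * se)
  # row sums over the off-diagonal equal the per-base substitution counts
  expect_equal(sum(spec2$counts), sum(calls2$nSub[!calls2$frameshift]))
})
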