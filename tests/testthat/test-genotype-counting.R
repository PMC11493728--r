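test_that("FASTQ loading preserves order, count, and gzip transparency", {
  ref <- testReference()
  lib <- buildLibrary(ref)
  counts <- stats::setNames(c(1L, 1L, 1L), variantLabels(lib)[1:3])
  reads <- simulateReads(counts, lib, seed = 1, shuffle = FALSE,
                         polSub = 0, polDel = 0, polIns = 0,
                         seqSub = 0, seqDel = 0, seqIns = 0)$reads
  f <- tempfile(fileext = ".fastq")
  fgz <- tempfile(fileext = ".fastq.gz")
  writeSimFastq(reads, f)
  writeSimFastq(reads, fgz)
  expect_equal(length(loadReads(f)), 3)
  expect_identical(as.character(loadReads(f)), as.character(reads))
  expect_identical(as.character(loadReads(f)), as.character(loadReads(fgz)))
  expect_error(loadReads(tempfile()), "no such file")
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_length(loadReads(empty), 0)
})

test_that("genotype calls recover constructed variants and rejections", {
  ref <- testReference()
  wt <- as.character(refSequence(ref))
  w <- codonWindows(ref)
  s1 <- IRanges::start(w)[1]; e1 <- IRanges::end(w)[1]
  s2 <- IRanges::start(w)[2]; e2 <- IRanges::end(w)[2]
  wtAA <- wtAminoAcids(ref)

  phe <- wt; substr(phe, s1, e1) <- "TTT"          # codon 10 -> Phe
  stopRead <- wt; substr(stopRead, s2, e2) <- "TAA" # stop at codon 11
  ambig <- wt; substr(ambig, s1, s1) <- "N"
  delInWin <- paste0(substr(wt, 1, s2), substr(wt, s2 + 2, nchar(wt)))
  junk <- paste(rep("A", nchar(wt)), collapse = "")

  calls <- callGenotypes(c(wt, phe, stopRead, ambig, delInWin, junk), ref)
  expect_identical(calls$genotype[1], "WT")
  expect_identical(calls$genotype[2], paste0(wtAA[1], "-10-F"))
  expect_identical(as.character(calls$reason[3]), "stop-codon")
  expect_identical(as.character(calls$reason[4]), "ambiguous-base")
  expect_identical(as.character(calls$reason[5]), "indel-in-window")
  expect_identical(as.character(calls$reason[6]), "alignment-fail")
  expect_true(all(xor(is.na(calls$genotype), !calls$rejected)))

  # reverse-complement retry recovers opposite-strand reads
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(phe)))
  rcCall <- callGenotypes(rc, ref)
  expect_identical(rcCall$genotype[1], paste0(wtAA[1], "-10-F"))
  expect_identical(as.character(callGenotypes(rc, ref,
                                              revcompRetry = FALSE)$reason[1]),
                   "alignment-fail")
})

test_that("coding changes outside the windows do not affect the call", {
  ref <- testReference()
  wt <- as.character(refSequence(ref))
  mutated <- wt
  substr(mutated, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                   substr(wt, 4, 4))[1]
  calls <- callGenotypes(mutated, ref)
  expect_identical(calls$genotype[1], "WT")
  expect_equal(calls$nSub[1], 1)
})

test_that("count tables satisfy the frequency identities", {
  ref <- testReference()
  wt <- as.character(refSequence(ref))
  w <- codonWindows(ref)
  varA <- wt; substr(varA, IRanges::start(w)[1], IRanges::end(w)[1]) <- "TTT"
  callsR0 <- callGenotypes(c(wt, wt, varA), ref)
  callsR1 <- callGenotypes(c(varA, varA, varA), ref)
  tab <- buildCountTable(callsR0, callsR1)
  fr <- variantFrequencies(tab)
  lab <- paste0(wtAminoAcids(ref)[1], "-10-F")
  expect_equal(fr[lab, "r0"], 1 / 3)
  expect_equal(fr[lab, "r1"], 1)
  expect_equal(unname(colSums(fr)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(roundTotals(tab)), c(3, 3))

  # identical call sets give identical frequency vectors
  tab2 <- buildCountTable(callsR0, callsR0)
  fr2 <- variantFrequencies(tab2)
  expect_identical(fr2[, "r0"], fr2[, "r1"])
  expect_error(buildCountTable(callsR0[0, ], callsR1), "r0")
})

test_that("error-free simulated reads reproduce the truth table exactly", {
  ref <- testReference()
  lib <- buildLibrary(ref)
  labs <- variantLabels(lib)
  fit <- stats::setNames(rep(0, 400), labs)
  fit[labs[5:8]] <- 1
  sim <- simulateCsrRun(lib, fit, cycles = 8, preDepth = 3000,
                        postDepth = 3000, seed = 5,
                        polSub = 0, polDel = 0, polIns = 0,
                        seqSub = 0, seqDel = 0, seqIns = 0)
  calls0 <- callGenotypes(sim$readsR0, ref)
  calls1 <- callGenotypes(sim$readsR1, ref)
  expect_equal(sum(calls0$rejected), 0)
  expect_equal(sum(calls1$rejected), 0)
  tab <- buildCountTable(calls0, calls1)
  tr <- sim$variantTruth
  tr <- tr[tr$preCount + tr$postCount > 0, ]
  m <- counts(tab)
  expect_setequal(rownames(m), tr$variant)
  expect_equal(m[tr$variant, "r0"], stats::setNames(tr$preCount, tr$variant))
  expect_equal(m[tr$variant, "r1"], stats::setNames(tr$postCount, tr$variant))
})

test_that("callable and rejected reads partition every round", {
  st <- studySimulation()
  for (calls in list(st$calls0, st$calls1)) {
    expect_equal(sum(!calls$rejected) + sum(calls$rejected), nrow(calls))
    expect_true(all(is.na(calls$genotype[calls$rejected])))
  }
  tab <- buildCountTable(st$calls0, st$calls1)
  fr <- variantFrequencies(tab)
  expect_equal(unname(colSums(fr)), c(1, 1), tolerance = 1e-12)
})
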