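test_that("exponential selection model has the expected closed forms", {
  pre <- c(A = 0.5, B = 0.5)
  # equal fitness leaves frequencies unchanged
  expect_equal(expectedPostFrequencies(pre, c(A = 1, B = 1), cycles = 7),
               pre)
  # one cycle, w = (1, 0): frequency ratio (1+1)/(1+0) = 2
  post <- expectedPostFrequencies(pre, c(A = 1, B = 0), cycles = 1)
  expect_equal(unname(post), c(2 / 3, 1 / 3))
  expect_equal(sum(post), 1)
  expect_error(expectedPostFrequencies(c(A = 0.4, B = 0.4), c(A = 1)),
               "sum to 1")
  expect_error(expectedPostFrequencies(pre, c(A = -1, B = 0)),
               "non-negative")
})

test_that("selection sampling conserves depth and is seed-reproducible", {
  pre <- stats::setNames(rep(1 / 50, 50), paste0("v", 1:50))
  fit <- stats::setNames(runif(50), names(pre))
  c1 <- simulateSelection(pre, fit, cycles = 5, depth = 12345, seed = 4)
  c2 <- simulateSelection(pre, fit, cycles = 5, depth = 12345, seed = 4)
  expect_identical(c1, c2)
  expect_equal(sum(c1), 12345)
  expect_error(simulateSelection(pre, fit, depth = 0), "depth > 0")
})

test_that("realized log frequency ratios match E_true within 3 SE", {
  # 400-variant library, 10 designated winners, 20 cycles, depth 1e5,
  # averaged over 10 seeds (count-level check against the closed form)
  labs <- paste0("v", 1:400)
  pre <- stats::setNames(rep(1 / 400, 400), labs)
  winners <- labs[1:10]
  fit <- stats::setNames(rep(0, 400), labs)
  fit[winners] <- 0.25
  eTrue <- trueEnrichment(pre, fit, cycles = 20)
  post <- expectedPostFrequencies(pre, fit, cycles = 20)
  depth <- 1e5
  for (v in c(winners[1], winners[5], "v200")) {
    realized <- vapply(1:10, function(s) {
      cts <- simulateSelection(pre, fit, cycles = 20, depth = depth,
                               seed = s)
      log((cts[v] / depth) / pre[v])
    }, numeric(1))
    # binomial SE of the log post-frequency at this depth
    se <- sqrt((1 - post[v]) / (post[v] * depth))
    expect_lt(abs(mean(realized) - eTrue[v]), 3 * se / sqrt(10) + 1e-3)
  }
})

test_that("read emission is exact with all error rates zero", {
  ref <- testReference()
  lib <- buildLibrary(ref)
  counts <- stats::setNames(rep(3L, 5), variantLabels(lib)[21:25])
  out <- simulateReads(counts, lib, round = "r1",
                       polSub = 0, polDel = 0, polIns = 0,
                       seqSub = 0, seqDel = 0, seqIns = 0, seed = 2)
  expect_equal(length(out$reads), 15)
  seqs <- csrseq:::.variantSequences(lib)
  expect_identical(as.character(unname(out$reads)),
                   unname(seqs[out$truth$variant]))
  expect_true(all(out$truth$nSub == 0 & out$truth$nDelBases == 0 &
                  out$truth$nInsBases == 0))
  # emitted read count equals requested depth exactly
  expect_equal(as.vector(table(out$truth$variant)), rep(3L, 5))
})

test_that("fixed seeds give byte-identical FASTQ output", {
  ref <- testReference()
  lib <- buildLibrary(ref)
  counts <- stats::setNames(rep(10L, 10), variantLabels(lib)[1:10])
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  writeSimFastq(simulateReads(counts, lib, seed = 9)$reads, f1)
  writeSimFastq(simulateReads(counts, lib, seed = 9)$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  r3 <- simulateReads(counts, lib, seed = 10)$reads
  expect_false(identical(as.character(r3),
                         as.character(simulateReads(counts, lib,
                                                    seed = 9)$reads)))
})

test_that("realized error rates converge to configured rates", {
  ref <- testReference(len = 150, positions = c(20L, 21L), seed = 5)
  lib <- buildLibrary(ref)
  counts <- stats::setNames(rep(20L, 334), variantLabels(lib)[1:334])
  out <- simulateReads(counts, lib, round = "r0",
                       seqSub = 1e-3, seqDel = 0, seqIns = 0, seed = 6)
  totalBases <- sum(nchar(as.character(out$reads)))
  expect_gt(totalBases, 9.9e5)
  nSub <- sum(out$truth$nSub)
  expected <- 1e-3 * 150 * length(out$reads)
  se <- sqrt(expected * (1 - 1e-3))
  expect_lt(abs(nSub - expected), 3 * se)
})

test_that("a 1% two-bp deletion rate yields ~1% frameshift frequency", {
  ref <- testReference(len = 150, positions = c(20L, 21L), seed = 5)
  lib <- buildLibrary(ref)
  counts <- stats::setNames(rep(25L, 400), variantLabels(lib))
  L <- 150
  delRate <- 2 * 0.01 / L # one 2-bp deletion event per 100 reads
  out <- simulateReads(counts, lib, round = "r0",
                       seqSub = 0, seqDel = delRate, seqIns = 0,
                       delLenProbs = c("2" = 1), seed = 8)
  n <- length(out$reads)
  fsTruth <- mean(out$truth$frameshift)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(fsTruth - 0.01), 3 * se + 2e-4)
  # the downstream profile recovers the same frameshift frequency
  calls <- callGenotypes(out$reads, ref)
  prof <- aggregateProfile(calls)
  expect_equal(prof@frameshiftFreq, fsTruth, tolerance = 0.1)
})

test_that("a complete simulated run carries consistent ground truth", {
  ref <- testReference()
  lib <- buildLibrary(ref)
  labs <- variantLabels(lib)
  fit <- stats::setNames(rep(0, 400), labs)
  fit[labs[1:4]] <- 0.5
  sim <- simulateCsrRun(lib, fit, cycles = 10, preDepth = 4000,
                        postDepth = 4000, seed = 21)
  expect_equal(sum(sim$preCounts), 4000)
  expect_equal(sum(sim$postCounts), 4000)
  tr <- sim$variantTruth
  expect_equal(sum(tr$preFreq), 1)
  expect_equal(sum(tr$postFreq), 1)
  expect_equal(tr$eTrue, log(tr$postFreq / tr$preFreq))
  expect_equal(length(sim$readsR0), 4000)
  expect_identical(nrow(sim$truthR1), 4000L)
})
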