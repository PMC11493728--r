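# Shared fixtures, built in code. The "study" simulation reproduces the
# desk-scale CSR selection used by the end-to-end checks: a 400-variant
# 2-codon saturation library on a 150 bp synthetic amplicon, 10 designated
# winners at per-cycle amplification w = 0.25 (~87-fold over 20 cycles, a
# moderately stringent selection that leaves the background measurable
# post-selection), 1e5 reads per round, default error model. It is
# expensive, so it is computed lazily and cached for the session.

.fixtureEnv <- new.env(parent = emptyenv())

testReference <- function(len = 90L, positions = c(10L, 11L), seed = 7L) {
  AmpliconReference(refSequence(syntheticAmplicon(len, seed = seed)),
                    targetedPositions = positions)
}

studyReference <- function() {
  AmpliconReference(refSequence(syntheticAmplicon(150, seed = 42)),
                    targetedPositions = c(20L, 21L))
}

studySimulation <- function() {
  if (!is.null(.fixtureEnv$study)) return(.fixtureEnv$study)
  ref <- studyReference()
  lib <- buildLibrary(ref)
  labs <- variantLabels(lib)
  winners <- labs[seq(1, 400, by = 40)][1:10]
  fitness <- stats::setNames(rep(0, 400), labs)
  fitness[winners] <- 0.25
  sim <- simulateCsrRun(lib, fitness, cycles = 20L,
                        preDepth = 1e5, postDepth = 1e5, seed = 11L)
  calls0 <- callGenotypes(sim$readsR0, ref)
  calls1 <- callGenotypes(sim$readsR1, ref)
  .fixtureEnv$study <- list(ref = ref, lib = lib, winners = winners,
                            fitness = fitness, sim = sim,
                            calls0 = calls0, calls1 = calls1)
  .fixtureEnv$study
}
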