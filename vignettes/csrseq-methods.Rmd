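---
title: "Analysing CSR selection outputs: models, parameters, and design choices"
author: "csrseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing CSR selection outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Compartmentalized self-replication (CSR) selects polymerase variants by
letting each variant amplify its own encoding gene inside a water-in-oil
compartment: activity maps to copy number. Deep sequencing of the library
before (r0) and after (r1) selection turns the experiment into a counting
problem — which genotypes rose in frequency, by how much, and with what
statistical support — plus two companion questions: what error spectrum did
each variant's polymerase leave on its own gene, and how much sequencing is
actually needed to call the winners reliably. `csrseq` implements that
analysis pipeline end to end, together with a seeded simulator that
generates saturation-mutagenesis libraries, selection rounds and noisy
amplicon reads with full ground truth, so that every stage can be tested
without external data.

# Genotype calling

Reads are aligned globally to the wild-type amplicon (Needleman–Wunsch with
affine gaps; match +1, mismatch −1, gap open −2, gap extend −1; ties broken
deterministically: mismatch over gap, deletion over insertion, gaps closed
as early as possible). Genotypes are read off the targeted codon windows
after alignment, not by fixed-offset slicing, so indels upstream of a
window do not shift it.

One subtlety matters here. At the targeted codons the *library* reference
is degenerate (any NNK codon), not the wild-type bases, so window positions
are scored as wildcards during read analysis. Without this, the 3–6
clustered mismatches of a legitimate variant codon attract spurious gapped
alignments, and a large fraction of perfectly good reads is rejected. A
consequence of wildcard windows is that gap placement near a window becomes
score-ambiguous; the `indel-in-window` rejection therefore flags not only
gaps inside a window but any gap that can slide into one through
score-neutral steps. Rejections (`indel-in-window`, `ambiguous-base`,
`stop-codon`, `alignment-fail`) are data, not errors; callable and rejected
reads always partition the input, and frequencies are computed over
callable reads only, so they sum to one per round — the published analyses
do not state their denominator, and this choice keeps the frequency vector
a probability distribution.

The standalone `alignToReference()`/`tallyErrors()` pair keeps the exact
fixed scoring with no wildcards; the test suite holds it to tally-level
agreement with an independent dynamic-programming implementation.

# Enrichment and the E-test

The enrichment score of mutant *m* is the natural-log frequency ratio

$$E_m = \ln\frac{\mathrm{Freq}_{m,r1}}{\mathrm{Freq}_{m,r0}}.$$

When one count is zero, 0.5 is added to both counts *for the score only*;
the significance test always sees raw counts, and variants absent from both
rounds are dropped. Note the add-half policy is deliberately not
scale-invariant, unlike the raw-count score.

Significance comes from an unconditional E-test for two Poisson means
(Krishnamoorthy–Thomson style): with exposures $t_0, t_1$ (callable reads
per round) and pooled rate $\hat\lambda = (c_0+c_1)/(t_0+t_1)$, the
statistic is

$$T = \frac{c_1/t_1 - c_0/t_0}{\sqrt{\hat\lambda\,(1/t_0 + 1/t_1)}},$$

and the two-sided p-value sums the null probability of all outcome pairs
$(y_0, y_1)$ with $|T(y_0,y_1)| \ge |T(c_0,c_1)|$ under independent
Poissons at the pooled rate. Numerically, $y_0$ is enumerated over its mean
± max(10·√mean, 50) — omitted tail mass < 1e−8 — while the $y_1$ tail is
summed in closed form through `ppois()`, so the test stays exact and fast
even at counts in the tens of thousands. Outcomes tied with the observed
statistic are included (a relative 1e−10 shrink of the threshold).
Antisymmetry under swapping rounds holds to the truncation level, not to
machine epsilon. At small expected counts the discrete test is
conservative: at rate 0.01 and exposures 1000 its empirical size at
α = 0.05 is ≈ 0.038.

Classification is `enriched` (p < α and E > 0), `depleted` (p < α and
E < 0), else `neutral`, with α = 0.05 two-sided by default and no
multiple-testing correction — the published workflow applies none — with an
optional Benjamini–Hochberg flag, and an optional post-hoc reporting filter
on post-selection counts (e.g. > 1000) that never feeds back into
classification.

When only a published count table is available, the unknown total-read
ratio ln(N0/N1) of a selection is recovered from any row with a known
score: `calibrateTotalRatio()` returns
`offset = E_ref − ln(c1_ref/c0_ref)`, and every other score in the same
selection is `ln(c1/c0) + offset`. This calibration is insensitive to
whether the published totals counted rejected reads.

# Fidelity profiling

Errors are tallied per read from the same alignments used for genotype
calling: mismatch columns are substitutions (accumulated in a 4×4
reference-by-read base matrix), gap-in-read columns are deletion bases,
gap-in-reference columns insertion bases; a k-bp gap contributes k bases
because rates are per base. The targeted codon windows are excluded from
error counting and from the bases analysed at *both* the per-mutant and the
library level — a variant's defining codons are not errors, and the
exclusion makes library-level rates exactly the read-weighted average of
per-genotype rates.

A read is a *frameshift* when the summed indel lengths inside the coding
region are not a multiple of 3 (by this definition a compensating 1-bp
insertion plus 1-bp deletion still counts; such reads are rare and the rule
is applied identically in the simulator truth). Frameshifted reads are
excluded from rate aggregation but counted in the frameshift frequency
(frameshifted reads over all reads analysed).

With a baseline profile — conventionally the pre-selection round, which
carries the shared PCR/sequencing noise — the corrected total is
`rate_total − baseline_total` and the fold is
`round(rate_total / baseline_total)`. The fold convention uses the
*uncorrected* total in the numerator; that convention reproduces the
published fold values, whereas corrected/baseline does not, but it remains
an inference since no published definition exists. Transitions are A↔G and
C↔T; the spectrum normalises each substitution cell by its reference-base
opportunity.

# Sequencing-coverage analysis

Coverage is defined as sequencing reads divided by the theoretical protein
library size (stops excluded): C = reads / 20^k. Thus 60× on a 5-codon
library (3.2 × 10⁶ variants) needs 1.92 × 10⁸ reads. `detectionTrials()`
subsamples the full read sets with replacement at each coverage pair
(conventional ladder 0.1–60×), reruns counting and classification per
trial, and records binary detection outcomes; the detection probability of
a mutant is its detection count over N trials (N = 10 by default). Genotype
calls are computed once on the full read sets and trials subsample read
indices — distribution-identical to re-calling each subsample, and orders
of magnitude cheaper. Trial seeds derive from a master seed by a counter
(`seed + trial index`), so the entire grid is reproducible.

Against the truth set (the enriched calls of the full-coverage analysis),
TP is the mean detection probability over truth mutants, FP the mean over
non-truth mutants ever detected, and precision TP/(TP+FP); with no
detections at all, precision is undefined and flagged. A
without-replacement switch exists for sensitivity checks; with it, the full
dataset as its own subsample reproduces the truth set exactly (TP = 1,
FP = 0).

# DoE factor importance

Selection-yield responses are background-corrected by negative-control
reactions — division for gel densitometry, subtraction (clamped at zero)
for spectrophotometric readings — then min–max scaled to 0–100%. Designs
are expanded to a model matrix with continuous factors standardised before
expansion, categoricals one-hot encoded against a declared reference level
(the natural-dNTP chemistry, listed first, is the reference for nucleotide
chemistry), all pairwise products for interactions and squares of
continuous factors for quadratic terms; constant columns are dropped with a
warning.

Importance uses repeated cross-validated Lasso (`glmnet`): each of 100
repeats reshuffles the fold assignment (5-fold by default), picks λ at
minimum CV error on a 100-point log-spaced grid, and records coefficients;
mean and mean-absolute coefficients over repeats are the importance scores.
The CV fold count and λ grid are not stated in the published protocol and
are declared defaults here. Metrics (R², MSE, MAE, AIC, BIC) are computed
on the full fit by default, matching the single-dataset setting (a held-out
option exists); AIC/BIC use the Gaussian log-likelihood up to constants
with the number of nonzero coefficients as effective degrees of freedom —
the standard Lasso df estimate, stated explicitly because the published
metrics come without a definition. A constant response returns all-zero
coefficients (with undefined R²) rather than an error. Boruta is a
published wrapper method and is not reimplemented; nothing in the pipeline
depends on it.

# The simulator and the study design

The generator needs a selection model the source experiments never
quantify, so it uses the simplest one that reproduces the log-linear
enrichment the analysis assumes: deterministic exponential amplification —
after c cycles variant m holds weight pre_m(1+w_m)^c — followed by
multinomial read sampling at the requested depth. Compartment occupancy,
emulsion physics and chemistry are deliberately out of scope. Reads are
full-length amplicons carrying the variant's codons (the scheme's canonical
codon per residue), mutated by a per-variant polymerase error model
(post-selection reads only) plus baseline noise on all reads; frameshifted
reads are emitted, not suppressed; FASTQ output is Phred+33 with constant
quality "I".

Defaults are anchored to the observed study conditions: baseline per-base
rates substitution 5.60e−4, deletion 2.20e−4, insertion 9.69e−6 (total
≈ 7.9e−4, the pre-selection round of the deep-sequenced 2-codon library);
per-variant polymerase substitution 7.4e−3 with deletions 2e−4 and
insertions 8e−5, matching corrected error rates of selected
exonuclease-deficient KOD variants; 20 selection cycles; a
transition:transversion weight of 2 (a substitution is a transition with
probability 2/3, giving a 2:1 rate ratio); indel event lengths default to
1 bp. The default synthetic reference amplicon is 664 bp, the length of the
real selection amplicon.

The end-to-end checks in the test suite run a desk-scale study: a 150 bp
synthetic amplicon (seed 42) with two targeted codons, the full 400-variant
library at uniform input, 10 designated winners, 20 cycles, and 10⁵ reads
per round — sizes chosen so the whole study simulates, genotypes and
classifies in about a minute. The winners' per-cycle fitness is w = 0.25
(≈ 87-fold amplification over 20 cycles). That value is a deliberate design
choice made by power analysis before the tests were frozen: with very
strong winners (w = 1) the background is driven to ~10⁻⁷ post-selection
frequency, its true log-enrichment (≈ −10) becomes unmeasurable at 10⁵
reads, and the truth–estimate correlation is capped by the zero-count floor
and by phantom single-codon neighbours that read errors create on dominant
winner reads; with w = 0.25 the background remains measurable (winners
≈ 4% of the post pool each, background ≈ 0.08%), estimates track truth
(Pearson r ≈ 0.965), winners separate cleanly (zero false positives at
full depth), and the coverage analysis still shows the expected behaviour —
detection probability non-decreasing in coverage, and unbalanced designs
(high pre-, sparse post-coverage) losing precision through sparse-count
false positives exactly as low-coverage theory predicts.

What passing these tests shows — and what it does not. The simulator
emulates selection-driven amplification, per-variant error spectra and
multinomial sampling noise; it does not emulate PCR jackpotting and
amplification bias, compartment-occupancy statistics, chimeric reads,
quality-score structure, or batch effects between sequencing runs. Results
on real data additionally depend on upstream read merging and filtering,
which are assumed done.

# Numerical choices and degenerate inputs

* E-test: y₀ truncation mean ± max(10√mean, 50); ties included via a
  relative 1e−10 threshold shrink; p capped at 1; both counts zero → p = 1.
* Enrichment: both counts zero → `NA`, dropped by classification; ordering
  is E descending with ties broken by post-selection count then label.
* Alignment: equal-length reads with ≤ 2 non-window mismatches take a
  gap-free fast path that is provably optimal under the fixed scoring (a
  gapped alignment of equal-length sequences scores at most L − 5).
* Coverage: draw counts are `ceiling(C × library size)`; detection
  probabilities are exact multiples of 1/N.
* Lasso: zero-variance response short-circuits to zero coefficients;
  reshuffled folds make repeats independent; everything is reproducible
  from one seed.

# Known limitations

The per-mutant fidelity attribution assumes each read's errors come from
its called genotype's polymerase, which inherits any miscalls; the
published workflow shares this assumption. The exponential selection model
has no carrying capacity, so very long selections exaggerate winner
dominance. The calibrated-offset route reproduces published scores only up
to the rounding of the calibrating row. Boruta-based cross-validation of
factor importance is intentionally not bundled.
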