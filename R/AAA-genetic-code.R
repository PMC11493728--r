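## standard genetic code helpers (loaded first)

.GENETIC_CODE <- Biostrings::GENETIC_CODE

.AA20 <- sort(setdiff(unique(.GENETIC_CODE), "*"))

.translateCodons <- function(codons) {
  aa <- unname(.GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # ambiguous / non-ACGT codon
  aa
}
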