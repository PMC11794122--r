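# Shared fixtures built in code.

table1 <- assayOligos()
table1_seqs <- setNames(as.character(table1), names(table1))

# Random ACGT string of length n under the current RNG stream.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small labeled population with fully specified conjugate counts.
manualLabeled <- function(bound_1, bound_2, dna_per = 3) {
  S4Vectors::DataFrame(is_tumor = rep(TRUE, length(bound_1)),
                       antigen_copies = bound_1 + bound_2,
                       bound_1 = as.integer(bound_1),
                       bound_2 = as.integer(bound_2),
                       dna_strands = as.integer(dna_per * (bound_1 + bound_2)))
}
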