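# Simulate the three-genome trio: one ancestor with planted genes, three
# independently evolved descendants (SAT, RUF, NIV) with full truth sets.

source("analysis/00_common.R")

sim <- simulate_trio(anc_length = ANC_LENGTH, n_genes = N_GENES,
                     params = TRIO_PARAMS, seed = SEED)

write_genome_fasta(sim$ancestor, file.path(SIM_DIR, "ancestor.fa"))
write_gff3(sim$genes, file.path(SIM_DIR, "ancestor_genes.gff3"))
for (g in names(sim$genomes)) {
  write_genome_fasta(sim$genomes[[g]], file.path(SIM_DIR, paste0(g, ".fa")))
  write_truth_tsv(sim$truths[[g]], file.path(SIM_DIR, paste0(g, "_truth.tsv")))
  write_gff3(sim$genes_by_genome[[g]], file.path(SIM_DIR, paste0(g, "_genes.gff3")))
}

for (g in names(sim$genomes)) {
  tr <- sim$truths[[g]]
  message(sprintf("%s: %s bp, %d SNPs, %d small indels, %d segmental events",
                  toupper(g), format(genome_length(sim$genomes[[g]]),
                                     big.mark = ","),
                  sum(tr$type == "snp"), sum(tr$type %in% c("ins", "del")),
                  sum(tr$type %in% c("pav_gain", "pav_loss"))))
}
message("simulation written to ", SIM_DIR)
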