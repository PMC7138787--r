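# SNPs and small indels from the SAT-RUF one-to-one alignment, functional
# effect annotation, the large-variant six-category classification, and
# the coding/intergenic indel size spectrum.

source("analysis/00_common.R")

sat <- read_genome_fasta(file.path(SIM_DIR, "sat.fa"), "SAT")
ruf <- read_genome_fasta(file.path(SIM_DIR, "ruf.fa"), "RUF")
blocks <- readRDS(file.path(ALN_DIR, "sat_ruf_blocks.rds"))
genes <- read_gff3(file.path(SIM_DIR, "sat_genes.gff3"))

vars <- call_small_variants(blocks, sat, ruf, CFG)
vars <- annotate_effects(vars, genes, sat)
write_vcf(vars, sat, file.path(RESULTS, "sat_ruf.vcf"))

eff <- table(vars$effect)
message(sprintf("%d SNPs, %d insertions, %d deletions (SAT vs RUF)",
                sum(vars$vtype == "snp"), sum(vars$vtype == "ins"),
                sum(vars$vtype == "del")))
message("effects: ", paste(names(eff), eff, collapse = ", "))
large_effect <- sum(vars$effect %in% c("stop_gain", "stop_loss", "frameshift"))
message(sprintf("large-effect mutations (stop gain/loss, frameshift): %d",
                large_effect))

large <- classify_large_variants(blocks, CFG)
write.table(large, file.path(RESULTS, "large_variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("large-variant categories: ",
        paste(names(table(large$category)), table(large$category),
              collapse = ", "))

sp <- indel_size_spectrum(vars)
write.table(sp, file.path(RESULTS, "indel_spectrum.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
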