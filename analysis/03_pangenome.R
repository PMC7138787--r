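# Tri-genome comparison: classify every base as core / dispensable /
# specific, compute pan- and core-genome sizes, and classify genes by
# membership; compare against the simulator truth.

source("analysis/00_common.R")

genomes <- list(
  sat = read_genome_fasta(file.path(SIM_DIR, "sat.fa"), "SAT"),
  ruf = read_genome_fasta(file.path(SIM_DIR, "ruf.fa"), "RUF"),
  niv = read_genome_fasta(file.path(SIM_DIR, "niv.fa"), "NIV"))
blocks <- lapply(c(sat_ruf = "sat_ruf", sat_niv = "sat_niv",
                   ruf_niv = "ruf_niv"), function(nm)
  readRDS(file.path(ALN_DIR, paste0(nm, "_blocks.rds"))))

pg <- build_pangenome(blocks$sat_ruf, blocks$sat_niv, blocks$ruf_niv,
                      lapply(genomes, chrom_lengths))
print(pg)

seg <- pg$segments
write_bed(cbind(seg[, c("chrom", "start", "end")],
                name = paste(seg$owner, seg$klass, sep = "_")),
          file.path(RESULTS, "pan_segments.bed"), extra = "name")
jsonlite::write_json(pg$stats, file.path(RESULTS, "pan_stats.json"),
                     auto_unbox = TRUE, digits = NA)

genes <- lapply(c(sat = "sat", ruf = "ruf", niv = "niv"), function(g)
  read_gff3(file.path(SIM_DIR, paste0(g, "_genes.gff3"))))
mem <- classify_gene_membership(genes, pg, CFG$presence_frac)
write.table(mem, file.path(RESULTS, "gene_membership.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
counts <- table(mem$klass[mem$genome == "sat"])
fr <- pan_fractions(pg$stats, as.list(counts))
message("fractions of the pan-genome: core ", fr$core_pct,
        "%, two-genome average ", fr$two_genome_avg_pct, "%")
message("SAT gene classes: ", paste(names(counts), counts, collapse = ", "))

truths <- lapply(c(sat = "sat", ruf = "ruf", niv = "niv"), function(g)
  read_truth_tsv(file.path(SIM_DIR, paste0(g, "_truth.tsv"))))
anc <- read_genome_fasta(file.path(SIM_DIR, "ancestor.fa"), "ancestor")
tp <- pan_truth(truths, anc)
message(sprintf("truth recovery: core %.3f%% off, dispensable %.3f%% off, specific %.3f%% off",
                100 * abs(pg$stats$core_bp - tp$core_bp) / tp$core_bp,
                100 * abs(pg$stats$dispensable_bp - tp$dispensable_bp) / tp$dispensable_bp,
                100 * abs(sum(pg$stats$specific_bp) - sum(tp$specific_bp)) / sum(tp$specific_bp)))
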