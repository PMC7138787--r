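# Presence-absence variation in the four classes (RS10/RS01/NS10/NS01)
# with gene assignment, and read-depth copy-number calling on a dedicated
# copy-number branch with truth scoring.

source("analysis/00_common.R")

genomes <- list(
  sat = read_genome_fasta(file.path(SIM_DIR, "sat.fa"), "SAT"),
  ruf = read_genome_fasta(file.path(SIM_DIR, "ruf.fa"), "RUF"),
  niv = read_genome_fasta(file.path(SIM_DIR, "niv.fa"), "NIV"))
blocks <- lapply(c(sat_ruf = "sat_ruf", sat_niv = "sat_niv"), function(nm)
  readRDS(file.path(ALN_DIR, paste0(nm, "_blocks.rds"))))
genes <- lapply(c(sat = "sat", ruf = "ruf", niv = "niv"), function(g)
  read_gff3(file.path(SIM_DIR, paste0(g, "_genes.gff3"))))

pav <- list(
  RS10 = call_pav_present_in_query(genomes$ruf, blocks$sat_ruf, genomes$sat,
                                   CFG, "RS10", genes$ruf),
  RS01 = call_pav_absent_in_query(genomes$sat, blocks$sat_ruf, CFG, "RS01",
                                  genes$sat),
  NS10 = call_pav_present_in_query(genomes$niv, blocks$sat_niv, genomes$sat,
                                   CFG, "NS10", genes$niv),
  NS01 = call_pav_absent_in_query(genomes$sat, blocks$sat_niv, CFG, "NS01",
                                  genes$sat))
all_rec <- do.call(rbind, lapply(pav, `[[`, "records"))
write.table(all_rec, file.path(RESULTS, "pav_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (nm in names(pav))
  message(sprintf("%s: %d segments, %s bp, %d specific genes", nm,
                  nrow(pav[[nm]]$records),
                  format(sum(pav[[nm]]$records$length), big.mark = ","),
                  length(pav[[nm]]$specific_genes)))

## copy-number branch: 30 planted events, Poisson depth at 40x
anc <- read_genome_fasta(file.path(SIM_DIR, "ancestor.fa"), "ancestor")
cn_sim <- evolve(anc, evolution_params(snp_rate = 0, indel_rate = 0,
                                       pav_count = 0, cnv_count = 30,
                                       cnv_len = c(1000, 2000)),
                 genome_id = "cnv_branch", seed = SEED + 11)
depth <- simulate_depth(anc, cn_sim$truth, mean_depth = 40, seed = SEED + 12)
write_depth_bed(depth, file.path(RESULTS, "depth.bed"))
cnv <- call_cnv(depth, CFG)
write.table(cnv, file.path(RESULTS, "cnv_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sc <- score_cnv(cnv, cn_sim$truth)
message(sprintf("cnv: %d calls for %d planted events; recall %.2f, precision %.2f",
                sc$n_calls, sc$n_truth, sc$recall, sc$precision))
gene_cnv <- classify_cnv_genes(genes$sat, cnv, CFG)
message("genes affected by CNV: ",
        sum(gene_cnv$call != "none"), " of ", nrow(gene_cnv))
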