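# Shared settings for the analysis scripts. Run the numbered scripts in
# order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_align.R
#   ...
# The seed can be overridden with the TRIPAN_SEED environment variable.

suppressMessages(library(tripan))

SEED <- as.integer(Sys.getenv("TRIPAN_SEED", "1"))
RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "simulation")
ALN_DIR <- file.path(RESULTS, "alignment")
for (d in c(RESULTS, SIM_DIR, ALN_DIR)) dir.create(d, showWarnings = FALSE,
                                                   recursive = TRUE)

# study-scale conditions: 1 Mb ancestor, 200 genes, three descendants
ANC_LENGTH <- 1e6
N_GENES <- 200
TRIO_PARAMS <- evolution_params(snp_rate = 0.005, pav_count = 20,
                                pav_len = c(1000, 5000),
                                pav_target_gene_frac = 0.5)
CFG <- threshold_config()
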