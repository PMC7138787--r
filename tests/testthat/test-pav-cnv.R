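cfg <- threshold_config()

test_that("presence-side PAV applies the length and identity filters", {
  anc <- simulate_ancestor(30000, seed = 91)
  # identical genomes: nothing to call
  b0 <- align_genomes(anc, anc, cfg)
  expect_equal(nrow(call_pav_present_in_query(anc, b0, anc, cfg)$records), 0L)

  insert_seg <- function(genome, at, seg) {
    s <- genome$seqs[[1]]
    genome_seq("q", c(c1 = paste0(substring(s, 1, at), seg,
                                  substring(s, at + 1, nchar(s)))))
  }
  # a 300 bp novel segment is one record; an 80 bp one fails the >100 bp rule
  set.seed(92)
  novel300 <- tripan:::random_dna(300)
  q1 <- insert_seg(anc, 12000, novel300)
  r1 <- call_pav_present_in_query(q1, align_genomes(anc, q1, cfg), anc, cfg,
                                  klass = "RS10")
  expect_equal(nrow(r1$records), 1L)
  expect_equal(r1$records$klass, "RS10")
  expect_equal(r1$records$length, 300)
  expect_lt(abs(r1$records$start - 12000), 25)

  q2 <- insert_seg(anc, 12000, tripan:::random_dna(80))
  r2 <- call_pav_present_in_query(q2, align_genomes(anc, q2, cfg), anc, cfg)
  expect_equal(nrow(r2$records), 0L)

  # a dispersed near-duplicate (about 98% identity) realigns above the
  # identity ceiling and is filtered out
  src <- substring(anc$seqs[[1]], 20001, 20600)
  chars <- strsplit(src, "")[[1]]
  mut <- sample(600, 12)
  for (m in mut) chars[m] <- setdiff(c("A", "C", "G", "T"), chars[m])[1]
  q3 <- insert_seg(anc, 5000, paste(chars, collapse = ""))
  r3 <- call_pav_present_in_query(q3, align_genomes(anc, q3, cfg), anc, cfg)
  expect_equal(nrow(r3$records), 0L)
})

test_that("absence-side PAV merges uncovered blocks below the distance rule", {
  anc <- simulate_ancestor(30000, seed = 95)
  b0 <- align_genomes(anc, anc, cfg)
  expect_equal(nrow(call_pav_absent_in_query(anc, b0, cfg)$records), 0L)

  # coverage leaving two 300 bp holes 400 bp apart merges to one 1000 bp record
  blocks <- as_blocks(data.frame(
    ref_chrom = "chr1",
    ref_start = c(0, 10300, 11000),
    ref_end = c(10000, 10700, 30000),
    qry_chrom = "chr1",
    qry_start = c(0, 10300, 11000),
    qry_end = c(10000, 10700, 30000),
    strand = "+", identity = 1, stringsAsFactors = FALSE))
  rec <- call_pav_absent_in_query(anc, blocks, cfg, klass = "RS01")$records
  expect_equal(nrow(rec), 1L)
  expect_equal(c(rec$start, rec$end, rec$length), c(10000, 11000, 1000))

  # a planted deletion in the query surfaces as one absence record +-50 bp
  s <- anc$seqs[[1]]
  q <- genome_seq("q", c(c1 = paste0(substring(s, 1, 15000),
                                     substring(s, 17001, 30000))))
  rec2 <- call_pav_absent_in_query(anc, align_genomes(anc, q, cfg), cfg)$records
  expect_equal(nrow(rec2), 1L)
  expect_lt(abs(rec2$start - 15000), 50)
  expect_lt(abs(rec2$end - 17000), 50)
})

test_that("PAV thresholds act monotonically and classes stay disjoint", {
  anc <- simulate_ancestor(60000, seed = 97)
  ev <- evolve(anc, evolution_params(pav_count = 8, pav_len = c(150, 2000)),
               seed = 98)
  blocks <- align_genomes(anc, ev$genome, cfg)
  counts <- sapply(c(100, 300, 900), function(ml) {
    c2 <- threshold_config(pav_min_len = ml)
    nrow(call_pav_present_in_query(ev$genome, blocks, anc, c2)$records)
  })
  expect_true(all(diff(counts) <= 0))
  counts_id <- sapply(c(0.99, 0.95, 0.5), function(mi) {
    c2 <- threshold_config(pav_max_identity = mi)
    nrow(call_pav_present_in_query(ev$genome, blocks, anc, c2)$records)
  })
  expect_true(all(diff(counts_id) <= 0))
  # presence records live on the query, absence records on the reference;
  # the same pair never yields both for one event
  pres <- call_pav_present_in_query(ev$genome, blocks, anc, cfg)$records
  abs_ <- call_pav_absent_in_query(anc, blocks, cfg)$records
  n_gain <- sum(ev$truth$type == "pav_gain")
  n_loss <- sum(ev$truth$type == "pav_loss")
  expect_equal(nrow(pres), n_gain)
  expect_equal(nrow(abs_), n_loss)
})

test_that("CNV calling thresholds normalized depth runs", {
  anc <- simulate_ancestor(50000, seed = 101)
  flat <- simulate_depth(anc, tripan:::empty_truth(), mean_depth = 40,
                         window = 200, noise = "none")
  expect_equal(nrow(call_cnv(flat, cfg)), 0L)
  expect_error(call_cnv(depth_track("x", flat$windows[0, ]), cfg), "input error")

  # a 2 kb run at twice the mean is a gain region
  w <- flat$windows
  sel <- w$start >= 20000 & w$start < 22000
  w$depth[sel] <- 80
  cn <- call_cnv(depth_track("x", w), cfg)
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$call, "gain")
  expect_equal(c(cn$start, cn$end), c(20000, 22000))
  # uniform rescaling leaves calls unchanged
  w2 <- w
  w2$depth <- w2$depth * 3.7
  expect_equal(call_cnv(depth_track("x", w2), cfg), cn, tolerance = 1e-12)
  # printed thresholds remain available as a configuration
  cfg_printed <- threshold_config(use_printed_cnv_thresholds = TRUE)
  expect_equal(c(cfg_printed$cnv_t_loss, cfg_printed$cnv_t_gain), c(1.2, 1.8))
})

test_that("gene-level CNV calls follow the exon-coverage rule", {
  gm <- gene_models(
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1", strand = "+",
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
               start = c(1000, 5000, 9000), end = c(2000, 6000, 10000)),
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
               start = c(1000, 5000, 9000), end = c(2000, 6000, 10000)))
  cnv <- data.frame(chrom = "c1", start = c(900, 5000, 8900, 9500),
                    end = c(2100, 5500, 9500, 10100),
                    norm_depth = c(2.5, 0.2, 2.5, 0.2),
                    call = c("gain", "loss", "gain", "loss"),
                    stringsAsFactors = FALSE)
  out <- classify_cnv_genes(gm, cnv, cfg)
  expect_equal(out$call[out$gene_id == "g1"], "gain")   # fully inside a gain
  expect_equal(out$call[out$gene_id == "g2"], "none")   # 50% < 80%
  expect_equal(out$call[out$gene_id == "g3"], "both")   # gain+loss cover >80%
})

test_that("planted copy-number events are recovered from noisy depth", {
  anc <- simulate_ancestor(3e5, seed = 105)
  cn_sim <- evolve(anc, evolution_params(snp_rate = 0, indel_rate = 0,
                                         pav_count = 0, cnv_count = 10,
                                         cnv_len = c(1000, 2000)),
                   seed = 106)
  depth <- simulate_depth(anc, cn_sim$truth, mean_depth = 40, seed = 107)
  calls <- call_cnv(depth, cfg)
  sc <- score_cnv(calls, cn_sim$truth)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
})
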