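test_that("ancestor simulation is deterministic with controlled composition", {
  expect_equal(genome_length(simulate_ancestor(0)), 0)
  g1 <- simulate_ancestor(1e5, gc = 0.43, seed = 4)
  g2 <- simulate_ancestor(1e5, gc = 0.43, seed = 4)
  expect_identical(g1$seqs, g2$seqs)
  gc_obs <- sum(strsplit(g1$seqs[[1]], "")[[1]] %in% c("G", "C")) / 1e5
  sigma <- sqrt(0.43 * 0.57 / 1e5)
  expect_lt(abs(gc_obs - 0.43), 4 * sigma)
  expect_error(simulate_ancestor(100, gc = 0), "gc")
})

test_that("evolution replays exactly and respects its event bookkeeping", {
  anc <- simulate_ancestor(50000, seed = 8)
  # no events: derived is the ancestor
  ev0 <- evolve(anc, evolution_params(snp_rate = 0, indel_rate = 0,
                                      pav_count = 0, cnv_count = 0), seed = 1)
  expect_identical(ev0$genome$seqs, anc$seqs)
  expect_equal(nrow(ev0$truth), 0L)
  for (seed in 1:4) {
    ev <- evolve(anc, evolution_params(pav_count = 6,
                                       cnv_count = 2, cnv_len = c(600, 1200)),
                 seed = seed)
    # replay property: applying the truth set reproduces the genome
    expect_identical(replay_truth(anc, ev$truth)$seqs, ev$genome$seqs)
    # length bookkeeping
    tr <- ev$truth
    gain <- sum(tr$len[tr$type %in% c("ins", "pav_gain")]) +
      sum((tr$copies[tr$type == "cnv_gain"] - 1) * tr$len[tr$type == "cnv_gain"])
    loss <- sum(tr$len[tr$type %in% c("del", "pav_loss", "cnv_loss")])
    expect_equal(genome_length(ev$genome), genome_length(anc) + gain - loss)
    # events non-overlapping on the ancestor
    spans <- tr[tr$anc_end > tr$anc_start, ]
    spans <- spans[order(spans$anc_start), ]
    expect_true(all(spans$anc_start[-1] >= spans$anc_end[-nrow(spans)]))
  }
})

test_that("substitution counts follow the binomial model", {
  anc <- simulate_ancestor(1e6, seed = 12)
  ev <- evolve(anc, evolution_params(snp_rate = 0.005, indel_rate = 0,
                                     pav_count = 0), seed = 13)
  n_snp <- sum(ev$truth$type == "snp")
  expect_lt(abs(n_snp - 5000), 4 * sqrt(1e6 * 0.005 * 0.995))
})

test_that("planted genes carry intact ORFs on both strands", {
  g <- simulate_ancestor(100000, seed = 21)
  expect_equal(nrow(plant_genes(g, 0)$genes$genes), 0L)
  pl <- plant_genes(g, 30, seed = 22)
  pl2 <- plant_genes(g, 30, seed = 22)
  expect_identical(pl2$genes$genes, pl$genes$genes)
  expect_true(any(pl$genes$genes$strand == "+") &&
                any(pl$genes$genes$strand == "-"))
  for (gid in pl$genes$genes$gene_id) {
    cds <- gene_cds_seq(pl$genome, pl$genes, gid)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substring(cds, 1, 3), "ATG")
    prot <- translate_cds(cds)
    expect_equal(substring(prot, nchar(prot), nchar(prot)), "*")
    # no internal stop
    expect_false(grepl("\\*", substring(prot, 1, nchar(prot) - 1)))
  }
  # genes do not overlap
  ex <- pl$genes$exons
  spans <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end))))
  expect_equal(interval_bp(spans), sum(spans$end - spans$start))
})

test_that("gene models lift onto derived coordinates", {
  g <- simulate_ancestor(100000, seed = 31)
  pl <- plant_genes(g, 20, seed = 32)
  # structural-only branch: substitutions would touch nearly every gene
  ev <- evolve(pl$genome, evolution_params(snp_rate = 0, indel_rate = 0,
                                           pav_count = 6,
                                           pav_target_gene_frac = 0.5),
               genes = pl$genes, seed = 33)
  lifted <- lift_genes(pl$genes, ev$truth)
  # genes deleted by targeted events are gone
  expect_lt(nrow(lifted$genes), nrow(pl$genes$genes) + 1)
  # genes untouched by any event keep their spliced CDS byte for byte
  ex <- pl$genes$exons
  spans <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end))))
  tr <- ev$truth
  untouched <- vapply(seq_len(nrow(spans)), function(i)
    !any(tr$chrom == spans$chrom[i] & tr$anc_start < spans$end[i] &
           tr$anc_end > spans$start[i]), logical(1))
  ids <- intersect(spans$gene_id[untouched], lifted$genes$gene_id)
  expect_gt(length(ids), 0)
  for (gid in ids) {
    expect_identical(gene_cds_seq(ev$genome, lifted, gid),
                     gene_cds_seq(pl$genome, pl$genes, gid))
  }
})

test_that("depth tracks scale with copy number and noise model", {
  anc <- simulate_ancestor(2e5, seed = 41)
  cn <- evolve(anc, evolution_params(snp_rate = 0, indel_rate = 0,
                                     pav_count = 0, cnv_count = 4,
                                     cnv_len = c(2000, 3000),
                                     cnv_copy_weights = c("0" = 0.5, "2" = 0,
                                                          "3" = 0.5)),
               seed = 42)
  flat <- simulate_depth(anc, cn$truth[0, ], mean_depth = 40, window = 200,
                         noise = "none")
  expect_true(all(flat$windows$depth == 40))
  exact <- simulate_depth(anc, cn$truth, mean_depth = 40, window = 200,
                          noise = "none")
  ev3 <- cn$truth[cn$truth$type == "cnv_gain" & cn$truth$copies == 3, ][1, ]
  inside <- exact$windows$start >= ev3$anc_start &
    exact$windows$end <= ev3$anc_end
  expect_true(all(exact$windows$depth[inside] == 120))
  ev0 <- cn$truth[cn$truth$type == "cnv_loss", ][1, ]
  in0 <- exact$windows$start >= ev0$anc_start & exact$windows$end <= ev0$anc_end
  expect_true(all(exact$windows$depth[in0] == 0))
  # Poisson noise: mean of copy-1 windows within 4 sigma
  big <- simulate_ancestor(1e6, seed = 43)
  pd <- simulate_depth(big, cn$truth[0, ], mean_depth = 40, window = 100,
                       seed = 44)
  nw <- nrow(pd$windows)
  expect_gte(nw, 1e4)
  expect_lt(abs(mean(pd$windows$depth) - 40), 4 * sqrt(40 / nw))
})

test_that("purifying mode restricts coding indels to codon multiples", {
  g <- simulate_ancestor(2e5, seed = 51)
  pl <- plant_genes(g, 60, seed = 52)
  ev <- evolve(pl$genome, evolution_params(indel_rate = 2e-3, snp_rate = 0,
                                           pav_count = 0, mode = "purifying"),
               genes = pl$genes, seed = 53)
  cds <- pl$genes$cds
  ind <- ev$truth[ev$truth$type %in% c("ins", "del"), ]
  in_cds <- vapply(seq_len(nrow(ind)), function(i)
    any(cds$chrom == ind$chrom[i] & cds$start <= ind$anc_start[i] &
          ind$anc_start[i] < cds$end), logical(1))
  expect_gt(sum(in_cds), 10)
  expect_true(all(ind$len[in_cds] %% 3 == 0))
})
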