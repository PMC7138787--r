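toy_block <- function(rc, rs, re, qc, qs, qe) {
  as_blocks(data.frame(ref_chrom = rc, ref_start = rs, ref_end = re,
                       qry_chrom = qc, qry_start = qs, qry_end = qe,
                       strand = "+", identity = 1, stringsAsFactors = FALSE))
}

test_that("three identical genomes are all core; unalignable genomes all specific", {
  L <- 30000
  full <- toy_block("c1", 0, L, "c1", 0, L)
  lens <- list(sat = c(c1 = L), ruf = c(c1 = L), niv = c(c1 = L))
  pg <- build_pangenome(full, full, full, lens)
  expect_equal(pg$stats$core_bp, L)
  expect_equal(pg$stats$pan_bp, L)
  expect_equal(pan_fractions(pg$stats)$core_pct, 100.0)

  none <- empty_blocks()
  pg0 <- build_pangenome(none, none, none, lens)
  expect_equal(pg0$stats$core_bp, 0)
  expect_equal(pg0$stats$pan_bp, 3 * L)
  expect_equal(unname(pg0$stats$specific_bp), rep(L, 3))
})

test_that("hand-built trio partitions exactly (A+B+C / A+B+D / A+C)", {
  # SAT = A(10k) + B(20k) + C(30k); RUF = A + B + D(15k); NIV = A + C
  lens <- list(sat = c(c1 = 60000), ruf = c(c1 = 45000), niv = c(c1 = 40000))
  sat_ruf <- rbind(toy_block("c1", 0, 10000, "c1", 0, 10000),       # A
                   toy_block("c1", 10000, 30000, "c1", 10000, 30000)) # B
  sat_niv <- rbind(toy_block("c1", 0, 10000, "c1", 0, 10000),       # A
                   toy_block("c1", 30000, 60000, "c1", 10000, 40000)) # C
  ruf_niv <- toy_block("c1", 0, 10000, "c1", 0, 10000)              # A
  pg <- build_pangenome(as_blocks(sat_ruf), as_blocks(sat_niv), ruf_niv, lens)
  expect_equal(pg$stats$core_bp, 10000)
  expect_equal(pg$stats$dispensable_bp, 50000)  # B (20k) + C (30k)
  expect_equal(unname(pg$stats$specific_bp), c(0, 15000, 0))  # D in RUF
  expect_equal(pg$stats$pan_bp, 75000)
  # presence masks on the segments
  seg <- pg$segments
  expect_equal(sum(seg$end - seg$start), 75000)
  b_seg <- seg[seg$owner == "sat" & seg$start == 10000, ]
  expect_true(b_seg$sat && b_seg$ruf && !b_seg$niv)
  expect_equal(b_seg$klass, "dispensable")
  # each genome is shorter than the pan-genome whenever specifics exist
  expect_true(all(unlist(lapply(lens, sum)) < pg$stats$pan_bp))
})

test_that("additivity is exact and coverage moves classes monotonically", {
  lens <- list(sat = c(c1 = 50000), ruf = c(c1 = 50000), niv = c(c1 = 50000))
  sat_ruf <- toy_block("c1", 0, 20000, "c1", 0, 20000)
  sat_niv <- toy_block("c1", 10000, 30000, "c1", 10000, 30000)
  ruf_niv <- empty_blocks()
  pg1 <- build_pangenome(sat_ruf, sat_niv, ruf_niv, lens)
  s1 <- pg1$stats
  expect_equal(s1$core_bp + s1$dispensable_bp + sum(s1$specific_bp), s1$pan_bp)

  # augment the sat-niv alignment: bases may only move toward core
  sat_niv2 <- rbind(sat_niv, toy_block("c1", 0, 10000, "c1", 40000, 50000))
  pg2 <- build_pangenome(sat_ruf, as_blocks(sat_niv2), ruf_niv, lens)
  s2 <- pg2$stats
  expect_gte(s2$core_bp, s1$core_bp)
  expect_lte(s2$specific_bp[["sat"]], s1$specific_bp[["sat"]])
  expect_equal(s2$core_bp + s2$dispensable_bp + sum(s2$specific_bp), s2$pan_bp)
})

test_that("simulated trios recover the truth partition and additivity", {
  sim <- simulate_trio(anc_length = 60000, n_genes = 15,
                       params = evolution_params(pav_count = 6), seed = 19)
  cfg <- threshold_config()
  b1 <- align_genomes(sim$genomes$sat, sim$genomes$ruf, cfg)
  b2 <- align_genomes(sim$genomes$sat, sim$genomes$niv, cfg)
  b3 <- align_genomes(sim$genomes$ruf, sim$genomes$niv, cfg)
  pg <- build_pangenome(b1, b2, b3, lapply(sim$genomes, chrom_lengths))
  s <- pg$stats
  expect_equal(s$core_bp + s$dispensable_bp + sum(s$specific_bp), s$pan_bp)
  tp <- pan_truth(sim$truths, sim$ancestor)
  expect_lt(abs(s$core_bp - tp$core_bp) / tp$core_bp, 0.02)
  expect_lt(abs(s$pan_bp - tp$pan_bp) / tp$pan_bp, 0.02)
})

test_that("gene membership follows CDS coverage of the pairwise alignments", {
  L <- 30000
  lens <- list(sat = c(c1 = L), ruf = c(c1 = L), niv = c(c1 = L))
  # sat aligned to ruf over [0, 20k), to niv over [0, 10k)
  pg <- build_pangenome(toy_block("c1", 0, 20000, "c1", 0, 20000),
                        toy_block("c1", 0, 10000, "c1", 0, 10000),
                        empty_blocks(), lens)
  mk_genes <- function(id, s, e) gene_models(
    data.frame(gene_id = id, chrom = rep("c1", length(id)),
               strand = rep("+", length(id)), stringsAsFactors = FALSE),
    data.frame(gene_id = id, chrom = rep("c1", length(id)), start = s, end = e),
    data.frame(gene_id = id, chrom = rep("c1", length(id)), start = s, end = e))
  empty <- mk_genes(character(0), numeric(0), numeric(0))
  core_gene <- mk_genes("gA", 1000, 2000)       # inside both coverages
  disp_gene <- mk_genes("gB", 15000, 16000)     # only ruf coverage
  spec_gene <- mk_genes("gC", 25000, 26000)     # outside all coverage
  for (case in list(list(core_gene, "core"), list(disp_gene, "dispensable"),
                    list(spec_gene, "specific"))) {
    mem <- classify_gene_membership(list(sat = case[[1]], ruf = empty,
                                         niv = empty), pg)
    expect_equal(mem$klass, case[[2]])
  }
})

test_that("pan fractions round half-up at 0.1% and reject a zero pan", {
  st <- list(pan_bp = 1000, core_bp = 616, dispensable_bp = 300,
             specific_bp = c(sat = 84, ruf = 0, niv = 0),
             two_genome_union_bp = c(921, 921, 921))
  fr <- pan_fractions(st)
  expect_equal(fr$core_pct, 61.6)
  expect_equal(fr$two_genome_avg_pct, 92.1)
  st$pan_bp <- 0
  expect_error(pan_fractions(st), "undefined")
})
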