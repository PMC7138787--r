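cfg <- threshold_config()

test_that("small-variant calling recovers constructed differences exactly", {
  anc <- simulate_ancestor(20000, seed = 61)
  # identical pair: no variants
  b0 <- align_genomes(anc, anc, cfg)
  expect_equal(nrow(call_small_variants(b0, anc, anc, cfg)), 0L)
  # one substitution
  s <- anc$seqs[[1]]
  pos <- 7000
  old <- substring(s, pos + 1, pos + 1)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substring(s, pos + 1, pos + 1) <- new
  mut <- genome_seq("mut", c(c1 = s))
  b1 <- align_genomes(anc, mut, cfg)
  v <- call_small_variants(b1, anc, mut, cfg)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, pos)
  expect_equal(v$ref, old)
  expect_equal(v$alt, new)
  expect_equal(v$vtype, "snp")
})

test_that("indels are left-normalized to the homopolymer start", {
  g <- genome_seq("r", c(c1 = "ACGTTTTTACGT"))
  v <- data.frame(chrom = "c1", pos = 6, end = 7, ref = "T", alt = "",
                  vtype = "del", stringsAsFactors = FALSE)
  nv <- normalize_indels(v, g)
  expect_equal(nv$pos, 3)  # leftmost equivalent deletion in the T run
  vi <- data.frame(chrom = "c1", pos = 8, end = 8, ref = "", alt = "T",
                   vtype = "ins", stringsAsFactors = FALSE)
  expect_equal(normalize_indels(vi, g)$pos, 3)
})

test_that("codon effects follow the genetic code on both strands", {
  # CDS ATG AAA TAG on the plus strand
  seqs <- paste0(strrep("C", 30), "ATGAAATAG", strrep("C", 30))
  g <- genome_seq("r", c(c1 = seqs))
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "c1", strand = "+",
               stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", chrom = "c1", start = 30, end = 39),
    data.frame(gene_id = "g1", chrom = "c1", start = 30, end = 39))
  mkv <- function(pos, ref, alt, vtype = "snp",
                  end = pos + as.integer(vtype == "snp"))
    data.frame(chrom = "c1", pos = pos, end = end, ref = ref, alt = alt,
               vtype = vtype, stringsAsFactors = FALSE)
  # AAA -> TAA at first base of codon 2: stop gained
  out <- annotate_effects(mkv(33, "A", "T"), gm, g)
  expect_equal(out$effect, "stop_gain")
  # AAA -> AGA: nonsynonymous
  expect_equal(annotate_effects(mkv(34, "A", "G"), gm, g)$effect, "nonsynonymous")
  # AAA -> AAG: synonymous (both lysine)
  expect_equal(annotate_effects(mkv(35, "A", "G"), gm, g)$effect, "synonymous")
  # TAG -> CAG: stop lost
  expect_equal(annotate_effects(mkv(36, "T", "C"), gm, g)$effect, "stop_loss")
  # outside the CDS
  expect_equal(annotate_effects(mkv(5, "C", "A"), gm, g)$effect, "intergenic")
  # 2 bp CDS deletion frameshifts, 3 bp stays in frame
  expect_equal(annotate_effects(mkv(33, "AA", "", "del", 35), gm, g)$effect,
               "frameshift")
  expect_equal(annotate_effects(mkv(33, "AAA", "", "del", 36), gm, g)$effect,
               "inframe")

  # minus strand: reverse-complement the cassette
  seqs2 <- paste0(strrep("C", 30), as.character(revcomp("ATGAAATAG")),
                  strrep("C", 30))
  g2 <- genome_seq("r2", c(c1 = seqs2))
  gm2 <- gene_models(
    data.frame(gene_id = "g1", chrom = "c1", strand = "-",
               stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", chrom = "c1", start = 30, end = 39),
    data.frame(gene_id = "g1", chrom = "c1", start = 30, end = 39))
  # genomic CTATTTCAT; codon-2 first base (spliced index 3) is genomic pos 35 (T)
  out2 <- annotate_effects(mkv(35, "T", "A"), gm2, g2)
  expect_equal(out2$effect, "stop_gain")
})

test_that("effect labels agree with the whole-protein translation oracle", {
  g0 <- simulate_ancestor(30000, seed = 71)
  pl <- plant_genes(g0, 12, seed = 72)
  g <- pl$genome
  gm <- pl$genes
  set.seed(73)
  cds <- gm$cds
  n <- 250
  rows <- cds[sample.int(nrow(cds), n, replace = TRUE), ]
  pos <- floor(runif(n, rows$start, rows$end))
  refb <- substring(g$seqs[rows$chrom], pos + 1, pos + 1)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  v <- data.frame(chrom = rows$chrom, pos = pos, end = pos + 1, ref = refb,
                  alt = unname(altb), vtype = "snp", stringsAsFactors = FALSE)
  v <- v[!duplicated(v$pos), ]
  ann <- annotate_effects(v, gm, g)
  oracle <- vapply(seq_len(nrow(v)), function(i)
    oracle_snp_effect(g, gm, v[i, ]), "")
  expect_identical(ann$effect, oracle)
})

test_that("the six-category classifier applies the documented gap rules", {
  blk <- function(rs, re, qs, qe, gaps = empty_gaps()) {
    b <- as_blocks(data.frame(ref_chrom = "c1", ref_start = rs, ref_end = re,
                              qry_chrom = "c1", qry_start = qs, qry_end = qe,
                              strand = "+", identity = 1,
                              stringsAsFactors = FALSE))
    b$gaps <- list(gaps)
    b$columns <- min(re - rs - sum(gaps$ref_gap), qe - qs - sum(gaps$qry_gap))
    b$matches <- b$columns
    b
  }
  # within-block gap: qry 50 bp longer -> insertion of size 50
  b <- blk(0, 1000, 0, 1050, data.frame(ref_pos = 400, ref_gap = 0, qry_gap = 50))
  lv <- classify_large_variants(b, cfg)
  expect_equal(lv$category, "insertion")
  expect_equal(lv$size, 50)
  # between blocks: plain gaps, repeat-like gaps, tandem overlaps
  cases <- list(
    list(b2 = c(1200, 2000, 1250, 2050), cat = "insertion"),        # dr=200,dq=250? no: see below
    list(b2 = c(1010, 2000, 1500, 2490), cat = "insertion"),        # dr=10, dq=500
    list(b2 = c(1500, 2000, 1010, 1510), cat = "deletion"),         # dr=500, dq=10
    list(b2 = c(1200, 2000, 1500, 2300), cat = "repeat_expansion"), # dr=200, dq=500
    list(b2 = c(1500, 2000, 1200, 1700), cat = "repeat_contraction"),# dr=500, dq=200
    list(b2 = c(800, 2000, 1000, 2200), cat = "tandem_expansion"),  # dr=-200, dq=0
    list(b2 = c(1000, 2000, 800, 1800), cat = "tandem_contraction") # dr=0, dq=-200
  )[-1]
  for (cs in cases) {
    pair <- as_blocks(rbind(blk(0, 1000, 0, 1000), blk(cs$b2[1], cs$b2[2],
                                                       cs$b2[3], cs$b2[4])))
    lv <- classify_large_variants(pair, cfg)
    lv <- lv[lv$source == "between_blocks", ]
    expect_equal(lv$category, cs$cat)
  }
  # unsorted input is rejected
  pair <- as_blocks(rbind(blk(5000, 6000, 5000, 6000), blk(0, 1000, 0, 1000)))
  expect_error(classify_large_variants(pair, cfg), "ordering")
})

test_that("category counts plus unclassified account for every record", {
  anc <- simulate_ancestor(80000, seed = 81)
  ev <- evolve(anc, evolution_params(pav_count = 8, pav_len = c(50, 400),
                                     cnv_count = 3, cnv_len = c(600, 1200),
                                     cnv_copy_weights = c("0" = 0, "2" = 0.5,
                                                          "3" = 0.5)),
               seed = 82)
  lv <- classify_large_variants(align_genomes(anc, ev$genome, cfg), cfg)
  six <- c("insertion", "deletion", "repeat_expansion", "repeat_contraction",
           "tandem_expansion", "tandem_contraction")
  expect_equal(sum(lv$category %in% six) + sum(lv$category == "unclassified"),
               nrow(lv))
  expect_true(all(lv$size >= cfg$large_variant_min))
})

test_that("indel spectra stratify by coding effect", {
  empty <- indel_size_spectrum(data.frame(chrom = character(), pos = numeric(),
                                          end = numeric(), ref = character(),
                                          alt = character(), vtype = character(),
                                          gene_id = character(),
                                          effect = character()))
  expect_equal(nrow(empty), 0L)
  v <- data.frame(chrom = "c1", pos = c(1, 2, 3), end = c(4, 2, 6),
                  ref = c("AAA", "", "CCC"), alt = c("", "GG", ""),
                  vtype = c("del", "ins", "del"),
                  gene_id = c("g1", "g1", NA), boundary = FALSE,
                  effect = c("inframe", "frameshift", "intergenic"),
                  stringsAsFactors = FALSE)
  sp <- indel_size_spectrum(v)
  expect_equal(sp$count[sp$stratum == "cds" & sp$size == -3], 1)
  expect_equal(sp$count[sp$stratum == "cds" & sp$size == 2], 1)
  expect_equal(sp$count[sp$stratum == "intergenic" & sp$size == -3], 1)
})
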