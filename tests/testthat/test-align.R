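cfg <- threshold_config()

test_that("anchor finding validates k and matches the hash-join oracle", {
  g <- simulate_ancestor(5000, seed = 1)
  expect_error(find_anchors(g, g, 20), "odd")
  expect_error(find_anchors(g, g, 9), "parameter")

  set.seed(2)
  anc <- simulate_ancestor(20000, seed = 2)
  ev <- evolve(anc, evolution_params(snp_rate = 0.01, pav_count = 2,
                                     pav_len = c(200, 800)), seed = 3)
  a <- find_anchors(anc, ev$genome, 21)
  o <- hash_join_anchors(anc$seqs[[1]], ev$genome$seqs[[1]], 21)
  key <- function(d) sort(paste(d$ref_start, d$qry_start, d$strand))
  expect_identical(key(a), key(o))
})

test_that("identical sequences give one full-identity block", {
  g <- simulate_ancestor(10000, seed = 5)
  a <- find_anchors(g, g, 21)
  # anchors tile every position holding a unique k-mer
  expect_gt(nrow(a), 10000 - 21 + 1 - 50)
  b <- chain_and_extend(a, g, g, cfg)
  expect_equal(nrow(b), 1L)
  expect_equal(b$identity, 1.0)
  expect_equal(c(b$ref_start, b$ref_end), c(0, 10000))
  expect_equal(nrow(b$gaps[[1]]), 0L)
})

test_that("reverse-complement queries align on the minus strand", {
  g <- simulate_ancestor(10000, seed = 6)
  rc <- genome_seq("rc", setNames(revcomp(g$seqs), names(g$seqs)))
  a <- find_anchors(g, rc, 21)
  expect_true(all(a$strand == "-"))
  b <- chain_and_extend(a, g, rc, cfg)
  expect_equal(nrow(b), 1L)
  expect_equal(b$strand, "-")
  expect_equal(b$identity, 1.0)
  validate_blocks(b)
  # variant calling across the minus strand stays clean
  v <- call_small_variants(b, g, rc, cfg)
  expect_equal(nrow(v), 0L)
})

test_that("a planted insertion is bridged into one block with its gap", {
  anc <- simulate_ancestor(20000, seed = 7)
  ins_at <- 9000
  ins_seq <- tripan:::random_dna(500, 0.43)
  d <- genome_seq("d", c(c1 = paste0(substring(anc$seqs[[1]], 1, ins_at),
                                     ins_seq,
                                     substring(anc$seqs[[1]], ins_at + 1, 20000))))
  b <- align_genomes(anc, d, cfg)
  expect_equal(nrow(b), 1L)
  g <- b$gaps[[1]]
  big <- g[g$qry_gap >= 400, ]
  expect_equal(nrow(big), 1L)
  expect_equal(big$qry_gap, 500)
  expect_equal(big$ref_gap, 0)
  # breakpoint within homopolymer ambiguity of the planted position
  expect_lt(abs(big$ref_pos - ins_at), 25)
})

test_that("identity estimates track the substitution rate", {
  anc <- simulate_ancestor(50000, seed = 8)
  ev <- evolve(anc, evolution_params(snp_rate = 0.01, indel_rate = 0,
                                     pav_count = 0), seed = 9)
  b <- align_genomes(anc, ev$genome, cfg)
  expect_equal(nrow(b), 1L)
  sigma <- sqrt(0.01 * 0.99 / 50000)
  expect_lt(abs((1 - b$identity) - 0.01), 4 * sigma)
})

test_that("one-to-one filtering keeps the heaviest consistent blocks", {
  b <- make_random_blocks(10, seed = 3)
  b <- b[order(b$ref_start), ]
  b$qry_start <- b$ref_start + 2e6  # guarantee disjoint query too
  b$qry_end <- b$ref_end + 2e6
  b <- as_blocks(b[!duplicated(b$ref_start), ])
  expect_equal(nrow(filter_one_to_one(b)), nrow(b))

  dup <- as_blocks(data.frame(
    ref_chrom = "c1", ref_start = c(0, 0), ref_end = c(1000, 1000),
    qry_chrom = "c2", qry_start = c(0, 5000), qry_end = c(1000, 6000),
    strand = "+", identity = c(0.99, 0.90), stringsAsFactors = FALSE))
  kept <- filter_one_to_one(dup, max_overlap_frac = 0, min_new_bp = Inf)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$identity, 0.99)
})

exhaustive_best <- function(b) {
  w <- b$identity * b$columns
  n <- nrow(b)
  overlaps <- function(i, j)
    (b$ref_start[i] < b$ref_end[j] && b$ref_start[j] < b$ref_end[i]) ||
    (b$qry_start[i] < b$qry_end[j] && b$qry_start[j] < b$qry_end[i])
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (i in seq_along(idx)[-1]) for (j in seq_len(i - 1))
        if (overlaps(idx[i], idx[j])) { ok <- FALSE; break }
    }
    if (ok) best <- max(best, sum(w[idx]))
  }
  best
}

test_that("greedy one-to-one score approaches the exhaustive optimum", {
  set.seed(44)
  # pairwise conflicts only (each lighter competitor nested inside its
  # partner): greedy equals the optimum exactly
  base <- (0:5) * 2000
  plen <- sample(400:900, 6, replace = TRUE)
  rs <- c(base, base + 100)
  len <- c(plen, rep(300, 6))
  qs <- c(base, base + 20000)        # query side conflict-free for competitors
  b <- as_blocks(data.frame(
    ref_chrom = "c1", ref_start = rs, ref_end = rs + len,
    qry_chrom = "c2", qry_start = qs, qry_end = qs + len,
    strand = "+", identity = c(runif(6, 0.95, 1), runif(6, 0.8, 0.9)),
    stringsAsFactors = FALSE))
  kept <- filter_one_to_one(b, max_overlap_frac = 0, min_new_bp = Inf)
  expect_equal(sum(kept$identity * kept$columns), exhaustive_best(b))

  # sparse random instances: greedy within 5% of the optimum
  for (rep in 1:3) {
    n <- 12
    rs <- sample.int(20000, n)
    len <- sample(200:900, n, replace = TRUE)
    qs <- sample.int(20000, n)
    b <- as_blocks(data.frame(
      ref_chrom = "c1", ref_start = rs, ref_end = rs + len,
      qry_chrom = "c2", qry_start = qs, qry_end = qs + len,
      strand = "+", identity = runif(n, 0.8, 1), stringsAsFactors = FALSE))
    kept <- filter_one_to_one(b, max_overlap_frac = 0, min_new_bp = Inf)
    expect_gte(sum(kept$identity * kept$columns), 0.95 * exhaustive_best(b))
  }
})

test_that("self-alignment covers the genome; coverage is symmetric", {
  anc <- simulate_ancestor(50000, seed = 10)
  b <- align_genomes(anc, anc, cfg)
  expect_gte(interval_bp(blocks_ref_coverage(b)) / 50000, 0.99)
  expect_true(all(b$identity == 1.0))

  ev <- evolve(anc, evolution_params(pav_count = 4), seed = 11)
  ab <- align_genomes(anc, ev$genome, cfg)
  ba <- align_genomes(ev$genome, anc, cfg)
  cov_ab <- interval_bp(blocks_ref_coverage(ab))
  cov_ba <- interval_bp(blocks_qry_coverage(ba))
  expect_lt(abs(cov_ab - cov_ba) / cov_ab, 0.01)
})

test_that("emitted blocks always satisfy the coordinate invariants", {
  anc <- simulate_ancestor(60000, seed = 12)
  for (seed in 1:3) {
    ev <- evolve(anc, evolution_params(pav_count = 6, cnv_count = 2,
                                       cnv_len = c(600, 1500),
                                       cnv_copy_weights = c("0" = 0.3, "2" = 0.4,
                                                            "3" = 0.3)),
                 seed = seed)
    b <- align_genomes(anc, ev$genome, cfg)
    expect_silent(validate_blocks(b))
    expect_true(all(b$identity > 0.9))
  }
})
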