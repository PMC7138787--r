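# Independent oracles used across the suite. These re-derive expected
# values by brute force and must stay independent of the implementation
# paths they check.

# Boolean-mask union of intervals on one chromosome of length L.
mask_union_bp <- function(iv, L) {
  m <- logical(L)
  for (i in seq_len(nrow(iv))) m[(iv$start[i] + 1):iv$end[i]] <- TRUE
  sum(m)
}

# Brute-force unique-k-mer hash join between two sequences (one chromosome
# each), counting a k-mer and its reverse complement together.
hash_join_anchors <- function(rseq, qseq, k) {
  canon_table <- function(s) {
    L <- nchar(s)
    kmers <- substring(s, 1:(L - k + 1), k:L)
    rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- pmin(kmers, rcs)
    orient <- kmers <= rcs
    cnt <- table(canon)
    uniq <- names(cnt)[cnt == 1]
    keep <- canon %in% uniq
    data.frame(canon = canon[keep], pos = which(keep) - 1L,
               orient = orient[keep], stringsAsFactors = FALSE)
  }
  a <- canon_table(rseq)
  b <- canon_table(qseq)
  m <- merge(a, b, by = "canon")
  data.frame(ref_start = m$pos.x, qry_start = m$pos.y,
             strand = ifelse(m$orient.x == m$orient.y, "+", "-"),
             stringsAsFactors = FALSE)
}

# Whole-protein translation oracle for SNP effect labels.
oracle_snp_effect <- function(genome, genes, v) {
  gm <- genes
  hit <- NULL
  for (gid in gm$genes$gene_id) {
    cd <- gm$cds[gm$cds$gene_id == gid, , drop = FALSE]
    if (any(cd$chrom == v$chrom & cd$start <= v$pos & v$pos < cd$end)) {
      hit <- gid
      break
    }
  }
  if (is.null(hit)) return("intergenic")
  mut <- genome
  s <- mut$seqs[[v$chrom]]
  substring(s, v$pos + 1, v$pos + 1) <- v$alt
  mut$seqs[[v$chrom]] <- s
  p0 <- translate_cds(gene_cds_seq(genome, gm, hit))
  p1 <- translate_cds(gene_cds_seq(mut, gm, hit))
  if (p0 == p1) return("synonymous")
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  a0 <- substring(p0, d[1], d[1]); a1 <- substring(p1, d[1], d[1])
  if (a1 == "*" && a0 != "*") "stop_gain"
  else if (a0 == "*" && a1 != "*") "stop_loss"
  else "nonsynonymous"
}

# One-sided Fisher p by explicit enumeration over all draws, from the
# closed-form hypergeometric terms written with log-binomials.
enum_fisher_p <- function(k, K, N, n) {
  js <- max(0, n + K - N):min(n, K)
  probs <- exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n))
  sum(probs[js >= k])
}

# Direct Benjamini-Hochberg step-up.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Random interval set on one chromosome.
random_intervals <- function(n, L, max_len = 500) {
  s <- sample.int(L - max_len, n, replace = TRUE) - 1L
  w <- sample.int(max_len, n, replace = TRUE)
  intervals("c1", s, pmin(s + w, L))
}

# Random gap-free block sets (ref and query lengths equal).
make_random_blocks <- function(n, seed = 1) {
  set.seed(seed)
  rs <- sort(sample.int(1e6, n))
  len <- sample(50:5000, n, replace = TRUE)
  qs <- sample.int(1e6, n)
  id <- round(runif(n, 0.80, 1.00), 2)  # identity exact at the 2 decimals written
  as_blocks(data.frame(
    ref_chrom = "c1", ref_start = rs, ref_end = rs + len,
    qry_chrom = "c2", qry_start = qs, qry_end = qs + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    identity = id, stringsAsFactors = FALSE))
}

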