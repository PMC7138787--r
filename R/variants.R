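## SNP / small-indel extraction from one-to-one alignments, functional
## effect annotation against gene models, and the six-category classifier
## for large (>= 10 bp) variants.

#' Call SNPs and small indels from alignment blocks
#'
#' Walks every block's aligned segments and gap records: one SNP per
#' mismatched aligned column, one indel per gap run of at most
#' `small_variant_max` bp. Alleles are reported on the reference strand;
#' indels are left-normalized (shifted to their leftmost equivalent
#' position, the usual VCF convention). Coordinates are 0-based: a deletion
#' spans `[pos, end)` on the reference, an insertion sits between `pos - 1`
#' and `pos` with `end == pos`.
#'
#' @param blocks One-to-one filtered alignment blocks.
#' @param ref,qry The two `genome_seq` objects.
#' @param config A [threshold_config()].
#' @return data.frame(chrom, pos, end, ref, alt, vtype) sorted by position.
#' @export
call_small_variants <- function(blocks, ref, qry, config = threshold_config()) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    rchrom <- blocks$ref_chrom[i]
    rseq <- ref$seqs[[rchrom]]
    qseq <- qry$seqs[[blocks$qry_chrom[i]]]
    if (is.null(rseq) || is.null(qseq))
      stop("consistency error: block references missing sequence")
    minus <- blocks$strand[i] == "-"
    sg <- block_segments(blocks, i)
    for (j in seq_len(nrow(sg$segs))) {
      s <- sg$segs[j, ]
      rstr <- substring(rseq, s$ref_s + 1, s$ref_e)
      qstr <- substring(qseq, s$qry_s + 1, s$qry_e)
      if (minus) qstr <- revcomp(qstr)
      mm <- mismatch_positions_cpp(rstr, qstr)
      if (length(mm) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = rchrom, pos = s$ref_s + mm, end = s$ref_s + mm + 1,
          ref = substring(rstr, mm + 1, mm + 1),
          alt = substring(qstr, mm + 1, mm + 1),
          vtype = "snp", stringsAsFactors = FALSE)
      }
    }
    g <- sg$gaps
    for (j in seq_len(nrow(g))) {
      if (g$ref_gap[j] > 0 && g$ref_gap[j] <= config$small_variant_max) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = rchrom, pos = g$ref_pos[j], end = g$ref_pos[j] + g$ref_gap[j],
          ref = substring(rseq, g$ref_pos[j] + 1, g$ref_pos[j] + g$ref_gap[j]),
          alt = "", vtype = "del", stringsAsFactors = FALSE)
      }
      if (g$qry_gap[j] > 0 && g$qry_gap[j] <= config$small_variant_max) {
        ins <- substring(qseq, g$qry_pos[j] + 1, g$qry_pos[j] + g$qry_gap[j])
        if (minus) ins <- revcomp(ins)
        out[[length(out) + 1L]] <- data.frame(
          chrom = rchrom, pos = g$ref_pos[j] + g$ref_gap[j],
          end = g$ref_pos[j] + g$ref_gap[j],
          ref = "", alt = ins, vtype = "ins", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos = numeric(), end = numeric(),
                      ref = character(), alt = character(), vtype = character(),
                      stringsAsFactors = FALSE))
  v <- do.call(rbind, out)
  v <- normalize_indels(v, ref)
  v <- v[!duplicated(v[, c("chrom", "pos", "vtype", "ref", "alt")]), , drop = FALSE]
  v <- v[order(v$chrom, v$pos, v$vtype), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Left-normalize indel records
#'
#' Shifts each insertion/deletion to its leftmost equivalent placement
#' (e.g. a deletion inside a homopolymer run moves to the run start).
#'
#' @param variants Variant data.frame.
#' @param genome Reference `genome_seq`.
#' @return The variants with normalized positions and alleles.
#' @export
normalize_indels <- function(variants, genome) {
  idx <- which(variants$vtype != "snp")
  for (i in idx) {
    chrom_seq <- genome$seqs[[variants$chrom[i]]]
    pos <- variants$pos[i]
    allele <- if (variants$vtype[i] == "del") variants$ref[i] else variants$alt[i]
    n <- nchar(allele)
    if (n == 0) next
    while (pos > 0) {
      prev <- substring(chrom_seq, pos, pos)
      if (prev != substring(allele, n, n)) break
      allele <- paste0(prev, substring(allele, 1, n - 1))
      pos <- pos - 1
    }
    shift <- variants$pos[i] - pos
    if (shift > 0) {
      variants$pos[i] <- pos
      variants$end[i] <- variants$end[i] - shift
      if (variants$vtype[i] == "del") variants$ref[i] <- allele
      else variants$alt[i] <- allele
    }
  }
  variants
}

aa_of <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Annotate functional effects of variants
#'
#' SNPs inside coding sequence are classified by comparing the reference
#' and mutated codon (synonymous, nonsynonymous, stop_gain, stop_loss);
#' coding indels by their length modulo three (frameshift, inframe). Codon
#' extraction is strand-aware. Variants partially overlapping a CDS
#' boundary keep their modulo-three effect on the overlapping bases and are
#' flagged (`boundary = TRUE`), not dropped; everything outside coding
#' sequence is "intergenic".
#'
#' @param variants Variant data.frame from [call_small_variants()].
#' @param genes A `gene_models` object (reference coordinates).
#' @param genome Reference `genome_seq`.
#' @return The variants with `effect`, `gene_id` and `boundary` columns.
#' @export
annotate_effects <- function(variants, genes, genome) {
  variants$effect <- "intergenic"
  variants$gene_id <- NA_character_
  variants$boundary <- FALSE
  if (nrow(variants) == 0L || nrow(genes$cds) == 0L) return(variants)
  unknown <- setdiff(unique(genes$genes$chrom), names(genome$seqs))
  if (length(unknown) > 0)
    stop("consistency error: gene on unknown chromosome ", unknown[1])

  cds <- genes$cds[order(genes$cds$gene_id, genes$cds$start), , drop = FALSE]
  ginfo <- new.env(parent = emptyenv())
  get_gene <- function(gid) {
    if (!is.null(ginfo[[gid]])) return(ginfo[[gid]])
    g <- genes$genes[genes$genes$gene_id == gid, ]
    cd <- cds[cds$gene_id == gid, , drop = FALSE]
    spliced <- gene_cds_seq(genome, genes, gid)
    info <- list(strand = g$strand, cd = cd,
                 cum = cumsum(c(0, cd$end - cd$start)),
                 total = sum(cd$end - cd$start), spliced = spliced)
    ginfo[[gid]] <- info
    info
  }

  cds_gr <- GenomicRanges::GRanges(cds$chrom, IRanges::IRanges(cds$start + 1, cds$end))
  ## insertions get a width-1 range at the base after the insertion point
  var_gr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos + 1,
                     ifelse(variants$vtype == "ins", variants$pos + 1, variants$end)))
  hits <- GenomicRanges::findOverlaps(var_gr, cds_gr)
  by_var <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  for (nm in names(by_var)) {
    i <- as.integer(nm)
    cis <- by_var[[nm]]
    gid <- cds$gene_id[cis[1]]
    cis <- cis[cds$gene_id[cis] == gid]
    info <- get_gene(gid)
    v <- variants[i, ]
    if (v$vtype == "snp") {
      variants$gene_id[i] <- gid
      exi <- which(info$cd$start <= v$pos & v$pos < info$cd$end)[1]
      asc_idx <- info$cum[exi] + (v$pos - info$cd$start[exi])
      sp_idx <- if (info$strand == "+") asc_idx else info$total - 1 - asc_idx
      codon_i <- sp_idx %/% 3
      within <- sp_idx %% 3
      codon <- substring(info$spliced, 3 * codon_i + 1, 3 * codon_i + 3)
      altb <- if (info$strand == "+") v$alt else comp_base(v$alt)
      newc <- codon
      substring(newc, within + 1, within + 1) <- altb
      a0 <- aa_of(codon); a1 <- aa_of(newc)
      if (is.na(a0) || is.na(a1)) {
        # trailing partial codon of a frame-disrupted gene model
        variants$gene_id[i] <- gid
        variants$boundary[i] <- TRUE
        variants$effect[i] <- "nonsynonymous"
        next
      }
      variants$effect[i] <-
        if (a0 == a1) "synonymous"
        else if (a1 == "*" && a0 != "*") "stop_gain"
        else if (a0 == "*" && a1 != "*") "stop_loss"
        else "nonsynonymous"
    } else if (v$vtype == "ins") {
      inside <- any(cds$start[cis] < v$pos & v$pos < cds$end[cis])
      if (!inside) next
      variants$gene_id[i] <- gid
      variants$effect[i] <- if (nchar(v$alt) %% 3 == 0) "inframe" else "frameshift"
    } else {
      ov <- sum(pmin(v$end, cds$end[cis]) - pmax(v$pos, cds$start[cis]))
      full <- ov == (v$end - v$pos)
      variants$gene_id[i] <- gid
      variants$boundary[i] <- !full
      variants$effect[i] <- if (ov %% 3 == 0) "inframe" else "frameshift"
    }
  }
  variants
}

#' Classify large variants into six structural categories
#'
#' Within a block, any gap whose reference and query sides differ by at
#' least `large_variant_min` bp is a plain insertion or deletion. Between
#' consecutive blocks of one chromosome/strand pairing, with `dr` the
#' reference gap and `dq` the strand-adjusted query gap: non-negative gaps
#' are plain indels when the smaller gap is at most `repeat_gap_min` and
#' repeat expansions/contractions otherwise; a negative `dr` (blocks
#' overlapping on the reference) is a tandem expansion and a negative `dq`
#' a tandem contraction. Pairs where both gaps are negative are reported as
#' "unclassified" and excluded from the six-category total.
#'
#' @param blocks One-to-one filtered alignment blocks, sorted by reference.
#' @param config A [threshold_config()].
#' @return data.frame(category, ref_chrom, ref_start, ref_end, qry_chrom,
#'   qry_start, qry_end, size, source).
#' @export
classify_large_variants <- function(blocks, config = threshold_config()) {
  if (nrow(blocks) > 1) {
    o <- order(blocks$ref_chrom, blocks$ref_start)
    if (!identical(o, seq_len(nrow(blocks))))
      stop("ordering error: blocks must be sorted by reference coordinate")
  }
  res <- list()
  emit <- function(category, b_chrom, rs, re, q_chrom, qs, qe, size, source) {
    res[[length(res) + 1L]] <<- data.frame(
      category = category, ref_chrom = b_chrom, ref_start = min(rs, re),
      ref_end = max(rs, re), qry_chrom = q_chrom, qry_start = min(qs, qe),
      qry_end = max(qs, qe), size = size, source = source,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(blocks))) {
    sg <- block_segments(blocks, i)
    g <- sg$gaps
    for (j in seq_len(nrow(g))) {
      d <- g$qry_gap[j] - g$ref_gap[j]
      if (abs(d) < config$large_variant_min) next
      emit(if (d > 0) "insertion" else "deletion",
           blocks$ref_chrom[i], g$ref_pos[j], g$ref_pos[j] + g$ref_gap[j],
           blocks$qry_chrom[i], g$qry_pos[j], g$qry_pos[j] + g$qry_gap[j],
           abs(d), "within_block")
    }
  }
  key <- paste(blocks$ref_chrom, blocks$qry_chrom, blocks$strand)
  for (kk in unique(key)) {
    sel <- which(key == kk)
    if (length(sel) < 2) next
    for (m in seq_len(length(sel) - 1)) {
      b1 <- blocks[sel[m], ]; b2 <- blocks[sel[m + 1], ]
      dr <- b2$ref_start - b1$ref_end
      dq <- if (b1$strand == "+") b2$qry_start - b1$qry_end
            else b1$qry_start - b2$qry_end
      if (dr > config$max_join || abs(dq) > config$max_join) next
      ## negative gaps no larger than the breakpoint-ambiguity scale are
      ## chance-match extension across the junction, not overlap evidence
      if (dr < 0 && dr >= -config$repeat_gap_min) dr <- 0
      if (dq < 0 && dq >= -config$repeat_gap_min) dq <- 0
      size <- abs(dq - dr)
      if (size < config$large_variant_min) next
      if (dr >= 0 && dq >= 0) {
        cat_ <- if (min(dr, dq) <= config$repeat_gap_min) {
          if (dq > dr) "insertion" else "deletion"
        } else {
          if (dq > dr) "repeat_expansion" else "repeat_contraction"
        }
      } else if (dr < 0 && dq >= 0) {
        cat_ <- "tandem_expansion"
      } else if (dq < 0 && dr >= 0) {
        cat_ <- "tandem_contraction"
      } else {
        cat_ <- "unclassified"
      }
      qa <- if (b1$strand == "+") c(b1$qry_end, b2$qry_start)
            else c(b2$qry_end, b1$qry_start)
      emit(cat_, b1$ref_chrom, b1$ref_end, b2$ref_start,
           b1$qry_chrom, qa[1], qa[2], size, "between_blocks")
    }
  }
  if (length(res) == 0L)
    return(data.frame(category = character(), ref_chrom = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      qry_chrom = character(), qry_start = numeric(),
                      qry_end = numeric(), size = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
}

#' Signed indel size spectrum by coding stratum
#'
#' @param variants Annotated variant data.frame ([annotate_effects()]).
#' @return data.frame(stratum, size, count): size is positive for
#'   insertions, negative for deletions; stratum is "cds" for variants with
#'   a coding effect and "intergenic" otherwise.
#' @export
indel_size_spectrum <- function(variants) {
  ind <- variants[variants$vtype %in% c("ins", "del"), , drop = FALSE]
  if (nrow(ind) == 0L)
    return(data.frame(stratum = character(), size = numeric(),
                      count = numeric(), stringsAsFactors = FALSE))
  size <- ifelse(ind$vtype == "ins", nchar(ind$alt), -nchar(ind$ref))
  stratum <- ifelse(!is.na(ind$gene_id) & ind$effect %in% c("frameshift", "inframe"),
                    "cds", "intergenic")
  tab <- as.data.frame(table(stratum = stratum, size = size),
                       stringsAsFactors = FALSE)
  tab$size <- as.numeric(tab$size)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  rownames(tab) <- NULL
  tab[order(tab$stratum, tab$size), , drop = FALSE]
}
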