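## Readers and writers. This is the only layer where 1-based inclusive
## coordinates (FASTA-adjacent formats, show-coords, GFF3, VCF) appear;
## everything internal is 0-based half-open.

#' Read a genome from FASTA
#' @param path FASTA file.
#' @param genome_id Label for the genome (defaults to the file name).
#' @return A `genome_seq` object.
#' @export
read_genome_fasta <- function(path, genome_id = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readDNAStringSet(path)
  genome_seq(genome_id, setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' Write a genome to FASTA (60-column wrapped)
#' @param g A `genome_seq`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

## ---- alignment coordinate files (show-coords tab dialect) ----------------

#' Read pairwise alignment blocks from a show-coords tab file
#'
#' Expects the tab dialect with columns S1 E1 S2 E2 LEN1 LEN2 \%IDY ref qry
#' (1-based inclusive). Reverse-strand records (S2 > E2) are normalized to
#' ascending query coordinates with strand "-". When LEN1 and LEN2 differ,
#' the length difference is recorded as a single unplaced indel gap at the
#' block end so that block bookkeeping stays exact; files produced by the
#' built-in aligner are written gap-balanced.
#'
#' @param path Coordinate file.
#' @return An alignment block data.frame (see [chain_and_extend()]).
#' @export
read_alignment_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blocks())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("parse error at line ", i, ": expected 9 tab-separated fields")
    v <- suppressWarnings(as.numeric(f[1:7]))
    if (anyNA(v))
      stop("parse error at line ", i, ": non-numeric coordinate field")
    s1 <- v[1]; e1 <- v[2]; s2 <- v[3]; e2 <- v[4]; idy <- v[7]
    if (s1 > e1) stop("parse error at line ", i, ": S1 > E1")
    strand <- if (s2 <= e2) "+" else "-"
    qlo <- min(s2, e2); qhi <- max(s2, e2)
    rs <- s1 - 1; re <- e1; qs <- qlo - 1; qe <- qhi
    rl <- re - rs; ql <- qe - qs
    gaps <- empty_gaps()
    if (rl != ql) {
      d <- ql - rl
      gaps <- data.frame(ref_pos = re, ref_gap = max(0, -d), qry_gap = max(0, d))
    }
    cols <- min(rl, ql)
    out[[i]] <- list(ref_chrom = f[8], ref_start = rs, ref_end = re,
                     qry_chrom = f[9], qry_start = qs, qry_end = qe,
                     strand = strand, matches = idy / 100 * cols,
                     columns = cols, identity = idy / 100,
                     gaps = list(gaps))
  }
  df <- do.call(rbind, lapply(out, function(x) {
    d <- data.frame(x[setdiff(names(x), "gaps")], stringsAsFactors = FALSE)
    d
  }))
  df$gaps <- lapply(out, function(x) x$gaps[[1]])
  as_blocks(df)
}

#' Write alignment blocks in the show-coords tab dialect
#' @param blocks Alignment block data.frame.
#' @param path Output file.
#' @export
write_alignment_coords <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(blocks) == 0L) return(invisible(path))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    s2 <- b$qry_start + 1; e2 <- b$qry_end
    if (b$strand == "-") { tmp <- s2; s2 <- e2; e2 <- tmp }
    writeLines(sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                       as.integer(b$ref_start + 1), as.integer(b$ref_end),
                       as.integer(s2), as.integer(e2),
                       as.integer(b$ref_end - b$ref_start),
                       as.integer(b$qry_end - b$qry_start),
                       100 * b$identity, b$ref_chrom, b$qry_chrom), con)
  }
  invisible(path)
}

## ---- GFF3 subset ---------------------------------------------------------

#' Write gene models as a GFF3 subset
#'
#' Emits gene, mRNA, exon and CDS features with `ID=`/`Parent=` attributes.
#' @param gm A `gene_models` object.
#' @param path Output file.
#' @param source Source column label.
#' @export
write_gff3 <- function(gm, path, source = "tripan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    ex <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    cd <- gm$cds[gm$cds$gene_id == g$gene_id, , drop = FALSE]
    lo <- min(ex$start); hi <- max(ex$end)
    row <- function(type, s, e, attr)
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", g$chrom, source, type,
              as.integer(s + 1), as.integer(e), g$strand, attr)
    writeLines(row("gene", lo, hi, paste0("ID=", g$gene_id)), con)
    mid <- paste0(g$gene_id, ".t1")
    writeLines(row("mRNA", lo, hi, paste0("ID=", mid, ";Parent=", g$gene_id)), con)
    for (j in seq_len(nrow(ex)))
      writeLines(row("exon", ex$start[j], ex$end[j], paste0("Parent=", mid)), con)
    for (j in seq_len(nrow(cd)))
      writeLines(row("CDS", cd$start[j], cd$end[j], paste0("Parent=", mid)), con)
  }
  invisible(path)
}

#' Read the GFF3 subset written by [write_gff3()]
#' @param path GFF3 file with gene/mRNA/exon/CDS rows and ID=/Parent=.
#' @return A `gene_models` object.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) < 9L)
  if (length(bad)) stop("parse error at line ", bad[1], ": expected 9 fields")
  m <- do.call(rbind, f)
  type <- m[, 3]
  attr_field <- function(a, key) {
    val <- rep(NA_character_, length(a))
    has <- grepl(paste0("(^|;)", key, "="), a)
    val[has] <- sub(paste0(".*(^|;)", key, "=([^;]+).*"), "\\2", a[has])
    val
  }
  ids <- attr_field(m[, 9], "ID")
  parents <- attr_field(m[, 9], "Parent")
  gene_rows <- type == "gene"
  mrna_rows <- type == "mRNA"
  mrna_gene <- setNames(parents[mrna_rows], ids[mrna_rows])
  genes <- data.frame(gene_id = ids[gene_rows], chrom = m[gene_rows, 1],
                      strand = m[gene_rows, 7], stringsAsFactors = FALSE)
  feat <- function(what) {
    r <- type == what
    data.frame(gene_id = unname(mrna_gene[parents[r]]), chrom = m[r, 1],
               start = as.numeric(m[r, 4]) - 1, end = as.numeric(m[r, 5]),
               stringsAsFactors = FALSE)
  }
  gene_models(genes, feat("exon"), feat("CDS"))
}

## ---- BED / depth / truth / VCF -------------------------------------------

#' Write intervals as BED
#' @param x Interval data.frame; extra columns (e.g. name, score) appended.
#' @param path Output file.
#' @param extra Character vector of extra column names to include.
#' @export
write_bed <- function(x, path, extra = character()) {
  cols <- c("chrom", "start", "end", extra)
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a depth track as BED4
#' @param track A `depth_track` object.
#' @param path Output file.
#' @export
write_depth_bed <- function(track, path) {
  write_bed(track$windows, path, extra = "depth")
}

#' Read a BED4 depth track
#' @param path BED4 file (chrom, start, end, depth).
#' @param genome_id Label.
#' @return A `depth_track` object.
#' @export
read_depth_bed <- function(path, genome_id = "genome") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "depth"),
                   stringsAsFactors = FALSE)
  depth_track(genome_id, df)
}

#' Write a truth set as TSV
#' @param truth Truth event data.frame.
#' @param path Output file.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth set TSV
#' @param path File written by [write_truth_tsv()].
#' @return Truth event data.frame.
#' @export
read_truth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write variants as minimal VCF 4.2
#'
#' Indels are anchored on the preceding reference base as VCF requires;
#' effect annotations (when present) are written as `EFF=` in INFO.
#'
#' @param variants Variant data.frame from [call_small_variants()].
#' @param genome The reference `genome_seq` (for anchor bases).
#' @param path Output file.
#' @export
write_vcf <- function(variants, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##reference=%s", genome$genome_id),
               "##INFO=<ID=EFF,Number=.,Type=String,Description=\"Predicted effect\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      chrom_seq <- genome$seqs[[v$chrom]]
      if (v$vtype == "snp") {
        pos <- v$pos + 1; ref <- v$ref; alt <- v$alt
      } else {
        anchor <- if (v$pos > 0) substring(chrom_seq, v$pos, v$pos) else "N"
        pos <- max(1, v$pos)
        if (v$vtype == "del") { ref <- paste0(anchor, v$ref); alt <- anchor }
        else { ref <- anchor; alt <- paste0(anchor, v$alt) }
      }
      info <- if (!is.null(variants$effect) && !is.na(v$effect))
        paste0("EFF=", v$effect) else "."
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                         v$chrom, as.integer(pos), ref, alt, info), con)
    }
  }
  invisible(path)
}
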