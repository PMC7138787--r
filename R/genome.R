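## Genome and gene-model containers.

#' Construct a genome object
#'
#' A genome is a set of named chromosome sequences plus an identifier.
#' Sequences are stored as upper-case character strings over the alphabet
#' A, C, G, T, N.
#'
#' @param genome_id Genome label (e.g. "SAT").
#' @param seqs Named character vector of chromosome sequences.
#' @return An object of class `genome_seq`.
#' @export
genome_seq <- function(genome_id, seqs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  seqs <- toupper(unlist(seqs))
  if (length(seqs) > 0) {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("chromosome names must be present and unique")
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) stop("sequence alphabet must be a subset of {A,C,G,T,N}")
  }
  structure(list(genome_id = genome_id, seqs = seqs), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("genome '%s': %d chromosome(s), %s bp total\n", x$genome_id,
              length(x$seqs), format(genome_length(x), big.mark = ",")))
  invisible(x)
}

#' Total genome length in bp
#' @param g A `genome_seq` object.
#' @return Total sequence length.
#' @export
genome_length <- function(g) sum(as.numeric(nchar(g$seqs)))

#' Per-chromosome lengths
#' @param g A `genome_seq` object.
#' @return Named numeric vector of chromosome lengths.
#' @export
chrom_lengths <- function(g) setNames(as.numeric(nchar(g$seqs)), names(g$seqs))

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Translate a coding sequence
#' @param x A DNA string whose length is a multiple of 3.
#' @return Amino-acid string (stop codon as `*`).
#' @export
translate_cds <- function(x) {
  stopifnot(nchar(x) %% 3 == 0)
  # plain genetic code: the first codon is not treated as an initiator
  # (a mutated start codon must translate to its own amino acid)
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

random_dna <- function(n, gc = 0.43) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Construct gene models
#'
#' Gene models are stored as three tables: one row per gene (id, chromosome,
#' strand) plus exon and CDS interval tables in 0-based half-open
#' coordinates. CDS intervals must lie within the exons of their gene.
#'
#' @param genes data.frame(gene_id, chrom, strand).
#' @param exons data.frame(gene_id, chrom, start, end).
#' @param cds data.frame(gene_id, chrom, start, end).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)),
            all(c("gene_id", "start", "end") %in% names(cds)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  obj <- structure(list(genes = genes, exons = exons, cds = cds),
                   class = "gene_models")
  if (nrow(cds) > 0) {
    stray <- interval_subtract(cds[, c("chrom", "start", "end")],
                               exons[, c("chrom", "start", "end")])
    if (interval_bp(stray) > 0)
      stop("CDS intervals extend outside exons")
  }
  obj
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene models: %d genes, %d exons, %d CDS intervals\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

n_genes <- function(gm) nrow(gm$genes)

#' Spliced CDS sequence of a gene
#'
#' Concatenates the CDS intervals in transcription order (reverse
#' complemented for minus-strand genes).
#'
#' @param genome A `genome_seq`.
#' @param gm A `gene_models` object.
#' @param gene_id Gene identifier.
#' @return The spliced coding sequence (5' to 3').
#' @export
gene_cds_seq <- function(genome, gm, gene_id) {
  g <- gm$genes[gm$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene ", gene_id)
  cd <- gm$cds[gm$cds$gene_id == gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  chrom_seq <- genome$seqs[[g$chrom]]
  if (is.null(chrom_seq)) stop("gene ", gene_id, " on unknown chromosome")
  parts <- substring(chrom_seq, cd$start + 1, cd$end)
  spliced <- paste(parts, collapse = "")
  if (g$strand == "-") spliced <- revcomp(spliced)
  spliced
}
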