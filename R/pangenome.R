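## Tri-genome comparison: project the three pairwise one-to-one alignment
## sets onto a reference-centric partition of the pan-genome.
##
## The first genome ("sat") is the pivot: its bases are core (aligned to
## both others), dispensable (aligned to exactly one) or pivot-specific.
## Bases of the second genome ("ruf") not aligned to the pivot are
## dispensable when the second-third alignment covers them, else
## ruf-specific. Bases of the third genome ("niv") aligned to neither are
## niv-specific. This makes the additivity identity
## pan = core + dispensable + specific exact by construction; shared
## ruf/niv sequence absent from the pivot is counted once, owned by ruf.

#' Build the tri-genome pan-genome partition
#'
#' @param sat_ruf One-to-one blocks, reference = sat, query = ruf.
#' @param sat_niv One-to-one blocks, reference = sat, query = niv.
#' @param ruf_niv One-to-one blocks, reference = ruf, query = niv.
#' @param genome_lengths list(sat=, ruf=, niv=) of named per-chromosome
#'   length vectors.
#' @return An object of class `pangenome`: list(segments, stats, coverage).
#'   `segments` carries owner, chrom, start, end, presence flags (sat, ruf,
#'   niv) and klass (core/dispensable/specific); `stats` the bp totals and
#'   pairwise union sizes.
#' @export
build_pangenome <- function(sat_ruf, sat_niv, ruf_niv, genome_lengths) {
  stopifnot(all(c("sat", "ruf", "niv") %in% names(genome_lengths)))
  check_bounds <- function(blocks, side, lens) {
    if (nrow(blocks) == 0) return(invisible())
    chrom <- blocks[[paste0(side, "_chrom")]]
    ends <- blocks[[paste0(side, "_end")]]
    if (any(!chrom %in% names(lens)) || any(ends > lens[chrom] + 1e-9))
      stop("consistency error: block coordinates exceed stated genome lengths")
  }
  check_bounds(sat_ruf, "ref", genome_lengths$sat)
  check_bounds(sat_niv, "ref", genome_lengths$sat)
  check_bounds(sat_ruf, "qry", genome_lengths$ruf)
  check_bounds(ruf_niv, "ref", genome_lengths$ruf)
  check_bounds(sat_niv, "qry", genome_lengths$niv)
  check_bounds(ruf_niv, "qry", genome_lengths$niv)

  cov <- list(sat_ruf = blocks_ref_coverage(sat_ruf),
              sat_niv = blocks_ref_coverage(sat_niv),
              ruf_sat = blocks_qry_coverage(sat_ruf),
              ruf_niv = blocks_ref_coverage(ruf_niv),
              niv_sat = blocks_qry_coverage(sat_niv),
              niv_ruf = blocks_qry_coverage(ruf_niv))

  core <- interval_intersect(cov$sat_ruf, cov$sat_niv)
  disp_sat_r <- interval_subtract(cov$sat_ruf, cov$sat_niv)
  disp_sat_n <- interval_subtract(cov$sat_niv, cov$sat_ruf)
  spec_sat <- interval_complement(interval_union(cov$sat_ruf, cov$sat_niv),
                                  genome_lengths$sat)
  unal_ruf <- interval_complement(cov$ruf_sat, genome_lengths$ruf)
  disp_ruf <- interval_intersect(unal_ruf, cov$ruf_niv)
  spec_ruf <- interval_subtract(unal_ruf, cov$ruf_niv)
  spec_niv <- interval_complement(interval_union(cov$niv_sat, cov$niv_ruf),
                                  genome_lengths$niv)

  seg <- function(x, owner, sat, ruf, niv, klass) {
    if (nrow(x) == 0) return(NULL)
    data.frame(owner = owner, x, sat = sat, ruf = ruf, niv = niv,
               klass = klass, stringsAsFactors = FALSE)
  }
  segments <- rbind(
    seg(core, "sat", TRUE, TRUE, TRUE, "core"),
    seg(disp_sat_r, "sat", TRUE, TRUE, FALSE, "dispensable"),
    seg(disp_sat_n, "sat", TRUE, FALSE, TRUE, "dispensable"),
    seg(spec_sat, "sat", TRUE, FALSE, FALSE, "specific"),
    seg(disp_ruf, "ruf", FALSE, TRUE, TRUE, "dispensable"),
    seg(spec_ruf, "ruf", FALSE, TRUE, FALSE, "specific"),
    seg(spec_niv, "niv", FALSE, FALSE, TRUE, "specific"))
  rownames(segments) <- NULL

  sat_len <- sum(genome_lengths$sat)
  ruf_len <- sum(genome_lengths$ruf)
  niv_len <- sum(genome_lengths$niv)
  unal_niv_sat <- niv_len - interval_bp(cov$niv_sat)
  unal_niv_ruf <- niv_len - interval_bp(cov$niv_ruf)
  stats <- list(
    core_bp = interval_bp(core),
    dispensable_bp = interval_bp(disp_sat_r) + interval_bp(disp_sat_n) +
      interval_bp(disp_ruf),
    specific_bp = c(sat = interval_bp(spec_sat), ruf = interval_bp(spec_ruf),
                    niv = interval_bp(spec_niv)),
    genome_bp = c(sat = sat_len, ruf = ruf_len, niv = niv_len),
    pan_bp = sat_len + interval_bp(unal_ruf) + interval_bp(spec_niv),
    two_genome_union_bp = c(
      sat_ruf = sat_len + interval_bp(unal_ruf),
      sat_niv = sat_len + unal_niv_sat,
      ruf_niv = ruf_len + unal_niv_ruf))
  total <- stats$core_bp + stats$dispensable_bp + sum(stats$specific_bp)
  if (abs(total - stats$pan_bp) > 1e-6)
    stop("internal error: pan-genome additivity violated")
  structure(list(segments = segments, stats = stats, coverage = cov,
                 genome_lengths = genome_lengths), class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  s <- x$stats
  cat(sprintf("pan-genome: %s bp\n  core        %s bp (%.1f%%)\n  dispensable %s bp (%.1f%%)\n  specific    %s bp (%.1f%%)\n",
              format(s$pan_bp, big.mark = ","),
              format(s$core_bp, big.mark = ","), 100 * s$core_bp / s$pan_bp,
              format(s$dispensable_bp, big.mark = ","),
              100 * s$dispensable_bp / s$pan_bp,
              format(sum(s$specific_bp), big.mark = ","),
              100 * sum(s$specific_bp) / s$pan_bp))
  invisible(x)
}

#' Classify genes as core / dispensable / specific
#'
#' A gene is present in its own genome and in every other genome to which
#' at least `presence_frac` of its CDS bases are aligned; presence in all
#' three genomes makes it core, in exactly two dispensable, in one
#' specific.
#'
#' @param genes_by_genome list(sat=, ruf=, niv=) of `gene_models`.
#' @param pg A `pangenome` object (for the pairwise coverage sets).
#' @param presence_frac CDS coverage fraction required for presence.
#' @return data.frame(genome, gene_id, in_sat, in_ruf, in_niv, klass).
#' @export
classify_gene_membership <- function(genes_by_genome, pg, presence_frac = 0.8) {
  ids <- c("sat", "ruf", "niv")
  stopifnot(all(ids %in% names(genes_by_genome)))
  ## per-gene CDS bp covered by one coverage set, computed in one overlap
  covered_by_gene <- function(cds, cover) {
    tot <- tapply(cds$end - cds$start, cds$gene_id, sum)
    got <- setNames(rep(0, length(tot)), names(tot))
    if (nrow(cover) > 0) {
      cg <- iv_to_gr(cds[, c("chrom", "start", "end")])
      vg <- GenomicRanges::reduce(iv_to_gr(cover))
      hits <- GenomicRanges::findOverlaps(cg, vg)
      if (length(hits) > 0) {
        q <- S4Vectors::queryHits(hits)
        w <- GenomicRanges::width(IRanges::pintersect(
          GenomicRanges::ranges(cg)[q],
          GenomicRanges::ranges(vg)[S4Vectors::subjectHits(hits)]))
        add <- tapply(w, cds$gene_id[q], sum)
        got[names(add)] <- add
      }
    }
    got / tot
  }
  out <- list()
  for (g in ids) {
    gm <- genes_by_genome[[g]]
    if (nrow(gm$genes) == 0) next
    if (!all(gm$cds$chrom %in% names(pg$genome_lengths[[g]])))
      stop("consistency error: gene on unknown chromosome")
    others <- setdiff(ids, g)
    pres <- matrix(FALSE, nrow(gm$genes), 3,
                   dimnames = list(gm$genes$gene_id, ids))
    pres[, g] <- TRUE
    for (o in others) {
      frac <- covered_by_gene(gm$cds, pg$coverage[[paste0(g, "_", o)]])
      pres[names(frac), o] <- frac >= presence_frac
    }
    klass <- c("specific", "dispensable", "core")[rowSums(pres)]
    out[[length(out) + 1L]] <- data.frame(
      genome = g, gene_id = rownames(pres), in_sat = pres[, "sat"],
      in_ruf = pres[, "ruf"], in_niv = pres[, "niv"], klass = klass,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pan-genome summary fractions
#'
#' @param stats The `stats` element of a `pangenome` object.
#' @param gene_counts Optional named counts (core, dispensable, specific)
#'   of gene classes to convert to fractions as well.
#' @return Named list of percentages rounded half-up to 0.1.
#' @export
pan_fractions <- function(stats, gene_counts = NULL) {
  if (stats$pan_bp <= 0) stop("undefined fraction: pan size is zero")
  out <- list(
    core_pct = round_half_up(100 * stats$core_bp / stats$pan_bp, 1),
    two_genome_avg_pct = round_half_up(
      100 * mean(stats$two_genome_union_bp) / stats$pan_bp, 1),
    dispensable_pct = round_half_up(
      100 * stats$dispensable_bp / stats$pan_bp, 1),
    specific_pct = round_half_up(
      100 * sum(stats$specific_bp) / stats$pan_bp, 1))
  if (!is.null(gene_counts)) {
    gene_counts <- unlist(gene_counts)
    tot <- sum(gene_counts)
    for (k in names(gene_counts))
      out[[paste0(k, "_gene_pct")]] <-
        round_half_up(100 * gene_counts[[k]] / tot, 1)
  }
  out
}
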