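## Presence-absence variation (four classes) and read-depth copy-number
## calling, with gene-level assignment.

#' Call PAV segments present in the query, absent from the reference
#'
#' Query intervals without aligned coverage and longer than `pav_min_len`
#' are re-searched against the reference with the anchor aligner; a
#' candidate survives when it has no hit or its best-scoring realignment
#' identity is at most `pav_max_identity`. Query genes with more than
#' `pav_gene_cds_frac` of their CDS bases inside surviving segments are
#' reported as query-specific.
#'
#' @param qry Query `genome_seq` (the genome carrying the sequence).
#' @param blocks One-to-one blocks with `qry` as query, reference `ref`.
#' @param ref Reference `genome_seq`.
#' @param config A [threshold_config()].
#' @param klass Class label for the records (e.g. "RS10", "NS10").
#' @param genes Optional query `gene_models` for gene assignment.
#' @return list(records = data.frame(klass, chrom, start, end, length,
#'   best_identity), specific_genes = character vector).
#' @export
call_pav_present_in_query <- function(qry, blocks, ref,
                                      config = threshold_config(),
                                      klass = "RS10", genes = NULL) {
  qcov <- blocks_qry_coverage(blocks)
  cand <- interval_complement(qcov, chrom_lengths(qry))
  cand <- cand[cand$end - cand$start > config$pav_min_len, , drop = FALSE]
  best <- rep(NA_real_, nrow(cand))
  if (nrow(cand) > 0) {
    seqs <- substring(qry$seqs[cand$chrom], cand$start + 1, cand$end)
    names(seqs) <- sprintf("cand_%d", seq_len(nrow(cand)))
    cg <- genome_seq("candidates", seqs)
    anchors <- find_anchors(ref, cg, config$anchor_k)
    rb <- chain_and_extend(anchors, ref, cg, config)
    if (nrow(rb) > 0) {
      w <- rb$identity * rb$columns
      for (i in seq_len(nrow(cand))) {
        sel <- rb$qry_chrom == names(seqs)[i]
        if (any(sel)) best[i] <- rb$identity[sel][which.max(w[sel])]
      }
    }
  }
  keep <- is.na(best) | best <= config$pav_max_identity
  records <- data.frame(klass = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        length = numeric(0), best_identity = numeric(0),
                        stringsAsFactors = FALSE)
  if (any(keep))
    records <- data.frame(klass = klass, chrom = cand$chrom[keep],
                          start = cand$start[keep], end = cand$end[keep],
                          length = cand$end[keep] - cand$start[keep],
                          best_identity = best[keep], stringsAsFactors = FALSE)
  specific_genes <- character(0)
  if (!is.null(genes) && nrow(records) > 0) {
    iv <- records[, c("chrom", "start", "end")]
    for (gid in genes$genes$gene_id) {
      cd <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
      if (nrow(cd) > 0 && covered_fraction(cd, iv) > config$pav_gene_cds_frac)
        specific_genes <- c(specific_genes, gid)
    }
  }
  list(records = records, specific_genes = specific_genes)
}

#' Call PAV segments present in the reference, absent from the query
#'
#' Reference stretches with zero query alignment coverage are merged when
#' closer than `pav_merge_gap` and reported when longer than `pav_min_len`.
#' Reference genes overlapping the merged blocks over at least
#' `pav_gene_len_frac` of their span are reported as reference-specific
#' relative to the query.
#'
#' @param ref Reference `genome_seq`.
#' @param blocks One-to-one blocks with `ref` as reference.
#' @param config A [threshold_config()].
#' @param klass Class label (e.g. "RS01", "NS01").
#' @param genes Optional reference `gene_models`.
#' @return list(records, specific_genes) as in
#'   [call_pav_present_in_query()] (best_identity is NA).
#' @export
call_pav_absent_in_query <- function(ref, blocks, config = threshold_config(),
                                     klass = "RS01", genes = NULL) {
  rcov <- blocks_ref_coverage(blocks)
  uncov <- interval_complement(rcov, chrom_lengths(ref))
  ## uncovered slivers at small-indel scale are deletion footprints already
  ## reported by the small-variant caller, not absence evidence
  uncov <- uncov[uncov$end - uncov$start > config$small_variant_max, , drop = FALSE]
  merged <- merge_intervals(uncov, config$pav_merge_gap)
  merged <- merged[merged$end - merged$start > config$pav_min_len, , drop = FALSE]
  records <- data.frame(klass = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        length = numeric(0), best_identity = numeric(0),
                        stringsAsFactors = FALSE)
  if (nrow(merged) > 0)
    records <- data.frame(klass = klass, chrom = merged$chrom,
                          start = merged$start, end = merged$end,
                          length = merged$end - merged$start,
                          best_identity = NA_real_, stringsAsFactors = FALSE)
  specific_genes <- character(0)
  if (!is.null(genes) && nrow(records) > 0) {
    iv <- records[, c("chrom", "start", "end")]
    for (gid in genes$genes$gene_id) {
      ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
      span <- data.frame(chrom = ex$chrom[1], start = min(ex$start),
                         end = max(ex$end))
      if (covered_fraction(span, iv) >= config$pav_gene_len_frac)
        specific_genes <- c(specific_genes, gid)
    }
  }
  list(records = records, specific_genes = specific_genes)
}

#' Call copy-number regions from a depth track
#'
#' Window depths are normalized by the genome median; runs of adjacent
#' windows whose normalized depth falls outside `[cnv_t_loss, cnv_t_gain]`
#' in the same direction are merged, and runs of at least `cnv_min_len` bp
#' are reported. Calls depend on depth only through the ratio, so they are
#' invariant under uniform rescaling of the track.
#'
#' @param depth A `depth_track`.
#' @param config A [threshold_config()].
#' @return data.frame(chrom, start, end, norm_depth, call).
#' @export
call_cnv <- function(depth, config = threshold_config()) {
  w <- depth$windows
  if (is.null(w) || nrow(w) == 0) stop("input error: empty depth track")
  med <- median(w$depth)
  if (med <= 0) stop("input error: median depth is zero")
  norm <- w$depth / med
  flag <- norm > config$cnv_t_gain | norm < config$cnv_t_loss
  dir <- ifelse(norm > 1, "gain", "loss")
  out <- list()
  for (chrom in unique(w$chrom)) {
    sel <- which(w$chrom == chrom)
    sel <- sel[order(w$start[sel])]
    run_start <- NA
    run_dir <- ""
    run_norm <- c()
    last_end <- NA
    flush <- function(end_pos) {
      if (!is.na(run_start) && end_pos - run_start >= config$cnv_min_len)
        out[[length(out) + 1L]] <<- data.frame(
          chrom = chrom, start = run_start, end = end_pos,
          norm_depth = mean(run_norm), call = run_dir,
          stringsAsFactors = FALSE)
    }
    for (i in sel) {
      if (flag[i] && !is.na(run_start) && run_dir == dir[i] &&
          w$start[i] == last_end) {
        run_norm <- c(run_norm, norm[i])
        last_end <- w$end[i]
      } else {
        if (!is.na(run_start)) flush(last_end)
        if (flag[i]) {
          run_start <- w$start[i]; run_dir <- dir[i]
          run_norm <- norm[i]; last_end <- w$end[i]
        } else run_start <- NA
      }
    }
    if (!is.na(run_start)) flush(last_end)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      norm_depth = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Gene-level copy-number calls
#'
#' A gene is affected when more than `cnv_gene_exon_frac` of its exon bases
#' lie inside copy-number regions; the call is "both" when gain and loss
#' regions each overlap its exons, else the direction of the overlapping
#' regions.
#'
#' @param genes A `gene_models` object.
#' @param cnv_regions Output of [call_cnv()].
#' @param config A [threshold_config()].
#' @return data.frame(gene_id, call) with call in gain/loss/both/none.
#' @export
classify_cnv_genes <- function(genes, cnv_regions, config = threshold_config()) {
  out <- list()
  gain <- cnv_regions[cnv_regions$call == "gain", , drop = FALSE]
  loss <- cnv_regions[cnv_regions$call == "loss", , drop = FALSE]
  for (gid in genes$genes$gene_id) {
    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    fu <- covered_fraction(ex, cnv_regions[, c("chrom", "start", "end")])
    call <- "none"
    if (fu > config$cnv_gene_exon_frac) {
      fg <- if (nrow(gain) > 0) covered_fraction(ex, gain[, c("chrom", "start", "end")]) else 0
      fl <- if (nrow(loss) > 0) covered_fraction(ex, loss[, c("chrom", "start", "end")]) else 0
      call <- if (fg > 0 && fl > 0) "both" else if (fg > 0) "gain" else "loss"
    }
    out[[length(out) + 1L]] <- data.frame(gene_id = gid, call = call,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
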