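#' Pipeline threshold configuration
#'
#' Central container for every tunable threshold of the comparison pipeline.
#' Defaults follow the published filtering rules of assembly-based rice
#' pan-genome comparisons: presence-absence segments must exceed 100 bp and
#' realign at below 95 percent identity, uncovered reference stretches closer
#' than 500 bp are merged, copy-number regions must span at least 500 bp,
#' variants of 10 bp or less are "small" and larger ones enter the structural
#' classifier, and genes are assigned to events by coding-sequence or exon
#' coverage fractions.
#'
#' The published read-depth bounds for copy-number calls ("below 1.2 or above
#' 1.8 of the mean") cannot both act on a depth *ratio* whose neutral value is
#' 1.0 (every normal window would satisfy the loss bound), so the working
#' defaults are a loss threshold of 0.5 and a gain threshold of 1.5; the
#' printed pair is still available by setting `use_printed_cnv_thresholds =
#' TRUE`.
#'
#' @param pav_min_len Minimum presence-absence segment length (bp).
#' @param pav_max_identity Maximum best-hit realignment identity for a
#'   segment to stay genome-specific.
#' @param pav_merge_gap Uncovered reference stretches closer than this are
#'   merged before absence calling (bp; strict inequality).
#' @param pav_gene_cds_frac CDS fraction of a gene that must fall in
#'   specific sequence for a gene-level presence call.
#' @param pav_gene_len_frac Gene-length overlap fraction for absence calls.
#' @param cnv_min_len Minimum copy-number region length (bp).
#' @param cnv_t_loss,cnv_t_gain Working normalized-depth thresholds.
#' @param use_printed_cnv_thresholds Use the published 1.2/1.8 bounds
#'   instead of the working 0.5/1.5 pair.
#' @param cnv_gene_exon_frac Exon-coverage fraction for gene-level CNV calls.
#' @param large_variant_min Minimum size (bp) of a "large" variant.
#' @param small_variant_max Maximum size (bp) of a small indel.
#' @param repeat_gap_min Between-block gap size (bp) above which both-sided
#'   gaps are repeat-like rather than plain indels.
#' @param anchor_k Anchor k-mer size (odd, 11-31).
#' @param min_chain_len Minimum anchored bp for a chain to be kept.
#' @param max_join Maximum interstice (bp) bridged inside a chain; larger
#'   gaps split chains and are handled between blocks.
#' @param max_overlap_frac Overlap fraction tolerated between retained
#'   blocks during one-to-one filtering (overlaps are the tandem signal,
#'   so they are bounded, not trimmed).
#' @param presence_frac CDS fraction for pan-genome gene membership.
#' @param chain_gap_penalty Per-bp gap penalty in the chaining DP.
#' @return An object of class `tripan_config` (a validated list).
#' @export
threshold_config <- function(pav_min_len = 100,
                             pav_max_identity = 0.95,
                             pav_merge_gap = 500,
                             pav_gene_cds_frac = 0.5,
                             pav_gene_len_frac = 0.5,
                             cnv_min_len = 500,
                             cnv_t_loss = 0.5,
                             cnv_t_gain = 1.5,
                             use_printed_cnv_thresholds = FALSE,
                             cnv_gene_exon_frac = 0.8,
                             large_variant_min = 10,
                             small_variant_max = 10,
                             repeat_gap_min = 50,
                             anchor_k = 21,
                             min_chain_len = 100,
                             max_join = 10000,
                             max_overlap_frac = 0.5,
                             presence_frac = 0.8,
                             chain_gap_penalty = 0.01) {
  cfg <- list(pav_min_len = pav_min_len, pav_max_identity = pav_max_identity,
              pav_merge_gap = pav_merge_gap, pav_gene_cds_frac = pav_gene_cds_frac,
              pav_gene_len_frac = pav_gene_len_frac, cnv_min_len = cnv_min_len,
              cnv_t_loss = cnv_t_loss, cnv_t_gain = cnv_t_gain,
              use_printed_cnv_thresholds = use_printed_cnv_thresholds,
              cnv_gene_exon_frac = cnv_gene_exon_frac,
              large_variant_min = large_variant_min,
              small_variant_max = small_variant_max,
              repeat_gap_min = repeat_gap_min, anchor_k = anchor_k,
              min_chain_len = min_chain_len, max_join = max_join,
              max_overlap_frac = max_overlap_frac, presence_frac = presence_frac,
              chain_gap_penalty = chain_gap_penalty)
  if (use_printed_cnv_thresholds) {
    cfg$cnv_t_loss <- 1.2
    cfg$cnv_t_gain <- 1.8
  }
  lens <- c("pav_min_len", "pav_merge_gap", "cnv_min_len", "large_variant_min",
            "small_variant_max", "repeat_gap_min", "min_chain_len", "max_join")
  for (f in lens) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive length")
  }
  fracs <- c("pav_max_identity", "pav_gene_cds_frac", "pav_gene_len_frac",
             "cnv_gene_exon_frac", "presence_frac")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop("config field '", f, "' must be a fraction in (0, 1]")
  }
  if (cfg$cnv_t_loss >= cfg$cnv_t_gain)
    stop("cnv_t_loss must be smaller than cnv_t_gain")
  if (cfg$anchor_k %% 2L != 1L || cfg$anchor_k < 11 || cfg$anchor_k > 31)
    stop("anchor_k must be odd and between 11 and 31")
  structure(cfg, class = "tripan_config")
}

#' @export
print.tripan_config <- function(x, ...) {
  cat("tripan threshold configuration:\n")
  for (f in names(x)) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}
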