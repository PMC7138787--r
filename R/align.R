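## Built-in pairwise whole-genome aligner: unique-k-mer anchors, diagonal
## collapsing, gap-bounded chaining, interstice closing, and ungapped
## end-extension. External show-coords files are the escape hatch for
## alignments produced elsewhere.

#' Find unique k-mer anchors between two genomes
#'
#' An anchor is an exact k-mer match whose k-mer (counting a k-mer and its
#' reverse complement together) occurs exactly once in each genome. Both
#' strands are searched; k must be odd so no k-mer is its own reverse
#' complement.
#'
#' @param ref,qry `genome_seq` objects.
#' @param k Odd k-mer size between 11 and 31.
#' @return data.frame(ref_chrom, ref_start, ref_end, qry_chrom, qry_start,
#'   qry_end, strand), sorted by reference position.
#' @export
find_anchors <- function(ref, qry, k = 21) {
  stopifnot(inherits(ref, "genome_seq"), inherits(qry, "genome_seq"))
  if (k %% 2 != 1 || k < 11 || k > 31)
    stop("parameter error: k must be odd and within [11, 31]")
  a <- find_anchors_cpp(unname(ref$seqs), unname(qry$seqs), as.integer(k))
  df <- data.frame(ref_chrom = names(ref$seqs)[a$ref_chrom_i],
                   ref_start = as.numeric(a$ref_start),
                   ref_end = as.numeric(a$ref_start) + k,
                   qry_chrom = names(qry$seqs)[a$qry_chrom_i],
                   qry_start = as.numeric(a$qry_start),
                   qry_end = as.numeric(a$qry_start) + k,
                   strand = ifelse(a$strand_i > 0, "+", "-"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$ref_chrom, df$ref_start, df$qry_chrom, df$qry_start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# Collapse runs of anchors on one diagonal into maximal exact segments.
collapse_anchors <- function(anchors, k) {
  if (nrow(anchors) == 0L) return(cbind(anchors, len = numeric()))
  plus <- anchors$strand == "+"
  diag <- ifelse(plus, anchors$ref_start - anchors$qry_start,
                 anchors$ref_start + anchors$qry_start)
  key <- paste(anchors$ref_chrom, anchors$qry_chrom, anchors$strand, diag)
  ord <- order(key, anchors$ref_start)
  a <- anchors[ord, , drop = FALSE]
  kv <- key[ord]
  new_run <- c(TRUE, kv[-1] != kv[-length(kv)] |
                 a$ref_start[-1] != a$ref_start[-nrow(a)] + 1)
  grp <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, nrow(a))
  out <- data.frame(ref_chrom = a$ref_chrom[first],
                    ref_start = a$ref_start[first],
                    ref_end = a$ref_start[last] + k,
                    qry_chrom = a$qry_chrom[first],
                    qry_start = pmin(a$qry_start[first], a$qry_start[last]),
                    qry_end = pmax(a$qry_start[first], a$qry_start[last]) + k,
                    strand = a$strand[first], stringsAsFactors = FALSE)
  out$len <- out$ref_end - out$ref_start
  out[order(out$ref_chrom, out$qry_chrom, out$strand, out$ref_start), ,
      drop = FALSE]
}

# Global alignment of one interstice; returns gap rows with offsets
# relative to the interstice start plus match/column counts.
align_interstice <- function(rstr, qstr) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rstr),
                                      Biostrings::DNAString(qstr),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 5, gapExtension = 2)
  rp <- charToRaw(as.character(Biostrings::alignedPattern(pa)))
  sp <- charToRaw(as.character(Biostrings::alignedSubject(pa)))
  dash <- charToRaw("-")
  rgap <- rp == dash  # reference missing: query insertion
  qgap <- sp == dash  # query missing: reference deletion
  aligned <- !rgap & !qgap
  ref_before <- cumsum(!rgap) - !rgap  # ref chars consumed before column
  state <- ifelse(rgap, 1L, ifelse(qgap, 2L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- empty_gaps()
  for (j in seq_along(r$values)) {
    if (r$values[j] == 0L) next
    off <- ref_before[starts[j]]
    if (r$values[j] == 1L)
      gaps <- rbind(gaps, data.frame(ref_pos = off, ref_gap = 0,
                                     qry_gap = r$lengths[j]))
    else
      gaps <- rbind(gaps, data.frame(ref_pos = off, ref_gap = r$lengths[j],
                                     qry_gap = 0))
  }
  list(gaps = gaps, matches = sum(aligned & rp == sp), columns = sum(aligned))
}

# Extract chain index lists from the DP result, best score first; chains
# truncate where they would reuse an anchor already claimed.
extract_chains <- function(dp, min_chain_len, weights) {
  n <- length(dp$score)
  used <- rep(FALSE, n)
  chains <- list()
  for (i in order(-dp$score)) {
    if (used[i]) next
    idx <- integer(0)
    j <- i
    while (j > 0 && !used[j]) {
      idx <- c(j, idx)
      used[j] <- TRUE
      j <- dp$parent[j]
    }
    if (sum(weights[idx]) >= min_chain_len) chains[[length(chains) + 1L]] <- idx
  }
  chains
}

#' Chain anchors and build alignment blocks
#'
#' Chains collinear anchors by a gap-bounded weighted dynamic programme,
#' closes the interstices between consecutive anchors (pure gaps become gap
#' records, equal-length interstices are compared base by base, small mixed
#' interstices are globally aligned), splits chains at repeat-like
#' interstices, and finally extends every block end by exact matching. The
#' end-extension is what lets two neighbouring blocks overlap on one genome
#' across a tandem duplication — the signature the structural-variant
#' classifier consumes.
#'
#' @param anchors Anchor table from [find_anchors()].
#' @param ref,qry The two `genome_seq` objects.
#' @param config A [threshold_config()].
#' @return Alignment block data.frame (see package overview), sorted by
#'   reference coordinate.
#' @export
chain_and_extend <- function(anchors, ref, qry, config = threshold_config()) {
  k_guess <- if (nrow(anchors) > 0)
    min(anchors$ref_end - anchors$ref_start) else config$anchor_k
  ca <- collapse_anchors(anchors, k = k_guess)
  if (nrow(ca) == 0L) return(empty_blocks())
  blocks <- list()
  grp <- interaction(ca$ref_chrom, ca$qry_chrom, ca$strand, drop = TRUE)
  for (g in levels(grp)) {
    sub <- ca[grp == g, , drop = FALSE]
    sub <- sub[order(sub$ref_start), , drop = FALSE]
    minus <- sub$strand[1] == "-"
    ys <- if (minus) -sub$qry_end else sub$qry_start
    ye <- if (minus) -sub$qry_start else sub$qry_end
    dp <- chain_dp_cpp(as.integer(sub$ref_start), as.integer(sub$ref_end),
                       as.integer(ys), as.integer(ye), sub$len,
                       config$max_join, config$chain_gap_penalty,
                       slack = k_guess)
    chains <- extract_chains(dp, config$min_chain_len, sub$len)
    rseq <- ref$seqs[[sub$ref_chrom[1]]]
    qseq <- qry$seqs[[sub$qry_chrom[1]]]
    for (idx in chains) {
      anc <- sub[idx, , drop = FALSE]
      blocks <- c(blocks,
                  build_chain_blocks(anc, rseq, qseq, minus, config))
    }
  }
  if (length(blocks) == 0L) return(empty_blocks())
  df <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(ref_chrom = b$ref_chrom, ref_start = b$rs, ref_end = b$re,
               qry_chrom = b$qry_chrom, qry_start = b$qlo, qry_end = b$qhi,
               strand = b$strand, matches = b$matches, columns = b$columns,
               identity = NA_real_, stringsAsFactors = FALSE)
  }))
  df$gaps <- lapply(blocks, function(b)
    if (nrow(b$gaps) > 0) b$gaps[order(b$gaps$ref_pos), , drop = FALSE]
    else empty_gaps())
  df <- extend_all_blocks(as_blocks(df), ref, qry)
  df$identity <- ifelse(df$columns > 0, df$matches / df$columns, 0)
  df <- df[order(df$ref_chrom, df$ref_start, df$qry_chrom, df$qry_start), ,
           drop = FALSE]
  rownames(df) <- NULL
  as_blocks(df)
}

# Walk one chain's anchors, bridging or splitting interstices. Anchor
# fields are pulled into plain vectors: this loop runs once per anchor
# over whole genomes.
build_chain_blocks <- function(anc, rseq, qseq, minus, config) {
  ars <- anc$ref_start; are <- anc$ref_end
  aqs <- anc$qry_start; aqe <- anc$qry_end; alen <- anc$len
  ref_chrom <- anc$ref_chrom[1]; qry_chrom <- anc$qry_chrom[1]
  strand <- anc$strand[1]
  out <- list()
  gp_pos <- gp_r <- gp_q <- numeric(0)
  rs <- ars[1]; re <- are[1]; qlo <- aqs[1]; qhi <- aqe[1]
  matches <- columns <- alen[1]
  close_block <- function() {
    out[[length(out) + 1L]] <<- list(
      ref_chrom = ref_chrom, qry_chrom = qry_chrom, strand = strand,
      rs = rs, re = re, qlo = qlo, qhi = qhi, matches = matches,
      columns = columns,
      gaps = data.frame(ref_pos = gp_pos, ref_gap = gp_r, qry_gap = gp_q))
  }
  for (i in seq_along(ars)[-1]) {
    a_rs <- ars[i]; a_re <- are[i]; a_qs <- aqs[i]; a_qe <- aqe[i]
    a_len <- alen[i]
    dr <- a_rs - re
    dq <- if (minus) qlo - a_qe else a_qs - qhi
    # trim breakpoint-ambiguity overlap off the incoming anchor front
    t <- max(0, -dr, -dq)
    if (t > 0) {
      if (t >= a_len) next
      a_rs <- a_rs + t
      if (minus) a_qe <- a_qe - t else a_qs <- a_qs + t
      a_len <- a_len - t
      dr <- dr + t
      dq <- dq + t
    }
    bridge <- dr >= 0 && dq >= 0 && max(dr, dq) <= config$max_join &&
      (min(dr, dq) <= config$repeat_gap_min ||
         (abs(dr - dq) < config$large_variant_min && max(dr, dq) <= 2000))
    if (!bridge) {
      close_block()
      gp_pos <- gp_r <- gp_q <- numeric(0)
      rs <- a_rs; re <- a_re; qlo <- a_qs; qhi <- a_qe
      matches <- columns <- a_len
      next
    }
    if (dr > 0 && dq == 0) {
      gp_pos <- c(gp_pos, re); gp_r <- c(gp_r, dr); gp_q <- c(gp_q, 0)
    } else if (dq > 0 && dr == 0) {
      gp_pos <- c(gp_pos, re); gp_r <- c(gp_r, 0); gp_q <- c(gp_q, dq)
    } else if (dr > 0 && dq > 0) {
      rstr <- substring(rseq, re + 1, a_rs)
      qstr <- if (minus) revcomp(substring(qseq, a_qe + 1, qlo))
              else substring(qseq, qhi + 1, a_qs)
      mm <- if (dr == dq) length(mismatch_positions_cpp(rstr, qstr)) else NA
      if (!is.na(mm) && !(dr >= 30 && dr <= 2000 && mm / dr > 0.3)) {
        matches <- matches + dr - mm
        columns <- columns + dr
      } else {
        ai <- align_interstice(rstr, qstr)
        if (nrow(ai$gaps) > 0) {
          gp_pos <- c(gp_pos, ai$gaps$ref_pos + re)
          gp_r <- c(gp_r, ai$gaps$ref_gap)
          gp_q <- c(gp_q, ai$gaps$qry_gap)
        }
        matches <- matches + ai$matches
        columns <- columns + ai$columns
      }
    }
    re <- a_re
    if (minus) qlo <- a_qs else qhi <- a_qe
    matches <- matches + a_len
    columns <- columns + a_len
  }
  close_block()
  out
}

extend_all_blocks <- function(blocks, ref, qry) {
  if (nrow(blocks) == 0L) return(blocks)
  key <- paste(blocks$ref_chrom, blocks$qry_chrom)
  for (kk in unique(key)) {
    sel <- which(key == kk)
    rc <- blocks$ref_chrom[sel[1]]
    qc <- blocks$qry_chrom[sel[1]]
    ext <- extend_blocks_cpp(ref$seqs[rc], qry$seqs[qc],
                             as.integer(blocks$ref_start[sel]),
                             as.integer(blocks$ref_end[sel]),
                             as.integer(blocks$qry_start[sel]),
                             as.integer(blocks$qry_end[sel]),
                             ifelse(blocks$strand[sel] == "+", 1L, -1L))
    blocks$ref_start[sel] <- ext$ref_start
    blocks$ref_end[sel] <- ext$ref_end
    blocks$qry_start[sel] <- ext$qry_start
    blocks$qry_end[sel] <- ext$qry_end
    blocks$matches[sel] <- blocks$matches[sel] + ext$added
    blocks$columns[sel] <- blocks$columns[sel] + ext$added
  }
  blocks
}

#' Reduce a block set to (near) one-to-one coverage
#'
#' Greedy selection by alignment weight (identity times aligned columns):
#' a block is kept while, on both genomes, it either overlaps already
#' retained blocks by at most `max_overlap_frac` of its span or
#' contributes at least `min_new_bp` of previously uncovered sequence.
#' Redundant alignments of the same region are dropped; blocks reaching
#' across a tandem duplication keep their bounded overlap (which the
#' structural-variant classifier needs) instead of being trimmed. With
#' `max_overlap_frac = 0` and `min_new_bp = Inf` the result is strictly
#' non-overlapping.
#'
#' @param blocks Alignment block data.frame.
#' @param max_overlap_frac Tolerated overlap fraction per side.
#' @param min_new_bp Alternative acceptance: new coverage contributed (bp).
#' @return Filtered block data.frame, sorted by reference coordinate.
#' @export
filter_one_to_one <- function(blocks, max_overlap_frac = 0.5,
                              min_new_bp = 100) {
  if (nrow(blocks) <= 1L) return(blocks)
  w <- blocks$identity * blocks$columns
  ord <- order(-w, blocks$ref_chrom, blocks$ref_start)
  kept_ref <- list(); kept_qry <- list()
  keep <- logical(nrow(blocks))
  ov_bp <- function(store, chrom, s, e) {
    ir <- store[[chrom]]
    if (is.null(ir)) return(0)
    sum(IRanges::width(IRanges::intersect(IRanges::reduce(ir),
                                          IRanges::IRanges(s + 1, e))))
  }
  add_iv <- function(store, chrom, s, e) {
    ir <- IRanges::IRanges(s + 1, e)
    store[[chrom]] <- if (is.null(store[[chrom]])) ir else
      c(store[[chrom]], ir)
    store
  }
  # largest sub-interval of [s, e) not covered by the store
  free_piece <- function(store, chrom, s, e) {
    ir <- store[[chrom]]
    if (is.null(ir)) return(c(s, e))
    gap <- IRanges::setdiff(IRanges::IRanges(s + 1, e), IRanges::reduce(ir))
    if (length(gap) == 0) return(NULL)
    j <- which.max(IRanges::width(gap))
    c(IRanges::start(gap)[j] - 1, IRanges::end(gap)[j])
  }
  strict <- max_overlap_frac == 0 && !is.finite(min_new_bp)
  for (i in ord) {
    rl <- blocks$ref_end[i] - blocks$ref_start[i]
    ql <- blocks$qry_end[i] - blocks$qry_start[i]
    ro <- ov_bp(kept_ref, blocks$ref_chrom[i], blocks$ref_start[i], blocks$ref_end[i])
    qo <- ov_bp(kept_qry, blocks$qry_chrom[i], blocks$qry_start[i], blocks$qry_end[i])
    ok_side <- function(ov, len) ov / len <= max_overlap_frac ||
      len - ov >= min_new_bp
    if (ok_side(ro, rl) && ok_side(qo, ql)) {
      keep[i] <- TRUE
      kept_ref <- add_iv(kept_ref, blocks$ref_chrom[i],
                         blocks$ref_start[i], blocks$ref_end[i])
      kept_qry <- add_iv(kept_qry, blocks$qry_chrom[i],
                         blocks$qry_start[i], blocks$qry_end[i])
    } else if (strict && nrow(blocks$gaps[[i]]) == 0 && (ro > 0 || qo > 0)) {
      # strict mode trims partially conflicting gap-free blocks to their
      # largest conflict-free remainder instead of dropping them whole
      minus <- blocks$strand[i] == "-"
      rs <- blocks$ref_start[i]; qs <- blocks$qry_start[i]
      qe <- blocks$qry_end[i]
      p <- free_piece(kept_ref, blocks$ref_chrom[i], rs, blocks$ref_end[i])
      if (is.null(p)) next
      qp <- if (minus) c(qe - (p[2] - rs), qe - (p[1] - rs))
            else c(qs + (p[1] - rs), qs + (p[2] - rs))
      q2 <- free_piece(kept_qry, blocks$qry_chrom[i], qp[1], qp[2])
      if (is.null(q2)) next
      r2 <- if (minus) c(p[1] + (qp[2] - q2[2]), p[1] + (qp[2] - q2[1]))
            else c(p[1] + (q2[1] - qp[1]), p[1] + (q2[2] - qp[1]))
      keep[i] <- TRUE
      len <- r2[2] - r2[1]
      blocks$ref_start[i] <- r2[1]; blocks$ref_end[i] <- r2[2]
      blocks$qry_start[i] <- q2[1]; blocks$qry_end[i] <- q2[2]
      blocks$matches[i] <- blocks$identity[i] * len
      blocks$columns[i] <- len
      kept_ref <- add_iv(kept_ref, blocks$ref_chrom[i], r2[1], r2[2])
      kept_qry <- add_iv(kept_qry, blocks$qry_chrom[i], q2[1], q2[2])
    }
  }
  out <- blocks[keep, , drop = FALSE]
  out <- out[order(out$ref_chrom, out$ref_start, out$qry_chrom, out$qry_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  as_blocks(out)
}

#' Align two genomes end to end
#'
#' Convenience wrapper: unique-k-mer anchors, chaining with interstice
#' closing and end-extension, then one-to-one filtering.
#'
#' @param ref,qry `genome_seq` objects.
#' @param config A [threshold_config()].
#' @return One-to-one filtered alignment blocks.
#' @export
align_genomes <- function(ref, qry, config = threshold_config()) {
  anchors <- find_anchors(ref, qry, config$anchor_k)
  blocks <- chain_and_extend(anchors, ref, qry, config)
  filter_one_to_one(blocks, config$max_overlap_frac)
}
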