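## Alignment block container.
##
## A block set is a data.frame with one row per pairwise aligned segment:
## ref_chrom/ref_start/ref_end, qry_chrom/qry_start/qry_end (both 0-based
## half-open, query ascending even on strand "-"), strand, matches, columns,
## identity, and a list-column `gaps` of data.frames (ref_pos, ref_gap,
## qry_gap) describing internal indels at absolute reference positions in
## reference walking order. The coordinate bookkeeping invariant is
##   ref_len + sum(qry_gap) == qry_len + sum(ref_gap).

empty_gaps <- function() {
  data.frame(ref_pos = numeric(), ref_gap = numeric(), qry_gap = numeric())
}

#' An empty alignment block set
#' @return A zero-row alignment block data.frame with the standard columns.
#' @export
empty_blocks <- function() {
  df <- data.frame(ref_chrom = character(), ref_start = numeric(),
                   ref_end = numeric(), qry_chrom = character(),
                   qry_start = numeric(), qry_end = numeric(),
                   strand = character(), matches = numeric(),
                   columns = numeric(), identity = numeric(),
                   stringsAsFactors = FALSE)
  df$gaps <- list()
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

#' Coerce a data.frame to an alignment block set
#'
#' Fills the `gaps` list-column (empty), `columns` and `matches` when
#' absent; useful for constructing toy block sets and for ingesting
#' external coordinate tables.
#'
#' @param df data.frame with ref_chrom/ref_start/ref_end,
#'   qry_chrom/qry_start/qry_end, strand and identity columns.
#' @return An `alignment_blocks` data.frame.
#' @export
as_blocks <- function(df) {
  stopifnot(all(c("ref_chrom", "ref_start", "ref_end", "qry_chrom",
                  "qry_start", "qry_end", "strand", "identity") %in% names(df)))
  if (is.null(df$gaps)) df$gaps <- replicate(nrow(df), empty_gaps(), simplify = FALSE)
  if (is.null(df$columns)) df$columns <- pmin(df$ref_end - df$ref_start,
                                              df$qry_end - df$qry_start)
  if (is.null(df$matches)) df$matches <- df$identity * df$columns
  rownames(df) <- NULL
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

#' Validate alignment block invariants
#'
#' Checks coordinate sanity, strand labels, identity range and the gap
#' bookkeeping identity relating reference and query lengths.
#'
#' @param blocks Alignment block data.frame.
#' @return Invisibly, the blocks; stops on violation.
#' @export
validate_blocks <- function(blocks) {
  if (nrow(blocks) == 0L) return(invisible(blocks))
  stopifnot(all(blocks$ref_start >= 0), all(blocks$qry_start >= 0),
            all(blocks$ref_start < blocks$ref_end),
            all(blocks$qry_start < blocks$qry_end),
            all(blocks$strand %in% c("+", "-")),
            all(blocks$identity >= 0 & blocks$identity <= 1 + 1e-12))
  for (i in seq_len(nrow(blocks))) {
    g <- blocks$gaps[[i]]
    rl <- blocks$ref_end[i] - blocks$ref_start[i]
    ql <- blocks$qry_end[i] - blocks$qry_start[i]
    if (rl + sum(g$qry_gap) != ql + sum(g$ref_gap))
      stop("block ", i, " violates the gap bookkeeping invariant")
    if (nrow(g) > 0) {
      if (is.unsorted(g$ref_pos)) stop("block ", i, " gaps not in reference order")
      if (any(g$ref_pos < blocks$ref_start[i]) ||
          any(g$ref_pos + g$ref_gap > blocks$ref_end[i]))
        stop("block ", i, " gap outside block")
    }
  }
  invisible(blocks)
}

#' Decompose a block into aligned segments and gaps
#'
#' Walks the gap structure of one block and returns the 1:1 aligned
#' segments with coordinates on both genomes, plus each gap annotated with
#' its query-side position. For minus-strand blocks, query coordinates of
#' consecutive reference segments descend.
#'
#' @param blocks Alignment block data.frame.
#' @param i Row index of the block to decompose.
#' @return list(segs = data.frame(ref_s, ref_e, qry_s, qry_e),
#'   gaps = data.frame(ref_pos, ref_gap, qry_gap, qry_pos)).
#' @export
block_segments <- function(blocks, i) {
  b <- blocks[i, ]
  g <- blocks$gaps[[i]]
  minus <- b$strand == "-"
  r <- b$ref_start
  q <- if (minus) b$qry_end else b$qry_start
  nseg <- nrow(g) + 1L
  segs <- data.frame(ref_s = numeric(nseg), ref_e = numeric(nseg),
                     qry_s = numeric(nseg), qry_e = numeric(nseg))
  gp <- numeric(nrow(g))
  for (j in seq_len(nrow(g))) {
    len <- g$ref_pos[j] - r
    if (len < 0) stop("gap before current position in block ", i)
    if (minus) {
      segs[j, ] <- c(r, r + len, q - len, q); q <- q - len
    } else {
      segs[j, ] <- c(r, r + len, q, q + len); q <- q + len
    }
    r <- r + len + g$ref_gap[j]
    if (g$qry_gap[j] > 0) {
      if (minus) { gp[j] <- q - g$qry_gap[j]; q <- q - g$qry_gap[j] }
      else { gp[j] <- q; q <- q + g$qry_gap[j] }
    } else gp[j] <- q
  }
  len <- b$ref_end - r
  if (minus) {
    segs[nseg, ] <- c(r, r + len, q - len, q); q <- q - len
    if (abs(q - b$qry_start) > 1e-9) stop("block ", i, " walk inconsistency")
  } else {
    segs[nseg, ] <- c(r, r + len, q, q + len); q <- q + len
    if (abs(q - b$qry_end) > 1e-9) stop("block ", i, " walk inconsistency")
  }
  segs <- segs[segs$ref_e > segs$ref_s, , drop = FALSE]
  gaps <- if (nrow(g) > 0) cbind(g, qry_pos = gp) else
    cbind(empty_gaps(), qry_pos = numeric())
  list(segs = segs, gaps = gaps)
}

block_coverage <- function(blocks, side = c("ref", "qry")) {
  side <- match.arg(side)
  if (nrow(blocks) == 0L) return(intervals())
  parts <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    segs <- block_segments(blocks, i)$segs
    parts[[i]] <- if (side == "ref")
      data.frame(chrom = blocks$ref_chrom[i], start = segs$ref_s, end = segs$ref_e)
    else
      data.frame(chrom = blocks$qry_chrom[i], start = segs$qry_s, end = segs$qry_e)
  }
  merge_intervals(do.call(rbind, parts))
}

#' Aligned-column coverage of a block set on the reference
#'
#' Gap-skipped bases do not count as covered: a bridged insertion inside a
#' block leaves its query bases uncovered and a bridged deletion leaves the
#' corresponding reference bases uncovered.
#'
#' @param blocks Alignment block data.frame.
#' @return Merged interval data.frame on the reference genome.
#' @export
blocks_ref_coverage <- function(blocks) block_coverage(blocks, "ref")

#' Aligned-column coverage of a block set on the query
#' @param blocks Alignment block data.frame.
#' @return Merged interval data.frame on the query genome.
#' @export
blocks_qry_coverage <- function(blocks) block_coverage(blocks, "qry")
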