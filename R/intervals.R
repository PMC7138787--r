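## Interval algebra on 0-based half-open coordinates.
##
## All genomic intervals inside the package are plain data.frames with
## columns chrom/start/end in the BED convention (0-based start, exclusive
## end); 1-based inclusive coordinates appear only inside file readers and
## writers. The set operations below delegate to IRanges/GenomicRanges.

#' Build an interval table
#'
#' @param chrom Chromosome labels.
#' @param start 0-based start positions.
#' @param end Exclusive end positions (`start < end`).
#' @return A data.frame with columns chrom, start, end.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0)) stop("coordinate error: negative start position")
  if (any(df$start >= df$end)) stop("coordinate error: start must be < end")
  invisible(df)
}

iv_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

gr_to_iv <- function(gr) {
  if (length(gr) == 0L) return(intervals())
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge intervals closer than a gap threshold
#'
#' Intervals separated by a gap strictly smaller than `max_gap` are merged
#' into one block (so `max_gap = 500` reproduces the "distance < 500 bp"
#' merging rule); overlapping intervals are always coalesced. With
#' `max_gap = 0` the covered base set is unchanged.
#'
#' @param x Interval data.frame (chrom, start, end).
#' @param max_gap Non-negative gap threshold in bp.
#' @return Sorted, merged interval data.frame whose pairwise gaps are all
#'   `>= max_gap`.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  validate_intervals(x)
  stopifnot(is.numeric(max_gap), length(max_gap) == 1L, max_gap >= 0)
  if (nrow(x) == 0L) return(intervals())
  gr <- GenomicRanges::reduce(iv_to_gr(x), min.gapwidth = max_gap)
  gr_to_iv(gr)
}

#' Fraction of target bases covered
#'
#' Computes bp(target intersect cover) / bp(target) over the unions of both
#' interval sets; used for every coverage-fraction gene rule (e.g. "genes
#' with > 50\% CDS regions covered").
#'
#' @param target,cover Interval data.frames on one chromosome namespace.
#' @return A fraction in \[0, 1\].
#' @export
covered_fraction <- function(target, cover) {
  validate_intervals(target)
  validate_intervals(cover)
  if (nrow(target) == 0L) stop("undefined fraction: empty target")
  tg <- GenomicRanges::reduce(iv_to_gr(target))
  tot <- sum(as.numeric(GenomicRanges::width(tg)))
  if (nrow(cover) == 0L) return(0)
  ov <- GenomicRanges::intersect(tg, GenomicRanges::reduce(iv_to_gr(cover)),
                                 ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov))) / tot
}

#' Total bases covered by an interval set
#' @param x Interval data.frame.
#' @return Number of distinct covered bases.
#' @export
interval_bp <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(iv_to_gr(x)))))
}

#' Intersection of two interval sets
#' @param a,b Interval data.frames.
#' @return Interval data.frame covering bases present in both.
#' @export
interval_intersect <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(intervals())
  gr_to_iv(GenomicRanges::intersect(GenomicRanges::reduce(iv_to_gr(a)),
                                    GenomicRanges::reduce(iv_to_gr(b)),
                                    ignore.strand = TRUE))
}

#' Set difference of two interval sets
#' @param a,b Interval data.frames; returns bases of `a` not in `b`.
#' @return Interval data.frame.
#' @export
interval_subtract <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L) return(intervals())
  if (nrow(b) == 0L) return(merge_intervals(a))
  gr_to_iv(GenomicRanges::setdiff(GenomicRanges::reduce(iv_to_gr(a)),
                                  GenomicRanges::reduce(iv_to_gr(b)),
                                  ignore.strand = TRUE))
}

#' Union of two interval sets
#' @param a,b Interval data.frames.
#' @return Merged interval data.frame.
#' @export
interval_union <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  merge_intervals(rbind(a[, c("chrom", "start", "end")],
                        b[, c("chrom", "start", "end")]))
}

#' Complement of an interval set within chromosomes
#' @param x Interval data.frame.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return Intervals covering every base of the chromosomes not in `x`.
#' @export
interval_complement <- function(x, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  whole <- intervals(names(chrom_lengths), 0, as.numeric(chrom_lengths))
  interval_subtract(whole, x)
}
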