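## Gene-set enrichment by one-sided Fisher exact test (hypergeometric
## over-representation tail) with Benjamini-Hochberg correction, and
## reproduction of printed percentages from printed operands.

#' Fisher exact-test gene-set enrichment
#'
#' For each annotation term, tests over-representation of the term in
#' `gene_set` against `universe` with the one-sided Fisher exact test (the
#' upper hypergeometric tail of the 2x2 table) and adjusts p-values by
#' Benjamini-Hochberg across all tested terms. Terms with no annotated
#' universe genes are skipped.
#'
#' @param gene_set Character vector of genes, a subset of `universe`.
#' @param universe Character vector of all genes under consideration.
#' @param annotations data.frame(gene, term).
#' @return data.frame(term, k, n, K, N, odds_ratio, p, q) sorted by p:
#'   `k` genes of the set with the term, `n` the set size, `K` universe
#'   genes with the term, `N` the universe size.
#' @export
fisher_enrichment <- function(gene_set, universe, annotations) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (length(universe) == 0) stop("input error: empty universe")
  if (length(gene_set) == 0) stop("input error: empty gene set")
  if (!all(gene_set %in% universe))
    stop("input error: gene_set must be a subset of universe")
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(gene_set)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    genes_t <- unique(ann$gene[ann$term == tm])
    K <- length(genes_t)
    if (K == 0) return(NULL)
    k <- sum(gene_set %in% genes_t)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - n - K + k)) / ((n - k) * (K - k))
    data.frame(term = tm, k = k, n = n, K = K, N = N, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Round half-up at a given number of decimals
#'
#' Commercial rounding (0.05 -> 0.1), matching how manuscripts round the
#' percentages they print; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Reproduce printed percentages from printed operands
#'
#' @param x data.frame with columns label, numerator, denominator,
#'   decimals (decimal places each value is printed with).
#' @return The input with a `pct` column: 100*numerator/denominator
#'   rounded half-up to the printed precision.
#' @export
printed_fraction_report <- function(x) {
  stopifnot(all(c("label", "numerator", "denominator", "decimals") %in% names(x)))
  if (any(x$denominator <= 0)) stop("undefined fraction: non-positive denominator")
  x$pct <- round_half_up(100 * x$numerator / x$denominator, x$decimals)
  x
}
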