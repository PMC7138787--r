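## Synthetic three-genome evolution with machine-readable truth.
##
## One ancestral genome is mutated independently into descendants (star
## phylogeny): SNPs, small indels (<= small-variant cutoff), segmental
## insertions/deletions (presence-absence events), and tandem copy-number
## events (copy 0 loss, copy 2/3 gain). Every event is recorded with both
## ancestor ("donor") and derived ("recipient") coordinates so that
## replaying the truth set on the ancestor reproduces the derived genome
## byte for byte.

#' Evolution parameters
#'
#' @param snp_rate Per-bp substitution probability.
#' @param indel_rate Per-bp probability of a small indel event.
#' @param indel_geom_p Geometric length parameter for small indels
#'   (lengths truncated at `small_variant_max`).
#' @param small_variant_max Small-indel length cap (bp).
#' @param pav_count Number of segmental presence-absence events.
#' @param pav_len Length range (bp) for segmental events, sampled uniformly.
#' @param pav_gain_frac Fraction of segmental events that are insertions of
#'   novel sequence (the rest are deletions).
#' @param pav_target_gene_frac Fraction of segmental deletions placed so
#'   that they delete a whole planted gene (requires gene models).
#' @param cnv_count Number of copy-number events.
#' @param cnv_len Length range (bp) for copy-number events.
#' @param cnv_copy_weights Named weights over resulting copy numbers
#'   "0" (loss), "2" and "3" (tandem gains).
#' @param mode "neutral", or "purifying" to restrict coding-sequence indels
#'   to lengths that are multiples of three (no frameshifts survive).
#' @param gc GC content of novel inserted sequence.
#' @param event_margin Minimum spacing (bp) kept between structural events
#'   so each is individually resolvable.
#' @return An `evolution_params` list.
#' @export
evolution_params <- function(snp_rate = 0.005,
                             indel_rate = 5e-4,
                             indel_geom_p = 0.5,
                             small_variant_max = 10,
                             pav_count = 20,
                             pav_len = c(1000, 5000),
                             pav_gain_frac = 0.5,
                             pav_target_gene_frac = 0,
                             cnv_count = 0,
                             cnv_len = c(1000, 2000),
                             cnv_copy_weights = c("0" = 0.5, "2" = 0, "3" = 0.5),
                             mode = c("neutral", "purifying"),
                             gc = 0.43,
                             event_margin = 50) {
  mode <- match.arg(mode)
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            pav_count >= 0, cnv_count >= 0,
            length(pav_len) == 2L, length(cnv_len) == 2L,
            all(c("0", "2", "3") %in% names(cnv_copy_weights)))
  structure(list(snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_geom_p = indel_geom_p,
                 small_variant_max = small_variant_max,
                 pav_count = pav_count, pav_len = pav_len,
                 pav_gain_frac = pav_gain_frac,
                 pav_target_gene_frac = pav_target_gene_frac,
                 cnv_count = cnv_count, cnv_len = cnv_len,
                 cnv_copy_weights = cnv_copy_weights, mode = mode, gc = gc,
                 event_margin = event_margin),
            class = "evolution_params")
}

#' Simulate an ancestral genome
#'
#' @param length Total length in bp (`length = 0` gives an empty genome).
#' @param gc GC content.
#' @param seed Optional RNG seed.
#' @param genome_id Label.
#' @param n_chrom Number of equally sized chromosomes.
#' @return A `genome_seq`.
#' @export
simulate_ancestor <- function(length, gc = 0.43, seed = NULL,
                              genome_id = "ancestor", n_chrom = 1L) {
  stopifnot(length >= 0, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  if (length == 0) return(genome_seq(genome_id, character()))
  per <- diff(round(seq(0, length, length.out = n_chrom + 1)))
  seqs <- vapply(per, random_dna, "", gc = gc)
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  genome_seq(genome_id, seqs)
}

empty_truth <- function() {
  data.frame(type = character(), chrom = character(),
             anc_start = numeric(), anc_end = numeric(),
             der_start = numeric(), der_end = numeric(),
             len = numeric(), copies = numeric(),
             ref_allele = character(), alt_allele = character(),
             stringsAsFactors = FALSE)
}

truth_row <- function(type, chrom, anc_start, anc_end, len, copies = NA_real_,
                      ref_allele = "", alt_allele = "") {
  data.frame(type = type, chrom = chrom, anc_start = anc_start,
             anc_end = anc_end, der_start = NA_real_, der_end = NA_real_,
             len = len, copies = copies, ref_allele = ref_allele,
             alt_allele = alt_allele, stringsAsFactors = FALSE)
}

# Rejection-sample a span of `len` bp avoiding `block` (TRUE = blocked),
# leaving `margin` clearance. Returns 0-based start or stops.
sample_free_span <- function(L, len, blocked, margin, max_tries = 1000L) {
  if (L - len - 2 < 1) stop("simulation error: chromosome too short for event")
  for (t in seq_len(max_tries)) {
    s <- sample.int(L - len - 1L, 1L)  # 0-based start in [1, L-len-1]
    a <- max(1L, s + 1L - margin)
    b <- min(L, s + len + margin)
    if (!any(blocked[a:b])) return(s)
  }
  stop("simulation error: could not place event after ", max_tries, " tries")
}

mark_span <- function(blocked, s, e, margin, L) {
  blocked[max(1L, s + 1L - margin):min(L, e + margin)] <- TRUE
  blocked
}

sample_indel_len <- function(p, cap, multiple_of_3 = FALSE) {
  if (multiple_of_3) {
    ks <- seq(3, cap, by = 3)
    if (length(ks) == 0) ks <- 3
    sample(rep(ks, 2), 1, prob = rep((1 - p)^(seq_along(ks) - 1), 2))
  } else {
    min(rgeom(1, p) + 1L, cap)
  }
}

#' Evolve a genome, emitting a truth set
#'
#' Applies SNPs, small indels, segmental insertions/deletions and tandem
#' copy-number events to an ancestor. Events never overlap on the ancestor;
#' when gene models are supplied, structural events avoid gene bodies except
#' for segmental deletions explicitly targeted at genes, so gene
#' annotations can be lifted onto the derived genome.
#'
#' @param ancestor A `genome_seq`.
#' @param params An `evolution_params` object.
#' @param genome_id Label for the derived genome.
#' @param genes Optional `gene_models` on the ancestor.
#' @param seed Optional RNG seed.
#' @return list(genome = derived `genome_seq`, truth = event data.frame
#'   with ancestor and derived coordinates).
#' @export
evolve <- function(ancestor, params, genome_id = "derived", genes = NULL,
                   seed = NULL) {
  stopifnot(inherits(ancestor, "genome_seq"), inherits(params, "evolution_params"))
  if (genome_length(ancestor) == 0) stop("ancestor must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  margin <- params$event_margin
  lens <- chrom_lengths(ancestor)
  chrom_pick <- function(n) sample(names(lens), n, replace = TRUE,
                                   prob = lens / sum(lens))

  all_truth <- list()
  for (chrom in names(lens)) {
    L <- as.integer(lens[[chrom]])
    anc_seq <- ancestor$seqs[[chrom]]
    blocked <- rep(FALSE, L)
    protect <- rep(FALSE, L)
    cds_mask <- rep(FALSE, L)
    gene_tab <- NULL
    if (!is.null(genes)) {
      ex <- genes$exons[genes$exons$chrom == chrom, , drop = FALSE]
      if (nrow(ex) > 0) {
        gids <- unique(ex$gene_id)
        spans <- do.call(rbind, lapply(gids, function(g) {
          e <- ex[ex$gene_id == g, ]
          data.frame(gene_id = g, start = min(e$start), end = max(e$end))
        }))
        gene_tab <- spans
        for (i in seq_len(nrow(spans)))
          protect[(spans$start[i] + 1):spans$end[i]] <- TRUE
      }
      cd <- genes$cds[genes$cds$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(cd))) cds_mask[(cd$start[i] + 1):cd$end[i]] <- TRUE
    }
    rows <- list()
    add <- function(r) rows[[length(rows) + 1L]] <<- r

    ## segmental presence-absence events (counted per genome, spread over
    ## chromosomes by length)
    n_pav <- sum(chrom_pick(params$pav_count) == chrom)
    n_gain <- round(n_pav * params$pav_gain_frac)
    n_loss <- n_pav - n_gain
    n_target <- if (!is.null(gene_tab))
      min(round(n_loss * params$pav_target_gene_frac), nrow(gene_tab)) else 0L
    if (n_target > 0) {
      picked <- gene_tab[sample.int(nrow(gene_tab), n_target), , drop = FALSE]
      for (i in seq_len(nrow(picked))) {
        s <- max(0L, as.integer(picked$start[i]) - margin)
        e <- min(L, as.integer(picked$end[i]) + margin)
        if (any(blocked[(s + 1):e])) next
        blocked <- mark_span(blocked, s, e, margin, L)
        add(truth_row("pav_loss", chrom, s, e, e - s,
                      ref_allele = substring(anc_seq, s + 1, e)))
      }
      n_loss <- n_loss - n_target
    }
    for (i in seq_len(n_gain)) {
      len <- as.integer(round(runif(1, params$pav_len[1], params$pav_len[2])))
      p <- sample_free_span(L, 1L, blocked | protect, margin)
      blocked <- mark_span(blocked, p, p + 1L, margin, L)
      add(truth_row("pav_gain", chrom, p, p, len,
                    alt_allele = random_dna(len, params$gc)))
    }
    for (i in seq_len(n_loss)) {
      len <- as.integer(round(runif(1, params$pav_len[1], params$pav_len[2])))
      s <- sample_free_span(L, len, blocked | protect, margin)
      blocked <- mark_span(blocked, s, s + len, margin, L)
      add(truth_row("pav_loss", chrom, s, s + len, len,
                    ref_allele = substring(anc_seq, s + 1, s + len)))
    }

    ## tandem copy-number events
    n_cnv <- sum(chrom_pick(params$cnv_count) == chrom)
    w <- params$cnv_copy_weights
    for (i in seq_len(n_cnv)) {
      len <- as.integer(round(runif(1, params$cnv_len[1], params$cnv_len[2])))
      copies <- as.integer(sample(names(w), 1, prob = w))
      s <- sample_free_span(L, len, blocked | protect, margin)
      blocked <- mark_span(blocked, s, s + len, margin, L)
      type <- if (copies == 0) "cnv_loss" else "cnv_gain"
      add(truth_row(type, chrom, s, s + len, len, copies = copies,
                    ref_allele = if (copies == 0)
                      substring(anc_seq, s + 1, s + len) else ""))
    }

    ## small indels
    n_indel <- rbinom(1, L, params$indel_rate)
    for (i in seq_len(n_indel)) {
      is_ins <- runif(1) < 0.5
      if (is_ins) {
        p <- sample_free_span(L, 1L, blocked, margin)
        in_cds <- cds_mask[p + 1]
        len <- sample_indel_len(params$indel_geom_p, params$small_variant_max,
                                params$mode == "purifying" && in_cds)
        blocked <- mark_span(blocked, p, p + 1L, margin, L)
        add(truth_row("ins", chrom, p, p, len,
                      alt_allele = random_dna(len, params$gc)))
      } else {
        placed <- FALSE
        for (t in 1:1000) {
          len <- sample_indel_len(params$indel_geom_p, params$small_variant_max,
                                  FALSE)
          s <- sample_free_span(L, len, blocked, margin)
          # any CDS base in the span counts as coding (a deletion reaching
          # into an exon frameshifts it just as well)
          in_cds <- any(cds_mask[(s + 1):min(L, s + len)])
          if (params$mode == "purifying" && in_cds) {
            len <- sample_indel_len(params$indel_geom_p,
                                    params$small_variant_max, TRUE)
            # keep coding deletions fully inside the coding region
            if (s + len > L || !all(cds_mask[(s + 1):(s + len)])) next
          }
          placed <- TRUE
          break
        }
        if (!placed) stop("simulation error: could not place deletion")
        blocked <- mark_span(blocked, s, s + len, margin, L)
        add(truth_row("del", chrom, s, s + len, len,
                      ref_allele = substring(anc_seq, s + 1, s + len)))
      }
    }

    ## SNPs: count drawn at the genome-wide per-bp rate, placed on
    ## event-free positions
    n_snp <- rbinom(1, L, params$snp_rate)
    if (n_snp > 0) {
      free <- which(!blocked) - 1L  # 0-based
      if (length(free) < n_snp) stop("simulation error: no room for SNPs")
      pos <- sort(sample(free, n_snp))
      refb <- strsplit(substring(anc_seq, 1, L), "")[[1]][pos + 1L]
      # substitute: pick uniformly among the three other bases
      bases <- c("A", "C", "G", "T")
      shift <- sample.int(3, length(pos), replace = TRUE)
      altb <- bases[((match(refb, bases) - 1 + shift) %% 4) + 1]
      keep <- refb %in% bases
      if (any(keep))
        add(data.frame(type = "snp", chrom = chrom, anc_start = pos[keep],
                       anc_end = pos[keep] + 1, der_start = NA_real_,
                       der_end = NA_real_, len = 1, copies = NA_real_,
                       ref_allele = refb[keep], alt_allele = altb[keep],
                       stringsAsFactors = FALSE))
    }
    if (length(rows) > 0) all_truth[[chrom]] <- do.call(rbind, rows)
  }

  truth <- if (length(all_truth) > 0) do.call(rbind, all_truth) else empty_truth()
  rownames(truth) <- NULL
  derived <- apply_truth(ancestor, truth, genome_id)
  truth <- derived$truth
  list(genome = derived$genome, truth = truth)
}

# Apply a truth set to the ancestor; fills derived coordinates.
apply_truth <- function(ancestor, truth, genome_id) {
  seqs <- character(0)
  out_truth <- list()
  for (chrom in names(ancestor$seqs)) {
    anc_seq <- ancestor$seqs[[chrom]]
    ev <- truth[truth$chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$anc_start, ev$anc_end), , drop = FALSE]
    pieces <- character(0)
    prev <- 0
    offset <- 0
    for (i in seq_len(nrow(ev))) {
      s <- ev$anc_start[i]; e <- ev$anc_end[i]
      if (s < prev) stop("truth events overlap on the ancestor")
      pieces <- c(pieces, substring(anc_seq, prev + 1, s))
      ev$der_start[i] <- s + offset
      piece <- switch(ev$type[i],
        snp = ev$alt_allele[i],
        ins = ,
        pav_gain = ev$alt_allele[i],
        del = ,
        pav_loss = ,
        cnv_loss = "",
        cnv_gain = strrep(substring(anc_seq, s + 1, e), ev$copies[i]),
        stop("unknown event type ", ev$type[i]))
      pieces <- c(pieces, piece)
      ev$der_end[i] <- ev$der_start[i] + nchar(piece)
      offset <- offset + nchar(piece) - (e - s)
      prev <- e
    }
    pieces <- c(pieces, substring(anc_seq, prev + 1, nchar(anc_seq)))
    seqs[[chrom]] <- paste(pieces, collapse = "")
    if (nrow(ev) > 0) out_truth[[chrom]] <- ev
  }
  truth_out <- if (length(out_truth)) do.call(rbind, out_truth) else empty_truth()
  rownames(truth_out) <- NULL
  list(genome = genome_seq(genome_id, seqs), truth = truth_out)
}

#' Replay a truth set on the ancestor
#'
#' @param ancestor The ancestral `genome_seq`.
#' @param truth Truth event data.frame from [evolve()].
#' @param genome_id Label for the rebuilt genome.
#' @return The derived `genome_seq`; identical to the one [evolve()]
#'   produced when the truth set is consistent.
#' @export
replay_truth <- function(ancestor, truth, genome_id = "replayed") {
  apply_truth(ancestor, truth, genome_id)$genome
}

#' Plant protein-coding genes into a genome
#'
#' Writes intact open reading frames (ATG start, sense codons, single stop)
#' into non-overlapping loci on both strands, optionally split across
#' multiple exons, and returns both the modified genome and the models.
#'
#' @param genome A `genome_seq`.
#' @param n_genes Number of genes to place.
#' @param exons_per_gene Integer vector sampled for the exon count.
#' @param cds_len_range CDS length range (bp); rounded to codons.
#' @param intron_len_range Intron length range (bp).
#' @param margin Minimum spacing between genes (bp).
#' @param seed Optional RNG seed.
#' @param prefix Gene id prefix.
#' @return list(genome = modified `genome_seq`, genes = `gene_models`).
#' @export
plant_genes <- function(genome, n_genes, exons_per_gene = 1:3,
                        cds_len_range = c(300, 1500),
                        intron_len_range = c(60, 300), margin = 200,
                        seed = NULL, prefix = "g") {
  stopifnot(inherits(genome, "genome_seq"), n_genes >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_genes == 0)
    return(list(genome = genome,
                genes = gene_models(
                  data.frame(gene_id = character(), chrom = character(),
                             strand = character(), stringsAsFactors = FALSE),
                  data.frame(gene_id = character(), chrom = character(),
                             start = numeric(), end = numeric()),
                  data.frame(gene_id = character(), chrom = character(),
                             start = numeric(), end = numeric()))))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  lens <- chrom_lengths(genome)
  chroms <- sample(names(lens), n_genes, replace = TRUE, prob = lens / sum(lens))
  genes <- exons <- cds <- list()
  edits <- list()  # per chromosome: list of (start, end, seq)
  blocked <- lapply(lens, function(L) rep(FALSE, as.integer(L)))
  for (i in seq_len(n_genes)) {
    chrom <- chroms[i]
    L <- as.integer(lens[[chrom]])
    n_cod <- round(runif(1, cds_len_range[1], cds_len_range[2]) / 3)
    cds_len <- 3L * max(3L, as.integer(n_cod))
    m <- sample(rep(exons_per_gene, 2), 1)
    # split the CDS into m chunks of at least 20 bp
    repeat {
      cuts <- sort(sample.int(cds_len - 1L, m - 1L))
      sizes <- diff(c(0L, cuts, cds_len))
      if (all(sizes >= 20L) || m == 1L) break
    }
    if (m == 1L) sizes <- cds_len
    introns <- if (m > 1)
      as.integer(round(runif(m - 1, intron_len_range[1], intron_len_range[2])))
    else integer()
    span <- cds_len + sum(introns)
    s <- sample_free_span(L, span, blocked[[chrom]], margin)
    blocked[[chrom]] <- mark_span(blocked[[chrom]], s, s + span, margin, L)
    strand <- sample(c("+", "-"), 1)
    codseq <- paste0("ATG", paste(sample(setdiff(sense, c("TAA", "TAG", "TGA")),
                                         n_cod - 2L, replace = TRUE), collapse = ""),
                     sample(stops, 1))
    stopifnot(nchar(codseq) == cds_len)
    chunks <- substring(codseq, cumsum(c(1L, sizes))[seq_len(m)],
                        cumsum(sizes))
    gid <- sprintf("%s%04d", prefix, i)
    pos <- s
    ex_rows <- list()
    for (j in seq_len(m)) {
      w <- sizes[j]
      piece <- if (strand == "+") chunks[j] else revcomp(chunks[m - j + 1L])
      wlen <- nchar(piece)
      ex_rows[[j]] <- data.frame(gene_id = gid, chrom = chrom,
                                 start = pos, end = pos + wlen)
      edits[[chrom]] <- c(edits[[chrom]],
                          list(list(start = pos, end = pos + wlen, seq = piece)))
      pos <- pos + wlen + if (j < m) introns[j] else 0L
    }
    # exon j (left to right) carries CDS chunk j (+) or chunk m-j+1
    # reverse-complemented (-), so transcription order reads the CDS 5'->3'
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             stringsAsFactors = FALSE)
    exons[[i]] <- do.call(rbind, ex_rows)
    cds[[i]] <- do.call(rbind, ex_rows)
  }
  seqs <- genome$seqs
  for (chrom in names(edits)) {
    ed <- edits[[chrom]]
    ord <- order(vapply(ed, `[[`, 0, "start"))
    ed <- ed[ord]
    pieces <- character(0)
    prev <- 0
    for (e in ed) {
      pieces <- c(pieces, substring(seqs[[chrom]], prev + 1, e$start), e$seq)
      prev <- e$end
    }
    pieces <- c(pieces, substring(seqs[[chrom]], prev + 1, nchar(seqs[[chrom]])))
    seqs[[chrom]] <- paste(pieces, collapse = "")
  }
  list(genome = genome_seq(genome$genome_id, seqs),
       genes = gene_models(do.call(rbind, genes), do.call(rbind, exons),
                           do.call(rbind, cds)))
}

#' Lift gene models onto a derived genome
#'
#' Shifts gene coordinates by the cumulative length change of truth events
#' upstream of each gene; genes fully contained in deleted spans are
#' dropped. Assumes structural events do not fall inside retained gene
#' bodies (which [evolve()] guarantees when genes are supplied).
#'
#' @param gm `gene_models` on the ancestor.
#' @param truth Truth set of the derived genome.
#' @return `gene_models` in derived coordinates.
#' @export
lift_genes <- function(gm, truth) {
  ## per chromosome: cumulative length change of events up to a position
  by_chrom <- split(truth, truth$chrom)
  offset_at <- function(chrom, pos) {
    ev <- by_chrom[[chrom]]
    if (is.null(ev) || nrow(ev) == 0) return(rep(0, length(pos)))
    ev <- ev[order(ev$anc_start), , drop = FALSE]
    delta <- (ev$der_end - ev$der_start) - (ev$anc_end - ev$anc_start)
    cumdel <- cumsum(delta)
    idx <- findInterval(pos, ev$anc_end)
    ifelse(idx == 0, 0, cumdel[pmax(idx, 1)])
  }
  deleted_gene <- function(chrom, s, e) {
    ev <- by_chrom[[chrom]]
    if (is.null(ev)) return(rep(FALSE, length(s)))
    del <- ev[ev$type %in% c("del", "pav_loss", "cnv_loss"), , drop = FALSE]
    out <- rep(FALSE, length(s))
    for (i in seq_len(nrow(del)))
      out <- out | (del$anc_start[i] <= s & del$anc_end[i] >= e)
    out
  }
  shift_tab <- function(df) {
    if (nrow(df) == 0) return(df)
    keep <- rep(TRUE, nrow(df))
    for (chrom in unique(df$chrom)) {
      sel <- df$chrom == chrom
      keep[sel] <- !deleted_gene(chrom, df$start[sel], df$end[sel])
      off <- offset_at(chrom, df$start[sel])
      df$start[sel] <- df$start[sel] + off
      df$end[sel] <- df$end[sel] + off
    }
    df[keep, , drop = FALSE]
  }
  ex <- shift_tab(gm$exons)
  cd <- shift_tab(gm$cds)
  kept <- intersect(unique(ex$gene_id), unique(cd$gene_id))
  gene_models(gm$genes[gm$genes$gene_id %in% kept, , drop = FALSE],
              ex[ex$gene_id %in% kept, , drop = FALSE],
              cd[cd$gene_id %in% kept, , drop = FALSE])
}

#' Depth track constructor
#' @param genome_id Label.
#' @param windows data.frame(chrom, start, end, depth).
#' @return A `depth_track` object.
#' @export
depth_track <- function(genome_id, windows) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(windows)),
            all(windows$depth >= 0))
  structure(list(genome_id = genome_id, windows = windows),
            class = "depth_track")
}

#' Simulate a copy-number-scaled read-depth track
#'
#' Tiles the genome with fixed windows and draws a mean fold-coverage for
#' each, centred at `mean_depth` times the local copy number implied by the
#' truth set's copy-number events (0 for losses, 2 or 3 for tandem gains,
#' 1 elsewhere), with overlap-weighted copy at event edges.
#'
#' @param genome The `genome_seq` whose coordinates the windows tile (the
#'   genome reads are mapped to).
#' @param truth Truth set carrying cnv_gain / cnv_loss events.
#' @param mean_depth Mean fold-coverage of copy-1 sequence.
#' @param window Window size in bp (>= 100).
#' @param noise "poisson" (default), "none" (exact expectation) or
#'   "nbinom" (overdispersed; see `size`).
#' @param size Negative-binomial size parameter when `noise = "nbinom"`.
#' @param seed Optional RNG seed.
#' @return A `depth_track`.
#' @export
simulate_depth <- function(genome, truth, mean_depth = 40, window = 200,
                           noise = c("poisson", "none", "nbinom"), size = 10,
                           seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(mean_depth > 0, window >= 100)
  if (!is.null(seed)) set.seed(seed)
  cnv <- truth[truth$type %in% c("cnv_gain", "cnv_loss"), , drop = FALSE]
  out <- list()
  for (chrom in names(genome$seqs)) {
    L <- nchar(genome$seqs[[chrom]])
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    copy <- rep(1, length(starts))
    ev <- cnv[cnv$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      ov <- pmax(0, pmin(ends, ev$anc_end[i]) - pmax(starts, ev$anc_start[i]))
      c_i <- if (ev$type[i] == "cnv_loss") 0 else ev$copies[i]
      copy <- copy + (c_i - 1) * ov / (ends - starts)
    }
    lambda <- mean_depth * copy
    depth <- switch(noise,
                    none = lambda,
                    poisson = rpois(length(lambda), lambda),
                    nbinom = rnbinom(length(lambda), mu = lambda, size = size))
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               depth = as.numeric(depth))
  }
  depth_track(genome$genome_id, do.call(rbind, out))
}

#' Simulate a three-genome trio from one ancestor
#'
#' Generates an ancestral genome, plants genes, and evolves three
#' descendants (labelled SAT, RUF, NIV) independently — a star phylogeny.
#'
#' @param anc_length Ancestor length (bp).
#' @param n_genes Genes planted on the ancestor.
#' @param params `evolution_params` shared by the three branches.
#' @param seed RNG seed; per-branch seeds are derived from it.
#' @param gc Ancestor GC content.
#' @return list(ancestor, genes, genomes = list(sat, ruf, niv),
#'   truths = list(sat, ruf, niv), genes_by_genome).
#' @export
simulate_trio <- function(anc_length = 1e6, n_genes = 200,
                          params = evolution_params(), seed = 1, gc = 0.43) {
  anc0 <- simulate_ancestor(anc_length, gc = gc, seed = seed)
  planted <- plant_genes(anc0, n_genes, seed = seed + 7)
  anc <- planted$genome
  genes <- planted$genes
  ids <- c("sat", "ruf", "niv")
  genomes <- truths <- gset <- list()
  for (i in seq_along(ids)) {
    ev <- evolve(anc, params, genome_id = toupper(ids[i]), genes = genes,
                 seed = seed + i)
    genomes[[ids[i]]] <- ev$genome
    truths[[ids[i]]] <- ev$truth
    gset[[ids[i]]] <- lift_genes(genes, ev$truth)
  }
  list(ancestor = anc, genes = genes, genomes = genomes, truths = truths,
       genes_by_genome = gset, params = params, seed = seed)
}
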