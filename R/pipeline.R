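## Orchestration and truth-recovery scoring: the demo pipeline runs
## simulate -> align -> pan-genome -> variants -> PAV -> CNV -> summaries
## and scores every stage against the simulator's truth sets.

#' Expected pan-genome partition from truth sets
#'
#' Computes, from the three descendants' truth sets, the expected core /
#' dispensable / specific base totals of the reference-centric partition:
#' ancestral bases classified by which descendants deleted them, plus each
#' genome's novel (inserted) bases as specific sequence.
#'
#' @param truths list(sat=, ruf=, niv=) truth sets from [evolve()].
#' @param ancestor The ancestral `genome_seq`.
#' @return list(core_bp, dispensable_bp, specific_bp, pan_bp).
#' @export
pan_truth <- function(truths, ancestor) {
  lens <- chrom_lengths(ancestor)
  del_iv <- function(tr) {
    d <- tr[tr$type %in% c("del", "pav_loss", "cnv_loss"), , drop = FALSE]
    if (nrow(d) == 0) return(intervals())
    merge_intervals(intervals(d$chrom, d$anc_start, d$anc_end))
  }
  novel_bp <- function(tr) {
    sum(tr$len[tr$type %in% c("ins", "pav_gain")]) +
      sum((tr$copies[tr$type == "cnv_gain"] - 1) * tr$len[tr$type == "cnv_gain"])
  }
  ds <- del_iv(truths$sat); dr <- del_iv(truths$ruf); dn <- del_iv(truths$niv)
  anc_iv <- intervals(names(lens), 0, as.numeric(lens))
  pres_s <- interval_subtract(anc_iv, ds)
  core <- interval_bp(interval_subtract(pres_s, interval_union(dr, dn)))
  sat_disp <- interval_bp(interval_intersect(
    pres_s, interval_union(interval_subtract(dr, dn), interval_subtract(dn, dr))))
  sat_spec <- interval_bp(interval_intersect(pres_s, interval_intersect(dr, dn))) +
    novel_bp(truths$sat)
  ruf_disp <- interval_bp(interval_subtract(interval_subtract(ds, dr), dn))
  ruf_spec <- interval_bp(interval_subtract(interval_intersect(ds, dn), dr)) +
    novel_bp(truths$ruf)
  niv_spec <- interval_bp(interval_subtract(interval_intersect(ds, dr), dn)) +
    novel_bp(truths$niv)
  list(core_bp = core, dispensable_bp = sat_disp + ruf_disp,
       specific_bp = c(sat = sat_spec, ruf = ruf_spec, niv = niv_spec),
       pan_bp = core + sat_disp + ruf_disp + sat_spec + ruf_spec + niv_spec)
}

truth_as_variants <- function(truth, ancestor) {
  sm <- truth[truth$type %in% c("snp", "ins", "del"), , drop = FALSE]
  v <- data.frame(chrom = sm$chrom, pos = sm$anc_start,
                  end = ifelse(sm$type == "ins", sm$anc_start, sm$anc_end),
                  ref = ifelse(sm$type == "ins", "", sm$ref_allele),
                  alt = ifelse(sm$type == "del", "", sm$alt_allele),
                  vtype = sm$type, stringsAsFactors = FALSE)
  normalize_indels(v, ancestor)
}

#' Score small-variant calls against simulator truth
#'
#' Truth events are canonicalized through the same left-normalization the
#' caller applies (a homopolymer indel's planted position is not
#' identifiable from sequence); matching is then exact on position and
#' alleles. Calls and truth within `sv_pad` bp of a structural event are
#' excluded (breakpoint ambiguity is not a caller defect).
#'
#' @param calls Variant data.frame (reference = the donor genome).
#' @param truth Truth set of the query genome.
#' @param ancestor The reference/donor `genome_seq`.
#' @param sv_pad Exclusion pad around structural events (bp).
#' @return list of precision/recall for SNPs and indels, plus counts.
#' @export
score_small_variants <- function(calls, truth, ancestor, sv_pad = 100) {
  sv <- truth[truth$type %in% c("pav_gain", "pav_loss", "cnv_gain", "cnv_loss"), ,
              drop = FALSE]
  excluded <- function(chrom, pos) {
    if (nrow(sv) == 0) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(sv))) {
      out <- out | (chrom == sv$chrom[i] & pos >= sv$anc_start[i] - sv_pad &
                      pos <= sv$anc_end[i] + sv_pad)
    }
    out
  }
  tv <- truth_as_variants(truth, ancestor)
  tv <- tv[!excluded(tv$chrom, tv$pos), , drop = FALSE]
  cl <- calls[!excluded(calls$chrom, calls$pos), , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, d$vtype, d$ref, d$alt)
  res <- list()
  for (cls in list(c("snp"), c("ins", "del"))) {
    t_k <- key(tv[tv$vtype %in% cls, ])
    c_k <- key(cl[cl$vtype %in% cls, ])
    tp <- sum(c_k %in% t_k)
    lab <- if ("snp" %in% cls) "snp" else "indel"
    res[[paste0(lab, "_precision")]] <- if (length(c_k)) tp / length(c_k) else NA
    res[[paste0(lab, "_recall")]] <- if (length(t_k)) tp / length(t_k) else NA
    res[[paste0(lab, "_n_truth")]] <- length(t_k)
    res[[paste0(lab, "_n_called")]] <- length(c_k)
  }
  res
}

#' Expected large-variant categories from a truth set
#'
#' Maps structural truth events of one genome pair to the category the
#' six-way classifier should assign, with the reference anchor interval to
#' match against. `side = "qry"` means the evolved genome is the query
#' (events appear as insertions/deletions/tandem expansions); `side =
#' "ref"` means it is the reference (the mirror categories).
#'
#' @param truth Truth set of the evolved genome.
#' @param side Which side of the pair the evolved genome is.
#' @return data.frame(chrom, start, end, category).
#' @export
expected_sv_table <- function(truth, side = c("qry", "ref")) {
  side <- match.arg(side)
  ev <- truth[truth$type %in% c("pav_gain", "pav_loss", "cnv_gain"), , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  if (side == "qry") {
    data.frame(chrom = ev$chrom, start = ev$anc_start, end = ev$anc_end,
               category = c(pav_gain = "insertion", pav_loss = "deletion",
                            cnv_gain = "tandem_expansion")[ev$type],
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = ev$chrom, start = ev$der_start, end = ev$der_end,
               category = c(pav_gain = "deletion", pav_loss = "insertion",
                            cnv_gain = "tandem_contraction")[ev$type],
               stringsAsFactors = FALSE)
  }
}

#' Score large-variant classification against expectations
#'
#' @param calls Output of [classify_large_variants()].
#' @param expected Output of [expected_sv_table()].
#' @param tol Breakpoint tolerance (bp).
#' @return list(matched, total, accuracy).
#' @export
score_sv_categories <- function(calls, expected, tol = 50) {
  matched <- 0L
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    hit <- calls$category == e$category & calls$ref_chrom == e$chrom &
      calls$ref_end >= e$start - tol & calls$ref_start <= e$end + tol
    if (any(hit)) matched <- matched + 1L
  }
  list(matched = matched, total = nrow(expected),
       accuracy = if (nrow(expected)) matched / nrow(expected) else NA)
}

#' Expected absence records for planted deletions
#'
#' Deletions closer on the reference than the merge distance are reported
#' as one merged absence block (the published "distance < 500 bp" rule),
#' so the expected record set is the merge of the planted spans under the
#' same rule.
#'
#' @param losses Truth rows of deletion-type events.
#' @param config A [threshold_config()].
#' @return data.frame(chrom, start, end) of expected absence records.
#' @export
expected_absence_records <- function(losses, config = threshold_config()) {
  if (nrow(losses) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  merge_intervals(intervals(losses$chrom, losses$anc_start, losses$anc_end),
                  config$pav_merge_gap)
}

#' Score PAV recovery against planted events
#'
#' @param records PAV records (presence side: query coordinates; absence
#'   side: reference coordinates).
#' @param expected data.frame(chrom, start, end) of expected segments.
#' @param tol Breakpoint tolerance (bp).
#' @return list(recalled, total, recall, n_records).
#' @export
score_pav <- function(records, expected, tol = 50) {
  recalled <- 0L
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    hit <- records$chrom == e$chrom & abs(records$start - e$start) <= tol &
      abs(records$end - e$end) <= tol
    if (any(hit)) recalled <- recalled + 1L
  }
  list(recalled = recalled, total = nrow(expected),
       recall = if (nrow(expected)) recalled / nrow(expected) else NA,
       n_records = nrow(records))
}

#' Score CNV calls against planted copy-number events
#'
#' A truth event is recovered when a call of the same direction covers at
#' least half of it; a call is a true positive when at least half of it
#' lies inside same-direction truth.
#'
#' @param calls Output of [call_cnv()].
#' @param truth Truth set with cnv events (donor coordinates).
#' @return list(recall, precision, n_truth, n_calls).
#' @export
score_cnv <- function(calls, truth) {
  ev <- truth[truth$type %in% c("cnv_gain", "cnv_loss"), , drop = FALSE]
  ev$dir <- ifelse(ev$type == "cnv_gain", "gain", "loss")
  ov <- function(a_s, a_e, b_s, b_e) pmax(0, pmin(a_e, b_e) - pmax(a_s, b_s))
  rec <- 0L
  for (i in seq_len(nrow(ev))) {
    sel <- calls$call == ev$dir[i] & calls$chrom == ev$chrom[i]
    o <- sum(ov(calls$start[sel], calls$end[sel], ev$anc_start[i], ev$anc_end[i]))
    if (o >= 0.5 * (ev$anc_end[i] - ev$anc_start[i])) rec <- rec + 1L
  }
  tp <- 0L
  for (j in seq_len(nrow(calls))) {
    sel <- ev$dir == calls$call[j] & ev$chrom == calls$chrom[j]
    o <- sum(ov(ev$anc_start[sel], ev$anc_end[sel], calls$start[j], calls$end[j]))
    if (o >= 0.5 * (calls$end[j] - calls$start[j])) tp <- tp + 1L
  }
  list(recall = if (nrow(ev)) rec / nrow(ev) else NA,
       precision = if (nrow(calls)) tp / nrow(calls) else NA,
       n_truth = nrow(ev), n_calls = nrow(calls))
}

#' Run the full demonstration pipeline on simulated genomes
#'
#' Simulates a three-genome trio, aligns the three pairs with the built-in
#' aligner, builds the pan-genome partition and gene membership, calls and
#' annotates small variants, classifies large variants, calls
#' presence-absence variation in all four classes, calls copy-number
#' regions from a simulated depth track (a dedicated copy-number
#' simulation so the planted events are unambiguous), and scores every
#' stage against truth.
#'
#' @param seed RNG seed controlling every stage.
#' @param anc_length Trio ancestor genome length (bp).
#' @param n_genes Planted gene count.
#' @param params Trio `evolution_params`.
#' @param config A [threshold_config()].
#' @param out_dir Optional directory to write FASTA/GFF3/coords/BED/VCF/JSON
#'   outputs into.
#' @param pair_length Ancestor length for the dedicated pair simulations
#'   that measure small-variant, structural-variant and PAV recovery under
#'   clean single-branch conditions (the trio's products remain the
#'   two-branch comparisons).
#' @param cnv_count Events in the dedicated copy-number simulation.
#' @param mean_depth Simulated mean fold-coverage.
#' @param quiet Suppress progress messages.
#' @return A list with the simulation, block sets, pan-genome, membership,
#'   variants, large variants, PAV and CNV calls, and a `scorecard`.
#' @export
run_pipeline <- function(seed = 1, anc_length = 1e6, n_genes = 200,
                         params = evolution_params(pav_target_gene_frac = 0.5),
                         config = threshold_config(), out_dir = NULL,
                         pair_length = 1e5, cnv_count = 30, mean_depth = 40,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("simulate: ancestor %d bp, %d genes, seed %d", anc_length, n_genes, seed)
  sim <- simulate_trio(anc_length = anc_length, n_genes = n_genes,
                       params = params, seed = seed)
  say("align: three genome pairs, k=%d", config$anchor_k)
  blocks <- list(
    sat_ruf = align_genomes(sim$genomes$sat, sim$genomes$ruf, config),
    sat_niv = align_genomes(sim$genomes$sat, sim$genomes$niv, config),
    ruf_niv = align_genomes(sim$genomes$ruf, sim$genomes$niv, config))
  for (nm in names(blocks)) say("  %s: %d blocks", nm, nrow(blocks[[nm]]))

  lens <- lapply(sim$genomes, chrom_lengths)
  pg <- build_pangenome(blocks$sat_ruf, blocks$sat_niv, blocks$ruf_niv, lens)
  membership <- classify_gene_membership(sim$genes_by_genome, pg,
                                         config$presence_frac)
  truth_pan <- pan_truth(sim$truths, sim$ancestor)

  say("variants: sat vs ruf")
  vars <- call_small_variants(blocks$sat_ruf, sim$genomes$sat, sim$genomes$ruf,
                              config)
  vars <- annotate_effects(vars, sim$genes_by_genome$sat, sim$genomes$sat)
  large <- classify_large_variants(blocks$sat_ruf, config)

  say("pav: four classes")
  pav <- list(
    rs10 = call_pav_present_in_query(sim$genomes$ruf, blocks$sat_ruf,
                                     sim$genomes$sat, config, "RS10",
                                     sim$genes_by_genome$ruf),
    rs01 = call_pav_absent_in_query(sim$genomes$sat, blocks$sat_ruf, config,
                                    "RS01", sim$genes_by_genome$sat),
    ns10 = call_pav_present_in_query(sim$genomes$niv, blocks$sat_niv,
                                     sim$genomes$sat, config, "NS10",
                                     sim$genes_by_genome$niv),
    ns01 = call_pav_absent_in_query(sim$genomes$sat, blocks$sat_niv, config,
                                    "NS01", sim$genes_by_genome$sat))

  ## dedicated single-branch pair simulations for truth recovery -----------
  say("scorecard: pair simulations (%d bp ancestor)", pair_length)
  panc0 <- simulate_ancestor(pair_length, seed = seed + 20, genome_id = "pair_anc")
  pplant <- plant_genes(panc0, max(10, round(n_genes * pair_length / anc_length)),
                        seed = seed + 21)
  panc <- pplant$genome

  ## small variants: substitution/indel-only branch
  var_sim <- evolve(panc, evolution_params(pav_count = 0, cnv_count = 0),
                    genome_id = "var_branch", genes = pplant$genes,
                    seed = seed + 22)
  var_blocks <- align_genomes(panc, var_sim$genome, config)
  var_calls <- call_small_variants(var_blocks, panc, var_sim$genome, config)
  small_score <- score_small_variants(var_calls, var_sim$truth, panc)

  ## structural variants: 10 plain indels >= 50 bp and 5 tandem gains on
  ## the query branch, 5 tandem gains on the reference branch (seen as
  ## tandem contractions)
  sv_par <- evolution_params(pav_count = 10, pav_len = c(50, 500),
                             cnv_count = 5, cnv_len = c(1000, 2000),
                             cnv_copy_weights = c("0" = 0, "2" = 0.5, "3" = 0.5))
  sv_simA <- evolve(panc, sv_par, genome_id = "sv_qry", seed = seed + 23)
  sv_simB <- evolve(panc, evolution_params(
    pav_count = 0, cnv_count = 5, cnv_len = c(1000, 2000),
    cnv_copy_weights = c("0" = 0, "2" = 0.5, "3" = 0.5)),
    genome_id = "sv_ref", seed = seed + 24)
  sv_callsA <- classify_large_variants(align_genomes(panc, sv_simA$genome, config),
                                       config)
  sv_callsB <- classify_large_variants(align_genomes(sv_simB$genome, panc, config),
                                       config)
  scA <- score_sv_categories(sv_callsA, expected_sv_table(sv_simA$truth, "qry"))
  scB <- score_sv_categories(sv_callsB, expected_sv_table(sv_simB$truth, "ref"))
  sv_score <- list(matched = scA$matched + scB$matched,
                   total = scA$total + scB$total,
                   accuracy = (scA$matched + scB$matched) / (scA$total + scB$total))

  ## presence-absence: segmental events only, on a branch long enough to
  ## hold 20 multi-kb segments
  seg_len <- max(2e5, pair_length)
  seg_anc <- simulate_ancestor(seg_len, seed = seed + 28, genome_id = "seg_anc")
  pav_sim <- evolve(seg_anc, evolution_params(pav_count = 20),
                    genome_id = "pav_branch", seed = seed + 25)
  pav_blocks <- align_genomes(seg_anc, pav_sim$genome, config)
  gains <- pav_sim$truth[pav_sim$truth$type == "pav_gain", , drop = FALSE]
  losses <- pav_sim$truth[pav_sim$truth$type == "pav_loss", , drop = FALSE]
  pav_pres <- call_pav_present_in_query(pav_sim$genome, pav_blocks, seg_anc, config)
  pav_abs <- call_pav_absent_in_query(seg_anc, pav_blocks, config)
  pav_score <- list(
    gains = score_pav(pav_pres$records,
                      data.frame(chrom = gains$chrom, start = gains$der_start,
                                 end = gains$der_end)),
    losses = score_pav(pav_abs$records,
                       expected_absence_records(losses, config)))

  say("cnv: %d planted events at depth %d", cnv_count, mean_depth)
  cnv_sim <- evolve(seg_anc, evolution_params(snp_rate = 0, indel_rate = 0,
                                              pav_count = 0, cnv_count = cnv_count,
                                              cnv_len = c(1000, 2000)),
                    genome_id = "cnv_branch", seed = seed + 26)
  depth <- simulate_depth(seg_anc, cnv_sim$truth, mean_depth = mean_depth,
                          seed = seed + 27)
  cnv <- call_cnv(depth, config)

  st <- pg$stats
  rel_err <- function(a, b) if (b == 0) as.numeric(a != 0) else abs(a - b) / b
  scorecard <- list(
    pan = list(core_bp = st$core_bp, core_bp_expected = truth_pan$core_bp,
               core_rel_err = rel_err(st$core_bp, truth_pan$core_bp),
               dispensable_rel_err = rel_err(st$dispensable_bp,
                                             truth_pan$dispensable_bp),
               specific_rel_err = rel_err(sum(st$specific_bp),
                                          sum(truth_pan$specific_bp))),
    small = small_score,
    sv = sv_score,
    pav = pav_score,
    cnv = score_cnv(cnv, cnv_sim$truth))

  result <- list(sim = sim, blocks = blocks, pangenome = pg,
                 membership = membership, truth_pan = truth_pan,
                 variants = vars, large_variants = large, pav = pav,
                 depth = depth, cnv = cnv, scorecard = scorecard,
                 config = config, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  for (g in names(result$sim$genomes))
    write_genome_fasta(result$sim$genomes[[g]], p(paste0(g, ".fa")))
  write_gff3(result$sim$genes, p("ancestor_genes.gff3"))
  for (nm in names(result$blocks))
    write_alignment_coords(result$blocks[[nm]], p(paste0(nm, ".coords")))
  seg <- result$pangenome$segments
  write_bed(cbind(seg[, c("chrom", "start", "end")], name = seg$klass),
            p("pan_segments.bed"), extra = "name")
  jsonlite::write_json(result$pangenome$stats, p("pan_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  write_vcf(result$variants, result$sim$genomes$sat, p("sat_ruf.vcf"))
  write.table(result$large_variants, p("large_variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(result$pav)) {
    r <- result$pav[[nm]]$records
    if (nrow(r) > 0)
      write_bed(cbind(r[, c("chrom", "start", "end")], name = r$klass),
                p(paste0("pav_", nm, ".bed")), extra = "name")
  }
  write.table(result$cnv, p("cnv_regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(result$scorecard, p("scorecard.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' The paper-trail percentage table
#'
#' The printed numerators and denominators of the published comparison
#' (core and two-genome pan sizes, gene-class counts, conserved-core-gene
#' recovery, positively selected gene fraction) packaged as data, for
#' recomputation of the printed percentages with
#' [printed_fraction_report()].
#'
#' @return data.frame(label, numerator, denominator, decimals, printed).
#' @export
reported_counts <- function() {
  path <- system.file("extdata", "reported_counts.csv", package = "tripan")
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
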