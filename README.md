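# tripan

Tri-genome pan-genome comparison and variant classification, in the style
of assembly-based rice pan-genome studies: a cultivated genome (SAT) is
compared with two wild relatives (RUF, NIV) by pairwise whole-genome
alignment, and the alignments drive every downstream analysis —
core/dispensable/specific classification of the pan-genome, SNP and small
indel extraction with functional effects, a six-category classifier for
large (>= 10 bp) structural variants, presence-absence variation (PAV)
calling, read-depth copy-number (CNV) calling, and Fisher exact-test
gene-set enrichment.

The package is aimed at comparative genomicists who want the published
*rules* of such an analysis as tested, reusable code. Since the original
assemblies are far beyond desk scale, a three-genome evolution simulator
with complete truth sets is part of the package: every stage is validated
by recovering planted events.

## The core definitions

With pairwise one-to-one whole-genome alignments between the pivot genome
S and the two others R and N:

* **core**: bases of S aligned to both R and N (and, gene-level, genes
  whose CDS is >= 80% covered by sequence aligned to all three genomes);
* **dispensable**: bases present in exactly two genomes;
* **specific**: bases present in one genome only;
* **pan**: `|S| + |R unaligned to S| + |N unaligned to S and R|`, so that
  `pan = core + dispensable + sum(specific)` holds exactly;
* **PAV**: segments > 100 bp with no aligned coverage whose best
  realignment identity is < 95%, absence-side blocks merged when closer
  than 500 bp (classes RS10/RS01/NS10/NS01 relative to the pivot);
* **CNV**: runs >= 500 bp of depth windows whose normalized depth leaves
  the neutral band (working thresholds 0.5/1.5; the published 1.2/1.8
  pair is available as a config option);
* **large-effect mutation**: a coding SNP/indel causing stop gain, stop
  loss, or a frameshift;
* **large variants**: >= 10 bp, classified from alignment-gap geometry as
  insertion, deletion, repeat expansion/contraction, or tandem
  expansion/contraction.

## Worked example

```r
library(tripan)

res <- run_pipeline(seed = 5, anc_length = 60000, n_genes = 15,
                    params = evolution_params(pav_count = 6,
                                              pav_len = c(300, 1500),
                                              pav_target_gene_frac = 0.5),
                    pair_length = 40000, cnv_count = 8, quiet = TRUE)
print(res$pangenome)
#> pan-genome: 66,921 bp
#>   core        50,895 bp (76.1%)
#>   dispensable 8,426 bp (12.6%)
#>   specific    7,600 bp (11.4%)
str(res$scorecard$small[c("snp_precision", "snp_recall")])
#> List of 2
#>  $ snp_precision: num 1
#>  $ snp_recall   : num 1
res$scorecard$sv
#> $matched
#> [1] 20
#> $total
#> [1] 20
#> $accuracy
#> [1] 1
```

A 60 kb ancestor evolves into three genomes; the pan-genome partition
says 76.1% of the 67 kb pan-genome is shared by all three descendants,
12.6% by exactly two, and 11.4% is genome-specific — and the scorecard
reports that every planted SNP was recovered exactly and all 20 planted
structural variants got the right category. The full study-scale run is
driven by the numbered scripts:

```sh
Rscript analysis/01_simulate.R   # 3 x 1 Mb trio with truth sets
Rscript analysis/02_align.R      # three pairwise one-to-one alignments
Rscript analysis/03_pangenome.R  # core/dispensable/specific + gene classes
Rscript analysis/04_variants.R   # SNPs/indels, effects, large variants
Rscript analysis/05_pav_cnv.R    # PAV (four classes) and CNV calling
Rscript analysis/06_enrichment.R # enrichment + printed-percentage table
```

Each writes its tables under `results/` and prints a summary of what it
found.

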