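label,numerator,denominator,decimals,printed
core_genome_pct,317729226,515500353,1,61.6
two_genome_pan_pct,474815432,515500353,1,92.1
core_gene_pct,14135,51533,1,27.4
dispensable_gene_pct,22979,51533,1,44.6
busco_core_pct,1402,1440,2,97.36
psg_pct,2053,10206,1,20.1
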