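name: DEMO1
chrom: amplicon1
tss: 500
strand: +
region_start: 1
region_end: 274
snp_position: 145
snp_ref: G
snp_alt: C
snp_role: pam
sgrna_sites: locus:116-135:136;allele:123-142:143
fasta: DEMO1.fasta
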