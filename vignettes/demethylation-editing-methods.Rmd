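---
title: "Methods: allele-specific demethylation editing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific demethylation editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demedit)
```

# Scope and model

`demedit` analyzes targeted DNA demethylation experiments in which a
dCas9-SunTag scaffold recruits the TET1 catalytic domain to a
methylated promoter amplicon, optionally to one allele singled out by
a heterozygous G-to-Y SNP that completes an NGG PAM on that allele
only. The read-out is strand-specific amplicon bisulfite sequencing:
unmethylated cytosines deaminate and are read as thymine, 5-methyl-
cytosine resists conversion and is read as cytosine. Everything the
package computes derives from that asymmetry.

The analysis unit is a single amplicon with at most two haplotype
references. This changes the computational problem compared to a
genome-scale bisulfite workflow: instead of a heuristic mapper we can
compare every read against both references exhaustively, which is
exact and fast at a few hundred basepairs. The conventional
trim/merge/map/call tool chain is therefore replaced by small,
testable, amplicon-scale reimplementations behind the same conceptual
interfaces (merging, bisulfite-aware alignment, per-CpG calling,
conversion QC).

## Coordinates

All coordinates are 1-based inclusive, matching the R/Bioconductor
sequence ecosystem the package is built on (Biostrings, IRanges). BED
and bedGraph exports convert to those formats' 0-based half-open
convention at the boundary. CpG identity **across alleles** is defined
by amplicon coordinate, not by allele-local site index, because a SNP
can create or destroy a CpG and thereby shift indices; the
`cpg_correspondence` table keeps allele-local indices side by side and
flags allele-unique sites instead of dropping them. Reports show both
views, since published site numberings are allele-local.

# The synthetic data generator

Each simulated molecule is drawn as: allele ~ Bernoulli(allele
fraction); per-CpG methylation states independent Bernoulli(m[allele,
site]); top-strand bisulfite conversion (unmethylated C→T with
probability `conversion_rate`, methylated C→T with
`overconversion_rate`, non-CpG cytosines always treated as
unmethylated); per-base uniform substitution error applied to each
mate independently; mates are the two amplicon ends, overlapping in
the middle. Ground truth (allele of origin, per-CpG states) is
emitted per read, keyed by read id, so downstream oracle tests are
exact rather than statistical where possible.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `conversion_rate` | 0.995 | typical completed bisulfite conversion |
| `overconversion_rate` | 0.005 | rare 5mC deamination |
| `seq_error_rate` | 0.001 | post-filter Illumina substitution rate |
| `allele_fraction` | 0.5 | heterozygous two-allele locus |
| `n_read_pairs` | 5000 | plausible amplicon depth; the source study does not print its depth |
| `read_length` | 150 bp | paired-end amplicon sequencing; chosen so mates overlap the 274-bp demo amplicon by 26 bp |

Only the top-converted strand is simulated by default because
strand-specific amplicon bisulfite PCR selects one converted template;
a `strand = "bottom"` flag mirrors the rule to the other strand.
Methylation states are independent across sites and reads — published
profiles report only marginal per-site levels, so no co-methylation
model is fitted. Base qualities are constant; quality modeling, PCR
duplicates/chimeras, indel errors and barcode hopping are out of
scope. Passing tests therefore demonstrate correctness of the
analysis under this generative model, not robustness to artifacts the
model excludes (e.g. real conversion failure is molecule-correlated,
which the conversion QC filter addresses, but chimeric reads are never
produced).

The built-in demo locus is a fully synthetic 274-bp two-allele
amplicon: 16 CpG units whose spacers are made pairwise-distinct via
the sixteen codewords of the [8,4] extended Hamming code (minimum
distance 4), so no shifted read-pair overlap can mimic the true one —
a deliberately non-repetitive sequence, as real amplicons are. The
G>C SNP sits between CpG units 8 and 9 in an `AG[G/C]T` context: the
G allele completes an AGG PAM, the C allele breaks it without
creating a CpG. An allele-specific protospacer (20 nt upstream of
that PAM) and a locus-specific protospacer starting 7 bp away mirror
the two-guide design of an allele-resolution study.

# Read processing

**Merging.** Mate 2 is reverse-complemented and every overlap length
from `min_overlap` (default 20 bp) to the shorter mate length is
evaluated; overlaps whose mismatch fraction exceeds
`max_mismatch_frac` (default 0.1) are discarded as candidates, and
among the admissible overlaps the one with the most matching bases
wins. Restricting candidates first is what makes the rule robust:
maximizing matches alone would favor long spurious overlaps on
repetitive sequence. Disagreements inside the overlap resolve to the
higher-quality base; with the simulator's constant qualities this
deterministically favors mate 1. A pair with no admissible overlap is
rejected and counted.

**Reference conversion and alignment.** Each haplotype is converted
in silico (non-CpG C→T on the top strand) with CpG cytosines kept as
masked ambiguity positions where read C (methylated) and read T
(unmethylated) both count as matches. Bisulfite asymmetry is encoded
only as read-T-versus-reference-C; read C against reference T is a
mismatch. Scoring is match +1 / mismatch −1, and a read is assigned
to the best-scoring haplotype. Reads whose length equals the
reference length — all merged amplicon-spanning reads — are scored by
direct ungapped comparison, which is exact here; other lengths fall
back to affine-gap global alignment (gap open 4, gap extend 1,
IUPAC-Y-masked reference) via `Biostrings::pairwiseAlignment()`.
Ties between references (e.g. a rare unconverted SNP cytosine that
matches neither reference better) resolve to the first reference;
allele attribution never relies on this, because allele calls come
from the SNP rule below, not from mapping.

**Calling and QC.** At each reference CpG cytosine the read base maps
to methylated (C), unmethylated (T) or ambiguous (anything else);
gapped positions are uncovered. The non-CpG conversion fraction —
fraction of reference non-CpG cytosine positions read as T — is the
per-read conversion QC; reads below `min_conversion` (default 0.9)
or below `min_identity` (default 0.8) are removed and counted per
filter. With `min_conversion = 0` nothing is conversion-filtered.

**Allele assignment.** At a G>C (or G>T) PAM SNP the rule is
bisulfite-aware: read G claims the G allele; for a pyrimidine allele
whose C lies outside any CpG, read T *or* C claims that allele (the
unmethylated C converts, a rare unconverted C is still the same
allele); if the alternative C creates a CpG, C and T still both claim
that allele and the base is additionally recorded as a methylation
observation. Any other base, a gap, or an uncovered SNP leaves the
read unassigned — it still contributes to the pooled (locus-mode)
profile.

# Quantitative analysis

Per-site methylation levels are methylated/(methylated+unmethylated)
counts; zero-coverage sites are flagged `NA`, never 0. Replicate
profiles are averaged per site, unweighted, before any further step
(the convention of averaged biological triplicates). Site selection
takes the day-6 treated versus untreated contrast on the
replicate-averaged profiles, computes the per-site drop, and keeps
sites with at least 50% of the maximal drop; the resulting set is
frozen and reused for every sample of the experiment, including the
off-target allele in allele mode. Whether the maximum should be taken
per replicate or on the replicate average is not decidable from
published descriptions; this package uses the average, which is less
noise-sensitive. Guide-footprint CpGs (sites protected by bound dCas9)
are not explicitly excluded — the 50% rule excludes them
automatically, which is documented behavior rather than an accident.

On the selected sites, M values are unweighted means of per-site
levels (not read-pooled counts), in percent. Then
D = (M<sub>control</sub> − M<sub>treated</sub>)/M<sub>control</sub> × 100,
stability = D<sub>day15</sub>/D<sub>day6</sub> × 100, and the
specificity fold D<sub>target</sub>/D<sub>background</sub> is rounded
half-up to an integer to match "n-fold" reporting (half-up, not
banker's rounding, so 7.5 reports as 8). Degenerate inputs raise
errors rather than propagate: M<sub>control</sub> ≤ 0 (efficiency
undefined), D<sub>day6</sub> ≤ 0 (stability undefined); a
non-positive background yields an explicit infinite-specificity flag
with a warning. Group comparisons use the classical two-sided
pooled-variance t-test, labelled "n.s." above p = 0.05.

# Expression-ratio analysis

Transcript (cDNA) and genomic amplicons are unconverted, so no
bisulfite logic applies. Reads are anchored at the 12 bases 5' of the
SNP (exact match first, then one mismatch, then the reverse
orientation) and the following base is tallied; "other" bases leave
the denominator. The genomic allele frequency comes from genomic
amplicon sequencing, never from bisulfite data. The expected
frequency under a copy-number model is target copies / total copies
(database copy numbers may be fractional; the integer-copy reading is
a reporting aid). Phasing pairs the genomic PAM-SNP allele with the
exonic-SNP allele of closest read fraction and raises an explicit
ambiguity error when the two candidate pairings differ by less than
`tolerance` (default 0.1 — allelic ratios near 0.5 cannot be phased
by ratio and must not be guessed silently). The expression shift is
the fold change of the target-allele fraction between locus- and
allele-specific treatment, reported exact, at one decimal, and as an
integer fold. −ΔCq = −(Cq<sub>target</sub> − Cq<sub>reference</sub>)
with undetected targets clamped to the 40-cycle limit of detection
before the difference; reference Cq values outside (0, 40] are
rejected.

# Guide design

The PAM-SNP scan considers both strands: a candidate is a
heterozygous G-to-Y SNP where the G allele completes an NGG whose GG
contains the SNP base and the pyrimidine allele breaks it, within
±2000 bp of the TSS (the promoter window), prioritized when inside a
supplied methylated-CGI interval. SNPs inside the 20-nt protospacer
of an allele-shared PAM are reported as a secondary, flagged
candidate class. Protospacers are exactly the 20 bases 5' of the PAM;
fewer than 20 bases of context is an error. Off-target enumeration is
an exhaustive Hamming scan of both strands at every NGG/NAG-adjacent
20-mer up to `max_mismatches` (default 3 — a repository choice, the
mismatch cutoff of the original online scans not being stated), which
keeps the scan exact; bulges/indels and efficiency scoring are out of
scope. Scope is sequence-file level (promoter FASTA + SNP table), not
genome-wide.

# Problem sizes and numerical checks in the test suite

The simulation-based acceptance checks run an allele-resolution time
course at the study's design scale: 5,000 read pairs per sample,
three biological replicates, untreated/day-6/day-15 conditions, with
the generative methylation levels 0.977 / 0.268 / 0.367 at the
responsive sites and an off-target allele at 0.85 with 5% background
demethylation. Oracle-equivalence checks use 1,000 pairs (merging),
a 10-kb random subject (off-target scan) and 400 error-free reads
(call-by-call ground-truth comparison). Stochastic property tests
state their sampling tolerances explicitly in terms of binomial
standard errors of the sizes actually simulated (e.g. the
ratio-shift bias check averages 20 seeds of 2,000 reads, whose mean
has ≈1% sampling error). Smaller unit fixtures are built in code.

# Known limitations

* Only substitution errors and complete reads are modeled; indel-rich
  or chimeric data will fall back to gapped alignment or be rejected
  at merging, and adapters are assumed already trimmed (a pass-through
  for pre-trimmed real data, since simulated reads carry none).
* One PAM SNP per locus is supported in the locus model;
  multi-SNP haplotypes would need the correspondence machinery
  extended.
* Demultiplexing is reduced to one FASTQ pair per sample; barcode
  schemes are upstream of this package.
* 5mC oxidation intermediates (5hmC/5fC/5caC) are biological context
  only — bisulfite sequencing cannot distinguish them from 5mC/C, and
  the package does not attempt to.
* The statistics quantify a demethylation time course; general
  differential-methylation testing beyond the stated t-tests is out
  of scope.
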