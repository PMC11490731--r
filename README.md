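# demedit

Analysis toolkit for **allele-specific DNA demethylation editing**
experiments read out by amplicon bisulfite sequencing.

In these experiments a catalytically dead Cas9 (dCas9-SunTag) recruits
the TET1 catalytic domain to a methylated promoter CpG island and
erases 5-methylcytosine there. When the locus carries a heterozygous
G-to-Y SNP that completes an NGG PAM on only one haplotype, the guide
RNA can address a single allele: the PAM-bearing ("on-target") allele
is demethylated while the other allele is left alone. `demedit` covers
the complete computational side of such a study at amplicon scale, for
epigenome-editing groups who want a tested, reproducible replacement
for ad-hoc spreadsheet pipelines:

* an amplicon/haplotype data model (two-allele loci, per-allele CpG
  maps, SNP-aware CpG correspondence);
* a bisulfite read **simulator** with per-allele per-CpG methylation
  states, incomplete/over-conversion and sequencing error, so every
  downstream stage is testable without external data;
* paired-read **merging**, bisulfite-aware **alignment** to the two
  converted haplotype references, per-read CpG **methylation calls**
  and conversion QC;
* SNP-tag **allele splitting** and per-allele methylation profiles;
* the quantitative statistics of a demethylation time course;
* **allelic expression ratios** from transcript amplicons, with
  read-ratio phasing of the genomic PAM SNP and an exonic SNP, and
  −ΔCq qPCR reporting with a limit-of-detection clamp;
* allele-specific **sgRNA design** (PAM-SNP scan, 20-nt protospacer
  extraction) and exhaustive mismatch off-target enumeration.

## The statistics at the core

For the CpG sites showing at least 50% of the maximal demethylation
effect (selected on the day-6 vs untreated contrast and then frozen for
all samples of the experiment), with mean methylation levels in
percent:

* demethylation efficiency **D** = (M<sub>control</sub> −
  M<sub>treated</sub>) / M<sub>control</sub> × 100
* **stability** = D<sub>day15</sub> / D<sub>day6</sub> × 100
* **specificity fold** = D<sub>target</sub> / D<sub>background</sub>,
  rounded half-up to an integer, where the background is either a
  scrambled-sgRNA control (locus mode) or the off-target allele
  (allele mode).

Allelic expression shifts are fold changes of the target-allele read
fraction at an exonic SNP between locus- and allele-specific
treatment; the exonic SNP is phased to the genomic PAM SNP by matching
allelic read ratios, with an explicit error when both ratios sit near
0.5.

## Worked example

Simulate and analyze an allele-specific demethylation time course on
the built-in synthetic two-allele locus (16 CpGs, G>C PAM SNP;
on-target allele 97.7% methylated, dropping to 26.8% at day 6 and
36.7% at day 15 at the responsive sites; off-target allele at 85% with
5% background demethylation; 5,000 read pairs per sample, three
replicates):

```r
library(demedit)

res <- run_demo_experiment(seed = 101, mode = "allele",
                           conditions = c("untreated", "day6", "day15"),
                           replicates = 3, n_read_pairs = 5000)
res$pipeline
#> <pipeline_result: 9 samples, mode=allele>
#> <demethylation_result [allele1]: 6 sites, M_control 97.1%, D_day6 71.8%, stability 87.0%>
#> <demethylation_result [allele2]: 6 sites, M_control 84.9%, D_day6 4.9%, stability 89.1%>
```

The pipeline selects the six responsive CpG sites (site-selection
rule), recovers the on-target day-6 demethylation efficiency (71.8%
against a generative truth of 72.6%), its stability to day 15 (87.0%),
and an on/off-target allele specificity of 71.8 / 4.9 ≈ 15-fold.
Per-sample profiles, the demethylation summary, a QC JSON and bedGraph
tracks are written when `out_dir` is given; every table header records
tool version, seed and a config hash.

A file-based locus definition (flat key-value config plus a haplotype
FASTA) ships under `inst/extdata/` and loads with
`load_locus_config()`.

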