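Package: demedit
Title: Allele-Specific DNA Demethylation Editing Analysis from Bisulfite
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for targeted DNA demethylation (dCas9-SunTag
    recruitment of the TET1 catalytic domain) experiments read out by
    amplicon bisulfite sequencing. Provides an amplicon/haplotype data
    model for loci carrying a heterozygous PAM SNP, a bisulfite read
    simulator with per-allele per-CpG methylation states and conversion
    error, paired-read merging and bisulfite-aware alignment with
    per-read CpG methylation calls, SNP-based allele splitting,
    demethylation efficiency / stability / specificity statistics,
    allelic expression-ratio analysis with read-ratio SNP phasing, and
    allele-specific sgRNA target design with mismatch off-target
    enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
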