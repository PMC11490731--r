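# A deterministic synthetic two-allele demo locus. The sequence is built
# by construction (no RNG): a C-free left flank, CpG units separated by
# pairwise-distinct spacers that contain non-CpG cytosines (needed for
# conversion QC), a heterozygous G>C SNP whose G allele completes an AGG
# PAM, and a right flank. It emulates the structure of a promoter CpG
# island amplicon with a PAM-disrupting SNP; it is synthetic, not a
# human sequence.
#
# Spacer template: positions 3 and 11 are fixed non-CpG Cs, 7-8 a fixed
# GG (so a locus-specific NGG PAM exists near the SNP), and the eight
# remaining positions carry A/T letters taken from the sixteen codewords
# of the [8,4] extended Hamming code. Any two spacers therefore differ
# at >= 4 positions, so no shifted read-pair overlap can reach the 90%
# identity a merge requires -- repeats that similar would defeat any
# overlap merger, and real amplicons are not periodic.

# 16 codewords of the [8,4,4] extended Hamming code
.hamming84 <- function() {
  words <- matrix(0L, 16L, 8L)
  for (i in 0:15) {
    d <- as.integer(intToBits(i))[1:4]
    words[i + 1L, ] <- c(d,
                         (d[2] + d[3] + d[4]) %% 2L,
                         (d[1] + d[3] + d[4]) %% 2L,
                         (d[1] + d[2] + d[4]) %% 2L,
                         (d[1] + d[2] + d[3]) %% 2L)
  }
  words
}

# spacer for CpG unit i (1-based); 12 bp, no CG dinucleotide
.demo_spacer <- function(i) {
  at <- c("A", "T")[.hamming84()[((i - 1L) %% 16L) + 1L, ] + 1L]
  paste0(at[1], at[2], "C", at[3], at[4], at[5], "GG", at[6], at[7], "C", at[8])
}

#' Build the synthetic demonstration locus
#'
#' Constructs a deterministic two-allele amplicon: 16 CpG sites, a
#' heterozygous G>C SNP between CpG sites 8 and 9 whose G allele (allele
#' 1) completes an AGG PAM while the C allele breaks it (the alt C is
#' followed by T, so no CpG is created), an allele-specific sgRNA site
#' (20 nt upstream of that PAM) and a locus-specific sgRNA site starting
#' within 20 bp of it.
#'
#' @param n_cpg number of CpG units (default 16).
#' @return list with `locus` ([target_locus()]), `haplotypes` (list of
#'   two [allele_haplotype()]) and `correspondence`.
#' @export
demo_locus <- function(n_cpg = 16L) {
  if (n_cpg < 10L || n_cpg > 16L) {
    stop("demo locus supports 10-16 CpG units", call. = FALSE)
  }
  left <- "ATTGAATGGATTAGTAGATTGAATTAGATG"        # C-free flank
  unit <- function(i) paste0("CG", .demo_spacer(i))
  # SNP cassette inserted after CpG unit 8: AG[G/C]T -- G completes AGG
  n_left_units <- 8L
  pre <- paste0(left,
                paste(vapply(seq_len(n_left_units), unit, ""), collapse = ""),
                "A", "G")
  snp_pos <- nchar(pre) + 1L
  post <- paste0("T",
                 paste(vapply((n_left_units + 1L):n_cpg, unit, ""), collapse = ""),
                 "ATTGAATAGATTGAAT")
  seq1 <- paste0(pre, "G", post)
  seq2 <- paste0(pre, "C", post)

  snp <- snp_spec(snp_pos, "G", "C", role = "pam")
  # allele-specific protospacer: 20 nt 5' of the PAM (PAM = snp_pos-2 .. snp_pos)
  pam_start <- snp_pos - 2L
  allele_site <- c(pam_start - 20L, pam_start - 1L)
  # locus-specific site: a nearby NGG PAM shared by both alleles; the GG of
  # the spacer "TTAGGATCA" upstream provides one. Find the GG closest to the
  # allele-specific PAM but distinct from it, with start within 20 bp.
  gg <- gregexpr("GG", seq1, fixed = TRUE)[[1]]
  gg <- gg[gg != pam_start + 1L & gg > 23L]
  locus_pam <- gg[which.min(abs(gg - 1L - pam_start))] - 1L  # PAM = NGG start
  locus_site <- c(locus_pam - 20L, locus_pam - 1L)

  sg <- data.frame(label = c("locus", "allele"),
                   start = c(locus_site[1], allele_site[1]),
                   end = c(locus_site[2], allele_site[2]),
                   pam_start = c(locus_pam, pam_start))
  locus <- target_locus("DEMO1", "amplicon1", tss = 500L, strand = "+",
                        region = c(1L, nchar(seq1)), sgrna_sites = sg,
                        snp = snp)
  h1 <- allele_haplotype("allele1", seq1, snp)
  h2 <- allele_haplotype("allele2", seq2, snp)
  validate_haplotype_pair(h1, h2, snp)
  list(locus = locus, haplotypes = list(allele1 = h1, allele2 = h2),
       correspondence = build_cpg_correspondence(h1, h2))
}

#' Per-CpG methylation arrays for a demethylation time course
#'
#' Emulates a locus-specific or allele-specific demethylation experiment
#' on the demo locus: the on-target allele starts highly methylated
#' (0.977), the editing drops a block of "responsive" CpG sites (indices
#' 9-14) to 0.268 at day 6 with partial regain to 0.367 at day 15; the
#' dCas9 footprint sites (6-7) stay protected; the remaining sites show
#' a weaker effect that falls below the 50%-of-maximum selection rule.
#' The scrambled control loses ~12% methylation uniformly. The
#' off-target allele sits at 0.85 and is demethylated only by the
#' configurable untargeted background activity.
#'
#' @param n_cpg number of CpG sites (matching [demo_locus()]).
#' @param off_target_d background demethylation fraction of the
#'   off-target allele at day 6 (default 0.05, i.e. 5% D).
#' @return named list of per-sample-condition lists, each with elements
#'   `allele1` and `allele2` (numeric vectors of per-CpG methylation
#'   probabilities). Conditions: `untreated`, `scrambled`, `day3`,
#'   `day6`, `day9`, `day15`.
#' @export
demo_methylation_arrays <- function(n_cpg = 16L, off_target_d = 0.05) {
  responsive <- 9:14
  footprint <- 6:7
  base_on <- rep(0.977, n_cpg)
  base_off <- rep(0.85, n_cpg)
  treated <- function(m_resp, m_other) {
    m <- rep(m_other, n_cpg)
    m[responsive] <- m_resp
    m[footprint] <- 0.95
    m
  }
  off_at <- function(d) base_off * (1 - d)
  list(
    untreated = list(allele1 = base_on, allele2 = base_off),
    scrambled = list(allele1 = base_on * 0.88, allele2 = off_at(0.03)),
    day3  = list(allele1 = treated(0.45, 0.75), allele2 = off_at(off_target_d / 2)),
    day6  = list(allele1 = treated(0.268, 0.65), allele2 = off_at(off_target_d)),
    day9  = list(allele1 = treated(0.32, 0.68), allele2 = off_at(off_target_d)),
    day15 = list(allele1 = treated(0.367, 0.70), allele2 = off_at(off_target_d * 0.8))
  )
}

#' Sample design for the demo time course
#'
#' @param conditions subset of names of [demo_methylation_arrays()] to
#'   include (default: untreated, scrambled, day6, day15).
#' @param replicates biological replicates per condition.
#' @param treatment treatment label for the edited samples (`"allele"`
#'   or `"locus"`).
#' @return data.frame with columns sample_id, treatment, day, replicate,
#'   condition.
#' @export
demo_design <- function(conditions = c("untreated", "scrambled", "day6", "day15"),
                        replicates = 3L, treatment = "allele") {
  rows <- lapply(conditions, function(cond) {
    trt <- switch(cond, untreated = "untreated", scrambled = "scrambled",
                  treatment)
    day <- switch(cond, untreated = 0L, scrambled = 6L,
                  as.integer(sub("^day", "", cond)))
    data.frame(sample_id = sprintf("%s_rep%d", cond, seq_len(replicates)),
               treatment = trt, day = day, replicate = seq_len(replicates),
               condition = cond)
  })
  do.call(rbind, rows)
}

#' Synthetic transcript amplicon with an exonic SNP
#'
#' A short unconverted (cDNA) amplicon carrying a heterozygous A/T SNP,
#' used by the expression-ratio analysis. Deterministic by construction.
#'
#' @return list with `sequence`, `sequence_alt`, `snp` ([snp_spec()],
#'   role `"exonic"`).
#' @export
demo_transcript_amplicon <- function() {
  # non-repetitive random backbone from a fixed seed, so SNP-flanking
  # anchors are unique within the amplicon
  backbone <- withr::with_seed(424242L, {
    paste(sample(c("A", "C", "G", "T"), 132L, replace = TRUE), collapse = "")
  })
  snp_pos <- 67L
  s1 <- backbone; substr(s1, snp_pos, snp_pos) <- "A"
  s2 <- backbone; substr(s2, snp_pos, snp_pos) <- "T"
  list(sequence = s1, sequence_alt = s2,
       snp = snp_spec(snp_pos, "A", "T", role = "exonic"))
}
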