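# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results by the simplest possible method so the
# implementation under test is never checked against itself.

# naive CG scan: walk the string position by position
oracle_cpg_scan <- function(s) {
  ch <- strsplit(s, "")[[1]]
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

# exhaustive per-read overlap merge: enumerate every overlap, keep those
# within the mismatch budget, pick the one with most matching bases
oracle_merge_one <- function(s1, s2rc, min_overlap, max_mm_frac) {
  l1 <- nchar(s1); l2 <- nchar(s2rc)
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2rc, "")[[1]]
  best <- NULL
  for (o in min_overlap:min(l1, l2)) {
    mm <- sum(a[(l1 - o + 1):l1] != b[1:o])
    if (mm > max_mm_frac * o) next
    matches <- o - mm
    if (is.null(best) || matches > best$matches) {
      best <- list(o = o, mm = mm, matches = matches)
    }
  }
  if (is.null(best)) return(NULL)
  list(sequence = paste0(s1, substr(s2rc, best$o + 1, l2)),
       overlap = best$o, mm = best$mm)
}

# naive off-target scan: substring comparison at every position of both
# strands, no vectorization shared with the implementation
oracle_offtargets <- function(proto, subject, max_mm, pams = c("NGG", "NAG")) {
  pc <- strsplit(proto, "")[[1]]
  scan <- function(s, strand, L) {
    rows <- list()
    for (i in seq_len(nchar(s) - 22)) {
      pam <- substr(s, i + 20, i + 22)
      cls <- if (substr(pam, 2, 3) == "GG") "NGG"
             else if (substr(pam, 2, 3) == "AG") "NAG" else NA
      if (is.na(cls) || !cls %in% pams) next
      w <- strsplit(substr(s, i, i + 19), "")[[1]]
      mm <- sum(w != pc)
      if (mm <= max_mm) {
        pos <- if (strand == "+") i else L - (i + 19) + 1
        rows[[length(rows) + 1]] <- data.frame(
          position = pos, strand = strand, mismatches = mm, pam = pam)
      }
    }
    do.call(rbind, rows)
  }
  L <- nchar(subject)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(subject)))
  out <- rbind(scan(subject, "+", L), scan(rc, "-", L))
  if (is.null(out)) return(data.frame(position = integer(0), strand = character(0),
                                      mismatches = integer(0), pam = character(0)))
  out[order(out$mismatches, out$position), , drop = FALSE]
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# random DNA string from an explicit local RNG state
random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# tiny two-allele pair where the SNP creates a CpG on allele2
cpg_gain_haplotypes <- function() {
  snp <- snp_spec(2, "G", "C", role = "pam")
  h1 <- allele_haplotype("allele1", "AGGCGA", snp)
  h2 <- allele_haplotype("allele2", "ACGCGA", snp)
  list(h1 = h1, h2 = h2, snp = snp)
}

# turn per-read ground-truth methylation state strings into a long
# data.frame comparable with align_reads() calls
gt_calls_long <- function(ground_truth, haplotypes) {
  do.call(rbind, lapply(seq_len(nrow(ground_truth)), function(i) {
    al <- ground_truth$allele[i]
    states <- as.integer(strsplit(ground_truth$meth_states[i], "")[[1]])
    data.frame(read_id = ground_truth$read_id[i],
               position = haplotypes[[al]]$cpg_positions,
               truth = ifelse(states == 1, "methylated", "unmethylated"))
  }))
}
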