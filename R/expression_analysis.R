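# Allelic expression-ratio analysis: SNP base counting on unconverted
# amplicon reads (genomic or cDNA), copy-number-expected frequencies,
# read-ratio phasing of the genomic PAM SNP with the exonic SNP, and
# -dCq expression reporting.

#' Count allele bases at a SNP in unconverted amplicon reads
#'
#' Reads are anchored to the (unconverted) amplicon reference by an
#' exact-context match immediately 5' of the SNP (one mismatch
#' tolerated; the reverse complement is tried for reads in the opposite
#' orientation), and the base following the anchor is tallied. The
#' allele-1 fraction excludes "other" bases from the denominator.
#'
#' @param reads named character vector of read sequences, or a FASTQ
#'   path.
#' @param reference unconverted amplicon sequence (allele-1 base at the
#'   SNP).
#' @param snp a [snp_spec()].
#' @param anchor_length bases of reference context used as anchor.
#' @return list of class `snp_count`: `counts` (named A/C/G/T/other),
#'   `n_informative`, `allele1_fraction`, `snp`.
#' @export
count_snp_alleles <- function(reads, reference, snp, anchor_length = 12L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  reference <- check_dna(reference, "reference")
  if (snp$position <= anchor_length) {
    stop("SNP too close to the amplicon start for anchoring", call. = FALSE)
  }
  anchor <- substr(reference, snp$position - anchor_length, snp$position - 1L)
  dna <- Biostrings::DNAStringSet(reads)
  base <- rep(NA_character_, length(reads))
  expected_start <- snp$position - anchor_length
  find_base <- function(set, idx, max_mm) {
    hits <- Biostrings::vmatchPattern(anchor, set[idx], max.mismatch = max_mm)
    n_hit <- lengths(hits)
    chars <- as.character(set[idx])
    # common case: exactly one anchor hit per read
    one <- which(n_hit == 1L)
    if (length(one)) {
      p <- unlist(end(hits[one]), use.names = FALSE) + 1L
      ok <- p <= nchar(chars[one])
      base[idx[one[ok]]] <<- substring(chars[one[ok]], p[ok], p[ok])
    }
    # repeats: prefer the hit at the expected amplicon offset
    for (i in which(n_hit > 1L)) {
      st <- start(hits[[i]])
      p <- end(hits[[i]])[which.min(abs(st - expected_start))] + 1L
      if (p <= nchar(chars[i])) base[idx[i]] <<- substring(chars[i], p, p)
    }
  }
  find_base(dna, seq_along(reads), 0L)       # exact anchors first (fast)
  miss <- which(is.na(base))
  if (length(miss)) find_base(dna, miss, 1L) # tolerate one anchor error
  miss <- which(is.na(base))
  if (length(miss)) {                        # opposite-orientation reads
    rc <- Biostrings::reverseComplement(dna)
    find_base(rc, miss, 0L)
    miss2 <- which(is.na(base))
    if (length(miss2)) find_base(rc, miss2, 1L)
  }
  base[is.na(base)] <- "other"
  base[!base %in% c("A", "C", "G", "T")] <- "other"
  counts <- vapply(c("A", "C", "G", "T", "other"),
                   function(b) sum(base == b), 0L)
  n_ref <- counts[[snp$ref_base]]
  n_alt <- counts[[snp$alt_base]]
  if (n_ref + n_alt == 0L) {
    stop("no informative reads at the SNP position", call. = FALSE)
  }
  structure(list(counts = counts, n_informative = n_ref + n_alt,
                 allele1_fraction = n_ref / (n_ref + n_alt), snp = snp),
            class = "snp_count")
}

#' @export
print.snp_count <- function(x, ...) {
  cat(sprintf("<snp_count %s>%s: %d informative reads, allele1 fraction %.3f>\n",
              x$snp$ref_base, x$snp$alt_base, x$n_informative,
              x$allele1_fraction))
  invisible(x)
}

#' Expected allele frequency from a gene copy number
#'
#' Single-copy minor-allele model: with `copies` total gene copies and
#' `target_copies` of them carrying the target allele, its expected
#' genomic frequency is `target_copies / copies`, rounded to two
#' decimals for reporting.
#'
#' @param copies total copy number (may be fractional, as database
#'   estimates are).
#' @param target_copies integer copies of the target allele (default 1).
#' @return expected allele fraction, rounded to 2 decimals.
#' @export
#' @examples
#' expected_frequency_from_copy_number(3.15)      # 0.32
#' expected_frequency_from_copy_number(4.28, 3)   # 0.70
expected_frequency_from_copy_number <- function(copies, target_copies = 1L) {
  if (copies < 1) stop("copy number must be >= 1", call. = FALSE)
  if (target_copies < 1 || target_copies > copies) {
    stop("target_copies must be between 1 and the total copy number", call. = FALSE)
  }
  round_half_up(target_copies / copies, 2)
}

#' Pair genomic and exonic SNP alleles by read-ratio
#'
#' Phases the two heterozygous SNPs by matching allele frequencies: the
#' genomic (PAM) SNP allele is paired with whichever exonic SNP allele
#' has the closer read fraction. If the two candidate pairings are
#' nearly equally good (both fractions near 0.5) an explicit ambiguity
#' error is raised rather than guessing.
#'
#' @param genomic `snp_count` at the PAM SNP (genomic amplicon).
#' @param exonic `snp_count` at the exonic SNP.
#' @param tolerance minimal difference between the two pairing distances
#'   required to call the phasing (default 0.1).
#' @return list of class `snp_phasing`: `mapping` (named character:
#'   genomic allele -> exonic allele), `distance`, `alt_distance`.
#' @export
phase_by_ratio <- function(genomic, exonic, tolerance = 0.1) {
  f_g <- genomic$allele1_fraction
  f_e <- exonic$allele1_fraction
  d_same <- abs(f_g - f_e)          # genomic allele1 <-> exonic allele1
  d_cross <- abs(f_g - (1 - f_e))   # genomic allele1 <-> exonic allele2
  if (abs(d_same - d_cross) < tolerance) {
    stop("ambiguous phasing: allelic ratios too close to 0.5 ",
         sprintf("(pairing distances %.3f vs %.3f)", d_same, d_cross),
         call. = FALSE)
  }
  if (d_same < d_cross) {
    mapping <- c(allele1 = "allele1", allele2 = "allele2")
    dist <- d_same; alt <- d_cross
  } else {
    mapping <- c(allele1 = "allele2", allele2 = "allele1")
    dist <- d_cross; alt <- d_same
  }
  structure(list(mapping = mapping, distance = dist, alt_distance = alt),
            class = "snp_phasing")
}

#' Shift in allelic expression ratio
#'
#' Fold change of the target-allele expressed fraction between
#' locus-specific and allele-specific treatment.
#'
#' @param fraction_locus target-allele expressed fraction after
#'   locus-specific demethylation (or a `snp_count`).
#' @param fraction_allele the same fraction after allele-specific
#'   demethylation (or a `snp_count`).
#' @return list: `fold` (exact), `fold_1dp`, `fold_integer` (half-up
#'   rounding used for "about n-fold" reporting). `fold = Inf` with a
#'   warning when the locus-specific fraction is zero.
#' @export
#' @examples
#' expression_ratio_shift(0.21, 0.80)$fold_1dp  # 3.8
expression_ratio_shift <- function(fraction_locus, fraction_allele) {
  if (inherits(fraction_locus, "snp_count")) fraction_locus <- fraction_locus$allele1_fraction
  if (inherits(fraction_allele, "snp_count")) fraction_allele <- fraction_allele$allele1_fraction
  if (fraction_locus <= 0) {
    warning("locus-specific fraction is zero; shift is unbounded")
    return(list(fold = Inf, fold_1dp = Inf, fold_integer = Inf))
  }
  fold <- fraction_allele / fraction_locus
  list(fold = fold, fold_1dp = round_half_up(fold, 1),
       fold_integer = round_half_up(fold))
}

#' -dCq expression measure from qPCR quantification cycles
#'
#' `-dCq = -(Cq_target - Cq_reference)`; an undetected target is clamped
#' to the limit of detection (default 40 cycles) before the difference
#' is formed.
#'
#' @param cq_target quantification cycle of the target gene; `NA` means
#'   undetected.
#' @param cq_reference quantification cycle of the reference
#'   (housekeeping) gene.
#' @param lod limit of detection in cycles (default 40).
#' @return -dCq (vectorized).
#' @export
#' @examples
#' minus_delta_cq(30, 25)   # -5
#' minus_delta_cq(NA, 24)   # -16 (LOD clamp)
minus_delta_cq <- function(cq_target, cq_reference, lod = 40) {
  if (any(is.na(cq_reference))) {
    stop("reference Cq is required for every sample", call. = FALSE)
  }
  if (any(cq_reference <= 0 | cq_reference > lod)) {
    stop("reference Cq outside the plausible range (0, lod]", call. = FALSE)
  }
  cq_target[is.na(cq_target)] <- lod
  cq_target <- pmin(cq_target, lod)
  -(cq_target - cq_reference)
}

#' Read a Cq table and compute per-sample -dCq
#'
#' Input CSV columns: `sample`, `target`, `replicate`, `Cq` (empty or NA
#' Cq = undetected). The reference gene rows are identified by
#' `reference_target`; technical replicates are averaged per sample
#' before the difference.
#'
#' @param path CSV path.
#' @param reference_target name of the reference (housekeeping) gene.
#' @param lod limit of detection in cycles.
#' @return data.frame `sample`, `target`, `cq_target`, `cq_reference`,
#'   `minus_delta_cq`.
#' @export
read_cq_table <- function(path, reference_target = "SDHA", lod = 40) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "replicate", "Cq")
  if (!all(need %in% names(df))) {
    stop("Cq table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ref <- df[df$target == reference_target, , drop = FALSE]
  if (nrow(ref) == 0L) stop("no rows for reference target ", reference_target,
                            call. = FALSE)
  tgt <- df[df$target != reference_target, , drop = FALSE]
  agg <- function(d) tapply(d$Cq, list(d$sample, d$target), mean, na.rm = FALSE)
  ref_cq <- tapply(ref$Cq, ref$sample, mean)
  out <- do.call(rbind, lapply(split(tgt, list(tgt$sample, tgt$target), drop = TRUE),
    function(d) {
      ct <- mean(d$Cq)  # NA if any technical replicate undetected? keep mean of NA -> NA
      data.frame(sample = d$sample[1], target = d$target[1],
                 cq_target = ct, cq_reference = unname(ref_cq[d$sample[1]]),
                 stringsAsFactors = FALSE)
    }))
  out$minus_delta_cq <- minus_delta_cq(out$cq_target, out$cq_reference, lod = lod)
  rownames(out) <- NULL
  out
}
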