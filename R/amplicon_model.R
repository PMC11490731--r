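# Amplicon data model: loci, SNPs, allele haplotypes, CpG maps, and their
# file I/O. Coordinates are 1-based inclusive throughout the package
# (Biostrings/IRanges convention); BED export converts to 0-based
# half-open.

#' Enumerate CpG dinucleotide start positions
#'
#' @param sequence DNA string.
#' @return integer vector of 1-based positions where a "CG" dinucleotide
#'   starts (the position of the C on the top strand).
#' @export
#' @examples
#' cpg_sites("ACGT")     # 2
#' cpg_sites("CGCG")     # 1 3
cpg_sites <- function(sequence) {
  sequence <- check_dna(sequence)
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Describe a single-nucleotide polymorphism within an amplicon
#'
#' For `role = "pam"` the SNP must be G-to-Y: the reference (targetable)
#' allele carries a G completing an NGG PAM, the alternative allele a
#' pyrimidine that breaks it.
#'
#' @param position 1-based position within the amplicon.
#' @param ref_base,alt_base single bases; `ref_base` is the allele-1 base.
#' @param role `"pam"` (PAM-disrupting genomic SNP) or `"exonic"`
#'   (transcript SNP used for expression ratios).
#' @return an object of class `snp_spec`.
#' @export
snp_spec <- function(position, ref_base, alt_base, role = c("pam", "exonic")) {
  role <- match.arg(role)
  stopifnot_scalar(position, "position")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!ref_base %in% c("A", "C", "G", "T") || !alt_base %in% c("A", "C", "G", "T")) {
    stop("SNP bases must be one of A/C/G/T", call. = FALSE)
  }
  if (ref_base == alt_base) stop("ref_base and alt_base must differ", call. = FALSE)
  if (role == "pam" && (ref_base != "G" || !alt_base %in% c("C", "T"))) {
    stop("a PAM SNP must be G-to-Y (ref G, alt C or T)", call. = FALSE)
  }
  structure(list(position = as.integer(position), ref_base = ref_base,
                 alt_base = alt_base, role = role),
            class = "snp_spec")
}

#' Construct one allele's amplicon haplotype
#'
#' CpG positions are always recomputed from the sequence, never supplied.
#'
#' @param allele_id `"allele1"` or `"allele2"`.
#' @param sequence amplicon DNA sequence of this allele.
#' @param snp optional [snp_spec()]; if given, the base at its position is
#'   recorded as `snp_base`.
#' @return an object of class `allele_haplotype` with fields `allele_id`,
#'   `sequence`, `cpg_positions`, `snp_base`.
#' @export
allele_haplotype <- function(allele_id, sequence, snp = NULL) {
  if (!allele_id %in% c("allele1", "allele2")) {
    stop("allele_id must be 'allele1' or 'allele2'", call. = FALSE)
  }
  sequence <- check_dna(sequence, "haplotype sequence")
  snp_base <- NA_character_
  if (!is.null(snp)) {
    if (snp$position > nchar(sequence)) {
      stop("SNP position lies outside the amplicon", call. = FALSE)
    }
    snp_base <- substr(sequence, snp$position, snp$position)
  }
  structure(list(allele_id = allele_id, sequence = sequence,
                 cpg_positions = cpg_sites(sequence), snp_base = snp_base),
            class = "allele_haplotype")
}

#' @export
print.allele_haplotype <- function(x, ...) {
  cat(sprintf("<allele_haplotype %s: %d bp, %d CpGs, SNP base %s>\n",
              x$allele_id, nchar(x$sequence), length(x$cpg_positions),
              x$snp_base))
  invisible(x)
}

#' Describe a target locus
#'
#' @param name,chrom identifiers.
#' @param tss transcription start site (genomic bp, 1-based).
#' @param strand `"+"` or `"-"`.
#' @param region length-2 integer vector, start/end of the analyzed
#'   (NGS) amplicon in amplicon-local coordinates.
#' @param sgrna_sites data.frame with columns `label` (`"locus"` or
#'   `"allele"`), `start`, `end` (the 20-bp protospacer interval) and
#'   `pam_start` (first base of the NGG PAM).
#' @param snp a [snp_spec()] with role `"pam"`.
#' @return an object of class `target_locus`.
#' @details Invariants checked: the analyzed region contains both sgRNA
#'   sites, protospacers are exactly 20 bp, and the locus- and
#'   allele-specific sites start within 20 bp of each other (the two
#'   guides bind nearly the same place so the same CpGs are edited).
#' @export
target_locus <- function(name, chrom, tss, strand, region, sgrna_sites, snp) {
  stopifnot(is.character(name), length(region) == 2L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (!inherits(snp, "snp_spec")) stop("snp must be a snp_spec", call. = FALSE)
  need <- c("label", "start", "end", "pam_start")
  if (!all(need %in% names(sgrna_sites))) {
    stop("sgrna_sites needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  widths <- sgrna_sites$end - sgrna_sites$start + 1L
  if (any(widths != 20L)) {
    stop("sgRNA protospacers must be exactly 20 bp", call. = FALSE)
  }
  if (any(sgrna_sites$start < region[1]) || any(sgrna_sites$end > region[2])) {
    stop("analyzed region must contain all sgRNA sites", call. = FALSE)
  }
  labs <- sgrna_sites$label
  if (all(c("locus", "allele") %in% labs)) {
    d <- abs(sgrna_sites$start[labs == "locus"][1] -
               sgrna_sites$start[labs == "allele"][1])
    if (d > 20L) {
      stop("locus- and allele-specific sgRNA sites must lie within 20 bp of each other",
           call. = FALSE)
    }
  }
  structure(list(name = name, chrom = chrom, tss = as.integer(tss),
                 strand = strand, region = as.integer(region),
                 sgrna_sites = sgrna_sites, snp = snp),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus %s (%s%s) region %d-%d, PAM SNP %s>%s at %d>\n",
              x$name, x$chrom, x$strand, x$region[1], x$region[2],
              x$snp$ref_base, x$snp$alt_base, x$snp$position))
  invisible(x)
}

#' Check that two haplotypes form a consistent allele pair
#'
#' Haplotypes of one locus must have equal length and differ exactly at
#' the declared SNP position(s); anything else is a configuration error.
#'
#' @param h1,h2 [allele_haplotype()] objects (allele1 carries the SNP ref
#'   base, allele2 the alt base).
#' @param snp the declared [snp_spec()].
#' @return `TRUE` invisibly, or an error.
#' @export
validate_haplotype_pair <- function(h1, h2, snp) {
  if (nchar(h1$sequence) != nchar(h2$sequence)) {
    stop("haplotypes must have equal length", call. = FALSE)
  }
  c1 <- seq_chars(h1$sequence); c2 <- seq_chars(h2$sequence)
  diffs <- which(c1 != c2)
  if (!identical(diffs, as.integer(snp$position))) {
    if (length(diffs) == 0L) {
      stop("haplotypes are identical but a SNP is declared", call. = FALSE)
    }
    stop("haplotypes differ outside the declared SNP position (at ",
         paste(setdiff(diffs, snp$position), collapse = ","), ")", call. = FALSE)
  }
  if (c1[snp$position] != snp$ref_base || c2[snp$position] != snp$alt_base) {
    stop("haplotype bases at the SNP do not match the declared ref/alt", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pair CpG sites of two allele haplotypes by amplicon coordinate
#'
#' A SNP can create or destroy a CpG, so CpG indices shift between
#' alleles; identity across alleles is therefore defined by amplicon
#' coordinate. Sites present in only one allele are flagged, never
#' dropped.
#'
#' @param h1,h2 [allele_haplotype()] objects over the same coordinates.
#' @return data.frame of class `cpg_correspondence` with columns
#'   `position`, `index_allele1`, `index_allele2` (allele-local CpG
#'   indices, `NA` when the site is absent in that allele), ordered by
#'   coordinate.
#' @export
build_cpg_correspondence <- function(h1, h2) {
  if (nchar(h1$sequence) != nchar(h2$sequence)) {
    stop("haplotypes must share amplicon coordinates", call. = FALSE)
  }
  pos <- sort(union(h1$cpg_positions, h2$cpg_positions))
  out <- data.frame(
    position = pos,
    index_allele1 = match(pos, h1$cpg_positions),
    index_allele2 = match(pos, h2$cpg_positions)
  )
  class(out) <- c("cpg_correspondence", "data.frame")
  out
}

#' Metadata for one sequenced sample
#'
#' @param sample_id unique identifier.
#' @param treatment one of `"untreated"`, `"scrambled"`, `"locus"`,
#'   `"allele"`.
#' @param day collection day (0, 3, 6, 9 or 15; untreated controls are
#'   day 0 in this design, scrambled controls are analyzed at day 6).
#' @param replicate biological replicate index (>= 1).
#' @return a one-row data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, treatment, day, replicate = 1L) {
  treatment <- match.arg(treatment, c("untreated", "scrambled", "locus", "allele"))
  if (!day %in% c(0, 3, 6, 9, 15)) {
    stop("day must be one of 0, 3, 6, 9, 15", call. = FALSE)
  }
  if (treatment == "untreated" && day != 0) {
    stop("untreated samples are day 0 in this design", call. = FALSE)
  }
  if (treatment == "scrambled" && day != 6) {
    stop("scrambled controls are analyzed at day 6 in this design", call. = FALSE)
  }
  if (replicate < 1) stop("replicate must be >= 1", call. = FALSE)
  out <- data.frame(sample_id = sample_id, treatment = treatment,
                    day = as.integer(day), replicate = as.integer(replicate))
  class(out) <- c("sample_meta", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Locus configuration I/O: flat DCF key-value file + FASTA of haplotypes.

#' Load a locus configuration
#'
#' Reads a flat key-value (DCF) file describing the locus plus a FASTA of
#' the two allele haplotypes (records named `allele1`, `allele2`,
#' allele1 carrying the SNP reference base). CpG maps are always
#' recomputed from the sequences, never read from the file, and the
#' haplotype pair is validated against the declared SNP.
#'
#' @param path path to the config file. Fields: `name`, `chrom`, `tss`,
#'   `strand`, `region_start`, `region_end`, `snp_position`, `snp_ref`,
#'   `snp_alt`, `snp_role`, `sgrna_sites`
#'   (semicolon list of `label:start-end:pam_start`), `fasta` (path,
#'   relative to the config file).
#' @return list with elements `locus` ([target_locus()]), `haplotypes`
#'   (list of two [allele_haplotype()]), and `correspondence`
#'   ([build_cpg_correspondence()]).
#' @export
load_locus_config <- function(path) {
  if (!file.exists(path)) stop("locus config not found: ", path, call. = FALSE)
  rec <- read.dcf(path)
  if (nrow(rec) != 1L) stop("locus config must contain exactly one record", call. = FALSE)
  f <- function(key) {
    if (!key %in% colnames(rec)) stop("locus config missing field: ", key, call. = FALSE)
    unname(rec[1, key])
  }
  snp <- snp_spec(as.integer(f("snp_position")), f("snp_ref"), f("snp_alt"),
                  f("snp_role"))
  sg <- do.call(rbind, lapply(strsplit(f("sgrna_sites"), ";", fixed = TRUE)[[1]],
    function(s) {
      m <- regmatches(s, regexec("^([a-z]+):(\\d+)-(\\d+):(\\d+)$", s))[[1]]
      if (length(m) != 5L) stop("malformed sgrna_sites entry: ", s, call. = FALSE)
      data.frame(label = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
                 pam_start = as.integer(m[5]))
    }))
  locus <- target_locus(f("name"), f("chrom"), as.integer(f("tss")), f("strand"),
                        c(as.integer(f("region_start")), as.integer(f("region_end"))),
                        sg, snp)
  fasta <- file.path(dirname(path), f("fasta"))
  if (!file.exists(fasta)) stop("haplotype FASTA not found: ", fasta, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!all(c("allele1", "allele2") %in% names(seqs))) {
    stop("haplotype FASTA must contain records 'allele1' and 'allele2'", call. = FALSE)
  }
  h1 <- allele_haplotype("allele1", as.character(seqs[["allele1"]]), snp)
  h2 <- allele_haplotype("allele2", as.character(seqs[["allele2"]]), snp)
  validate_haplotype_pair(h1, h2, snp)
  list(locus = locus, haplotypes = list(allele1 = h1, allele2 = h2),
       correspondence = build_cpg_correspondence(h1, h2))
}

#' Write a locus configuration
#'
#' Inverse of [load_locus_config()]; emits `<name>.cfg` and
#' `<name>.fasta` into `dir`.
#'
#' @param locus a [target_locus()].
#' @param haplotypes list of two [allele_haplotype()] objects.
#' @param dir output directory (created if needed).
#' @return path to the config file.
#' @export
write_locus_config <- function(locus, haplotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- paste0(locus$name, ".fasta")
  seqs <- Biostrings::DNAStringSet(vapply(haplotypes, `[[`, "", "sequence"))
  names(seqs) <- vapply(haplotypes, `[[`, "", "allele_id")
  Biostrings::writeXStringSet(seqs, file.path(dir, fasta))
  sg <- sprintf("%s:%d-%d:%d", locus$sgrna_sites$label, locus$sgrna_sites$start,
                locus$sgrna_sites$end, locus$sgrna_sites$pam_start)
  rec <- matrix(c(locus$name, locus$chrom, locus$tss, locus$strand,
                  locus$region[1], locus$region[2], locus$snp$position,
                  locus$snp$ref_base, locus$snp$alt_base, locus$snp$role,
                  paste(sg, collapse = ";"), fasta), nrow = 1)
  colnames(rec) <- c("name", "chrom", "tss", "strand", "region_start",
                     "region_end", "snp_position", "snp_ref", "snp_alt",
                     "snp_role", "sgrna_sites", "fasta")
  cfg <- file.path(dir, paste0(locus$name, ".cfg"))
  write.dcf(rec, cfg)
  cfg
}

#' Export sgRNA sites and the analyzed region as BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention.
#'
#' @param locus a [target_locus()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_sites_bed <- function(locus, path) {
  df <- rbind(
    data.frame(chrom = locus$chrom, start = locus$region[1] - 1L,
               end = locus$region[2], name = paste0(locus$name, "_region")),
    data.frame(chrom = locus$chrom, start = locus$sgrna_sites$start - 1L,
               end = locus$sgrna_sites$end,
               name = paste0(locus$name, "_sgrna_", locus$sgrna_sites$label))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
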