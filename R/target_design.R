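# Allele-specific sgRNA target design: scan a promoter sequence for
# heterozygous G-to-Y SNPs that complete an NGG PAM on exactly one
# allele, extract the 20-nt protospacer, and enumerate mismatch
# off-target candidates by exhaustive Hamming scan.

# all NGG PAM start positions (position of N) in a plain sequence
.pam_starts <- function(chars, pam = c("G", "G")) {
  L <- length(chars)
  if (L < 3L) return(integer(0))
  which(chars[2:(L - 1)] == pam[1] & chars[3:L] == pam[2])
}

# scan one strand for PAM-SNP candidates; seq/snps in this strand's
# coordinates
.scan_strand <- function(sequence, snps, strand_label) {
  chars_ref <- seq_chars(sequence)
  out <- list()
  for (i in seq_len(nrow(snps))) {
    pos <- snps$pos[i]; ref <- toupper(snps$ref[i]); alt <- toupper(snps$alt[i])
    # orient so g_base is the allele contributing the G
    if (ref == "G" && alt %in% c("C", "T")) {
      g_base <- ref; y_base <- alt; g_is_ref <- TRUE
    } else if (alt == "G" && ref %in% c("C", "T")) {
      g_base <- alt; y_base <- ref; g_is_ref <- FALSE
    } else next  # not G-to-Y on this strand
    g_chars <- chars_ref; g_chars[pos] <- g_base
    y_chars <- chars_ref; y_chars[pos] <- y_base
    # the SNP G must sit in the GG of an NGG: PAM start p with p+1==pos or p+2==pos
    for (p in c(pos - 1L, pos - 2L)) {
      if (p < 1L || p + 2L > length(g_chars)) next
      is_pam_g <- g_chars[p + 1L] == "G" && g_chars[p + 2L] == "G"
      is_pam_y <- y_chars[p + 1L] == "G" && y_chars[p + 2L] == "G"
      if (is_pam_g && !is_pam_y) {
        out[[length(out) + 1L]] <- data.frame(
          snp_pos = pos, ref = ref, alt = alt, strand = strand_label,
          pam_start = p,
          pam_sequence = paste(g_chars[p:(p + 2L)], collapse = ""),
          protospacer = if (p > 20L) paste(g_chars[(p - 20L):(p - 1L)], collapse = "") else NA_character_,
          g_allele = if (g_is_ref) "ref" else "alt",
          candidate_class = "pam_snp",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Find allele-specific PAM-SNP sgRNA candidates
#'
#' Scans both strands of a promoter sequence for heterozygous G-to-Y
#' SNPs where one allele contributes the G completing an NGG PAM while
#' the pyrimidine allele breaks it. Candidates are restricted to a
#' window around the TSS and flagged when they fall inside a
#' (methylated) CpG-island interval. SNPs that do not touch a PAM but
#' fall inside the 20-nt protospacer of an allele-shared PAM are
#' reported as a secondary candidate class (`"protospacer_snp"`).
#'
#' @param sequence promoter/locus DNA sequence (plus strand).
#' @param snps data.frame of heterozygous SNPs with columns `pos`,
#'   `ref`, `alt` (1-based, plus-strand bases).
#' @param tss TSS coordinate within `sequence`.
#' @param window maximum |SNP - TSS| distance in bp (default 2000).
#' @param cgi_intervals optional data.frame `start`,`end` of CGI
#'   intervals for the `within_cgi` flag.
#' @param include_protospacer_snps also report the secondary class
#'   (default TRUE).
#' @return data.frame of candidates: `snp_pos`, `ref`, `alt`, `strand`,
#'   `pam_start` (plus-strand coordinate of the NGG start for `+`;
#'   strand-local for `-`, with `pam_start_plus` giving the plus-strand
#'   leftmost base), `pam_sequence`, `protospacer` (20 nt, on the
#'   PAM-bearing strand of the G allele), `candidate_class`,
#'   `distance_to_tss`, `within_cgi`.
#' @export
find_pam_snps <- function(sequence, snps, tss, window = 2000L,
                          cgi_intervals = NULL,
                          include_protospacer_snps = TRUE) {
  sequence <- check_dna(sequence)
  if (is.null(snps) || nrow(snps) == 0L) return(.empty_candidates())
  if (any(snps$pos < 1L | snps$pos > nchar(sequence))) {
    stop("SNP positions must lie within the sequence", call. = FALSE)
  }
  L <- nchar(sequence)
  plus <- .scan_strand(sequence, snps, "+")
  # minus strand: operate on the reverse complement with mirrored SNPs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snps_rc <- data.frame(pos = L - snps$pos + 1L,
                        ref = unname(comp[toupper(snps$ref)]),
                        alt = unname(comp[toupper(snps$alt)]))
  minus <- .scan_strand(revcomp(sequence), snps_rc, "-")
  if (!is.null(minus) && nrow(minus)) {
    # map strand-local coordinates back to plus strand
    minus$snp_pos <- L - minus$snp_pos + 1L
    minus$pam_start_plus <- L - (minus$pam_start + 2L) + 1L
    minus$ref <- unname(comp[minus$ref])   # report plus-strand bases
    minus$alt <- unname(comp[minus$alt])
  }
  if (!is.null(plus) && nrow(plus)) plus$pam_start_plus <- plus$pam_start
  out <- rbind(plus, minus)
  if (include_protospacer_snps) {
    ps <- .protospacer_snp_candidates(sequence, snps)
    if (!is.null(ps) && nrow(ps)) out <- rbind(out, ps)
  }
  if (is.null(out) || nrow(out) == 0L) return(.empty_candidates())
  out$distance_to_tss <- abs(out$snp_pos - as.integer(tss))
  out <- out[out$distance_to_tss <= window, , drop = FALSE]
  out$within_cgi <- logical(nrow(out))
  if (!is.null(cgi_intervals) && nrow(cgi_intervals)) {
    for (j in seq_len(nrow(cgi_intervals))) {
      out$within_cgi <- out$within_cgi |
        (out$snp_pos >= cgi_intervals$start[j] & out$snp_pos <= cgi_intervals$end[j])
    }
  }
  # CGI candidates first, then by mismatch-free geometry (position)
  out <- out[order(!out$within_cgi, out$snp_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(snp_pos = integer(0), ref = character(0), alt = character(0),
             strand = character(0), pam_start = integer(0),
             pam_sequence = character(0), protospacer = character(0),
             g_allele = character(0), candidate_class = character(0),
             pam_start_plus = integer(0), distance_to_tss = integer(0),
             within_cgi = logical(0))
}

# secondary class: G>Y SNP inside the protospacer of a PAM shared by
# both alleles (sgRNA-binding-site SNP rather than PAM SNP)
.protospacer_snp_candidates <- function(sequence, snps) {
  L <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scan_one <- function(chars, snps_s, strand_label) {
    pams <- .pam_starts(chars)
    pams <- pams[pams > 20L]
    out <- list()
    for (i in seq_len(nrow(snps_s))) {
      pos <- snps_s$pos[i]; ref <- toupper(snps_s$ref[i]); alt <- toupper(snps_s$alt[i])
      gy <- (ref == "G" && alt %in% c("C", "T")) || (alt == "G" && ref %in% c("C", "T"))
      if (!gy) next
      hit <- pams[pos >= pams - 20L & pos <= pams - 1L]
      # PAM must be intact on both alleles (SNP not inside the NGG)
      for (p in hit) {
        if (pos %in% c(p + 1L, p + 2L)) next
        out[[length(out) + 1L]] <- data.frame(
          snp_pos = pos, ref = ref, alt = alt, strand = strand_label,
          pam_start = p, pam_sequence = paste(chars[p:(p + 2L)], collapse = ""),
          protospacer = paste(chars[(p - 20L):(p - 1L)], collapse = ""),
          g_allele = if (ref == "G") "ref" else "alt",
          candidate_class = "protospacer_snp", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  plus <- scan_one(seq_chars(sequence), snps, "+")
  snps_rc <- data.frame(pos = L - snps$pos + 1L,
                        ref = unname(comp[toupper(snps$ref)]),
                        alt = unname(comp[toupper(snps$alt)]))
  minus <- scan_one(seq_chars(revcomp(sequence)), snps_rc, "-")
  if (!is.null(minus) && nrow(minus)) {
    minus$snp_pos <- L - minus$snp_pos + 1L
    minus$pam_start_plus <- L - (minus$pam_start + 2L) + 1L
    minus$ref <- unname(comp[minus$ref]); minus$alt <- unname(comp[minus$alt])
  }
  if (!is.null(plus) && nrow(plus)) plus$pam_start_plus <- plus$pam_start
  rbind(plus, minus)
}

#' Extract the 20-nt protospacer for a PAM position
#'
#' The sgRNA spacer is the 20 bases immediately 5' of the PAM on the
#' PAM-bearing strand.
#'
#' @param sequence sequence of the PAM-bearing strand (for a candidate
#'   from [find_pam_snps()] on `-`, pass the reverse complement and the
#'   strand-local `pam_start`).
#' @param pam_start 1-based position of the PAM's first base (the N).
#' @return 20-character protospacer string.
#' @export
design_sgrna <- function(sequence, pam_start) {
  sequence <- check_dna(sequence)
  if (pam_start <= 20L) {
    stop("insufficient 5' context: need 20 bp upstream of the PAM", call. = FALSE)
  }
  if (pam_start + 2L > nchar(sequence)) {
    stop("PAM extends beyond the sequence", call. = FALSE)
  }
  substr(sequence, pam_start - 20L, pam_start - 1L)
}

#' Enumerate mismatch off-target candidates for a protospacer
#'
#' Exhaustive Hamming scan of both strands of every subject sequence:
#' at each PAM-adjacent 20-mer (PAM classes NGG and, optionally, NAG)
#' the mismatch count against the protospacer is computed; hits within
#' `max_mismatches` are returned sorted by mismatch count, subject, and
#' position.
#'
#' @param protospacer 20-nt spacer sequence.
#' @param subjects named character vector of subject sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param max_mismatches maximum Hamming distance (default 3).
#' @param pam_classes PAM classes to accept (subset of `c("NGG","NAG")`).
#' @return data.frame of class `offtarget_hits`: `subject`, `position`
#'   (plus-strand start of the 20-mer), `strand`, `mismatches`, `pam`,
#'   `pam_class`.
#' @export
enumerate_offtargets <- function(protospacer, subjects, max_mismatches = 3L,
                                 pam_classes = c("NGG", "NAG")) {
  protospacer <- check_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt", call. = FALSE)
  pam_classes <- match.arg(pam_classes, c("NGG", "NAG"), several.ok = TRUE)
  if (is.character(subjects) && length(subjects) == 1L && file.exists(subjects)) {
    subjects <- Biostrings::readDNAStringSet(subjects)
  }
  if (inherits(subjects, "DNAStringSet")) {
    subjects <- setNames(as.character(subjects),
                         sub("\\s.*$", "", names(subjects)))
  }
  if (length(subjects) == 0L) stop("subjects must be non-empty", call. = FALSE)
  if (is.null(names(subjects))) names(subjects) <- sprintf("subject%d", seq_along(subjects))
  proto <- seq_chars(protospacer)
  mid_bases <- c(NGG = "G", NAG = "A")[pam_classes]
  rows <- list()
  for (sj in names(subjects)) {
    L <- nchar(subjects[[sj]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subjects[[sj]] else revcomp(subjects[[sj]])
      chars <- seq_chars(s)
      if (L < 23L) next
      # candidate protospacer starts i: PAM at i+20..i+22
      starts <- seq_len(L - 22L)
      pam_mid <- chars[starts + 21L]
      pam_ok <- pam_mid %in% mid_bases & chars[starts + 22L] == "G"
      starts <- starts[pam_ok]
      if (!length(starts)) next
      W <- matrix(chars[outer(starts, 0:19, "+")], nrow = length(starts))
      mm <- rowSums(W != matrix(proto, length(starts), 20L, byrow = TRUE))
      keep <- mm <= max_mismatches
      if (!any(keep)) next
      st <- starts[keep]
      pam <- paste0(chars[st + 20L], chars[st + 21L], chars[st + 22L])
      pos_plus <- if (strand == "+") st else L - (st + 19L) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sj, position = pos_plus, strand = strand,
        mismatches = mm[keep], pam = pam,
        pam_class = ifelse(substr(pam, 2, 2) == "G", "NGG", "NAG"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), position = integer(0),
               strand = character(0), mismatches = integer(0),
               pam = character(0), pam_class = character(0))
  out <- out[order(out$mismatches, out$subject, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("offtarget_hits", "data.frame")
  out
}
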