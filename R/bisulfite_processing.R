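# Read-pair merging, bisulfite-aware alignment against converted
# haplotype references, per-read CpG methylation calling and conversion
# QC. The genome-scale mapper of a conventional WGBS chain is replaced
# by exhaustive comparison against the (at most two) haplotype
# references of one amplicon, which is exact at this scale.

#' Merge overlapping read pairs
#'
#' PEAR-style consensus merging: mate 2 is reverse-complemented and every
#' overlap length from `min_overlap` up to the shorter mate length is
#' scored; among the overlaps whose mismatch fraction stays within
#' `max_mismatch_frac`, the one maximizing the number of matching bases
#' wins (long spurious overlaps full of mismatches are never candidates).
#' The pair is rejected when no admissible overlap exists. With the
#' simulator's constant base qualities, disagreeing overlap bases are
#' resolved in favor of mate 1 (the quality tie-break).
#'
#' @param r1,r2 named character vectors of mate sequences (same order;
#'   names are read ids, an optional `/1`,`/2` suffix is ignored).
#' @param min_overlap minimum acceptable overlap (bp).
#' @param max_mismatch_frac maximum fraction of mismatching bases within
#'   the best overlap.
#' @return list with `merged` (data.frame: `read_id`, `sequence`,
#'   `overlap_length`, `n_overlap_mismatches`) and `rejected`
#'   (character vector of read ids).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_frac = 0.1) {
  if (length(r1) != length(r2)) stop("mates must have equal length", call. = FALSE)
  if (length(r1) == 0L) {
    return(list(merged = data.frame(read_id = character(0), sequence = character(0),
                                    overlap_length = integer(0),
                                    n_overlap_mismatches = integer(0)),
                rejected = character(0)))
  }
  ids1 <- sub("/[12]$", "", names(r1) %||% as.character(seq_along(r1)))
  ids2 <- sub("/[12]$", "", names(r2) %||% as.character(seq_along(r2)))
  if (!identical(ids1, ids2)) stop("mates do not share read ids", call. = FALSE)
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
  l1 <- nchar(r1); l2 <- nchar(rc2)
  n <- length(r1)
  best_o <- integer(n); best_mm <- integer(n); best_match <- rep(-1L, n)
  if (length(unique(l1)) == 1L && length(unique(l2)) == 1L) {
    # vectorized path: all mates equal length
    A1 <- .char_matrix(r1); A2 <- .char_matrix(rc2)
    L1 <- l1[1]; L2 <- l2[1]
    for (o in seq.int(min_overlap, min(L1, L2))) {
      mm <- rowSums(A1[, (L1 - o + 1L):L1, drop = FALSE] !=
                      A2[, 1L:o, drop = FALSE])
      sc <- o - mm
      upd <- mm <= max_mismatch_frac * o & sc > best_match
      best_match[upd] <- sc[upd]; best_o[upd] <- o; best_mm[upd] <- mm[upd]
    }
  } else {
    for (i in seq_len(n)) {
      a <- charToRaw(r1[i]); b <- charToRaw(rc2[i])
      for (o in seq.int(min_overlap, min(l1[i], l2[i]))) {
        mm <- sum(a[(l1[i] - o + 1L):l1[i]] != b[1L:o])
        if (mm <= max_mismatch_frac * o && o - mm > best_match[i]) {
          best_match[i] <- o - mm; best_o[i] <- o; best_mm[i] <- mm
        }
      }
    }
  }
  ok <- best_o >= min_overlap
  merged_seq <- paste0(r1, substr(rc2, best_o + 1L, l2))
  out <- data.frame(read_id = ids1[ok], sequence = merged_seq[ok],
                    overlap_length = as.integer(best_o[ok]),
                    n_overlap_mismatches = as.integer(best_mm[ok]),
                    stringsAsFactors = FALSE)
  list(merged = out, rejected = ids1[!ok])
}

.char_matrix <- function(x) {
  # equal-width character vector -> matrix of single bases
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

#' Bisulfite-convert a haplotype reference
#'
#' For the top strand every non-CpG cytosine is rewritten to T (it is
#' always unmethylated, hence fully converted in expectation) while CpG
#' cytosines are kept and masked as ambiguity positions where a read C
#' (methylated) or T (unmethylated) both count as matches. The bottom
#' strand applies the mirror-image rule to G positions.
#'
#' @param hap an [allele_haplotype()].
#' @param strand `"top"` or `"bottom"`.
#' @return list of class `converted_reference`: `haplotype_id`,
#'   `original`, `converted`, `ambiguous_pos` (masked CpG C positions),
#'   `non_cpg_c` (positions used for conversion QC), `cpg_positions`.
#' @export
convert_reference <- function(hap, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  chars <- seq_chars(hap$sequence)
  if (strand == "top") {
    cpg_c <- hap$cpg_positions
    all_c <- which(chars == "C")
    non_cpg <- setdiff(all_c, cpg_c)
    conv <- chars
    conv[non_cpg] <- "T"
  } else {
    cpg_c <- hap$cpg_positions + 1L  # the G of CG carries bottom-strand 5mC
    all_c <- which(chars == "G")
    non_cpg <- setdiff(all_c, cpg_c)
    conv <- chars
    conv[non_cpg] <- "A"
  }
  structure(list(haplotype_id = hap$allele_id, original = hap$sequence,
                 converted = paste(conv, collapse = ""),
                 ambiguous_pos = cpg_c, non_cpg_c = non_cpg,
                 cpg_positions = hap$cpg_positions, strand = strand),
            class = "converted_reference")
}

# score merged reads (equal length to reference) against one converted
# reference; returns list(score, identity, call matrix, conversion)
.score_against_reference <- function(A, ref, match = 1, mismatch = -1) {
  L <- nchar(ref$converted)
  refvec <- seq_chars(ref$converted)
  n <- nrow(A)
  eq <- A == matrix(refvec, n, L, byrow = TRUE)
  if (length(ref$ambiguous_pos)) {
    amb <- ref$ambiguous_pos
    eq[, amb] <- A[, amb, drop = FALSE] == "C" | A[, amb, drop = FALSE] == "T"
  }
  nmatch <- rowSums(eq)
  score <- nmatch * match + (L - nmatch) * mismatch
  identity <- nmatch / L
  # per-read CpG calls at the reference CpG C positions
  cp <- if (ref$strand == "top") ref$cpg_positions else ref$cpg_positions + 1L
  meth_base <- if (ref$strand == "top") "C" else "G"
  unmeth_base <- if (ref$strand == "top") "T" else "A"
  calls <- matrix("ambiguous", n, length(cp))
  if (length(cp)) {
    obs <- A[, cp, drop = FALSE]
    calls[obs == meth_base] <- "methylated"
    calls[obs == unmeth_base] <- "unmethylated"
  }
  conv_frac <- rep(NA_real_, n)
  if (length(ref$non_cpg_c)) {
    obs <- A[, ref$non_cpg_c, drop = FALSE]
    conv_frac <- rowSums(obs == unmeth_base) / length(ref$non_cpg_c)
  }
  list(score = score, identity = identity, calls = calls, conversion = conv_frac)
}

#' Align merged reads to converted haplotype references
#'
#' Every read is scored against each converted reference with
#' bisulfite-aware matching (read T or C at a masked CpG C both match;
#' elsewhere match +1 / mismatch -1) and assigned to the best-scoring
#' haplotype. Reads whose length equals the amplicon length are scored
#' by direct ungapped comparison (exact here, since merged amplicon
#' reads span the template end to end); other lengths fall back to
#' affine-gap semi-global alignment via
#' [Biostrings::pairwiseAlignment()].
#'
#' @param merged data.frame from [merge_pairs()], or a named character
#'   vector of read sequences.
#' @param refs list of [convert_reference()] objects (one or two).
#' @param match,mismatch,gap_opening,gap_extension scoring parameters.
#' @param min_identity reads below this identity are flagged unmapped.
#' @return list of class `read_alignments`:
#'   * `alignments`: data.frame with `read_id`, `haplotype_id`,
#'     `identity`, `score`, `nonCpG_conversion`, `mapped`, and
#'     `aligned_seq` (read in reference coordinates);
#'   * `calls`: long data.frame `read_id`, `haplotype_id`, `cpg_index`,
#'     `position`, `call` in
#'     \{methylated, unmethylated, ambiguous, uncovered\}.
#' @export
align_reads <- function(merged, refs, match = 1, mismatch = -1,
                        gap_opening = 4, gap_extension = 1,
                        min_identity = 0.8) {
  if (is.data.frame(merged)) {
    seqs <- setNames(merged$sequence, merged$read_id)
  } else {
    seqs <- merged
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d", seq_along(seqs))
  }
  if (length(refs) == 0L) stop("at least one reference is required", call. = FALSE)
  L <- nchar(refs[[1]]$converted)
  n <- length(seqs)
  res <- list(alignments = data.frame(), calls = data.frame())
  full <- which(nchar(seqs) == L)
  other <- setdiff(seq_len(n), full)
  parts_aln <- list(); parts_calls <- list()
  if (length(full)) {
    A <- .char_matrix(unname(seqs[full]))
    per_ref <- lapply(refs, function(r) .score_against_reference(A, r, match, mismatch))
    scores <- vapply(per_ref, `[[`, numeric(length(full)), "score")
    scores <- matrix(scores, nrow = length(full))
    best <- max.col(scores, ties.method = "first")
    ids <- names(seqs)[full]
    aln <- data.frame(
      read_id = ids,
      haplotype_id = vapply(refs, `[[`, "", "haplotype_id")[best],
      identity = vapply(seq_along(full),
                        function(i) per_ref[[best[i]]]$identity[i], 0),
      score = vapply(seq_along(full), function(i) scores[i, best[i]], 0),
      nonCpG_conversion = vapply(seq_along(full),
                                 function(i) per_ref[[best[i]]]$conversion[i], 0),
      aligned_seq = unname(seqs[full]),
      stringsAsFactors = FALSE
    )
    parts_aln[[1]] <- aln
    calls_l <- lapply(seq_along(refs), function(k) {
      sel <- which(best == k)
      if (!length(sel)) return(NULL)
      cp <- refs[[k]]$cpg_positions
      if (!length(cp)) return(NULL)
      data.frame(read_id = rep(ids[sel], times = length(cp)),
                 haplotype_id = refs[[k]]$haplotype_id,
                 cpg_index = rep(seq_along(cp), each = length(sel)),
                 position = rep(cp, each = length(sel)),
                 call = as.vector(per_ref[[k]]$calls[sel, , drop = FALSE]),
                 stringsAsFactors = FALSE)
    })
    parts_calls <- c(parts_calls, calls_l)
  }
  if (length(other)) {
    gap <- .align_gapped(seqs[other], refs, match, mismatch, gap_opening,
                         gap_extension)
    parts_aln[[length(parts_aln) + 1L]] <- gap$alignments
    parts_calls[[length(parts_calls) + 1L]] <- gap$calls
  }
  alignments <- do.call(rbind, parts_aln)
  alignments <- alignments[match(names(seqs), alignments$read_id), , drop = FALSE]
  rownames(alignments) <- NULL
  alignments$mapped <- alignments$identity >= min_identity
  calls <- do.call(rbind, Filter(Negate(is.null), parts_calls))
  if (is.null(calls)) {
    calls <- data.frame(read_id = character(0), haplotype_id = character(0),
                        cpg_index = integer(0), position = integer(0),
                        call = character(0))
  }
  rownames(calls) <- NULL
  structure(list(alignments = alignments, calls = calls, refs = refs),
            class = "read_alignments")
}

# gap-tolerant fallback: semi-global alignment against each reference,
# with masked CpG Cs encoded as IUPAC Y so that read C and T both match.
.align_gapped <- function(seqs, refs, match, mismatch, gap_opening, gap_extension) {
  bases <- c("A", "C", "G", "T", "Y", "N")
  sm <- matrix(mismatch, 6, 6, dimnames = list(bases, bases))
  diag(sm) <- match
  sm["C", "Y"] <- sm["Y", "C"] <- match
  sm["T", "Y"] <- sm["Y", "T"] <- match
  sm["N", ] <- sm[, "N"] <- 0
  aln_rows <- list(); call_rows <- list()
  for (k in seq_along(refs)) {
    ref <- refs[[k]]
    subj_chars <- seq_chars(ref$converted)
    subj_chars[ref$ambiguous_pos] <- "Y"
    subj <- paste(subj_chars, collapse = "")
    pw <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(unname(seqs)), subject = subj,
      type = "global", substitutionMatrix = sm,
      gapOpening = gap_opening, gapExtension = gap_extension)
    aligned <- as.character(Biostrings::aligned(pw))  # pattern in subject coords
    A <- .char_matrix(aligned)
    sc <- .score_against_reference(A, ref, match, mismatch)
    uncov <- A == "-"
    cp <- if (ref$strand == "top") ref$cpg_positions else ref$cpg_positions + 1L
    calls <- sc$calls
    if (length(cp)) calls[uncov[, cp, drop = FALSE]] <- "uncovered"
    aln_rows[[k]] <- data.frame(read_id = names(seqs), haplotype_id = ref$haplotype_id,
                                identity = sc$identity,
                                score = Biostrings::score(pw),
                                nonCpG_conversion = sc$conversion,
                                aligned_seq = aligned, stringsAsFactors = FALSE)
    call_rows[[k]] <- if (length(cp)) {
      data.frame(read_id = rep(names(seqs), times = length(cp)),
                 haplotype_id = ref$haplotype_id,
                 cpg_index = rep(seq_along(ref$cpg_positions), each = length(seqs)),
                 position = rep(ref$cpg_positions, each = length(seqs)),
                 call = as.vector(calls), stringsAsFactors = FALSE)
    } else NULL
  }
  # keep best-scoring reference per read
  all_aln <- do.call(rbind, aln_rows)
  best <- do.call(rbind, lapply(split(all_aln, all_aln$read_id), function(d) {
    d[which.max(d$score), , drop = FALSE]
  }))
  key <- paste(best$read_id, best$haplotype_id)
  all_calls <- do.call(rbind, Filter(Negate(is.null), call_rows))
  if (!is.null(all_calls)) {
    all_calls <- all_calls[paste(all_calls$read_id, all_calls$haplotype_id) %in% key, ,
                           drop = FALSE]
  }
  list(alignments = best, calls = all_calls)
}

#' Filter aligned reads on conversion and identity
#'
#' Drops reads with incomplete bisulfite conversion (non-CpG conversion
#' fraction below `min_conversion`; such molecules would inflate
#' apparent methylation) or poor identity to any haplotype.
#'
#' @param aln a `read_alignments` object from [align_reads()].
#' @param min_conversion minimum non-CpG C->T conversion fraction.
#' @param min_identity minimum alignment identity.
#' @return list with `alignments`, `calls` (filtered) and `qc`, a list of
#'   counts per filter suitable for JSON export.
#' @export
filter_reads <- function(aln, min_conversion = 0.9, min_identity = 0.8) {
  a <- aln$alignments
  if (nrow(a) == 0L) {
    return(list(alignments = a, calls = aln$calls,
                qc = list(n_input = 0L, n_low_identity = 0L,
                          n_low_conversion = 0L, n_pass = 0L)))
  }
  low_id <- a$identity < min_identity
  low_conv <- !is.na(a$nonCpG_conversion) & a$nonCpG_conversion < min_conversion
  keep <- !low_id & !low_conv
  kept <- a[keep, , drop = FALSE]
  calls <- aln$calls[aln$calls$read_id %in% kept$read_id, , drop = FALSE]
  list(alignments = kept, calls = calls,
       qc = list(n_input = nrow(a),
                 n_low_identity = sum(low_id),
                 n_low_conversion = sum(low_conv & !low_id),
                 n_pass = nrow(kept)))
}

#' Write a QC report as JSON
#'
#' @param qc list as returned in `filter_reads()$qc` (or any named list
#'   of counts).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
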