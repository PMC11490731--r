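# Bisulfite amplicon read simulator. Generates paired-end FASTQ files
# with known per-read allele of origin and per-CpG methylation states so
# that every downstream stage can be tested against ground truth.
#
# Generative model (per molecule):
#   allele ~ Bernoulli(allele_fraction)            (allele1 with prob. f)
#   state_j ~ Bernoulli(m[allele][j]) independently per CpG site
#   bisulfite (top strand): unmethylated C -> T with prob conversion_rate,
#     methylated C -> T with prob overconversion_rate, non-CpG C treated
#     as unmethylated
#   sequencing error: each read base substituted by a uniform other base
#     with prob seq_error_rate, independently per mate
#   mate 1 = first read_length bases of the converted top strand,
#   mate 2 = reverse complement of the last read_length bases.

#' Simulation configuration
#'
#' @param haplotypes list of two [allele_haplotype()] objects.
#' @param m per-allele per-CpG methylation probabilities: named list
#'   (`allele1`, `allele2`) of numeric vectors, one value per CpG of
#'   that allele; a single vector is recycled to both alleles.
#' @param n_read_pairs number of read pairs (molecules).
#' @param read_length mate length in bp.
#' @param conversion_rate probability that an unmethylated C reads as T.
#' @param overconversion_rate probability that a methylated C reads as T.
#' @param seq_error_rate per-base substitution error probability.
#' @param allele_fraction probability that a molecule comes from allele1.
#' @param strand `"top"` (default) simulates the top-converted template
#'   only, matching strand-specific amplicon bisulfite PCR; `"bottom"`
#'   simulates the bottom strand.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(haplotypes, m, n_read_pairs = 5000L, read_length = 150L,
                       conversion_rate = 0.995, overconversion_rate = 0.005,
                       seq_error_rate = 0.001, allele_fraction = 0.5,
                       strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  if (!is.list(m) || is.numeric(m)) m <- list(allele1 = m, allele2 = m)
  for (a in c("allele1", "allele2")) {
    k <- length(haplotypes[[a]]$cpg_positions)
    if (length(m[[a]]) == 1L) m[[a]] <- rep(m[[a]], k)
    if (length(m[[a]]) != k) {
      stop("m[", a, "] must have one probability per CpG (", k, ")", call. = FALSE)
    }
    if (any(m[[a]] < 0 | m[[a]] > 1)) stop("methylation probabilities must be in [0,1]",
                                           call. = FALSE)
  }
  probs <- c(conversion_rate, overconversion_rate, seq_error_rate, allele_fraction)
  if (any(probs < 0 | probs > 1)) stop("all rate parameters must be in [0,1]", call. = FALSE)
  if (n_read_pairs < 1L) stop("n_read_pairs must be >= 1", call. = FALSE)
  amplen <- nchar(haplotypes$allele1$sequence)
  if (read_length > amplen) stop("read_length exceeds the amplicon length", call. = FALSE)
  if (2L * read_length - amplen < 20L) {
    stop("read pairs must overlap by >= 20 bp (increase read_length)", call. = FALSE)
  }
  structure(list(haplotypes = haplotypes, m = m,
                 n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 conversion_rate = conversion_rate,
                 overconversion_rate = overconversion_rate,
                 seq_error_rate = seq_error_rate,
                 allele_fraction = allele_fraction, strand = strand),
            class = "sim_config")
}

# apply per-base substitution errors to a character matrix of reads
.apply_seq_error <- function(mat, rate) {
  if (rate <= 0 || length(mat) == 0L) return(mat)
  hit <- which(runif(length(mat)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # uniform over the three other bases
    repl <- vapply(mat[hit], function(b) sample(setdiff(bases, b), 1L), "")
    mat[hit] <- repl
  }
  mat
}

# simulate converted full-length molecules for one allele; returns list
# with char matrix of molecules and the methylation state matrix
.simulate_molecules <- function(hap, m, n, conversion_rate, overconversion_rate,
                                strand) {
  tmpl <- seq_chars(hap$sequence)
  L <- length(tmpl)
  if (n == 0L) {
    return(list(molecules = matrix(character(0), 0L, L),
                states = matrix(0L, 0L, length(hap$cpg_positions))))
  }
  if (strand == "bottom") {
    # operate on the reverse complement, then flip back at the end so all
    # coordinates stay in top-strand space
    tmpl_rc <- seq_chars(revcomp(hap$sequence))
    cpg_rc <- sort(L - hap$cpg_positions)  # C of the bottom-strand CpG
    mol <- matrix(tmpl_rc, nrow = n, ncol = L, byrow = TRUE)
    cpg_cols <- cpg_rc
    m_use <- rev(m)  # bottom-strand CpGs pair with reversed site order
  } else {
    mol <- matrix(tmpl, nrow = n, ncol = L, byrow = TRUE)
    cpg_cols <- hap$cpg_positions
    m_use <- m
  }
  k <- length(cpg_cols)
  states <- matrix(0L, n, k)
  if (k > 0L && n > 0L) {
    states <- matrix(rbinom(n * k, 1L, rep(m_use, each = n)), n, k)
    u <- matrix(runif(n * k), n, k)
    to_t <- ifelse(states == 1L, u < overconversion_rate, u < conversion_rate)
    for (j in seq_len(k)) {
      mol[to_t[, j], cpg_cols[j]] <- "T"
    }
  }
  # non-CpG cytosines: all unmethylated
  non_cpg_c <- setdiff(which((if (strand == "bottom") seq_chars(revcomp(hap$sequence)) else tmpl) == "C"),
                       cpg_cols)
  if (length(non_cpg_c) && n > 0L) {
    conv <- matrix(runif(n * length(non_cpg_c)) < conversion_rate, n)
    for (j in seq_along(non_cpg_c)) {
      mol[conv[, j], non_cpg_c[j]] <- "T"
    }
  }
  if (strand == "bottom") {
    # return to top-strand orientation: reverse columns and complement
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    mol <- matrix(comp[mol[, L:1, drop = FALSE]], nrow = n)
    if (k > 0L) states <- states[, k:1, drop = FALSE]
  }
  list(molecules = mol, states = states)
}

#' Simulate paired-end bisulfite amplicon reads
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the same seed yields byte-identical FASTQ.
#' @param out_dir directory for the FASTQ pair (created if needed).
#' @param prefix file name prefix; mates are `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz` (set `compress = FALSE` for plain FASTQ).
#' @param compress gzip the FASTQ files (default TRUE).
#' @return list of class `sim_result`: `fastq1`, `fastq2` (paths) and
#'   `ground_truth`, a data.frame with `read_id`, `allele`, and
#'   `meth_states` (string of 0/1 per CpG of the allele of origin, in
#'   allele-local site order).
#' @export
simulate_bisulfite_reads <- function(cfg, seed, out_dir = tempdir(),
                                     prefix = "sim", compress = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(as.integer(seed), {
    n <- cfg$n_read_pairs
    RL <- cfg$read_length
    from_a1 <- runif(n) < cfg$allele_fraction
    alleles <- ifelse(from_a1, "allele1", "allele2")
    L <- nchar(cfg$haplotypes$allele1$sequence)
    mol <- matrix("", n, L)
    states_str <- character(n)
    for (a in c("allele1", "allele2")) {
      idx <- which(alleles == a)
      sim <- .simulate_molecules(cfg$haplotypes[[a]], cfg$m[[a]], length(idx),
                                 cfg$conversion_rate, cfg$overconversion_rate,
                                 cfg$strand)
      if (length(idx)) {
        mol[idx, ] <- sim$molecules
        states_str[idx] <- apply(sim$states, 1L, paste, collapse = "")
      }
    }
    r1 <- .apply_seq_error(mol[, seq_len(RL), drop = FALSE], cfg$seq_error_rate)
    r2f <- .apply_seq_error(mol[, (L - RL + 1L):L, drop = FALSE], cfg$seq_error_rate)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    r2 <- matrix(comp[r2f[, RL:1, drop = FALSE]], nrow = n)
    ids <- sprintf("%s_read%06d", prefix, seq_len(n))
    s1 <- apply(r1, 1L, paste, collapse = "")
    s2 <- apply(r2, 1L, paste, collapse = "")
    ext <- if (compress) ".fastq.gz" else ".fastq"
    f1 <- file.path(out_dir, paste0(prefix, "_R1", ext))
    f2 <- file.path(out_dir, paste0(prefix, "_R2", ext))
    write_fastq(setNames(s1, paste0(ids, "/1")), f1)
    write_fastq(setNames(s2, paste0(ids, "/2")), f2)
    gt <- data.frame(read_id = ids, allele = alleles, meth_states = states_str,
                     stringsAsFactors = FALSE)
    attr(gt, "allele_fraction") <- cfg$allele_fraction
    structure(list(fastq1 = f1, fastq2 = f2, ground_truth = gt),
              class = "sim_result")
  })
}

#' Simulate a demethylation time course
#'
#' One [simulate_bisulfite_reads()] call per sample with derived seeds
#' (`seed + sample index`), so the whole experiment is reproducible from
#' a single seed.
#'
#' @param haplotypes list of two [allele_haplotype()] objects.
#' @param design data.frame with columns `sample_id`, `treatment`, `day`,
#'   `replicate`, `condition`; sample ids must be unique.
#' @param m_arrays named list: for each `condition` in `design`, a list
#'   with per-allele methylation probability vectors (see
#'   [demo_methylation_arrays()]).
#' @param seed base integer seed.
#' @param out_dir output directory.
#' @param ... further arguments passed to [sim_config()]
#'   (`n_read_pairs`, `read_length`, rates, ...).
#' @return list with `manifest` (design plus `fastq1`/`fastq2` columns)
#'   and `ground_truth` (named list per sample).
#' @export
simulate_timecourse <- function(haplotypes, design, m_arrays, seed,
                                out_dir = tempdir(), ...) {
  if (nrow(design) == 0L) {
    return(list(manifest = cbind(design, fastq1 = character(0), fastq2 = character(0)),
                ground_truth = list()))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  missing_cond <- setdiff(design$condition, names(m_arrays))
  if (length(missing_cond)) {
    stop("no methylation array for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  gt <- list()
  f1 <- f2 <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    cfg <- sim_config(haplotypes, m_arrays[[design$condition[i]]], ...)
    res <- simulate_bisulfite_reads(cfg, seed = as.integer(seed) + i,
                                    out_dir = out_dir,
                                    prefix = design$sample_id[i])
    f1[i] <- res$fastq1; f2[i] <- res$fastq2
    gt[[design$sample_id[i]]] <- res$ground_truth
  }
  manifest <- cbind(design, fastq1 = f1, fastq2 = f2)
  list(manifest = manifest, ground_truth = gt)
}

#' Simulate transcript (cDNA) amplicon reads with an exonic SNP
#'
#' Unconverted single-end reads over an exonic amplicon: each read
#' carries the allele-1 SNP base with probability `allele_ratio`, plus
#' uniform substitution error. Models the read-out used for allelic
#' expression ratios.
#'
#' @param reference amplicon sequence carrying the allele-1 base at the
#'   SNP position.
#' @param snp an exonic [snp_spec()].
#' @param allele_ratio probability a read comes from allele 1.
#' @param n_reads number of reads.
#' @param error_rate per-base substitution error.
#' @param seed integer seed.
#' @param out_dir,prefix output location.
#' @param compress gzip output (default TRUE).
#' @return list with `fastq` (path) and `ground_truth` data.frame
#'   (`read_id`, `allele`).
#' @export
simulate_transcript_reads <- function(reference, snp, allele_ratio, n_reads,
                                      error_rate = 0.001, seed = 1L,
                                      out_dir = tempdir(), prefix = "tx",
                                      compress = TRUE) {
  if (allele_ratio < 0 || allele_ratio > 1) {
    stop("allele_ratio must be in [0,1]", call. = FALSE)
  }
  reference <- check_dna(reference, "transcript reference")
  withr::with_seed(as.integer(seed), {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tmpl <- seq_chars(reference)
    if (tmpl[snp$position] != snp$ref_base) {
      stop("reference does not carry the SNP ref base at its position", call. = FALSE)
    }
    n <- as.integer(n_reads)
    mat <- matrix(tmpl, n, length(tmpl), byrow = TRUE)
    from_a1 <- runif(n) < allele_ratio
    mat[!from_a1, snp$position] <- snp$alt_base
    mat <- .apply_seq_error(mat, error_rate)
    ids <- sprintf("%s_read%06d", prefix, seq_len(n))
    ext <- if (compress) ".fastq.gz" else ".fastq"
    fq <- file.path(out_dir, paste0(prefix, ext))
    write_fastq(setNames(apply(mat, 1L, paste, collapse = ""), ids), fq)
    list(fastq = fq,
         ground_truth = data.frame(read_id = ids,
                                   allele = ifelse(from_a1, "allele1", "allele2"),
                                   stringsAsFactors = FALSE))
  })
}
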