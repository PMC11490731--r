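demo <- demo_locus()

test_that("reference conversion rewrites non-CpG cytosines and masks CpGs", {
  h <- allele_haplotype("allele1", "ACTCGA")
  cv <- convert_reference(h)
  expect_identical(cv$converted, "ATTCGA")
  expect_identical(cv$ambiguous_pos, 4L)   # the CpG C stays, masked
  expect_identical(cv$non_cpg_c, 2L)
  h2 <- allele_haplotype("allele1", "ATTGTA")
  expect_identical(convert_reference(h2)$converted, "ATTGTA")
  h3 <- allele_haplotype("allele1", "CCCC")
  expect_identical(convert_reference(h3)$converted, "TTTT")
  # bottom strand converts non-CpG Gs (in top-strand space) instead,
  # keeping the CpG G that pairs with the bottom-strand methylatable C
  hb <- allele_haplotype("allele1", "AGTCGA")
  cvb <- convert_reference(hb, strand = "bottom")
  expect_identical(cvb$converted, "AATCGA")
  expect_identical(cvb$ambiguous_pos, 5L)
})

test_that("pair merging finds the true overlap and resolves disagreements", {
  # identical fully-overlapping mates
  s <- random_dna(100, 21)
  mg <- merge_pairs(c(r1 = s), c(r1 = revcomp_str(s)))
  expect_identical(mg$merged$sequence, s)
  expect_identical(mg$merged$overlap_length, 100L)
  expect_identical(mg$merged$n_overlap_mismatches, 0L)

  # 40-bp overlap with one disagreement, mate-1 base wins
  amp <- random_dna(80, 22)
  m1 <- substr(amp, 1, 60)
  m2_fwd <- substr(amp, 21, 80)
  flip <- 25  # inside the overlap region 21..60 -> offset 5 of m2_fwd
  m2_chars <- strsplit(m2_fwd, "")[[1]]
  m2_chars[5] <- setdiff(c("A", "C", "G", "T"), m2_chars[5])[1]
  m2 <- revcomp_str(paste(m2_chars, collapse = ""))
  mg2 <- merge_pairs(c(x = m1), c(x = m2))
  expect_identical(nchar(mg2$merged$sequence), 80L)
  expect_identical(mg2$merged$overlap_length, 40L)
  expect_identical(mg2$merged$n_overlap_mismatches, 1L)
  expect_identical(substr(mg2$merged$sequence, flip, flip), substr(amp, flip, flip))

  # non-overlapping random mates are rejected
  a <- random_dna(60, 23); b <- random_dna(60, 24)
  mg3 <- merge_pairs(c(y = a), c(y = revcomp_str(b)), min_overlap = 20)
  expect_identical(nrow(mg3$merged), 0L)
  expect_identical(mg3$rejected, "y")

  # mate-id mismatch is an error; empty input is fine
  expect_error(merge_pairs(c(a = "ACGT"), c(b = "ACGT")), "share read ids")
  expect_identical(nrow(merge_pairs(character(0), character(0))$merged), 0L)
})

test_that("pair merging equals the exhaustive per-read oracle", {
  m <- demo_methylation_arrays()
  cfg <- sim_config(demo$haplotypes, m$day6, n_read_pairs = 300,
                    read_length = 150, seq_error_rate = 0.003)
  sim <- simulate_bisulfite_reads(cfg, seed = 31)
  r1 <- read_fastq(sim$fastq1); r2 <- read_fastq(sim$fastq2)
  got <- merge_pairs(r1, r2)
  rc2 <- vapply(r2, revcomp_str, "")
  for (i in seq(1, length(r1), by = 7)) {
    want <- oracle_merge_one(unname(r1[i]), unname(rc2[i]), 20, 0.1)
    id <- sub("/1$", "", names(r1)[i])
    row <- got$merged[got$merged$read_id == id, ]
    if (is.null(want)) {
      expect_identical(nrow(row), 0L)
    } else {
      expect_identical(row$sequence, want$sequence)
      expect_identical(row$overlap_length, as.integer(want$overlap))
    }
  }
  # variable-length mates exercise the per-read fallback path
  r1v <- r1[1:5]; r2v <- r2[1:5]
  r1v[2] <- substr(r1v[2], 1, 146)  # still >= 20 bp of true overlap
  gotv <- merge_pairs(r1v, r2v)
  wantv <- oracle_merge_one(unname(r1v[2]), revcomp_str(unname(r2v[2])), 20, 0.1)
  rowv <- gotv$merged[gotv$merged$read_id == sub("/1$", "", names(r1v)[2]), ]
  expect_identical(rowv$sequence, wantv$sequence)
})

test_that("bisulfite-aware alignment calls methylation exactly on clean reads", {
  refs <- lapply(demo$haplotypes, convert_reference)
  # a fully methylated, fully converted, error-free allele1 molecule
  cfg <- sim_config(demo$haplotypes, m = 1, n_read_pairs = 5, read_length = 150,
                    conversion_rate = 1, overconversion_rate = 0,
                    seq_error_rate = 0, allele_fraction = 1)
  sim <- simulate_bisulfite_reads(cfg, seed = 5)
  mg <- merge_pairs(read_fastq(sim$fastq1), read_fastq(sim$fastq2))
  aln <- align_reads(mg$merged, refs)
  expect_true(all(aln$alignments$haplotype_id == "allele1"))
  expect_true(all(aln$alignments$identity == 1))
  expect_true(all(aln$alignments$nonCpG_conversion == 1))
  expect_true(all(aln$calls$call == "methylated"))

  # flip a single CpG C to T: exactly that site becomes unmethylated
  seqs <- mg$merged
  p <- demo$haplotypes$allele1$cpg_positions[3]
  substr(seqs$sequence[1], p, p) <- "T"
  aln2 <- align_reads(seqs[1, ], refs)
  calls2 <- aln2$calls
  expect_identical(calls2$call[calls2$position == p], "unmethylated")
  expect_true(all(calls2$call[calls2$position != p] == "methylated"))

  # a random sequence does not map
  rnd <- data.frame(read_id = "rnd", sequence = random_dna(274, 99))
  aln3 <- align_reads(rnd, refs, min_identity = 0.9)
  expect_false(aln3$alignments$mapped)
})

test_that("reads with indels fall back to gapped alignment", {
  refs <- lapply(demo$haplotypes, convert_reference)
  cfg <- sim_config(demo$haplotypes, m = 1, n_read_pairs = 2, read_length = 150,
                    conversion_rate = 1, overconversion_rate = 0,
                    seq_error_rate = 0, allele_fraction = 1)
  sim <- simulate_bisulfite_reads(cfg, seed = 6)
  mg <- merge_pairs(read_fastq(sim$fastq1), read_fastq(sim$fastq2))
  s <- mg$merged$sequence[1]
  # delete one base in the left flank (no CpG there)
  s_del <- paste0(substr(s, 1, 9), substr(s, 11, nchar(s)))
  aln <- align_reads(data.frame(read_id = "del1", sequence = s_del), refs)
  expect_identical(aln$alignments$haplotype_id, "allele1")
  expect_gt(aln$alignments$identity, 0.95)
  expect_true(all(aln$calls$call == "methylated"))
})

test_that("conversion filtering drops incompletely converted molecules", {
  m <- demo_methylation_arrays()
  good <- sim_config(demo$haplotypes, m$untreated, n_read_pairs = 190,
                     read_length = 150, seq_error_rate = 0)
  bad <- sim_config(demo$haplotypes, m$untreated, n_read_pairs = 10,
                    read_length = 150, conversion_rate = 0.2,
                    seq_error_rate = 0)
  sg <- simulate_bisulfite_reads(good, seed = 41, prefix = "good")
  sb <- simulate_bisulfite_reads(bad, seed = 42, prefix = "bad")
  r1 <- c(read_fastq(sg$fastq1), read_fastq(sb$fastq1))
  r2 <- c(read_fastq(sg$fastq2), read_fastq(sb$fastq2))
  mg <- merge_pairs(r1, r2)
  aln <- align_reads(mg$merged, lapply(demo$haplotypes, convert_reference))
  flt <- filter_reads(aln, min_conversion = 0.9)
  expect_identical(flt$qc$n_input, 200L)
  # about 5% (the conversion-failure molecules) are dropped
  expect_gte(flt$qc$n_low_conversion, 8L)
  expect_lte(flt$qc$n_low_conversion, 12L)
  dropped <- setdiff(aln$alignments$read_id, flt$alignments$read_id)
  expect_true(mean(grepl("^bad_", dropped)) > 0.9)
  # min_conversion = 0 keeps everything
  expect_identical(filter_reads(aln, min_conversion = 0)$qc$n_pass, 200L)
  # empty input
  empty_aln <- list(alignments = aln$alignments[0, ], calls = aln$calls[0, ])
  e <- filter_reads(empty_aln)
  expect_identical(e$qc$n_input, 0L)
  expect_identical(e$qc$n_pass, 0L)
})

test_that("true-haplotype alignment scores at least the other haplotype", {
  m <- demo_methylation_arrays()
  cfg <- sim_config(demo$haplotypes, m$day6, n_read_pairs = 200,
                    read_length = 150, seq_error_rate = 0)
  sim <- simulate_bisulfite_reads(cfg, seed = 55)
  mg <- merge_pairs(read_fastq(sim$fastq1), read_fastq(sim$fastq2))
  refs <- lapply(demo$haplotypes, convert_reference)
  aln <- align_reads(mg$merged, refs)
  gt <- sim$ground_truth
  truth <- gt$allele[match(aln$alignments$read_id, gt$read_id)]
  # whenever the SNP base is unambiguous (G for allele1, converted T for
  # allele2), the best-scoring haplotype is the true one; a rare
  # unconverted SNP C ties both references and is legitimately ambiguous
  p <- demo$locus$snp$position
  base <- substr(aln$alignments$aligned_seq, p, p)
  unambig <- base %in% c("G", "T")
  expect_gt(mean(unambig), 0.98)
  expect_identical(aln$alignments$haplotype_id[unambig], truth[unambig])
})
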