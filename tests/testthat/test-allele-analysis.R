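demo <- demo_locus()

fake_aln <- function(bases, snp_pos = demo$locus$snp$position, len = 274) {
  seqs <- vapply(bases, function(b) {
    s <- strrep("A", len)
    if (b != "-") substr(s, snp_pos, snp_pos) <- b
    s
  }, "")
  data.frame(read_id = sprintf("r%d", seq_along(bases)),
             aligned_seq = unname(seqs), stringsAsFactors = FALSE)
}

test_that("allele assignment follows the bisulfite-aware SNP rule", {
  # non-CpG G>C SNP: G -> allele1; T and C -> allele2 (converted /
  # unconverted alt C); anything else unassigned
  asg <- assign_alleles(fake_aln(c("G", "T", "C", "A", "-")),
                        demo$locus$snp, demo$haplotypes)
  expect_identical(asg$assigned, c("allele1", "allele2", "allele2",
                                   "unassigned", "unassigned"))
  expect_true(all(is.na(asg$snp_meth_call)))

  # SNP whose alt C creates a CpG: C/T still claim allele2 but are also
  # methylation observations
  hp <- cpg_gain_haplotypes()
  aln <- fake_aln(c("G", "C", "T"), snp_pos = 2, len = 6)
  asg2 <- assign_alleles(aln, hp$snp, list(allele1 = hp$h1, allele2 = hp$h2))
  expect_identical(asg2$assigned, c("allele1", "allele2", "allele2"))
  expect_identical(asg2$snp_meth_call, c(NA, "methylated", "unmethylated"))
})

test_that("profiles aggregate counts with NA (not zero) at uncovered sites", {
  calls <- data.frame(
    read_id = rep(sprintf("r%d", 1:10), times = 2),
    haplotype_id = "allele1",
    cpg_index = rep(1:2, each = 10),
    position = rep(c(31L, 45L), each = 10),
    call = c(rep("methylated", 10), rep(c("methylated", "unmethylated"), 5)))
  asg <- data.frame(read_id = sprintf("r%d", 1:10), assigned = "allele1")
  prof <- build_profiles(calls, asg, demo$correspondence)
  a1 <- prof[prof$allele == "allele1", ]
  expect_identical(a1$level[a1$position == 31], 1)
  expect_identical(a1$coverage[a1$position == 31], 10L)
  expect_identical(a1$level[a1$position == 45], 0.5)
  # uncovered allele1 sites are present with NA level
  expect_true(all(is.na(a1$level[!a1$position %in% c(31, 45)])))
  # no reads were assigned to allele2: its profile is all-undefined
  a2 <- prof[prof$allele == "allele2", ]
  expect_true(all(is.na(a2$level)))
  # pooled equals allele1 here (all reads assigned there)
  pooled <- prof[prof$allele == "pooled", ]
  expect_identical(pooled$n_meth[pooled$position == 45], 5L)
})

test_that("pooled profile is the coverage-weighted mean of allele profiles", {
  m <- demo_methylation_arrays()
  cfg <- sim_config(demo$haplotypes, m$day6, n_read_pairs = 800,
                    read_length = 150)
  sim <- simulate_bisulfite_reads(cfg, seed = 61)
  ps <- process_sample(sim$fastq1, sim$fastq2, demo$haplotypes, demo$locus$snp)
  prof <- build_profiles(ps$calls, ps$assignments, demo$correspondence)
  w <- merge(prof[prof$allele == "allele1", ],
             prof[prof$allele == "allele2", ], by = "position")
  pooled <- prof[prof$allele == "pooled", ]
  pooled <- pooled[match(w$position, pooled$position), ]
  weighted <- (w$n_meth.x + w$n_meth.y) / (w$coverage.x + w$coverage.y)
  # pooled additionally counts unassigned reads; at sites where the two
  # allele strata account for the full pooled coverage the pooled level
  # must equal the coverage-weighted mean exactly
  keep <- pooled$coverage == w$coverage.x + w$coverage.y
  expect_true(mean(keep) > 0.9)  # few unassigned reads
  expect_equal(pooled$level[keep], weighted[keep], tolerance = 1e-12)
})

test_that("site selection applies the 50%-of-maximum rule", {
  control <- data.frame(position = 1:4, level = c(0.9, 0.9, 0.9, 0.9))
  treated <- data.frame(position = 1:4, level = c(0.8, 0.2, 0.3, 0.7))
  # effects 0.10, 0.70, 0.60, 0.20 -> threshold 0.35 -> sites 2 and 3
  expect_identical(select_quant_sites(control, treated), c(2L, 3L))
  # uniform effect selects every site
  uni <- data.frame(position = 1:4, level = rep(0.5, 4))
  expect_identical(select_quant_sites(control, uni), 1:4)
  # no effect: empty selection with a warning
  expect_warning(s <- select_quant_sites(control, control), "empty")
  expect_identical(s, integer(0))
})

test_that("demethylation statistics reproduce the published arithmetic", {
  d6 <- demethylation_efficiency(97.7, 26.8)
  expect_equal(d6, 72.569, tolerance = 1e-4)
  expect_identical(round_half_up(d6), 73)
  d15 <- demethylation_efficiency(97.7, 36.7)
  expect_equal(round_half_up(d15, 1), 62.4)
  expect_identical(demethylation_efficiency(55, 55), 0)
  st <- stability_fraction(d6, d15)
  expect_identical(round_half_up(st), 86)
  expect_identical(stability_fraction(40, 40), 100)
  expect_identical(specificity_fold(72.6, 12), 6)
  expect_identical(specificity_fold(86, 11), 8)
  expect_identical(specificity_fold(33, 33), 1)
  expect_error(demethylation_efficiency(0, 10), "undefined")
  expect_error(stability_fraction(0, 10), "undefined")
  expect_warning(f <- specificity_fold(50, 0), "unbounded")
  expect_identical(f, Inf)
})

test_that("replicate averaging is per site and unweighted", {
  p1 <- data.frame(allele = "pooled", position = c(1L, 2L), n_meth = c(9L, 1L),
                   n_unmeth = c(1L, 9L), coverage = 10L, level = c(0.9, 0.1))
  p2 <- data.frame(allele = "pooled", position = c(1L, 2L), n_meth = c(5L, 3L),
                   n_unmeth = c(95L, 7L), coverage = c(100L, 10L),
                   level = c(0.05, 0.3))
  avg <- average_profiles(list(a = p1, b = p2))
  # unweighted mean of levels, coverage ignored
  expect_equal(avg$level, c((0.9 + 0.05) / 2, (0.1 + 0.3) / 2))
  expect_identical(avg$n_replicates, c(2L, 2L))
})

test_that("quantitative analysis freezes one site set across samples", {
  res <- run_demo_experiment(seed = 11, mode = "allele",
                             conditions = c("untreated", "day6", "day15"),
                             replicates = 1, n_read_pairs = 1200)
  r1 <- res$pipeline$results$allele1
  r2 <- res$pipeline$results$allele2
  # the off-target allele reuses the on-target site set
  expect_identical(r1$selected_sites, r2$selected_sites)
  # the responsive block (allele-local CpG sites 9-14) is what the rule picks
  expect_identical(r1$selected_sites,
                   demo$haplotypes$allele1$cpg_positions[9:14])
  expect_true(all(!is.na(r1$m_table$D[r1$m_table$treatment == "allele"])))
})
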