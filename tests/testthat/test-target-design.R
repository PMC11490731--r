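test_that("PAM-SNP scan finds allele-discriminating NGG sites", {
  # SNP G completes TGG on the plus strand; the C allele breaks it
  seq <- paste0(random_dna(30, 71), "AAAT", "G", "GAAA", random_dna(30, 72))
  snp_pos <- 35L
  snps <- data.frame(pos = snp_pos, ref = "G", alt = "C")
  cand <- find_pam_snps(seq, snps, tss = 35, window = 2000,
                        include_protospacer_snps = FALSE)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$strand, "+")
  expect_identical(cand$pam_start, snp_pos - 1L)
  expect_identical(cand$pam_sequence, "TGG")
  expect_identical(nchar(cand$protospacer), 20L)
  # no SNPs -> empty; G>A is not G-to-Y -> excluded
  expect_identical(nrow(find_pam_snps(seq, snps[0, ], tss = 35)), 0L)
  snps_ga <- data.frame(pos = snp_pos, ref = "G", alt = "A")
  expect_identical(nrow(find_pam_snps(seq, snps_ga, tss = 35,
                                      include_protospacer_snps = FALSE)), 0L)
  # outside the promoter window -> excluded
  expect_identical(nrow(find_pam_snps(seq, snps, tss = 35, window = 2000,
                                      include_protospacer_snps = FALSE)),
                   1L)
  far <- find_pam_snps(seq, snps, tss = 3000, window = 2000,
                       include_protospacer_snps = FALSE)
  expect_identical(nrow(far), 0L)
})

test_that("every candidate is NGG on the G allele and broken on the Y allele", {
  for (seed in 81:84) {
    seq <- random_dna(400, seed)
    pos <- seq(30, 370, by = 17)
    ch <- strsplit(seq, "")[[1]]
    snps <- data.frame(pos = pos, ref = ch[pos],
                       alt = ifelse(ch[pos] == "G", "C", "G"))
    cand <- find_pam_snps(seq, snps, tss = 200, window = 2000,
                          include_protospacer_snps = FALSE)
    for (i in seq_len(nrow(cand))) {
      s <- if (cand$strand[i] == "+") seq else revcomp_str(seq)
      p_snp <- if (cand$strand[i] == "+") cand$snp_pos[i] else nchar(seq) - cand$snp_pos[i] + 1L
      g <- strsplit(s, "")[[1]]; y <- g
      is_ref_g <- cand$g_allele[i] == "ref"
      strand_base <- function(b) if (cand$strand[i] == "+") b else revcomp_str(b)
      g[p_snp] <- strand_base(if (is_ref_g) cand$ref[i] else cand$alt[i])
      y[p_snp] <- strand_base(if (is_ref_g) cand$alt[i] else cand$ref[i])
      ps <- cand$pam_start[i]
      expect_identical(paste(g[(ps + 1):(ps + 2)], collapse = ""), "GG")
      expect_false(paste(y[(ps + 1):(ps + 2)], collapse = "") == "GG")
    }
  }
})

test_that("PAM-SNP scan is strand-symmetric", {
  seq <- random_dna(300, 91)
  ch <- strsplit(seq, "")[[1]]
  pos <- seq(25, 275, by = 13)
  snps <- data.frame(pos = pos, ref = ch[pos],
                     alt = ifelse(ch[pos] == "G", "C",
                                  ifelse(ch[pos] == "C", "G", "T")))
  keep <- snps$ref %in% c("G", "C")  # G-to-Y on one of the strands
  snps <- snps[keep, ]
  fwd <- find_pam_snps(seq, snps, tss = 150, include_protospacer_snps = FALSE)
  L <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snps_rc <- data.frame(pos = L - snps$pos + 1L,
                        ref = unname(comp[snps$ref]),
                        alt = unname(comp[snps$alt]))
  rev <- find_pam_snps(revcomp_str(seq), snps_rc, tss = L - 150 + 1L,
                       include_protospacer_snps = FALSE)
  expect_identical(nrow(fwd), nrow(rev))
  expect_setequal(L - fwd$snp_pos + 1L, rev$snp_pos)
  expect_setequal(fwd$protospacer, rev$protospacer)
})

test_that("sgRNA design extracts the 20 nt upstream of the PAM", {
  # the scrambled control guide has the canonical spacer length
  scrambled <- "GAACAGTCGCGTTTGCGACT"
  expect_identical(nchar(scrambled), 20L)
  seq50 <- random_dna(50, 95)
  expect_identical(design_sgrna(seq50, 26), substr(seq50, 6, 25))
  expect_identical(nchar(design_sgrna(seq50, 26)), 20L)
  expect_error(design_sgrna(seq50, 11), "context")
  expect_error(design_sgrna(seq50, 49), "beyond")
})

test_that("off-target enumeration recovers planted sites and nothing else", {
  proto <- design_sgrna(random_dna(40, 101), 25)
  backbone <- random_dna(3000, 102)
  # plant exact + 2-mismatch sites with NGG PAMs, one on the minus strand
  p2 <- proto
  substr(p2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(p2, 3, 3))[1]
  substr(p2, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(p2, 15, 15))[1]
  subject <- paste0(substr(backbone, 1, 500), proto, "TGG",
                    substr(backbone, 501, 1500), p2, "AGG",
                    substr(backbone, 1501, 2000),
                    revcomp_str(paste0(proto, "CGG")),
                    substr(backbone, 2001, 3000))
  hits0 <- enumerate_offtargets(proto, c(s = subject), max_mismatches = 0)
  expect_true(any(hits0$position == 501 & hits0$strand == "+"))
  h1 <- enumerate_offtargets(proto, c(s = subject), max_mismatches = 1)
  expect_false(any(h1$mismatches == 2))
  h2 <- enumerate_offtargets(proto, c(s = subject), max_mismatches = 2)
  expect_true(any(h2$mismatches == 2 & h2$strand == "+"))
  expect_true(any(h2$mismatches == 0 & h2$strand == "-"))
  # sorted by mismatch count
  expect_true(!is.unsorted(h2$mismatches))
  # NAG sites only appear when the class is allowed
  hNGG <- enumerate_offtargets(proto, c(s = subject), max_mismatches = 2,
                               pam_classes = "NGG")
  expect_true(all(hNGG$pam_class == "NGG"))
  # a PAM-free subject yields nothing
  expect_identical(nrow(enumerate_offtargets(proto, c(t = strrep("AT", 50)))), 0L)
  expect_error(enumerate_offtargets("ACGT", c(s = subject)), "20 nt")
})

test_that("off-target scan agrees with the naive brute force", {
  proto <- design_sgrna(random_dna(40, 111), 25)
  subject <- random_dna(2000, 112)
  got <- enumerate_offtargets(proto, c(s = subject), max_mismatches = 3)
  want <- oracle_offtargets(proto, subject, 3)
  expect_identical(nrow(got), nrow(want))
  key <- function(d) sort(paste(d$position, d$strand, d$mismatches))
  expect_identical(key(got), key(want))
})

test_that("demo locus allele-specific guide is recovered by the designer", {
  demo <- demo_locus()
  seq <- demo$haplotypes$allele1$sequence
  snps <- data.frame(pos = demo$locus$snp$position, ref = "G", alt = "C")
  cand <- find_pam_snps(seq, snps, tss = demo$locus$snp$position,
                        include_protospacer_snps = FALSE)
  expect_gte(nrow(cand), 1L)
  plus <- cand[cand$strand == "+", ][1, ]
  sg_row <- demo$locus$sgrna_sites[demo$locus$sgrna_sites$label == "allele", ]
  expect_identical(plus$pam_start, sg_row$pam_start)
  expect_identical(plus$protospacer, design_sgrna(seq, sg_row$pam_start))
  expect_identical(plus$protospacer,
                   substr(seq, sg_row$start, sg_row$end))
})
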