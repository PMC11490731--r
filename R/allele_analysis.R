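# Allele splitting by SNP tag, per-allele methylation profiles, and the
# quantitative demethylation statistics: efficiency D, stability and
# specificity fold.

#' Assign reads to alleles by the SNP base
#'
#' Bisulfite-aware assignment rule at a G-to-Y PAM SNP, applied to the
#' base each read shows at the SNP position (in reference coordinates):
#' * read G claims the G allele (allele 1);
#' * for a C (or T) alternative allele outside any CpG context, read T
#'   or C claims the Y allele -- the unmethylated SNP C converts to T,
#'   but rare unconverted C is the same allele;
#' * if the alternative C creates a CpG on that allele, read C and T
#'   still both claim the Y allele and the base is additionally recorded
#'   as a methylation observation (C methylated, T unmethylated);
#' * any other base, gap, or a read not covering the SNP is unassigned.
#'
#' @param aln a `read_alignments` object from [align_reads()] (or its
#'   `alignments` data.frame).
#' @param snp the locus [snp_spec()].
#' @param haplotypes list of the two [allele_haplotype()] objects, used
#'   to decide whether the alternative allele's SNP base sits in a CpG.
#' @return data.frame of class `allele_assignment`: `read_id`,
#'   `assigned` (allele1/allele2/unassigned), `snp_base`, `rule`, and
#'   `snp_meth_call` (NA unless the SNP creates a CpG on the Y allele).
#' @export
assign_alleles <- function(aln, snp, haplotypes) {
  a <- if (inherits(aln, "read_alignments")) aln$alignments else aln
  pos <- snp$position
  base <- toupper(substr(a$aligned_seq, pos, pos))
  base[base == "" | is.na(base)] <- "-"
  # does the alt-allele SNP base create a CpG on allele2?
  alt_seq <- haplotypes$allele2$sequence
  alt_in_cpg <- snp$alt_base == "C" &&
    substr(alt_seq, pos, pos + 1L) == "CG"
  assigned <- rep("unassigned", nrow(a))
  rule <- rep("uncovered_or_other", nrow(a))
  snp_meth <- rep(NA_character_, nrow(a))
  is_ref <- base == snp$ref_base
  assigned[is_ref] <- "allele1"
  rule[is_ref] <- "ref_base"
  if (snp$alt_base == "C") {
    is_alt <- base %in% c("C", "T")
    assigned[is_alt] <- "allele2"
    rule[is_alt] <- if (alt_in_cpg) "alt_cpg_c_or_t" else "alt_converted_c"
    if (alt_in_cpg) {
      snp_meth[base == "C"] <- "methylated"
      snp_meth[base == "T"] <- "unmethylated"
      snp_meth[assigned != "allele2"] <- NA_character_
    }
  } else {
    is_alt <- base == snp$alt_base
    assigned[is_alt] <- "allele2"
    rule[is_alt] <- "alt_base"
  }
  out <- data.frame(read_id = a$read_id, assigned = assigned, snp_base = base,
                    rule = rule, snp_meth_call = snp_meth,
                    stringsAsFactors = FALSE)
  class(out) <- c("allele_assignment", "data.frame")
  out
}

#' Build per-allele and pooled methylation profiles
#'
#' Aggregates per-read CpG calls into per-site methylated/unmethylated
#' counts and levels, once per allele and once pooled over all reads
#' (the locus-specific view). Sites with zero coverage get `level = NA`,
#' never 0.
#'
#' @param calls long data.frame of per-read calls (from [align_reads()]
#'   / [filter_reads()]).
#' @param assignments an `allele_assignment` data.frame from
#'   [assign_alleles()]; reads absent from it (or unassigned) only
#'   contribute to the pooled profile.
#' @param correspondence optional [build_cpg_correspondence()] result;
#'   when given, sites are keyed by amplicon position and allele-unique
#'   sites retain their flags.
#' @return data.frame of class `methylation_profile` with columns
#'   `allele` (allele1/allele2/pooled), `position`, `n_meth`,
#'   `n_unmeth`, `coverage`, `level`.
#' @export
build_profiles <- function(calls, assignments = NULL, correspondence = NULL) {
  informative <- calls[calls$call %in% c("methylated", "unmethylated"), ,
                       drop = FALSE]
  tab_one <- function(d, label) {
    if (nrow(d) == 0L) {
      return(data.frame(allele = character(0), position = integer(0),
                        n_meth = integer(0), n_unmeth = integer(0),
                        coverage = integer(0), level = numeric(0)))
    }
    m <- tapply(d$call == "methylated", d$position, sum)
    u <- tapply(d$call == "unmethylated", d$position, sum)
    pos <- as.integer(names(m))
    data.frame(allele = label, position = pos, n_meth = as.integer(m),
               n_unmeth = as.integer(u),
               coverage = as.integer(m + u),
               level = as.integer(m) / as.integer(m + u))
  }
  parts <- list(tab_one(informative, "pooled"))
  if (!is.null(assignments)) {
    for (al in c("allele1", "allele2")) {
      ids <- assignments$read_id[assignments$assigned == al]
      parts[[al]] <- tab_one(informative[informative$read_id %in% ids, ,
                                         drop = FALSE], al)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (!is.null(correspondence)) {
    # make sure allele-unique sites appear (flagged by NA level) rather
    # than being silently dropped
    for (al in c("allele1", "allele2")) {
      col <- paste0("index_", al)
      have <- correspondence$position[!is.na(correspondence[[col]])]
      miss <- setdiff(have, out$position[out$allele == al])
      if (length(miss) && al %in% out$allele) {
        out <- rbind(out, data.frame(allele = al, position = miss, n_meth = 0L,
                                     n_unmeth = 0L, coverage = 0L,
                                     level = NA_real_))
      }
    }
    out <- out[order(out$allele, out$position), ]
    rownames(out) <- NULL
  }
  class(out) <- c("methylation_profile", "data.frame")
  out
}

#' Average replicate methylation profiles per site
#'
#' Unweighted mean of per-site levels across replicate profiles (figure
#' convention: "lines and bars show the average" of biological
#' replicates).
#'
#' @param profiles list of `methylation_profile` data.frames.
#' @param allele which profile stratum to average (default `"pooled"`).
#' @return data.frame `position`, `level` (mean over replicates,
#'   NA-removed), `n_replicates`.
#' @export
average_profiles <- function(profiles, allele = "pooled") {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    p[p$allele == allele, c("position", "level"), drop = FALSE]
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(position = integer(0), level = numeric(0),
                      n_replicates = integer(0)))
  }
  lv <- tapply(rows$level, rows$position, mean, na.rm = TRUE)
  nn <- tapply(!is.na(rows$level), rows$position, sum)
  data.frame(position = as.integer(names(lv)), level = as.numeric(lv),
             n_replicates = as.integer(nn))
}

#' Select CpG sites for quantitative analysis
#'
#' Implements the site-selection rule: per site, the demethylation
#' effect is the drop in (replicate-averaged) methylation level between
#' control and day-6 treated profiles; sites showing at least `fraction`
#' (default 50%) of the maximal effect are selected. The returned set is
#' then frozen and reused for every sample of the experiment.
#'
#' @param control,treated data.frames with `position` and `level`
#'   (replicate-averaged, e.g. from [average_profiles()]).
#' @param fraction fraction of the maximal effect (default 0.5).
#' @return integer vector of selected CpG positions (possibly empty,
#'   with a warning, when no site is demethylated).
#' @export
select_quant_sites <- function(control, treated, fraction = 0.5) {
  shared <- intersect(control$position, treated$position)
  delta <- control$level[match(shared, control$position)] -
    treated$level[match(shared, treated$position)]
  ok <- !is.na(delta)
  shared <- shared[ok]; delta <- delta[ok]
  if (length(delta) == 0L || all(delta <= 0)) {
    warning("no site shows a demethylation effect; empty selection")
    return(integer(0))
  }
  thr <- fraction * max(delta)
  sort(shared[delta >= thr])
}

#' Demethylation efficiency D
#'
#' `D = (M_control - M_treated) / M_control * 100`, both inputs in
#' percent methylation averaged over the selected CpG sites.
#'
#' @param m_control,m_treated mean methylation (%) of the untreated and
#'   treated sample over the selected sites.
#' @return demethylation efficiency in percent (vectorized).
#' @export
#' @examples
#' demethylation_efficiency(97.7, 26.8)  # 72.57...
demethylation_efficiency <- function(m_control, m_treated) {
  if (any(m_control <= 0)) {
    stop("demethylation efficiency is undefined for M_control <= 0", call. = FALSE)
  }
  (m_control - m_treated) / m_control * 100
}

#' Stability of demethylation
#'
#' Fraction of the initial (day-6) demethylation still present at day
#' 15: `D_day15 / D_day6 * 100`.
#'
#' @param d_day6,d_day15 demethylation efficiencies in percent.
#' @return stability in percent.
#' @export
stability_fraction <- function(d_day6, d_day15) {
  if (any(d_day6 <= 0)) stop("stability undefined for D_day6 <= 0", call. = FALSE)
  d_day15 / d_day6 * 100
}

#' Specificity fold of targeted over background demethylation
#'
#' Ratio of the targeted demethylation efficiency to the background
#' (scrambled-control or off-target-allele) efficiency, rounded half-up
#' to an integer to match "n-fold" reporting.
#'
#' @param d_target,d_background demethylation efficiencies in percent.
#' @return integer fold (Inf, with a warning, when the background is
#'   zero or negative).
#' @export
specificity_fold <- function(d_target, d_background) {
  if (any(d_background <= 0)) {
    warning("background demethylation <= 0; specificity is unbounded")
    return(Inf)
  }
  round_half_up(d_target / d_background)
}

#' Quantitative demethylation analysis of a processed experiment
#'
#' Applies the full quantitative recipe: average replicate profiles,
#' select quantification sites on the day-6 vs untreated contrast,
#' freeze that site set, compute per-sample mean methylation (M, %) and
#' demethylation efficiency D, then stability (day 15 vs day 6) and, if
#' a scrambled control is present, the specificity fold.
#'
#' @param profiles named list of `methylation_profile` data.frames, one
#'   per sample (names = sample ids).
#' @param samples data.frame with `sample_id`, `treatment`, `day`,
#'   `replicate` covering the profiles.
#' @param allele which stratum to analyze (`"pooled"` for locus-specific
#'   mode, `"allele1"`/`"allele2"` for allelic resolution).
#' @param select_day treatment day used for site selection (default 6,
#'   the day of maximal effect).
#' @param sites optional pre-selected site positions; when given, the
#'   selection step is skipped (used to reuse on-target sites for the
#'   off-target allele).
#' @param fraction site-selection fraction, see [select_quant_sites()].
#' @return list of class `demethylation_result`: `selected_sites`,
#'   `m_table` (per-sample mean methylation % and D), `m_control`,
#'   `d_day6`, `d_day15`, `stability`, `specificity_fold` (vs scrambled;
#'   NA without a scrambled control).
#' @export
demethylation_analysis <- function(profiles, samples, allele = "pooled",
                                   select_day = 6L, sites = NULL,
                                   fraction = 0.5) {
  stopifnot(all(samples$sample_id %in% names(profiles)))
  grp <- function(treatment, day = NULL) {
    sel <- samples$treatment == treatment
    if (!is.null(day)) sel <- sel & samples$day == day
    samples$sample_id[sel]
  }
  ctrl_ids <- grp("untreated")
  if (length(ctrl_ids) == 0L) stop("no untreated control samples", call. = FALSE)
  avg <- function(ids) average_profiles(profiles[ids], allele = allele)
  ctrl_avg <- avg(ctrl_ids)
  if (is.null(sites)) {
    d6_ids <- samples$sample_id[samples$treatment %in% c("locus", "allele") &
                                  samples$day == select_day]
    if (length(d6_ids) == 0L) stop("no treated samples at the selection day", call. = FALSE)
    sites <- select_quant_sites(ctrl_avg, avg(d6_ids), fraction = fraction)
  }
  mean_m <- function(avg_profile) {
    100 * mean(avg_profile$level[avg_profile$position %in% sites], na.rm = TRUE)
  }
  # per-sample M over frozen sites (on each sample's own profile)
  m_sample <- vapply(samples$sample_id, function(sid) {
    p <- profiles[[sid]]
    p <- p[p$allele == allele & p$position %in% sites, , drop = FALSE]
    100 * mean(p$level, na.rm = TRUE)
  }, 0)
  m_control <- mean_m(ctrl_avg)
  m_table <- cbind(samples,
                   M = unname(m_sample),
                   D = ifelse(samples$treatment == "untreated", NA,
                              demethylation_efficiency(m_control, unname(m_sample))))
  day_d <- function(day) {
    ids <- samples$treatment %in% c("locus", "allele") & samples$day == day
    if (!any(ids)) return(NA_real_)
    demethylation_efficiency(m_control, mean(m_sample[ids]))
  }
  d6 <- day_d(6L); d15 <- day_d(15L)
  stab <- if (!is.na(d6) && !is.na(d15) && d6 > 0) stability_fraction(d6, d15) else NA_real_
  scr_ids <- grp("scrambled")
  spec <- NA_real_
  if (length(scr_ids) && !is.na(d6)) {
    d_scr <- demethylation_efficiency(m_control, mean(m_sample[samples$sample_id %in% scr_ids]))
    if (d_scr > 0) spec <- specificity_fold(d6, d_scr)
  }
  structure(list(selected_sites = sites, m_table = m_table,
                 m_control = m_control, d_day6 = d6, d_day15 = d15,
                 stability = stab, specificity_fold = spec, allele = allele),
            class = "demethylation_result")
}

#' @export
print.demethylation_result <- function(x, ...) {
  cat(sprintf("<demethylation_result [%s]: %d sites, M_control %.1f%%, D_day6 %.1f%%, stability %.1f%%>\n",
              x$allele, length(x$selected_sites), x$m_control,
              x$d_day6 %||% NA, x$stability %||% NA))
  invisible(x)
}

#' Plot methylation profiles
#'
#' Per-CpG methylation levels (y) along the amplicon CpG index (x), one
#' line per sample, with sgRNA binding sites shaded -- the standard
#' profile view of a demethylation time course.
#'
#' @param profiles named list of `methylation_profile` data.frames.
#' @param allele stratum to plot.
#' @param locus optional [target_locus()] whose sgRNA sites are shaded.
#' @return a ggplot object.
#' @export
plot_methylation_profiles <- function(profiles, allele = "pooled", locus = NULL) {
  df <- do.call(rbind, lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    p <- p[p$allele == allele, , drop = FALSE]
    if (nrow(p) == 0L) return(NULL)
    p$sample <- sid
    p
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = position, y = level,
                                         colour = sample)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "CpG position (bp)", y = "methylation level",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(locus)) {
    gg <- gg + ggplot2::annotate("rect",
                                 xmin = locus$sgrna_sites$start,
                                 xmax = locus$sgrna_sites$end,
                                 ymin = 0, ymax = 1, alpha = 0.15,
                                 fill = "goldenrod")
  }
  gg
}

#' Export a methylation profile as bedGraph
#'
#' One-basepair intervals at each CpG C (converted to bedGraph's 0-based
#' half-open coordinates) with the methylation level as score.
#'
#' @param profile a `methylation_profile` data.frame.
#' @param chrom chromosome/amplicon name.
#' @param path output path.
#' @param allele stratum to export.
#' @param offset genomic offset added to amplicon-local positions.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(profile, chrom, path, allele = "pooled", offset = 0L) {
  p <- profile[profile$allele == allele & !is.na(profile$level), , drop = FALSE]
  df <- data.frame(chrom = chrom,
                   start = p$position + offset - 1L,
                   end = p$position + offset,
                   score = p$level)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s_methylation", chrom), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
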