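# Targeted-panel (TMS-style) on-target / off-target quantification:
# coverage masking, per-CpG locus profiles with net specific effect,
# gRNA-footprint annotation, and the EM-seq differential filter.

#' Mask beta values below a coverage floor
#'
#' Converts coverage records to beta values, assigning `NA` ("missing")
#' wherever total coverage is strictly below `min_cov` -- sites covered at
#' exactly `min_cov` are kept. Missing is explicit and propagates through
#' all downstream means; it is never coded as zero methylation.
#'
#' @param records coverage data.frame from [read_bismark_coverage()]
#'   (columns `chrom`, `pos`, `count_methylated`, `count_unmethylated`).
#' @param min_cov minimum total read coverage (default 10).
#' @return data.frame `chrom`, `pos`, `beta` with `NA` where masked.
#' @export
mask_low_coverage <- function(records, min_cov = 10L) {
  total <- records$count_methylated + records$count_unmethylated
  beta <- ifelse(total >= min_cov,
                 records$count_methylated / total, NA_real_)
  data.frame(chrom = records$chrom, pos = records$pos, beta = beta)
}

#' Assemble a targeted panel design
#'
#' @param target_loci region annotation of the on-target locus/loci
#'   (category `target_locus`).
#' @param offtarget_loci predicted off-target loci (category
#'   `offtarget_locus`); may be empty.
#' @param footprints gRNA binding footprint interval(s) (category
#'   `grna_footprint`); may be empty.
#' @return list of class `PanelDesign`.
#' @export
panel_design <- function(target_loci, offtarget_loci = NULL, footprints = NULL) {
  empty <- region_annotation(character(), integer(), integer(), character(),
                             "offtarget_locus")
  offtarget_loci <- offtarget_loci %||% empty
  footprints <- footprints %||% empty
  for (x in list(target_loci, offtarget_loci)) {
    if (nrow(x) > 1) {
      gr <- regions_gr(x)
      if (any(GenomicRanges::countOverlaps(gr, gr) > 1))
        stop_("panel loci overlap within a category")
    }
  }
  structure(list(target_loci = target_loci, offtarget_loci = offtarget_loci,
                 footprints = footprints), class = "PanelDesign")
}

site_in_regions <- function(sites, regions) {
  # half-open containment: start <= pos < end
  if (nrow(regions) == 0) return(rep(FALSE, nrow(sites)))
  gr_s <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  GenomicRanges::countOverlaps(gr_s, regions_gr(regions)) > 0
}

#' Per-CpG and per-locus editing profiles for a targeted panel
#'
#' For every panel locus (on-target and predicted off-target), computes the
#' group-mean beta per CpG for the targeting-gRNA condition, the
#' non-targeting control (NTC) and the reference control (typically the
#' catalytically dead construct), the deltas against the reference, and the
#' net specific effect of the targeting gRNA,
#' `net_effect = delta(targeting vs ref) - delta(NTC vs ref)` --
#' algebraically equal to `mean(targeting) - mean(NTC)`, so the choice of
#' common reference cancels. CpGs inside a gRNA footprint are flagged and
#' additionally summarized separately in the locus table, since the
#' dCas9-gRNA complex sterically protects them from deposition.
#'
#' @param beta `BetaMatrix`.
#' @param design `PanelDesign` from [panel_design()].
#' @param targeting,ntc,reference character vectors of `sample_id`s for the
#'   three conditions.
#' @return list with `cpgs` (per-CpG data.frame: locus, coordinates,
#'   per-condition means, `delta_targeting`, `delta_ntc`, `net_effect`,
#'   `footprint`) and `loci` (per-locus summary with means over non-missing
#'   CpGs, footprint/non-footprint breakdown, covered CpG count, and a
#'   `no_coverage` warning flag for loci with zero covered CpGs).
#' @export
locus_profiles <- function(beta, design, targeting, ntc, reference) {
  stopifnot(inherits(beta, "BetaMatrix"), inherits(design, "PanelDesign"))
  loci <- rbind(design$target_loci, design$offtarget_loci)
  if (nrow(loci) == 0) stop_("panel design has no loci")
  group_mean <- function(ids) {
    v <- beta$values[, ids, drop = FALSE]
    n <- rowSums(!is.na(v))
    ifelse(n > 0, rowMeans(v, na.rm = TRUE), NA_real_)
  }
  mt <- group_mean(targeting); mn <- group_mean(ntc); mr <- group_mean(reference)
  fp <- site_in_regions(beta$sites, design$footprints)

  cpg_rows <- list(); locus_rows <- list()
  for (i in seq_len(nrow(loci))) {
    inside <- beta$sites$chrom == loci$chrom[i] &
      beta$sites$pos >= loci$start[i] & beta$sites$pos < loci$end[i]
    idx <- which(inside)
    if (length(idx) == 0) {
      warning(sprintf("locus '%s' has no covered CpGs", loci$label[i]),
              call. = FALSE)
      locus_rows[[i]] <- data.frame(
        locus = loci$label[i], category = loci$category[i], n_cpgs = 0L,
        mean_targeting = NA_real_, mean_ntc = NA_real_, mean_reference = NA_real_,
        mean_delta_targeting = NA_real_, mean_delta_ntc = NA_real_,
        mean_net_effect = NA_real_, mean_net_effect_footprint = NA_real_,
        mean_net_effect_nonfootprint = NA_real_, no_coverage = TRUE)
      next
    }
    cpg <- data.frame(locus = loci$label[i], category = loci$category[i],
                      chrom = beta$sites$chrom[idx], pos = beta$sites$pos[idx],
                      beta_targeting = mt[idx], beta_ntc = mn[idx],
                      beta_reference = mr[idx],
                      delta_targeting = mt[idx] - mr[idx],
                      delta_ntc = mn[idx] - mr[idx],
                      net_effect = mt[idx] - mn[idx],
                      footprint = fp[idx])
    cpg_rows[[i]] <- cpg
    mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    locus_rows[[i]] <- data.frame(
      locus = loci$label[i], category = loci$category[i],
      n_cpgs = length(idx),
      mean_targeting = mean_na(cpg$beta_targeting),
      mean_ntc = mean_na(cpg$beta_ntc),
      mean_reference = mean_na(cpg$beta_reference),
      mean_delta_targeting = mean_na(cpg$delta_targeting),
      mean_delta_ntc = mean_na(cpg$delta_ntc),
      mean_net_effect = mean_na(cpg$net_effect),
      mean_net_effect_footprint = mean_na(cpg$net_effect[cpg$footprint]),
      mean_net_effect_nonfootprint = mean_na(cpg$net_effect[!cpg$footprint]),
      no_coverage = FALSE)
  }
  list(cpgs = do.call(rbind, cpg_rows), loci = do.call(rbind, locus_rows))
}

#' EM-seq style differential CpG filter
#'
#' Joins two coverage tables by site and retains CpGs that are covered at
#' `>= min_cov` in both conditions and whose beta difference is
#' `>= min_diff` (inclusive). Note the deliberate asymmetry with the DMR
#' caller: the coverage floor and the difference threshold here are both
#' inclusive (`>=`), whereas the DMR effect-size rule is strict (`>`); each
#' follows the convention of the workflow it models.
#'
#' @param cov_a,cov_b coverage data.frames (see
#'   [read_bismark_coverage()]) for the two conditions.
#' @param min_cov minimum coverage in each condition (default 10,
#'   inclusive).
#' @param min_diff minimum absolute beta difference (default 0.10,
#'   inclusive).
#' @return data.frame of retained CpGs: `chrom`, `pos`, `beta_a`, `beta_b`,
#'   `diff` (= `beta_a - beta_b`).
#' @export
emseq_filter <- function(cov_a, cov_b, min_cov = 10L, min_diff = 0.10) {
  prep <- function(x) {
    total <- x$count_methylated + x$count_unmethylated
    data.frame(chrom = x$chrom, pos = x$pos,
               beta = ifelse(total > 0, x$count_methylated / total, NA_real_),
               cov = total)
  }
  a <- prep(cov_a)
  b <- prep(cov_b)
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  # inclusive boundary with a float guard: count-ratio differences like
  # 5/10 - 4/10 must count as exactly 0.10
  keep <- m$cov_a >= min_cov & m$cov_b >= min_cov &
    !is.na(m$beta_a) & !is.na(m$beta_b) &
    abs(m$beta_a - m$beta_b) >= min_diff - 1e-12
  out <- m[keep, c("chrom", "pos", "beta_a", "beta_b")]
  out$diff <- out$beta_a - out$beta_b
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
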