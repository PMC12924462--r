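# Per-CpG differential methylation and the effect-size DMR run rule.

#' Per-CpG delta-beta between two sample groups
#'
#' For each CpG site, delta = mean(beta over treatment replicates) -
#' mean(beta over control replicates), means taken over non-missing values
#' only. A site is missing in the output when either group is fully missing
#' there.
#'
#' @param beta `BetaMatrix`.
#' @param treatment,control character vectors of `sample_id`s; must be
#'   non-empty and disjoint.
#' @return A `DeltaTrack`: data.frame with columns `chrom`, `pos`, `delta`,
#'   `n_treat`, `n_ctrl` (non-missing replicate counts), sorted by
#'   `(chrom, pos)`.
#' @export
compute_delta <- function(beta, treatment, control) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (length(treatment) == 0) stop_("empty treatment selector")
  if (length(control) == 0) stop_("empty control selector")
  if (length(intersect(treatment, control)) > 0)
    stop_("treatment and control selectors overlap: %s",
          paste(intersect(treatment, control), collapse = ", "))
  miss <- setdiff(c(treatment, control), beta$samples$sample_id)
  if (length(miss) > 0)
    stop_("unknown sample_id(s): %s", paste(miss, collapse = ", "))
  vt <- beta$values[, treatment, drop = FALSE]
  vc <- beta$values[, control, drop = FALSE]
  nt <- rowSums(!is.na(vt))
  nc <- rowSums(!is.na(vc))
  mt <- ifelse(nt > 0, rowMeans(vt, na.rm = TRUE), NA_real_)
  mc <- ifelse(nc > 0, rowMeans(vc, na.rm = TRUE), NA_real_)
  out <- data.frame(chrom = beta$sites$chrom, pos = beta$sites$pos,
                    delta = mt - mc, n_treat = nt, n_ctrl = nc)
  class(out) <- c("DeltaTrack", "data.frame")
  out
}

#' Call differentially methylated regions
#'
#' A DMR is a maximal run of at least `min_cpgs` consecutive CpG sites that
#' all exceed the effect-size threshold in the same direction
#' (`|delta| > min_abs_delta`, strict) with every successive-position gap
#' strictly below `max_gap`. Any intervening site that does not qualify --
#' whether missing, sub-threshold, or of the opposite sign -- breaks the run:
#' intermediate evidence must be present and concordant. The same rule is
#' applied to each sign separately, yielding hypermethylated (`hyper`,
#' delta > threshold) and hypomethylated (`hypo`, delta < -threshold)
#' regions. The reported interval spans the first to last member cytosine,
#' half-open: `[first_pos, last_pos + 1)`.
#'
#' Runs are formed over consecutive qualifying CpGs among all sites present
#' in the input track, not over adjacent array probes: if the input omits a
#' site, it cannot break a run.
#'
#' @param delta `DeltaTrack` from [compute_delta()], sorted by
#'   `(chrom, pos)`.
#' @param min_cpgs minimum member CpGs per DMR (default 2).
#' @param min_abs_delta effect-size threshold, strict `>` (default 0.1).
#' @param max_gap maximum successive CpG gap in bp, strict `<`
#'   (default 2000).
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `n_cpgs`,
#'   `direction`, `mean_delta`, and a list-column `cpg_positions` of member
#'   cytosine positions.
#' @export
call_dmrs <- function(delta, min_cpgs = 2L, min_abs_delta = 0.1,
                      max_gap = 2000L) {
  if (!all(c("chrom", "pos", "delta") %in% names(delta)))
    stop_("delta must have columns chrom, pos, delta")
  if (min_cpgs < 1 || min_abs_delta <= 0 || max_gap <= 0)
    stop_("thresholds must be positive")
  n <- nrow(delta)
  if (!identical(order(delta$chrom, delta$pos), seq_len(n)))
    stop_("delta track must be sorted by (chrom, pos)")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), direction = character(),
                      mean_delta = numeric())
  empty$cpg_positions <- list()
  if (n == 0) return(empty)

  d <- delta$delta
  s <- ifelse(!is.na(d) & abs(d) > min_abs_delta, sign(d), 0)
  # A new run starts where the sign changes, the site disqualifies, the
  # chromosome changes, or the gap to the previous site reaches max_gap.
  new_chrom <- c(TRUE, delta$chrom[-1] != delta$chrom[-n])
  gap_break <- c(TRUE, (delta$pos[-1] - delta$pos[-n]) >= max_gap)
  run_id <- cumsum(new_chrom | gap_break | c(TRUE, s[-1] != s[-n]))

  keep <- s != 0
  if (!any(keep)) return(empty)
  runs <- split(which(keep), run_id[keep])
  runs <- runs[lengths(runs) >= min_cpgs]
  if (length(runs) == 0) return(empty)
  out <- do.call(rbind, lapply(runs, function(ix) {
    data.frame(chrom = delta$chrom[ix[1]],
               start = delta$pos[ix[1]],
               end = delta$pos[ix[length(ix)]] + 1L,
               n_cpgs = length(ix),
               direction = if (s[ix[1]] > 0) "hyper" else "hypo",
               mean_delta = mean(d[ix]))
  }))
  out$cpg_positions <- unname(lapply(runs, function(ix) delta$pos[ix]))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Summarize a DMR set by direction
#'
#' Counts of hyper- and hypomethylated regions with integer percentages
#' (round-half-up). Because the two percentages are rounded independently
#' they may sum to 99, 100 or 101.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @return one-row data.frame: `total`, `n_hyper`, `n_hypo`, `pct_hyper`,
#'   `pct_hypo`.
#' @export
summarize_dmrs <- function(dmrs) {
  n_hyper <- sum(dmrs$direction == "hyper")
  n_hypo <- sum(dmrs$direction == "hypo")
  total <- n_hyper + n_hypo
  data.frame(total = total, n_hyper = n_hyper, n_hypo = n_hypo,
             pct_hyper = if (total > 0) round_half_up(100 * n_hyper / total) else 0,
             pct_hypo = if (total > 0) round_half_up(100 * n_hypo / total) else 0)
}
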