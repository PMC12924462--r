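# Temporal persistence of DMR sets and pairwise sharedness across conditions.

dmr_cpg_keys <- function(dmrs) {
  # one character vector per DMR: "chrom:pos:direction"
  Map(function(chrom, pos, dir) paste(chrom, pos, dir, sep = ":"),
      dmrs$chrom, dmrs$cpg_positions, dmrs$direction)
}

#' Overlap between two DMR sets
#'
#' A DMR of `a` counts as overlapping when it shares at least one member CpG
#' position with a same-direction DMR of `b` (method `"cpg"`, the default:
#' array-derived DMRs are built from a fixed probe set, so CpG identity is
#' the natural overlap unit and immune to interval-edge artifacts).
#' `method = "bp"` instead requires base-pair interval intersection with a
#' same-direction DMR. Direction must match in both modes: a region hyper at
#' one timepoint and hypo at another is not stable.
#'
#' @param a,b DMR data.frames from [call_dmrs()], same coordinate system.
#' @param method `"cpg"` (shared member CpG) or `"bp"` (interval overlap).
#' @return list with `n_early` (= `nrow(a)`), `n_late` (= `nrow(b)`),
#'   `n_overlap` (DMRs of `a` overlapping `b`), and `persistence_pct`
#'   (`100 * n_overlap / n_early`, `NA` when `a` is empty).
#' @export
overlap_dmr_sets <- function(a, b, method = c("cpg", "bp")) {
  method <- match.arg(method)
  n_early <- nrow(a)
  n_late <- nrow(b)
  if (n_early == 0 || n_late == 0) {
    n_overlap <- 0L
  } else if (method == "cpg") {
    b_keys <- unique(unlist(dmr_cpg_keys(b)))
    n_overlap <- sum(vapply(dmr_cpg_keys(a), function(k) any(k %in% b_keys), TRUE))
  } else {
    hit <- rep(FALSE, n_early)
    for (dir in c("hyper", "hypo")) {
      ia <- which(a$direction == dir)
      ib <- which(b$direction == dir)
      if (length(ia) == 0 || length(ib) == 0) next
      ov <- GenomicRanges::findOverlaps(regions_gr(a[ia, , drop = FALSE]),
                                        regions_gr(b[ib, , drop = FALSE]))
      hit[ia[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
    n_overlap <- sum(hit)
  }
  list(n_early = n_early, n_late = n_late, n_overlap = as.integer(n_overlap),
       persistence_pct = if (n_early > 0) 100 * n_overlap / n_early else NA_real_)
}

#' Persistence fraction of an early DMR set
#'
#' @param n_early number of DMRs at the earlier timepoint (> 0).
#' @param n_overlap how many of them are still present later
#'   (`<= n_early`).
#' @return percentage `100 * n_overlap / n_early` (unrounded).
#' @seealso [format_percent()] for the display convention.
#' @export
persistence_fraction <- function(n_early, n_overlap) {
  if (length(n_early) != 1 || is.na(n_early) || n_early <= 0)
    stop_("n_early must be a single positive count")
  if (n_overlap > n_early) stop_("n_overlap (%d) exceeds n_early (%d)", n_overlap, n_early)
  if (n_overlap < 0) stop_("negative n_overlap")
  100 * n_overlap / n_early
}

#' Display formatting for percentages
#'
#' Fractions of at least 1% are shown as integers (round-half-up), smaller
#' ones with one decimal, so a 5.17% persistence displays as `"5%"` and a
#' 0.317% one as `"0.3%"`.
#'
#' @param pct numeric percentage(s).
#' @return character vector like `"5%"`, `"0.3%"`.
#' @export
format_percent <- function(pct) {
  ifelse(pct >= 1,
         sprintf("%d%%", round_half_up(pct)),
         sprintf("%.1f%%", pct))
}

#' Pairwise sharedness matrix of DMR sets
#'
#' Entry `(i, j)` is the percentage of set `i`'s DMRs that overlap set `j`
#' (row-normalized, hence asymmetric: sets of sizes 4 and 8 sharing 2 DMRs
#' give 50 and 25).
#'
#' @param sets named list of DMR data.frames (length >= 2).
#' @param method overlap criterion, see [overlap_dmr_sets()].
#' @return numeric matrix of percentages with the set names as dimnames;
#'   rows for empty sets are `NA`.
#' @export
pairwise_sharedness <- function(sets, method = c("cpg", "bp")) {
  method <- match.arg(method)
  if (length(sets) < 2) stop_("need at least two DMR sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  k <- length(sets)
  m <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- overlap_dmr_sets(sets[[i]], sets[[j]], method)$persistence_pct
  }
  m
}
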