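# Methylome-transcriptome integration: CpG-gene correlation, DMR-DEG
# intersection, chromatin-state enrichment, predicted off-target overlap,
# gene-set overrepresentation and sequence-preference profiling.

#' Correlate CpG methylation with gene expression
#'
#' For each CpG-gene pair, correlates the beta values with the CPM of the
#' linked gene across samples matched by `sample_id`, pairwise-complete.
#' Spearman is appropriate for the monotone, rank-level question; Pearson
#' for linear per-CpG profiling. Spearman p-values use the exact
#' permutation null for n <= 9 complete pairs (small per-condition sample
#' counts make the asymptotic approximation unsafe) and the t-approximation
#' otherwise. Pairs with fewer than 3 complete observations, or zero
#' variance on either side, are reported as skipped with a reason instead
#' of a coefficient.
#'
#' @param beta `BetaMatrix`.
#' @param expr `NormalizedCounts` from [tmm_normalize()].
#' @param pairs data.frame linking sites to genes: columns `chrom`, `pos`,
#'   `gene`.
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: `chrom`, `pos`, `gene`, `method`, `n`, `r`, `p`,
#'   `significant`, `skipped`, `reason`.
#' @export
cpg_gene_correlation <- function(beta, expr, pairs,
                                 method = c("spearman", "pearson"),
                                 alpha = 0.05) {
  stopifnot(inherits(beta, "BetaMatrix"), inherits(expr, "NormalizedCounts"))
  method <- match.arg(method)
  shared <- intersect(colnames(beta$values), colnames(expr$cpm))
  site_key <- paste(beta$sites$chrom, beta$sites$pos)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    out <- data.frame(chrom = pairs$chrom[k], pos = pairs$pos[k],
                      gene = pairs$gene[k], method = method,
                      n = NA_integer_, r = NA_real_, p = NA_real_,
                      significant = NA, skipped = TRUE, reason = "")
    i <- match(paste(pairs$chrom[k], pairs$pos[k]), site_key)
    j <- match(pairs$gene[k], rownames(expr$cpm))
    if (is.na(i)) { out$reason <- "site not in beta matrix"; return(out) }
    if (is.na(j)) { out$reason <- "gene not in expression matrix"; return(out) }
    x <- beta$values[i, shared]
    y <- expr$cpm[j, shared]
    ok <- !is.na(x) & !is.na(y)
    out$n <- sum(ok)
    if (sum(ok) < 3) { out$reason <- "fewer than 3 complete pairs"; return(out) }
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) { out$reason <- "zero variance"; return(out) }
    ct <- suppressWarnings(cor.test(x, y, method = method,
                                    exact = method == "spearman" && length(x) <= 9))
    out$r <- unname(ct$estimate)
    out$p <- ct$p.value
    out$significant <- ct$p.value < alpha
    out$skipped <- FALSE
    out
  })
  do.call(rbind, rows)
}

#' Map DMRs to genes and intersect with DEGs
#'
#' A DMR maps to a gene when it overlaps the gene body or the promoter
#' window (`promoter_upstream` bp upstream to `promoter_downstream` bp
#' downstream of the annotated gene start). A DMR-DEG is emitted for every
#' mapped gene whose expression screen flagged it (`is_deg`), i.e. a gene
#' showing both a methylation change (`|mean delta-beta| > 0.1` by
#' construction of the DMR set) and an expression change.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param degs DEG data.frame from [call_degs()].
#' @param gene_regions region annotation of gene bodies (category `gene`,
#'   `label` = gene id matching the count matrix).
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   gene start in bp (defaults 1500 and 500).
#' @return data.frame with one row per (DMR, gene) hit where the gene is a
#'   DEG: DMR coordinates and effect, `gene`, `log2fc`, `mapping_rule`
#'   (`"promoter"`, `"body"` or `"promoter+body"`).
#' @export
intersect_dmr_deg <- function(dmrs, degs, gene_regions,
                              promoter_upstream = 1500L,
                              promoter_downstream = 500L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), mean_delta = numeric(),
                      gene = character(), log2fc = numeric(),
                      mapping_rule = character())
  if (nrow(dmrs) == 0 || nrow(gene_regions) == 0) return(empty)
  gr_d <- regions_gr(dmrs)
  gr_body <- regions_gr(gene_regions)
  prom <- data.frame(chrom = gene_regions$chrom,
                     start = pmax(0L, gene_regions$start - promoter_upstream),
                     end = gene_regions$start + promoter_downstream)
  gr_prom <- regions_gr(prom)
  hit_body <- GenomicRanges::findOverlaps(gr_d, gr_body)
  hit_prom <- GenomicRanges::findOverlaps(gr_d, gr_prom)
  key <- function(h) paste(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
  all_keys <- union(key(hit_body), key(hit_prom))
  if (length(all_keys) == 0) return(empty)
  parts <- do.call(rbind, strsplit(all_keys, " "))
  qi <- as.integer(parts[, 1]); gi <- as.integer(parts[, 2])
  rule <- ifelse(all_keys %in% key(hit_prom) & all_keys %in% key(hit_body),
                 "promoter+body",
                 ifelse(all_keys %in% key(hit_prom), "promoter", "body"))
  out <- data.frame(chrom = dmrs$chrom[qi], start = dmrs$start[qi],
                    end = dmrs$end[qi], direction = dmrs$direction[qi],
                    mean_delta = dmrs$mean_delta[qi],
                    gene = gene_regions$label[gi],
                    mapping_rule = rule)
  m <- match(out$gene, degs$gene)
  out$log2fc <- degs$log2fc[m]
  out <- out[!is.na(m) & degs$is_deg[m], , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$gene), ]
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "direction", "mean_delta", "gene",
        "log2fc", "mapping_rule")]
}

assign_state <- function(chrom, midpoint, states) {
  # midpoint containment in the half-open state segmentation
  gr_m <- GenomicRanges::GRanges(chrom, IRanges::IRanges(midpoint + 1L, midpoint + 1L))
  ov <- GenomicRanges::findOverlaps(gr_m, regions_gr(states), select = "first")
  ifelse(is.na(ov), "Unannotated", states$label[ov])
}

#' Chromatin-state enrichment of a DMR set
#'
#' Each query DMR (and each background element) is assigned the chromatin
#' state at its midpoint -- deterministic and tie-free, unlike
#' maximal-overlap assignment. Per state, a 2x2 table of query in/out of the
#' state versus background in/out yields the sample odds ratio (cross
#' product) and a two-sided Fisher exact p-value; both enrichment and
#' depletion are reported (direction by odds ratio versus 1). Midpoints
#' falling in a segmentation gap are assigned `"Unannotated"`.
#'
#' @param query DMR data.frame (or any table with `chrom`, `start`, `end`).
#' @param states chromatin-state region annotation (should tile the
#'   annotated genome without overlap).
#' @param background region table or site table (`chrom`, `pos`) defining
#'   the comparison universe; the choice of background (all probes, all
#'   candidate regions, ...) is the caller's and is echoed in the result.
#' @return data.frame: `state`, `n_in_query`, `n_in_background`,
#'   `odds_ratio`, `p`, `direction`; attribute `background_n` records the
#'   background size.
#' @export
chromhmm_enrichment <- function(query, states, background) {
  q_state <- assign_state(query$chrom,
                          (query$start + query$end) %/% 2L, states)
  b_mid <- if ("pos" %in% names(background)) background$pos
           else (background$start + background$end) %/% 2L
  b_state <- assign_state(background$chrom, b_mid, states)
  labels <- unique(c(states$label, "Unannotated"))
  labels <- labels[labels %in% c(q_state, b_state)]
  nq <- length(q_state); nb <- length(b_state)
  rows <- lapply(labels, function(st) {
    a <- sum(q_state == st); b <- nq - a
    c_ <- sum(b_state == st); d <- nb - c_
    or <- (a * d) / (b * c_)
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(state = st, n_in_query = a, n_in_background = c_,
               odds_ratio = or, p = p,
               direction = if (is.nan(or) || or >= 1) "enriched" else "depleted")
  })
  out <- do.call(rbind, rows)
  attr(out, "background_n") <- nb
  out
}

#' Overlap of predicted off-target loci with observed changes
#'
#' Of the in-silico predicted off-target binding loci, what fraction shows
#' any methylation response (>= 1 CpG with `|delta-beta| > beta_thresh`)
#' and what fraction an expression response of the associated gene
#' (`|log2FC| > logfc_thresh`)? Loci without an associated gene are excluded
#' from the expression denominator.
#'
#' @param predicted off-target region annotation; `label` carries the
#'   associated gene id (empty/`"."` for none).
#' @param delta `DeltaTrack` from [compute_delta()].
#' @param degs DEG table from [call_degs()].
#' @param beta_thresh methylation threshold (default 0.05, strict `>`).
#' @param logfc_thresh expression threshold (default 0.05, strict `>`).
#' @return list: `n_predicted`, `n_meth`, `n_expr`, `frac_meth_pct`,
#'   `frac_expr_pct`, `empty` flag.
#' @export
predicted_offtarget_overlap <- function(predicted, delta, degs,
                                        beta_thresh = 0.05,
                                        logfc_thresh = 0.05) {
  n <- nrow(predicted)
  if (n == 0)
    return(list(n_predicted = 0L, n_meth = 0L, n_expr = 0L,
                frac_meth_pct = NA_real_, frac_expr_pct = NA_real_,
                empty = TRUE))
  hot <- !is.na(delta$delta) & abs(delta$delta) > beta_thresh
  sites_hot <- delta[hot, , drop = FALSE]
  meth_hit <- if (nrow(sites_hot) == 0) rep(FALSE, n) else {
    gr_s <- GenomicRanges::GRanges(sites_hot$chrom,
                                   IRanges::IRanges(sites_hot$pos + 1L, sites_hot$pos + 1L))
    GenomicRanges::countOverlaps(regions_gr(predicted), gr_s) > 0
  }
  has_gene <- !is.na(predicted$label) & nzchar(predicted$label) & predicted$label != "."
  m <- match(predicted$label, degs$gene)
  expr_hit <- has_gene & !is.na(m) & abs(degs$log2fc[m]) > logfc_thresh
  list(n_predicted = n,
       n_meth = sum(meth_hit),
       n_expr = sum(expr_hit),
       frac_meth_pct = 100 * sum(meth_hit) / n,
       frac_expr_pct = if (any(has_gene)) 100 * sum(expr_hit) / sum(has_gene) else NA_real_,
       empty = FALSE)
}

#' Gene-set overrepresentation analysis
#'
#' One-sided hypergeometric upper-tail test of each gene set against a
#' query drawn from a declared universe, with Benjamini-Hochberg adjustment
#' across all tested sets. Sets with no member in the universe are skipped
#' with a reason.
#'
#' @param gene_sets named list of character vectors.
#' @param query_genes character vector, must be a subset of `universe`.
#' @param universe character vector of all considered genes (non-empty).
#' @return data.frame: `set`, `n_set`, `n_overlap`, `odds_ratio`, `p`,
#'   `p_adj`, `skipped`, `reason`.
#' @export
ora <- function(gene_sets, query_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_("empty universe")
  query_genes <- unique(query_genes)
  extra <- setdiff(query_genes, universe)
  if (length(extra) > 0)
    stop_("query gene(s) outside the universe: %s",
          paste(head(extra, 3), collapse = ", "))
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  N <- length(universe); n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    if (K == 0)
      return(data.frame(set = nm, n_set = 0L, n_overlap = NA_integer_,
                        odds_ratio = NA_real_, p = NA_real_,
                        skipped = TRUE, reason = "set disjoint from universe"))
    k <- length(intersect(set, query_genes))
    or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
    data.frame(set = nm, n_set = K, n_overlap = k,
               odds_ratio = or,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               skipped = FALSE, reason = "")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !out$skipped
  out$p_adj[tested] <- p.adjust(out$p[tested], method = "BH")
  out[c("set", "n_set", "n_overlap", "odds_ratio", "p", "p_adj",
        "skipped", "reason")]
}

#' Extract fixed-width sequence windows around CpG sites
#'
#' Cuts the `2k + 1`-mer centered on each cytosine out of per-chromosome
#' sequences. Windows truncated at a sequence edge are skipped and counted.
#'
#' @param sequences named list (or character vector) of chromosome
#'   sequences.
#' @param sites data.frame with `chrom`, `pos` (0-based cytosine position).
#' @param k flank size in bp (default 5, i.e. 11-mers).
#' @return list: `windows` (character vector), `n_skipped`.
#' @export
extract_cpg_windows <- function(sequences, sites, k = 5L) {
  seqs <- as.list(sequences)
  win <- character(0); skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$chrom[i]]]
    if (is.null(s)) { skipped <- skipped + 1L; next }
    # 0-based pos -> 1-based substring index
    from <- sites$pos[i] + 1L - k
    to <- sites$pos[i] + 1L + k
    if (from < 1 || to > nchar(s)) { skipped <- skipped + 1L; next }
    win <- c(win, substr(s, from, to))
  }
  list(windows = win, n_skipped = skipped)
}

#' Sequence preference of DMR CpGs
#'
#' Builds the position frequency matrix (PFM) over fixed-width windows
#' centered on DMR CpGs and tests whether a short motif (default `GCGC`,
#' the DNMT3A-preferred context) occurs in more query windows than
#' background windows (Fisher exact on the 2x2 of motif-containing
#' windows).
#'
#' @param query_windows character vector of equal-length windows around DMR
#'   CpGs (see [extract_cpg_windows()]).
#' @param background_windows windows around non-DMR CpGs.
#' @param motif motif string (default `"GCGC"`).
#' @return list of class `SeqPreference`: `pfm` (4 x width count matrix
#'   over A/C/G/T, each column summing to the number of contributing
#'   windows), `n_query`, `n_background`, `query_with_motif`,
#'   `background_with_motif`, `odds_ratio`, `p`.
#' @export
sequence_preference <- function(query_windows, background_windows,
                                motif = "GCGC") {
  if (length(query_windows) == 0) stop_("no query windows")
  widths <- unique(nchar(c(query_windows, background_windows)))
  if (length(widths) != 1) stop_("windows must all have the same width")
  qs <- Biostrings::DNAStringSet(query_windows)
  pfm <- Biostrings::consensusMatrix(qs)[c("A", "C", "G", "T"), , drop = FALSE]
  has_motif <- function(w) Biostrings::vcountPattern(motif, Biostrings::DNAStringSet(w)) > 0
  qm <- sum(has_motif(query_windows))
  bm <- sum(has_motif(background_windows))
  nq <- length(query_windows); nb <- length(background_windows)
  tab <- matrix(c(qm, nq - qm, bm, nb - bm), 2, byrow = TRUE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- if (nb > 0) fisher.test(tab)$p.value else NA_real_
  structure(list(pfm = pfm, n_query = nq, n_background = nb,
                 query_with_motif = qm, background_with_motif = bm,
                 odds_ratio = or, p = p, motif = motif),
            class = "SeqPreference")
}

#' @export
print.SeqPreference <- function(x, ...) {
  cat(sprintf("SeqPreference: motif %s in %d/%d query vs %d/%d background windows (OR %.2f, p %.3g)\n",
              x$motif, x$query_with_motif, x$n_query,
              x$background_with_motif, x$n_background, x$odds_ratio, x$p))
  invisible(x)
}
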