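# Count filtering, TMM/CPM normalization and DEG screening.

#' Construct a count matrix object
#'
#' @param genes character vector of unique gene identifiers.
#' @param samples sample sheet data.frame (see [beta_matrix()] for the
#'   required columns).
#' @param counts genes-by-samples matrix of non-negative integers.
#' @return object of class `CountMatrix`.
#' @export
count_matrix <- function(genes, samples, counts) {
  genes <- as.character(genes)
  samples <- validate_sample_sheet(samples)
  counts <- as.matrix(counts)
  if (anyDuplicated(genes)) stop_("duplicate gene id '%s'", genes[duplicated(genes)][1])
  if (nrow(counts) != length(genes) || ncol(counts) != nrow(samples))
    stop_("counts must be %d genes x %d samples", length(genes), nrow(samples))
  if (any(is.na(counts)) || any(counts < 0))
    stop_("counts must be non-negative and complete")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(genes, samples$sample_id)
  structure(list(genes = genes, samples = samples, counts = counts),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n", length(x$genes), nrow(x$samples)))
  invisible(x)
}

#' Filter low-expressed genes
#'
#' Keeps a gene when its count reaches `min_count` in at least
#' `ceiling(min_frac * n_samples)` samples -- by default at least 5 reads in
#' at least 25% of the samples.
#'
#' @param counts `CountMatrix`.
#' @param min_count minimum count (default 5).
#' @param min_frac minimum fraction of samples (default 0.25).
#' @return filtered `CountMatrix`.
#' @export
filter_low_expressed <- function(counts, min_count = 5L, min_frac = 0.25) {
  stopifnot(inherits(counts, "CountMatrix"))
  need <- ceiling(min_frac * ncol(counts$counts))
  keep <- rowSums(counts$counts >= min_count) >= need
  count_matrix(counts$genes[keep], counts$samples,
               counts$counts[keep, , drop = FALSE])
}

#' TMM normalization and counts-per-million
#'
#' Between-sample scaling by the trimmed mean of M-values (TMM): per-sample
#' scale factors from a weighted mean of log ratios against a reference
#' sample after trimming 30% on M (log ratio) and 5% on A (log abundance),
#' zeros excluded pairwise; factors are renormalized to geometric mean 1 and
#' CPM uses the effective library size (library size times factor).
#' Computation is delegated to edgeR's implementation of the method.
#'
#' @param counts `CountMatrix` with at least two samples and nonzero library
#'   sizes.
#' @return object of class `NormalizedCounts`: list with `cpm` (gene x
#'   sample matrix), `tmm_factors`, `lib_sizes`, `samples`.
#' @export
tmm_normalize <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (ncol(counts$counts) < 2) stop_("TMM needs at least two samples")
  lib <- colSums(counts$counts)
  if (any(lib == 0))
    stop_("sample(s) with zero total counts: %s",
          paste(counts$samples$sample_id[lib == 0], collapse = ", "))
  d <- edgeR::DGEList(counts = counts$counts)
  d <- edgeR::calcNormFactors(d, method = "TMM")
  structure(list(cpm = edgeR::cpm(d, normalized.lib.sizes = TRUE),
                 tmm_factors = setNames(d$samples$norm.factors,
                                        counts$samples$sample_id),
                 lib_sizes = lib,
                 samples = counts$samples),
            class = "NormalizedCounts")
}

#' @export
print.NormalizedCounts <- function(x, ...) {
  cat(sprintf("NormalizedCounts: %d genes x %d samples (TMM factors %.3f-%.3f)\n",
              nrow(x$cpm), ncol(x$cpm), min(x$tmm_factors), max(x$tmm_factors)))
  invisible(x)
}

#' Screen for differentially expressed genes
#'
#' log2 fold change of group-mean CPM with a pseudocount:
#' `log2((mean CPM_treatment + pc) / (mean CPM_control + pc))`. A gene is
#' flagged (`is_deg`) when `|log2fc| > logfc_thresh` and -- when the test is
#' enabled -- its BH-adjusted p-value is below `alpha`. The default is
#' `test = "off"` (pure effect-size screen); `test = "on"` adds a two-sided
#' Welch t-test on `log2(CPM + pc)` per gene with Benjamini-Hochberg
#' adjustment across all tested genes, and requires at least two replicates
#' per group.
#'
#' @param norm `NormalizedCounts` from [tmm_normalize()].
#' @param treatment,control character vectors of `sample_id`s.
#' @param logfc_thresh absolute log2FC threshold, strict `>` (default 1).
#' @param alpha adjusted-p threshold when testing (default 0.05).
#' @param test `"off"` or `"on"`.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data.frame: `gene`, `log2fc`, `p`, `p_adj` (NA when
#'   `test = "off"`), `is_deg`.
#' @export
call_degs <- function(norm, treatment, control, logfc_thresh = 1.0,
                      alpha = 0.05, test = c("off", "on"), pseudocount = 0.5) {
  stopifnot(inherits(norm, "NormalizedCounts"))
  test <- match.arg(test)
  ids <- colnames(norm$cpm)
  miss <- setdiff(c(treatment, control), ids)
  if (length(miss) > 0) stop_("unknown sample_id(s): %s", paste(miss, collapse = ", "))
  if (length(treatment) == 0 || length(control) == 0)
    stop_("both groups must have at least one sample")
  ct <- norm$cpm[, treatment, drop = FALSE]
  cc <- norm$cpm[, control, drop = FALSE]
  log2fc <- log2((rowMeans(ct) + pseudocount) / (rowMeans(cc) + pseudocount))
  p <- p_adj <- rep(NA_real_, nrow(norm$cpm))
  if (test == "on") {
    if (length(treatment) < 2 || length(control) < 2)
      stop_("test = 'on' needs >= 2 replicates per group; use test = 'off' for singletons")
    lt <- log2(ct + pseudocount); lc <- log2(cc + pseudocount)
    p <- vapply(seq_len(nrow(lt)), function(i) {
      x <- lt[i, ]; y <- lc[i, ]
      if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
      t.test(x, y)$p.value
    }, 0)
    p_adj <- p.adjust(p, method = "BH")
  }
  is_deg <- abs(log2fc) > logfc_thresh
  if (test == "on") is_deg <- is_deg & p_adj < alpha
  data.frame(gene = rownames(norm$cpm), log2fc = log2fc, p = p, p_adj = p_adj,
             is_deg = is_deg, row.names = NULL)
}
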