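# Independent oracles and small fixture builders used across the suite.

# quick sample sheet: n replicates per condition given as construct/guide
make_sheet <- function(conds, n_rep = 2, timepoint = 3) {
  do.call(rbind, lapply(seq_along(conds), function(i) {
    cg <- strsplit(conds[i], "/", fixed = TRUE)[[1]]
    data.frame(sample_id = sprintf("%s_%s_r%d", cg[1], cg[2], seq_len(n_rep)),
               construct = cg[1], guide = cg[2],
               timepoint_days = timepoint, replicate = seq_len(n_rep))
  }))
}

# BetaMatrix on one chromosome from a sites-by-samples value matrix
make_beta <- function(values, positions, sheet, chrom = "chr1") {
  beta_matrix(data.frame(chrom = chrom, pos = positions), sheet, values)
}

# Brute-force enumeration of maximal qualifying runs, independent of
# call_dmrs: greedy left-to-right extension over the site list.
brute_force_dmrs <- function(delta, min_cpgs = 2L, min_abs_delta = 0.1,
                             max_gap = 2000L) {
  out <- list()
  for (ch in unique(delta$chrom)) {
    d <- delta[delta$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    n <- nrow(d)
    qual <- function(i, sgn) !is.na(d$delta[i]) && abs(d$delta[i]) > min_abs_delta &&
      sign(d$delta[i]) == sgn
    i <- 1
    while (i <= n) {
      if (is.na(d$delta[i]) || abs(d$delta[i]) <= min_abs_delta) { i <- i + 1; next }
      sgn <- sign(d$delta[i])
      j <- i
      while (j < n && qual(j + 1, sgn) && (d$pos[j + 1] - d$pos[j]) < max_gap)
        j <- j + 1
      if (j - i + 1 >= min_cpgs) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = d$pos[i], end = d$pos[j] + 1L,
          n_cpgs = j - i + 1L,
          direction = if (sgn > 0) "hyper" else "hypo",
          mean_delta = mean(d$delta[i:j]))
      }
      i <- j + 1
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), direction = character(),
                      mean_delta = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Reference TMM scale factors, written from the published description of
# the method: reference column by 75th-percentile count fraction closest to
# the mean; weighted (inverse asymptotic variance) mean of M-values after
# trimming 30% on M and 5% on A, zeros excluded pairwise; factors
# renormalized to geometric mean 1.
ref_tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) unname(quantile(counts[, j], 0.75)) / lib[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    no <- counts[, j]; No <- lib[j]
    nr <- counts[, ref]; Nr <- lib[ref]
    keep <- no > 0 & nr > 0
    no <- no[keep]; nr <- nr[keep]
    M <- log2((no / No) / (nr / Nr))
    A <- 0.5 * log2((no / No) * (nr / Nr))
    v <- (No - no) / (No * no) + (Nr - nr) / (Nr * nr)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    val <- 2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
    if (!is.finite(val)) 1 else val
  }, 0)
  f / exp(mean(log(f)))
}

# exact two-sided Spearman permutation p for small n (full enumeration)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  perms <- perm_matrix(length(x))
  r_null <- apply(perms, 1, function(p) cor(rx[p], ry))
  mean(abs(r_null) >= abs(r_obs) - 1e-12)
}

# hypergeometric upper-tail p by direct summation
hyper_tail_p <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

tmpdir <- function() {
  d <- tempfile("epieditr_test_")
  dir.create(d)
  d
}
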