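delta_track <- function(pos, delta, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), delta = delta,
             n_treat = 2L, n_ctrl = 2L)
}

test_that("compute_delta takes group-mean differences with missing propagation", {
  sheet <- make_sheet(c("3A/targeting", "d3A/NTC"), n_rep = 2)
  vals <- rbind(c(0.6, 0.7, 0.1, 0.1),
                c(0.5, 0.5, 0.5, 0.5),
                c(0.2, 0.4, NA, NA),
                c(0.9, NA, 0.3, 0.5))
  b <- make_beta(vals, c(100L, 200L, 300L, 400L), sheet)
  treat <- samples_where(b, construct = "3A")
  ctrl <- samples_where(b, construct = "d3A")
  d <- compute_delta(b, treat, ctrl)
  expect_equal(d$delta[1], 0.55)            # mean difference
  expect_equal(d$delta[2], 0)               # identical groups
  expect_true(is.na(d$delta[3]))            # control fully missing
  expect_equal(d$delta[4], 0.9 - 0.4)       # pairwise-complete means
  expect_equal(d$n_treat, c(2L, 2L, 2L, 1L))

  expect_error(compute_delta(b, character(0), ctrl), "empty")
  expect_error(compute_delta(b, treat, treat), "overlap")
})

test_that("call_dmrs reproduces the worked run example", {
  d <- delta_track(c(100, 500, 3000, 3400, 3800),
                   c(0.15, 0.20, -0.15, -0.12, 0.05))
  dmrs <- call_dmrs(d)
  expect_equal(nrow(dmrs), 2)
  expect_equal(dmrs$start, c(100L, 3000L))
  expect_equal(dmrs$end, c(501L, 3401L))
  expect_equal(dmrs$direction, c("hyper", "hypo"))
  expect_equal(dmrs$n_cpgs, c(2L, 2L))
  expect_equal(dmrs$mean_delta, c(0.175, -0.135))
  expect_equal(dmrs$cpg_positions, list(c(100L, 500L), c(3000L, 3400L)))
})

test_that("call_dmrs boundary behaviour: strict gap, strict threshold, run breaks", {
  # gap of exactly max_gap does not join ("less than 2 kb" is strict)
  expect_equal(nrow(call_dmrs(delta_track(c(0, 2000), c(0.2, 0.2)))), 0)
  expect_equal(nrow(call_dmrs(delta_track(c(0, 1999), c(0.2, 0.2)))), 1)
  # |delta| equal to the threshold does not qualify (strict >)
  expect_equal(nrow(call_dmrs(delta_track(c(0, 100), c(0.1, 0.1)))), 0)
  # all-zero track
  expect_equal(nrow(call_dmrs(delta_track(c(0, 100, 200), c(0, 0, 0)))), 0)
  # a missing CpG breaks a run rather than being skipped
  broken <- call_dmrs(delta_track(c(0, 100, 200, 300), c(0.2, 0.2, NA, 0.2)))
  expect_equal(nrow(broken), 1)
  expect_equal(broken$n_cpgs, 2L)
  # a sub-threshold CpG also breaks a run
  broken2 <- call_dmrs(delta_track(c(0, 100, 200, 300, 400),
                                   c(0.2, 0.2, 0.05, 0.2, 0.2)))
  expect_equal(nrow(broken2), 2)
  # unsorted input is rejected
  expect_error(call_dmrs(delta_track(c(500, 100), c(0.2, 0.2))), "sorted")
})

test_that("call_dmrs equals brute-force maximal-run enumeration on random tracks", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(5:300, 1)
    pos <- cumsum(sample(50:5000, n, replace = TRUE))
    delta <- runif(n, -0.3, 0.3)
    delta[runif(n) < 0.08] <- NA  # sprinkle missing sites
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    d <- data.frame(chrom = chrom, pos = pos, delta = delta)
    d <- d[order(d$chrom, d$pos), ]
    got <- call_dmrs(d)
    want <- brute_force_dmrs(d)
    rownames(want) <- NULL
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("DMR calling is monotone in the threshold and symmetric in sign", {
  set.seed(7)
  n <- 200
  d <- delta_track(cumsum(sample(50:3000, n, replace = TRUE)),
                   runif(n, -0.4, 0.4))
  thresholds <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  counts <- vapply(thresholds,
                   function(t) nrow(call_dmrs(d, min_abs_delta = t)), 0L)
  expect_true(all(diff(counts) <= 0))

  neg <- d; neg$delta <- -neg$delta
  s1 <- summarize_dmrs(call_dmrs(d))
  s2 <- summarize_dmrs(call_dmrs(neg))
  expect_equal(s1$n_hyper, s2$n_hypo)
  expect_equal(s1$n_hypo, s2$n_hyper)
})

test_that("within a direction DMRs are disjoint and separated by a break", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:150, 1)
    d <- delta_track(cumsum(sample(50:3000, n, replace = TRUE)),
                     runif(n, -0.3, 0.3))
    dmrs <- call_dmrs(d)
    for (dir in c("hyper", "hypo")) {
      g <- dmrs[dmrs$direction == dir, ]
      if (nrow(g) < 2) next
      g <- g[order(g$start), ]
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      # between consecutive same-direction DMRs there is a disqualifying
      # CpG or a >= max_gap gap
      for (k in seq_len(nrow(g) - 1)) {
        between <- d$pos > g$end[k] - 1 & d$pos < g$start[k + 1]
        gap_sep <- (g$start[k + 1] - (g$end[k] - 1)) >= 2000 ||
          any(diff(d$pos[d$pos >= g$end[k] - 1 & d$pos <= g$start[k + 1]]) >= 2000)
        sgn <- if (dir == "hyper") 1 else -1
        disq <- any(is.na(d$delta[between]) | abs(d$delta[between]) <= 0.1 |
                      sign(d$delta[between]) != sgn)
        expect_true(gap_sep || disq)
      }
    }
  }
})

test_that("summarize_dmrs rounds percentages half-up by direction", {
  mk <- function(n_hyper, n_hypo) {
    data.frame(chrom = "chr1", start = seq_len(n_hyper + n_hypo) * 10L,
               end = seq_len(n_hyper + n_hypo) * 10L + 5L,
               n_cpgs = 2L,
               direction = rep(c("hyper", "hypo"), c(n_hyper, n_hypo)),
               mean_delta = rep(c(0.2, -0.2), c(n_hyper, n_hypo)))
  }
  s <- summarize_dmrs(mk(21282, 195))
  expect_equal(s$total, 21477)
  expect_equal(s$pct_hyper, 99)
  expect_equal(s$pct_hypo, 1)

  s <- summarize_dmrs(mk(16, 493))
  expect_equal(s$total, 509)
  expect_equal(s$pct_hypo, 97)

  s <- summarize_dmrs(mk(1, 0))
  expect_equal(s$pct_hyper, 100)

  s <- summarize_dmrs(mk(1, 0)[0, ])
  expect_equal(s$total, 0)
  expect_equal(s$pct_hyper, 0)

  # independent rounding may overshoot 100
  s <- summarize_dmrs(mk(1, 1))
  expect_true((s$pct_hyper + s$pct_hypo) %in% c(99, 100, 101))
})
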