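test_that("with all randomness off, only target CpGs shift, by exactly the target delta", {
  cfg <- sim_config(n_regions = 50L, off_target_rate = 0, noise_sd = 0,
                    on_target_delta = 0.5, seed = 5L)
  sim <- simulate_dataset(cfg)
  b <- sim$beta$day3
  treat <- samples_where(b, guide = "targeting")
  ctrl <- samples_where(b, construct = "d3A")
  d <- compute_delta(b, treat, ctrl)
  on_target <- sim$truth$cpgs$region_id == 1
  fp <- sim$truth$cpgs$footprint
  expect_equal(unname(d$delta[on_target & !fp]),
               rep(0.5, sum(on_target & !fp)))
  expect_equal(unname(d$delta[on_target & fp]),
               rep(0.5 * (1 - cfg$footprint_protection), sum(fp)))
  expect_equal(unname(d$delta[!on_target]), rep(0, sum(!on_target)))
  # NTC indistinguishable from control when nothing is deposited
  dn <- compute_delta(b, samples_where(b, construct = "CRISPRoff", guide = "NTC"), ctrl)
  expect_equal(unname(dn$delta), rep(0, length(dn$delta)))
})

test_that("simulation is bit-identical under the same seed and differs across seeds", {
  cfg <- sim_config(n_regions = 60L, seed = 9L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$beta$day3$values, s2$beta$day3$values)
  expect_identical(s1$counts$day7$counts, s2$counts$day7$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(sim_config(n_regions = 60L, seed = 10L))
  expect_false(identical(s1$beta$day3$values, s3$beta$day3$values))
})

test_that("zero persistence wipes all off-target deposits at the late timepoint", {
  cfg <- sim_config(n_regions = 120L, noise_sd = 0,
                    persistence = c("3" = 1, "7" = 0.5, "30" = 0), seed = 2L)
  sim <- simulate_dataset(cfg)
  b30 <- sim$beta$day30
  d30 <- compute_delta(b30, samples_where(b30, guide = "targeting"),
                       samples_where(b30, construct = "d3A"))
  outside <- sim$truth$cpgs$region_id != 1
  expect_equal(unname(d30$delta[outside]), rep(0, sum(outside)))
  # on-target editing persists
  expect_true(all(d30$delta[!outside & !sim$truth$cpgs$footprint] > 0.4))
})

test_that("deposited-region count falls in the central 99% binomial band", {
  cfg <- sim_config(n_regions = 1000L, seed = 13L)
  sim <- simulate_dataset(cfg)
  vocab <- cfg$state_vocab
  p_region <- cfg$off_target_rate *
    vocab$weight[match(sim$truth$regions$state, vocab$state)]
  p_region[1] <- 0  # target region excluded from off-target draws
  observed <- sum(sim$truth$regions$deposited_targeting)
  # oracle: Monte-Carlo the Poisson-binomial count distribution
  set.seed(1)
  null_counts <- replicate(4000, sum(rbinom(length(p_region), 1, p_region)))
  band <- quantile(null_counts, c(0.005, 0.995))
  expect_gte(observed, band[[1]])
  expect_lte(observed, band[[2]])
})

test_that("deposition magnitude decreases with baseline methylation", {
  sim <- simulate_dataset(sim_config(n_regions = 3000L, seed = 21L))
  tr <- sim$truth$regions
  dep <- tr$deposited_targeting | tr$deposited_ntc
  low <- dep & tr$baseline < 0.2
  high <- dep & tr$baseline > 0.6
  expect_gt(sum(low), 5)
  expect_gt(sum(high), 5)
  expect_gt(mean(tr$magnitude[low]), mean(tr$magnitude[high]))
})

test_that("truth_expected_dmrs applies threshold, minimum CpGs and persistence", {
  truth <- list(
    regions = data.frame(region_id = 1:3, is_target = FALSE,
                         present_targeting_day3 = c(TRUE, TRUE, TRUE),
                         present_targeting_day7 = c(FALSE, TRUE, TRUE)),
    cpgs = data.frame(
      region_id = rep(1:3, c(5, 3, 1)),
      chrom = "chr1",
      pos = c(100L, 200L, 300L, 400L, 500L, 5000L, 5100L, 5200L, 9000L),
      baseline = 0.05,
      delta_targeting = c(rep(0.3, 5), rep(0.05, 3), 0.4),
      delta_ntc = 0, footprint = FALSE))
  d3 <- truth_expected_dmrs(truth, "targeting", 3)
  expect_equal(nrow(d3), 1)                  # region 2 sub-threshold, region 3 one CpG
  expect_equal(d3$region_id, 1)
  expect_equal(d3$n_cpgs, 5)
  expect_equal(d3$start, 100L)
  expect_equal(d3$end, 501L)
  d7 <- truth_expected_dmrs(truth, "targeting", 7)
  expect_equal(nrow(d7), 0)                  # region 1 did not persist
})

test_that("expected DMRs from truth match the caller on noiseless data", {
  cfg <- sim_config(n_regions = 400L, noise_sd = 0, deposit_jitter_sd = 0,
                    seed = 33L)
  sim <- simulate_dataset(cfg)
  for (tp in c(3, 7)) {
    b <- sim$beta[[paste0("day", tp)]]
    d <- compute_delta(b, samples_where(b, guide = "targeting"),
                       samples_where(b, construct = "d3A"))
    called <- call_dmrs(d)
    expected <- truth_expected_dmrs(sim$truth, "targeting", tp)
    expect_equal(nrow(called), nrow(expected))
    expect_equal(called$start, expected$start)
    expect_equal(called$end, expected$end)
    expect_equal(called$direction, expected$direction)
  }
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(on_target_delta = 1.5), "on_target_delta")
  expect_error(sim_config(off_target_rate = -0.1), "off_target_rate")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(simulate_dataset(sim_config(n_regions = 0L)), "degenerate")
})

test_that("simulated CpG windows center a CpG and embed the motif on demand", {
  w <- simulate_cpg_windows(50, k = 5, gc = 0.5, motif_rate = 0, seed = 3)
  expect_true(all(nchar(w) == 11))
  expect_true(all(substr(w, 6, 7) == "CG"))
  wm <- simulate_cpg_windows(50, k = 5, motif_rate = 1, motif = "GCGC", seed = 3)
  expect_true(all(grepl("GCGC", wm, fixed = TRUE)))
  expect_true(all(substr(wm, 6, 7) == "CG"))
})
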