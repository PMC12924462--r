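# Synthetic methylome + transcriptome generator with ground truth.
#
# Emulates the statistical structure of an epimodifier experiment: a bimodal
# baseline methylome; strong, exact deposition at one gRNA-targeted
# promoter-like region with steric protection under the gRNA footprint;
# random region-wise off-target deposition biased toward low-to-medium
# methylated promoter-like chromatin; per-deposit decay over later
# timepoints; and negative-binomial expression with partial
# methylation-expression coupling plus methylation-independent expression
# changes specific to the non-targeting control gRNA.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

#' Default chromatin-state vocabulary for simulation
#'
#' States with genome-occupancy priors, deposition weights (the per-state
#' multiplier on the off-target deposition rate -- highest for
#' promoter-like open chromatin, near zero for closed chromatin) and a
#' promoter-like flag controlling the baseline methylation mode.
#' @return data.frame: `state`, `prior`, `weight`, `promoter_like`.
#' @export
sim_state_vocab <- function() {
  data.frame(
    state = c("ActiveTSS", "BivalentTSS", "Enhancer", "Transcribed",
              "RepressedPolycomb", "Heterochromatin", "Quiescent"),
    prior = c(0.12, 0.05, 0.12, 0.18, 0.08, 0.15, 0.30),
    weight = c(1.00, 0.90, 0.50, 0.15, 0.20, 0.05, 0.05),
    promoter_like = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

#' Simulation configuration
#'
#' Returns the default simulation parameters, overridable by name. The
#' defaults encode the study conditions the analysis targets: a potent
#' editor (`on_target_delta = 0.5` on the beta scale), off-target
#' deposition hitting roughly 10% of susceptible regions with magnitude
#' decreasing in baseline methylation (`off_target_magnitude`, default
#' `0.3 * (1 - beta0)`), strong footprint protection (0.8 multiplicative
#' attenuation), per-deposit persistence of 1 / 0.5 / 0.1 at days 3 / 7 /
#' 30, replicate beta noise of 0.03, four replicates, and
#' negative-binomial expression where 20% of deposited promoter-like
#' regions repress their gene at `coupling_slope` log2FC per unit
#' delta-beta, alongside 50 methylation-independent expression changes
#' specific to the non-targeting control.
#'
#' @param ... named overrides of any default field.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_regions = 2000L,
    cpgs_per_region = c(3L, 10L),
    target_cpgs = 10L,
    footprint_cpgs = 3L,
    state_vocab = sim_state_vocab(),
    baseline = list(promoter_low = c(1.5, 25), promoter_low_weight = 0.9,
                    other_high = c(20, 3.5), other_high_weight = 0.85,
                    mid = c(2, 8), cpg_logit_sd = 0.15),
    on_target_delta = 0.5,
    off_target_rate = 0.1,
    off_target_magnitude = function(beta0) 0.3 * (1 - beta0),
    deposit_jitter_sd = 0.02,
    footprint_protection = 0.8,
    persistence = c("3" = 1.0, "7" = 0.5, "30" = 0.1),
    timepoints = c(3L, 7L, 30L),
    noise_sd = 0.03,
    n_replicates = 4L,
    construct = "CRISPRoff",
    control_construct = "d3A",
    n_predicted_offtargets = 60L,
    expression = list(mean_log = log(150), sd_log = 1, dispersion = 0.15,
                      coupling_fraction = 0.2, coupling_slope = -5,
                      depth_sd = 0.15),
    grna_independent_degs = list(n = 50L, log2fc = 1.5),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop_("unknown sim_config field(s): %s", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$on_target_delta < 0 || cfg$on_target_delta > 1)
    stop_("on_target_delta must be in [0, 1]")
  if (cfg$off_target_rate < 0 || cfg$off_target_rate > 1)
    stop_("off_target_rate must be in [0, 1]")
  if (any(cfg$persistence < 0 | cfg$persistence > 1))
    stop_("persistence probabilities must be in [0, 1]")
  if (cfg$noise_sd < 0) stop_("noise_sd must be >= 0")
  if (cfg$footprint_protection < 0 || cfg$footprint_protection > 1)
    stop_("footprint_protection must be in [0, 1]")
  structure(cfg, class = c("SimConfig", "list"))
}

draw_baseline <- function(states, vocab, pars) {
  promo <- vocab$promoter_like[match(states, vocab$state)]
  n <- length(states)
  u <- runif(n)
  b <- numeric(n)
  low <- rbeta(n, pars$promoter_low[1], pars$promoter_low[2])
  high <- rbeta(n, pars$other_high[1], pars$other_high[2])
  mid <- rbeta(n, pars$mid[1], pars$mid[2])
  b[promo] <- ifelse(u[promo] < pars$promoter_low_weight, low[promo], mid[promo])
  b[!promo] <- ifelse(u[!promo] < pars$other_high_weight, high[!promo], mid[!promo])
  b
}

# Replicate noise on the logit scale, rescaled by the delta method so the
# realized beta-scale standard deviation matches noise_sd away from the
# boundaries; betas stay strictly inside (0, 1).
add_beta_noise <- function(mu, noise_sd) {
  if (noise_sd == 0) return(mu)
  mu_c <- clamp01(mu, 1e-3)
  sd_logit <- noise_sd / pmax(mu_c * (1 - mu_c), 0.05)
  plogis(qlogis(mu_c) + rnorm(length(mu)) * sd_logit)
}

#' Simulate a full methylome + transcriptome dataset with ground truth
#'
#' Deterministic given `cfg$seed` (the caller's RNG state is untouched).
#' Region 1 is the on-target locus: its non-footprint CpGs gain exactly
#' `on_target_delta` (before clipping at 1) in targeting-guide samples at
#' every timepoint, while CpGs under the gRNA footprint are attenuated by
#' `footprint_protection`. Every other region is depositable per guide with
#' probability `off_target_rate * state_weight`; a deposit shifts all of
#' the region's CpGs by `off_target_magnitude(baseline)` plus per-CpG
#' jitter, and survives to a later timepoint `t` with probability
#' `persistence[t]` (one latent uniform per deposit, so survival is
#' monotone in time). Counts are negative binomial; genes of coupled
#' deposited promoter-like regions shift their log2 mean by
#' `coupling_slope * mean(delta)` while the deposit persists; the
#' non-targeting control additionally perturbs `grna_independent_degs$n`
#' random genes independently of methylation.
#'
#' @param cfg `SimConfig` from [sim_config()].
#' @return list with elements `beta` (named list of `BetaMatrix`, one per
#'   timepoint, keys `"day3"` etc.), `counts` (named list of
#'   `CountMatrix`), `regions` (list of region annotation data.frames:
#'   `chromatin_state`, `target_locus`, `offtarget_locus`,
#'   `grna_footprint`, `gene`, `promoter`), `truth` (list: `regions`
#'   table, `cpgs` table of exact per-CpG deltas per guide,
#'   `ntc_independent_degs`), and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$n_regions < 1) stop_("degenerate config: n_regions must be >= 1")
  with_seed(cfg$seed, {
    vocab <- cfg$state_vocab
    R <- cfg$n_regions
    state <- sample(vocab$state, R, replace = TRUE, prob = vocab$prior)
    state[1] <- "ActiveTSS"  # the targeted promoter
    n_cpgs <- sample(seq(cfg$cpgs_per_region[1], cfg$cpgs_per_region[2]),
                     R, replace = TRUE)
    n_cpgs[1] <- cfg$target_cpgs

    # layout: regions in order along 5 chromosomes, CpG gaps 30-300 bp,
    # inter-region gaps of 5 kb so no DMR can bridge two regions
    n_chrom <- min(5L, R)
    chrom_of <- paste0("chr", rep(seq_len(n_chrom), length.out = R))
    chrom_of <- chrom_of[order(chrom_of)]
    pos_list <- vector("list", R)
    cursor <- setNames(rep(1000L, n_chrom), paste0("chr", seq_len(n_chrom)))
    for (i in seq_len(R)) {
      ch <- chrom_of[i]
      gaps <- if (n_cpgs[i] > 1) sample(30:300, n_cpgs[i] - 1, replace = TRUE) else integer(0)
      pos_list[[i]] <- cursor[ch] + c(0L, cumsum(gaps))
      cursor[ch] <- pos_list[[i]][n_cpgs[i]] + 5000L
    }
    region_start <- vapply(pos_list, function(p) p[1] - 100L, 0L)
    region_end <- vapply(pos_list, function(p) p[length(p)] + 100L, 0L)

    baseline_region <- draw_baseline(state, vocab, cfg$baseline)
    cpg_baseline <- unlist(lapply(seq_len(R), function(i) {
      clamp01(plogis(qlogis(clamp01(baseline_region[i], 1e-3)) +
                     rnorm(n_cpgs[i]) * cfg$baseline$cpg_logit_sd))
    }))
    region_id <- rep(seq_len(R), n_cpgs)
    cpg_chrom <- rep(chrom_of, n_cpgs)
    cpg_pos <- unlist(pos_list)

    # footprint: central CpGs of the target region
    fp_n <- min(cfg$footprint_cpgs, n_cpgs[1])
    fp_from <- (n_cpgs[1] - fp_n) %/% 2 + 1
    fp_idx_local <- seq(fp_from, fp_from + fp_n - 1)
    footprint_cpg <- region_id == 1L & ave(seq_along(region_id), region_id,
                                           FUN = seq_along) %in% fp_idx_local

    weight <- vocab$weight[match(state, vocab$state)]
    magnitude <- cfg$off_target_magnitude(baseline_region)

    guides <- c("targeting", "NTC")
    deposited <- matrix(FALSE, R, 2, dimnames = list(NULL, guides))
    surv_u <- matrix(runif(R * 2), R, 2, dimnames = list(NULL, guides))
    for (g in guides) {
      deposited[, g] <- rbinom(R, 1, cfg$off_target_rate * weight) == 1
    }
    deposited[1, ] <- FALSE  # the target locus is handled explicitly

    # exact per-CpG day-3 deltas per guide
    delta <- matrix(0, length(cpg_pos), 2, dimnames = list(NULL, guides))
    for (g in guides) {
      for (i in which(deposited[, g])) {
        ix <- which(region_id == i)
        delta[ix, g] <- pmax(0, magnitude[i] + rnorm(length(ix)) * cfg$deposit_jitter_sd)
      }
    }
    on_idx <- which(region_id == 1L)
    delta[on_idx, "targeting"] <- cfg$on_target_delta *
      ifelse(footprint_cpg[on_idx], 1 - cfg$footprint_protection, 1)

    pers <- cfg$persistence
    present_at <- function(guide, tp) {
      # TRUE per region: deposit present at timepoint tp
      p <- pers[as.character(tp)]
      if (is.na(p)) stop_("no persistence probability declared for timepoint %s", tp)
      keep <- deposited[, guide] & surv_u[, guide] <= p
      keep[1] <- guide == "targeting"  # on-target editing persists
      keep
    }

    # sample sheets and beta matrices per timepoint
    make_sheet <- function(tp) {
      grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          cond = c("targeting", "NTC", "control"),
                          stringsAsFactors = FALSE)
      data.frame(
        sample_id = sprintf("%s_%s_d%d_r%d",
                            ifelse(grid$cond == "control", cfg$control_construct, cfg$construct),
                            ifelse(grid$cond == "control", "NTC", grid$cond),
                            tp, grid$replicate),
        construct = ifelse(grid$cond == "control", cfg$control_construct, cfg$construct),
        guide = ifelse(grid$cond == "control", "NTC", grid$cond),
        timepoint_days = tp, replicate = grid$replicate,
        cond = grid$cond)
    }

    sites <- data.frame(chrom = cpg_chrom, pos = cpg_pos)
    beta_list <- list(); sheet_list <- list()
    for (tp in cfg$timepoints) {
      sheet <- make_sheet(tp)
      mu_by_cond <- list(
        targeting = clamp01(cpg_baseline +
                              delta[, "targeting"] * present_at("targeting", tp)[region_id]),
        NTC = clamp01(cpg_baseline +
                        delta[, "NTC"] * present_at("NTC", tp)[region_id]),
        control = cpg_baseline)
      vals <- vapply(seq_len(nrow(sheet)), function(j) {
        add_beta_noise(mu_by_cond[[sheet$cond[j]]], cfg$noise_sd)
      }, numeric(length(cpg_pos)))
      beta_list[[paste0("day", tp)]] <-
        beta_matrix(sites, sheet[setdiff(names(sheet), "cond")], vals)
      sheet_list[[paste0("day", tp)]] <- sheet
    }

    # expression
    genes <- sprintf("gene_%04d", seq_len(R))
    ex <- cfg$expression
    base_mean <- rlnorm(R, ex$mean_log, ex$sd_log)
    promo <- vocab$promoter_like[match(state, vocab$state)]
    coupled <- matrix(FALSE, R, 2, dimnames = list(NULL, guides))
    for (g in guides) {
      cand <- deposited[, g] & promo
      coupled[cand, g] <- rbinom(sum(cand), 1, ex$coupling_fraction) == 1
    }
    coupled[1, "targeting"] <- TRUE  # the targeted gene is repressed
    mean_delta_g <- sapply(guides, function(g)
      vapply(seq_len(R), function(i) mean(delta[region_id == i, g]), 0))
    lfc_true <- ifelse(coupled, ex$coupling_slope * mean_delta_g, 0)

    ntc_ind <- sample(seq_len(R), min(cfg$grna_independent_degs$n, R))
    ntc_ind_lfc <- cfg$grna_independent_degs$log2fc *
      sample(c(-1, 1), length(ntc_ind), replace = TRUE)

    counts_list <- list()
    for (tp in cfg$timepoints) {
      sheet <- sheet_list[[paste0("day", tp)]]
      depth <- rlnorm(nrow(sheet), 0, ex$depth_sd)
      cmat <- matrix(0, R, nrow(sheet))
      for (j in seq_len(nrow(sheet))) {
        lfc <- rep(0, R)
        if (sheet$cond[j] == "targeting") {
          on <- present_at("targeting", tp)
          lfc <- lfc_true[, "targeting"] * on
        } else if (sheet$cond[j] == "NTC") {
          on <- present_at("NTC", tp)
          lfc <- lfc_true[, "NTC"] * on
          lfc[ntc_ind] <- lfc[ntc_ind] + ntc_ind_lfc
        }
        mu <- base_mean * 2^lfc * depth[j]
        cmat[, j] <- rnbinom(R, mu = mu, size = 1 / ex$dispersion)
      }
      counts_list[[paste0("day", tp)]] <-
        count_matrix(genes, sheet[setdiff(names(sheet), "cond")], cmat)
    }

    # region annotations; chromatin states tile each chromosome
    state_rows <- do.call(rbind, lapply(split(seq_len(R), chrom_of), function(ix) {
      o <- ix[order(region_start[ix])]
      brk <- c(0L, as.integer((region_end[o][-length(o)] + region_start[o][-1]) %/% 2),
               region_end[o][length(o)] + 5000L)
      data.frame(chrom = chrom_of[o], start = brk[-length(brk)],
                 end = brk[-1], label = state[o])
    }))
    regions <- list(
      chromatin_state = region_annotation(state_rows$chrom, state_rows$start,
                                          state_rows$end, state_rows$label,
                                          "chromatin_state"),
      target_locus = region_annotation(chrom_of[1], region_start[1],
                                       region_end[1], "target", "target_locus"),
      grna_footprint = region_annotation(
        chrom_of[1], pos_list[[1]][fp_idx_local[1]],
        pos_list[[1]][fp_idx_local[fp_n]] + 1L, "g_footprint", "grna_footprint"),
      gene = region_annotation(chrom_of, region_start, region_end + 1000L,
                               genes, "gene"),
      promoter = region_annotation(chrom_of, region_start, region_end,
                                   genes, "promoter"))
    pred_ix <- sort(sample(setdiff(seq_len(R), 1L),
                           min(cfg$n_predicted_offtargets, R - 1L)))
    regions$offtarget_locus <- region_annotation(
      chrom_of[pred_ix], region_start[pred_ix], region_end[pred_ix],
      genes[pred_ix], "offtarget_locus")

    truth_regions <- data.frame(
      region_id = seq_len(R), chrom = chrom_of, start = region_start,
      end = region_end, state = state, n_cpgs = n_cpgs,
      baseline = baseline_region, gene = genes,
      is_target = seq_len(R) == 1L,
      deposited_targeting = deposited[, "targeting"],
      deposited_ntc = deposited[, "NTC"],
      magnitude = magnitude,
      surv_u_targeting = surv_u[, "targeting"],
      surv_u_ntc = surv_u[, "NTC"],
      coupled_targeting = coupled[, "targeting"],
      coupled_ntc = coupled[, "NTC"],
      lfc_targeting = lfc_true[, "targeting"],
      lfc_ntc = lfc_true[, "NTC"])
    for (tp in cfg$timepoints) {
      truth_regions[[paste0("present_targeting_day", tp)]] <- present_at("targeting", tp)
      truth_regions[[paste0("present_ntc_day", tp)]] <- present_at("NTC", tp)
    }
    truth_cpgs <- data.frame(region_id = region_id, chrom = cpg_chrom,
                             pos = cpg_pos, baseline = cpg_baseline,
                             delta_targeting = delta[, "targeting"],
                             delta_ntc = delta[, "NTC"],
                             footprint = footprint_cpg)

    list(beta = beta_list, counts = counts_list, regions = regions,
         truth = list(regions = truth_regions, cpgs = truth_cpgs,
                      ntc_independent_degs = data.frame(
                        gene = genes[ntc_ind], log2fc = ntc_ind_lfc)),
         config = cfg)
  })
}

#' Expected DMR intervals from simulation ground truth
#'
#' From the exact (noiseless) per-CpG truth deltas, returns the intervals a
#' caller with the given thresholds should recover for one guide and
#' timepoint: maximal runs of at least `min_cpgs` consecutive CpGs with
#' same-sign `|delta| > min_abs_delta` and successive gaps `< max_gap`,
#' scanned independently of [call_dmrs()].
#'
#' @param truth the `truth` element of [simulate_dataset()] output.
#' @param guide `"targeting"` or `"NTC"`.
#' @param timepoint_days a timepoint present in the simulated design.
#' @param min_cpgs,min_abs_delta,max_gap caller thresholds (defaults 2,
#'   0.1, 2000).
#' @return data.frame of expected intervals: `region_id`, `chrom`, `start`,
#'   `end`, `n_cpgs`, `direction`.
#' @export
truth_expected_dmrs <- function(truth, guide = c("targeting", "NTC"),
                                timepoint_days = 3, min_cpgs = 2L,
                                min_abs_delta = 0.1, max_gap = 2000L) {
  guide <- match.arg(guide)
  gcol <- if (guide == "targeting") "delta_targeting" else "delta_ntc"
  pcol <- sprintf("present_%s_day%d",
                  if (guide == "targeting") "targeting" else "ntc",
                  timepoint_days)
  if (!pcol %in% names(truth$regions))
    stop_("timepoint %d not in the simulated design", timepoint_days)
  present <- truth$regions[[pcol]]
  cpgs <- truth$cpgs
  d <- cpgs[[gcol]] * present[cpgs$region_id]
  rows <- list()
  for (i in unique(cpgs$region_id)) {
    ix <- which(cpgs$region_id == i)
    ix <- ix[order(cpgs$pos[ix])]
    di <- d[ix]
    s <- ifelse(abs(di) > min_abs_delta, sign(di), 0)
    gap_ok <- c(TRUE, diff(cpgs$pos[ix]) < max_gap)
    run <- cumsum(!gap_ok | c(TRUE, s[-1] != s[-length(s)]))
    for (r in unique(run[s != 0])) {
      m <- which(run == r & s != 0)
      if (length(m) >= min_cpgs) {
        rows[[length(rows) + 1]] <- data.frame(
          region_id = i, chrom = cpgs$chrom[ix[1]],
          start = cpgs$pos[ix[m[1]]],
          end = cpgs$pos[ix[m[length(m)]]] + 1L,
          n_cpgs = length(m),
          direction = if (s[m[1]] > 0) "hyper" else "hypo")
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(region_id = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cpgs = integer(), direction = character()))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Simulate CpG-centered sequence windows
#'
#' Random `2k + 1`-mers with a fixed CpG dinucleotide at the center
#' (cytosine at position `k + 1`), flanks drawn with the given GC
#' probability, and an optional chance of embedding a motif whose internal
#' CpG aligns with the center (default `GCGC`, the context preferred by
#' DNMT3A-family editors).
#'
#' @param n number of windows.
#' @param k flank size (default 5).
#' @param gc GC probability of flanking bases (default 0.5).
#' @param motif_rate probability a window carries the centered motif
#'   (default 0).
#' @param motif motif string containing `CG` (default `"GCGC"`).
#' @param seed integer seed.
#' @return character vector of windows.
#' @export
simulate_cpg_windows <- function(n, k = 5L, gc = 0.5, motif_rate = 0,
                                 motif = "GCGC", seed = 1L) {
  off <- regexpr("CG", motif, fixed = TRUE)
  if (off < 0) stop_("motif must contain a CG dinucleotide")
  with_seed(seed, {
    width <- 2L * k + 1L
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    vapply(seq_len(n), function(i) {
      w <- sample(names(probs), width + 1L, replace = TRUE, prob = probs)
      w[k + 1L] <- "C"; w[k + 2L] <- "G"
      if (runif(1) < motif_rate) {
        at <- k + 2L - off  # align the motif's CG with the center
        w[seq(at, at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
      }
      paste(w[seq_len(width)], collapse = "")
    }, "")
  })
}
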