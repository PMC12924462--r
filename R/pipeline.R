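# End-to-end pipeline: simulate (or load) -> DMR calling per contrast and
# timepoint -> stability -> expression screen -> integration, with a
# reproducibility manifest.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one dataset and writes TSV/BED outputs plus a
#' JSON run manifest (configuration snapshot, seed, package version,
#' per-stage row counts, and md5 digests of every output file) to
#' `out_dir`. Deterministic stages rerun with an identical manifest
#' reproduce byte-identical outputs.
#'
#' Input is either a simulation (`config` carries a `SimConfig` under
#' `$sim`, the default) or files on disk (`config` carries paths `beta`,
#' `sheet`, `counts` plus optional BEDs); a key-value config file path (see
#' [read_config()]) is also accepted. Thresholds come from
#' [default_thresholds()], overridable via `config$thresholds`.
#'
#' Stages, per timepoint: delta-beta and DMRs for targeting-vs-control and
#' NTC-vs-control plus targeting-vs-NTC, with direction summaries; DMR
#' persistence across timepoints and the pairwise sharedness matrix; DEG
#' screening on TMM-normalized CPM; DMR-DEG intersection, chromatin-state
#' enrichment of the day-3 targeting DMRs, and predicted off-target overlap
#' fractions. Any stage failure aborts with the stage name.
#'
#' @param config list (or path to a key-value file). Recognized keys:
#'   `sim` (a `SimConfig`; default `sim_config()`), `thresholds` (named
#'   list of overrides), or file paths `beta`/`sheet`/`counts` for
#'   file-based input.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with all in-memory stage results and
#'   `manifest`.
#' @export
run_all <- function(config = list(), out_dir = tempfile("epieditr_run_")) {
  if (is.character(config)) config <- read_config(config, defaults = list())
  thr <- modifyList(default_thresholds(), config$thresholds %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$beta)) {
      for (key in c("beta", "sheet", "counts")) {
        if (is.null(config[[key]]))
          stop_("config is missing required key '%s'", key)
        if (!file.exists(config[[key]]))
          stop_("config key '%s' names a missing file: %s", key, config[[key]])
      }
      sheet <- read_sample_sheet(config$sheet)
      tps <- sort(unique(sheet$timepoint_days))
      beta_all <- read_beta_matrix(config$beta, sheet)
      counts_all <- read_count_matrix(config$counts, sheet)
      subset_tp <- function(obj, tp, what) {
        ids <- samples_where(obj, timepoint_days = tp)
        sel <- match(ids, obj$samples$sample_id)
        if (what == "beta")
          beta_matrix(obj$sites, obj$samples[sel, ], obj$values[, sel, drop = FALSE])
        else count_matrix(obj$genes, obj$samples[sel, ], obj$counts[, sel, drop = FALSE])
      }
      sim <- list(
        beta = setNames(lapply(tps, subset_tp, obj = beta_all, what = "beta"),
                        paste0("day", tps)),
        counts = setNames(lapply(tps, subset_tp, obj = counts_all, what = "counts"),
                          paste0("day", tps)),
        regions = list(
          chromatin_state = if (!is.null(config$states)) read_regions_bed(config$states, "chromatin_state"),
          gene = if (!is.null(config$genes)) read_regions_bed(config$genes, "gene"),
          offtarget_locus = if (!is.null(config$offtargets)) read_regions_bed(config$offtargets, "offtarget_locus")),
        truth = NULL, config = NULL)
      target_construct <- config$construct %||% unique(sheet$construct[sheet$guide == "targeting"])[1]
      control_construct <- config$control_construct %||% "d3A"
    } else {
      simcfg <- config$sim %||% sim_config()
      stage <- "simulate"
      sim <- simulate_dataset(simcfg)
      target_construct <- simcfg$construct
      control_construct <- simcfg$control_construct
      tps <- simcfg$timepoints
    }

    stage <- "call-dmrs"
    contrasts <- list(
      targeting_vs_control = function(b) list(
        t = samples_where(b, construct = target_construct, guide = "targeting"),
        c = samples_where(b, construct = control_construct)),
      ntc_vs_control = function(b) list(
        t = samples_where(b, construct = target_construct, guide = "NTC"),
        c = samples_where(b, construct = control_construct)),
      targeting_vs_ntc = function(b) list(
        t = samples_where(b, construct = target_construct, guide = "targeting"),
        c = samples_where(b, construct = target_construct, guide = "NTC")))
    deltas <- list(); dmrs <- list(); summaries <- list()
    for (tp in names(sim$beta)) {
      b <- sim$beta[[tp]]
      for (cn in names(contrasts)) {
        sel <- contrasts[[cn]](b)
        if (length(sel$t) == 0 || length(sel$c) == 0) next
        key <- paste(cn, tp, sep = ".")
        deltas[[key]] <- compute_delta(b, sel$t, sel$c)
        dmrs[[key]] <- call_dmrs(deltas[[key]], min_cpgs = thr$min_cpgs,
                                 min_abs_delta = thr$delta_beta,
                                 max_gap = thr$max_gap)
        summaries[[key]] <- cbind(contrast = cn, timepoint = tp,
                                  summarize_dmrs(dmrs[[key]]))
        write_regions_bed(dmrs[[key]], file.path(out_dir, paste0("dmrs_", key, ".bed")))
      }
    }
    write_tsv(do.call(rbind, summaries), file.path(out_dir, "dmr_summary.tsv"))

    stage <- "stability"
    stability <- list()
    for (cn in names(contrasts)) {
      keys <- paste(cn, names(sim$beta), sep = ".")
      keys <- keys[keys %in% names(dmrs)]
      if (length(keys) >= 2) {
        sets <- setNames(dmrs[keys], sub(paste0(cn, "."), "", keys, fixed = TRUE))
        stability[[cn]] <- pairwise_sharedness(sets)
        write_tsv(cbind(set = rownames(stability[[cn]]),
                        as.data.frame(stability[[cn]])),
                  file.path(out_dir, paste0("sharedness_", cn, ".tsv")))
      }
    }

    stage <- "degs"
    norms <- list(); degs <- list()
    for (tp in names(sim$counts)) {
      cm <- filter_low_expressed(sim$counts[[tp]], thr$count_min, thr$count_frac)
      norms[[tp]] <- tmm_normalize(cm)
      for (cn in c("targeting_vs_control", "ntc_vs_control")) {
        sel <- contrasts[[cn]](norms[[tp]])
        if (length(sel$t) == 0 || length(sel$c) == 0) next
        key <- paste(cn, tp, sep = ".")
        degs[[key]] <- call_degs(norms[[tp]], sel$t, sel$c,
                                 logfc_thresh = thr$logfc,
                                 pseudocount = thr$pseudocount)
        write_tsv(degs[[key]], file.path(out_dir, paste0("degs_", key, ".tsv")))
      }
    }

    stage <- "integrate"
    integ <- list()
    first_tp <- names(sim$beta)[1]
    key1 <- paste("targeting_vs_control", first_tp, sep = ".")
    if (!is.null(sim$regions$gene) && key1 %in% names(dmrs) && key1 %in% names(degs)) {
      integ$dmr_deg <- intersect_dmr_deg(dmrs[[key1]], degs[[key1]],
                                         sim$regions$gene,
                                         thr$promoter_upstream,
                                         thr$promoter_downstream)
      write_tsv(integ$dmr_deg, file.path(out_dir, "dmr_degs.tsv"))
    }
    if (!is.null(sim$regions$chromatin_state) && key1 %in% names(dmrs)) {
      bg <- sim$regions$gene %||% sim$regions$chromatin_state
      integ$state_enrichment <- chromhmm_enrichment(dmrs[[key1]],
                                                    sim$regions$chromatin_state, bg)
      write_tsv(integ$state_enrichment, file.path(out_dir, "state_enrichment.tsv"))
    }
    if (!is.null(sim$regions$offtarget_locus) && key1 %in% names(deltas) &&
        key1 %in% names(degs)) {
      ot <- predicted_offtarget_overlap(sim$regions$offtarget_locus,
                                        deltas[[key1]], degs[[key1]])
      integ$offtarget_overlap <- ot
      write_tsv(as.data.frame(ot[c("n_predicted", "n_meth", "n_expr",
                                   "frac_meth_pct", "frac_expr_pct")]),
                file.path(out_dir, "predicted_offtarget_overlap.tsv"))
    }

    stage <- "manifest"
    outputs <- list.files(out_dir, full.names = TRUE)
    outputs <- outputs[basename(outputs) != "manifest.json"]
    manifest <- list(
      tool = "epieditr",
      version = as.character(packageVersion("epieditr")),
      seed = if (!is.null(sim$config)) sim$config$seed else config$seed %||% NA,
      thresholds = thr,
      stages = list(
        dmr_sets = lapply(dmrs, nrow),
        deg_tables = lapply(degs, nrow)),
      outputs = as.list(md5sum(outputs)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    list(data = sim, deltas = deltas, dmrs = dmrs, summaries = summaries,
         stability = stability, norms = norms, degs = degs,
         integration = integ, manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop_("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}
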