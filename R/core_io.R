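# Data model and readers/writers.
#
# Coordinate discipline: every interval held in memory is 0-based half-open
# (BED-compatible); a CpG site is stored as the 0-based position of the
# cytosine on the + strand, i.e. the interval [pos, pos + 1). Inputs that use
# 1-based inclusive coordinates (Bismark coverage files, array-style site
# tables) are converted on read and back-converted on write.

#' Guide vocabulary
#'
#' Allowed values of the `guide` column of a sample sheet: a locus-targeting
#' gRNA, a non-targeting control gRNA (NTC), a gRNA scaffold with no spacer,
#' or a cassette with the scaffold removed entirely.
#' @export
GUIDE_LEVELS <- c("targeting", "NTC", "scaffold", "empty")

#' Epimodifier construct vocabulary
#'
#' Default vocabulary of dCas9 fusion constructs. `d3A` (catalytically dead
#' DNMT3A) and `NT` (non-transfected) are the usual controls.
#' @export
CONSTRUCT_LEVELS <- c("CRISPRoff", "3A", "3A3L", "3A3A", "3A-KRAB", "mut3A",
                      "M.SssI", "SunTag", "d3A", "NT")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Construct a beta-value matrix object
#'
#' A `BetaMatrix` bundles a sorted table of CpG sites, per-sample metadata and
#' a sites-by-samples matrix of methylation fractions (beta values) in
#' \[0, 1\], with `NA` as the explicit missing marker. Missingness is
#' first-class: sub-coverage calls are `NA`, never 0, and all downstream
#' means are computed over non-missing values only.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based cytosine
#'   position) and optionally `strand`; must be unique by `(chrom, pos)`.
#' @param samples data.frame with columns `sample_id`, `construct`, `guide`,
#'   `timepoint_days`, `replicate`.
#' @param values numeric matrix, `nrow(sites)` x `nrow(samples)`, values in
#'   \[0, 1\] or `NA`.
#' @return An object of class `BetaMatrix`: a list with elements `sites`,
#'   `samples`, `values`.
#' @export
beta_matrix <- function(sites, samples, values) {
  sites <- validate_sites(sites)
  samples <- validate_sample_sheet(samples)
  values <- as.matrix(values)
  if (nrow(values) != nrow(sites))
    stop_("values has %d rows but there are %d sites", nrow(values), nrow(sites))
  if (ncol(values) != nrow(samples))
    stop_("values has %d columns but there are %d samples", ncol(values), nrow(samples))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_("beta value %g outside [0, 1] at %s:%d, sample '%s'",
          values[i, j], sites$chrom[i], sites$pos[i], samples$sample_id[j])
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]
  rownames(sites) <- NULL
  dimnames(values) <- list(paste0(sites$chrom, ":", sites$pos), samples$sample_id)
  structure(list(sites = sites, samples = samples, values = values),
            class = "BetaMatrix")
}

validate_sites <- function(sites) {
  sites <- as.data.frame(sites)
  for (col in c("chrom", "pos"))
    if (!col %in% names(sites)) stop_("sites is missing column '%s'", col)
  if (!"strand" %in% names(sites)) sites$strand <- "*"
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(is.na(sites$chrom) | !nzchar(sites$chrom))) stop_("empty chromosome name in sites")
  if (any(is.na(sites$pos) | sites$pos < 0)) stop_("negative or missing CpG position")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_("duplicate CpG site at %s", sub(" ", ":", d))
  }
  sites[c("chrom", "pos", "strand")]
}

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "construct", "guide", "timepoint_days", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) stop_("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$construct <- as.character(samples$construct)
  samples$guide <- as.character(samples$guide)
  samples$timepoint_days <- as.integer(samples$timepoint_days)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    stop_("duplicate sample_id '%s'", samples$sample_id[duplicated(samples$sample_id)][1])
  bad_guide <- setdiff(unique(samples$guide), GUIDE_LEVELS)
  if (length(bad_guide) > 0)
    stop_("unknown guide value(s): %s (allowed: %s)",
          paste(bad_guide, collapse = ", "), paste(GUIDE_LEVELS, collapse = ", "))
  if (any(is.na(samples$timepoint_days) | samples$timepoint_days <= 0))
    stop_("timepoint_days must be a positive integer")
  key <- paste(samples$construct, samples$guide, samples$timepoint_days, samples$replicate)
  if (anyDuplicated(key))
    stop_("duplicate (construct, guide, timepoint_days, replicate) combination: %s",
          key[duplicated(key)][1])
  rownames(samples) <- NULL
  samples[need]
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpG sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$sites$chrom), collapse = ", ")))
  cat(sprintf("  missing beta: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `construct`, `guide`, `timepoint_days`,
#' `replicate`. `guide` must be one of [GUIDE_LEVELS].
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a beta-value matrix from TSV
#'
#' The TSV must have columns `chrom`, `pos` (1-based cytosine position, as in
#' array-style site tables; converted to the 0-based internal convention),
#' then one column per `sample_id` in the sample sheet. Columns not declared
#' in the sheet are rejected. Missing values may be written as `NA` or left
#' empty.
#'
#' @param path beta matrix TSV.
#' @param sample_sheet path to the sample sheet TSV, or a data.frame.
#' @return [beta_matrix()] object.
#' @export
read_beta_matrix <- function(path, sample_sheet) {
  sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
           else validate_sample_sheet(sample_sheet)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  for (col in c("chrom", "pos"))
    if (!col %in% names(tab)) stop_("'%s': missing column '%s'", path, col)
  value_cols <- setdiff(names(tab), c("chrom", "pos"))
  unknown <- setdiff(value_cols, sheet$sample_id)
  if (length(unknown) > 0)
    stop_("'%s': sample column(s) not in sample sheet: %s", path,
          paste(unknown, collapse = ", "))
  sheet <- sheet[match(value_cols, sheet$sample_id), , drop = FALSE]
  sites <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos) - 1L)
  vals <- as.matrix(tab[value_cols])
  storage.mode(vals) <- "double"
  beta_matrix(sites, sheet, vals)
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]: positions are written back as 1-based.
#'
#' @param x `BetaMatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "BetaMatrix"))
  out <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos + 1L,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(x$values, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style cytosine coverage file
#'
#' Dialect: `chrom  start  end  percent_methylation  count_methylated
#' count_unmethylated`, 1-based inclusive coordinates. The beta value is
#' recomputed from the counts -- the percent column is parsed but not trusted.
#' A site with zero total coverage is retained with `beta = NA` (0/0 is
#' undefined, not zero).
#'
#' @param path coverage file (tab-separated).
#' @return data.frame of coverage records with columns `chrom`, `pos`
#'   (0-based), `count_methylated`, `count_unmethylated`, `beta`.
#' @export
read_bismark_coverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      count_methylated = integer(), count_unmethylated = integer(),
                      beta = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6))
    stop_("'%s': malformed coverage line %d (%d columns, expected 6)",
          path, which(nf != 6)[1], nf[nf != 6][1])
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  cm <- suppressWarnings(as.integer(m[, 5]))
  cu <- suppressWarnings(as.integer(m[, 6]))
  if (any(is.na(cm) | is.na(cu)))
    stop_("'%s': non-integer count on line %d", path, which(is.na(cm) | is.na(cu))[1])
  if (any(cm < 0 | cu < 0))
    stop_("'%s': negative count on line %d", path, which(cm < 0 | cu < 0)[1])
  total <- cm + cu
  data.frame(chrom = m[, 1],
             pos = as.integer(m[, 2]) - 1L,
             count_methylated = cm,
             count_unmethylated = cu,
             beta = ifelse(total > 0, cm / total, NA_real_))
}

#' Construct a region annotation table
#'
#' Labeled genomic intervals, 0-based half-open. `category` declares what the
#' intervals are: a chromatin-state segmentation, the targeted locus/loci of
#' a panel, predicted off-target loci, the gRNA binding footprint, gene
#' bodies, or promoters.
#'
#' @param chrom,start,end interval coordinates (`start < end`).
#' @param label free-text label (state name, locus name, gene id).
#' @param category one of `chromatin_state`, `target_locus`,
#'   `offtarget_locus`, `grna_footprint`, `gene`, `promoter`.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `category`.
#' @export
region_annotation <- function(chrom, start, end, label,
                              category = c("chromatin_state", "target_locus",
                                           "offtarget_locus", "grna_footprint",
                                           "gene", "promoter")) {
  category <- match.arg(category)
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), label = as.character(label),
                  category = rep(category, length.out = length(chrom)))
  if (any(x$start >= x$end)) stop_("region with start >= end (half-open intervals require start < end)")
  if (any(x$start < 0)) stop_("negative region start")
  x
}

#' Write regions or DMRs to BED
#'
#' Standard BED (0-based half-open). For region annotations the name column
#' is the label and the score 0; for DMRs (output of [call_dmrs()]) the name
#' is the direction (`hyper`/`hypo`) and the score the mean delta-beta scaled
#' by 1000 and rounded. Output is sorted by `(chrom, start, end)`; an empty
#' input produces a file holding only the header comment.
#'
#' @param x region annotation data.frame or DMR data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(x, path) {
  is_dmr <- "direction" %in% names(x)
  if (nrow(x) == 0) {
    writeLines("#chrom\tstart\tend\tname\tscore", path)
    return(invisible(path))
  }
  name <- if (is_dmr) x$direction else x$label
  score <- if (is_dmr) as.integer(round(1000 * x$mean_delta)) else 0L
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = name, score = score)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of labeled regions
#'
#' Counterpart of [write_regions_bed()] for region annotations: `#` comment
#' lines are skipped, columns beyond the fifth ignored.
#'
#' @param path BED path.
#' @param category category to stamp on the regions (see
#'   [region_annotation()]).
#' @return region annotation data.frame (with a `score` column).
#' @export
read_regions_bed <- function(path, category = "chromatin_state") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- region_annotation(character(), integer(), integer(), character(),
                             category)
    out$score <- integer()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop_("'%s': BED line %d has fewer than 3 columns", path, which(nf < 3)[1])
  get <- function(i, default) vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  out <- region_annotation(chrom = get(1, ""),
                           start = as.integer(get(2, NA)),
                           end = as.integer(get(3, NA)),
                           label = get(4, "."),
                           category = category)
  out$score <- suppressWarnings(as.integer(get(5, "0")))
  out
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column `gene`, one column per `sample_id`. Counts must be
#' non-negative integers.
#'
#' @param path counts TSV.
#' @param sample_sheet sample sheet path or data.frame.
#' @return [count_matrix()] object.
#' @export
read_count_matrix <- function(path, sample_sheet) {
  sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
           else validate_sample_sheet(sample_sheet)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop_("'%s': missing column 'gene'", path)
  value_cols <- setdiff(names(tab), "gene")
  unknown <- setdiff(value_cols, sheet$sample_id)
  if (length(unknown) > 0)
    stop_("'%s': sample column(s) not in sample sheet: %s", path,
          paste(unknown, collapse = ", "))
  sheet <- sheet[match(value_cols, sheet$sample_id), , drop = FALSE]
  counts <- as.matrix(tab[value_cols])
  count_matrix(tab$gene, sheet, counts)
}

#' Write a count matrix to TSV
#' @param x `CountMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  out <- cbind(data.frame(gene = x$genes),
               as.data.frame(x$counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default analysis thresholds
#'
#' One place for every threshold the pipeline uses. Defaults follow the
#' analysis conventions the package implements: DMR effect size
#' `delta_beta = 0.1` (strict `>`), maximum intra-DMR CpG gap 2000 bp
#' (strict `<`), at least 2 CpGs per DMR, coverage mask at 10x (strictly
#' less than 10 is missing), DEG screen at `|log2FC| > 1`, expression filter
#' "count >= 5 in >= 25% of samples", alpha 0.05, promoter window -1500/+500
#' around the annotated gene start.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(delta_beta = 0.1, max_gap = 2000L, min_cpgs = 2L,
       coverage_min = 10L, emseq_min_diff = 0.10,
       logfc = 1.0, count_min = 5L, count_frac = 0.25,
       alpha = 0.05, pseudocount = 0.5,
       promoter_upstream = 1500L, promoter_downstream = 500L)
}

#' Read a plain key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers become numeric, `true`/`false` become logical, everything else
#' stays character. Keys present in `defaults` but absent from the file keep
#' their default.
#'
#' @param path config file path.
#' @param defaults named list of defaults (default [default_thresholds()]).
#' @return named list.
#' @export
read_config <- function(path, defaults = default_thresholds()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop_("config line without '=': '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
                  else val
  }
  out
}

#' Select sample ids by metadata
#'
#' Convenience selector over a `BetaMatrix`, `CountMatrix`,
#' `NormalizedCounts` or plain sample sheet.
#'
#' @param x object carrying a `samples` data.frame, or the data.frame itself.
#' @param construct,guide,timepoint_days,replicate optional filters; each may
#'   be a vector of allowed values.
#' @return character vector of matching `sample_id`s.
#' @export
samples_where <- function(x, construct = NULL, guide = NULL,
                          timepoint_days = NULL, replicate = NULL) {
  s <- if (is.data.frame(x)) x else x$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(construct)) keep <- keep & s$construct %in% construct
  if (!is.null(guide)) keep <- keep & s$guide %in% guide
  if (!is.null(timepoint_days)) keep <- keep & s$timepoint_days %in% timepoint_days
  if (!is.null(replicate)) keep <- keep & s$replicate %in% replicate
  s$sample_id[keep]
}

# GRanges view of a region table or DMR table (internal).
regions_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}
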