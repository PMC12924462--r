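---
title: "Profiling on- and off-target effects of dCas9 methylation editors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling on- and off-target effects of dCas9 methylation editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

CRISPR/dCas9 epimodifiers — fusions of catalytically dead Cas9 with a DNA
methyltransferase module such as the DNMT3A catalytic domain, DNMT3A–DNMT3L,
or the CRISPRoff cassette — deposit CpG methylation at a gRNA-targeted
promoter. They also deposit methylation where they should not: genome-wide,
preferentially at lowly-to-intermediately methylated promoter-like open
chromatin, and even when loaded with a non-targeting control gRNA (NTC).
`epieditr` implements the downstream analysis of such experiments, starting
from processed matrices: per-CpG beta values (methylation fractions in
[0, 1]) with genomic coordinates, cytosine coverage counts for targeted and
enzymatic methyl-seq, and gene-level RNA-seq counts.

The pipeline answers five questions: where are the differentially
methylated regions (DMRs) relative to a control; how strong and how
specific is the on-target edit relative to the NTC; how stable are the
changes over days; which expression changes accompany them; and how do
methylome and transcriptome changes relate (gene mapping, chromatin state,
sequence context).

## The DMR rule

Differential methylation is screened purely by effect size. For each CpG,

$$\Delta\beta = \bar\beta_{\text{treatment}} - \bar\beta_{\text{control}},$$

with group means over non-missing replicates. A DMR is a maximal run of at
least `min_cpgs = 2` consecutive CpGs whose $|\Delta\beta|$ exceeds
`delta_beta = 0.1` (strict) in the same direction, with every
successive-position gap strictly below `max_gap = 2000` bp. The identical
run rule is applied to each sign separately, which is what produces the
hypomethylated DMR counts alongside the dominant hypermethylated ones in a
deposition experiment. Three deliberate readings of this rule:

* **A disqualifying CpG breaks a run.** Whether a site between two
  qualifying CpGs is missing, sub-threshold, or of opposite sign, the run
  ends there. The alternative (skipping over sub-threshold probes) would
  let a DMR span contradictory intermediate evidence; we require the
  evidence inside a region to be present and concordant. A corollary used
  by the tests: two same-direction DMRs are always separated by a
  disqualifying CpG or a $\ge$ 2 kb gap.
* **Runs are formed over the sites present in the input**, not over
  adjacent probes of a particular array design. If a site is absent from
  the track it cannot break a run. This is documented behaviour, not an
  option.
* **Strictness follows the rule's wording**: $|\Delta\beta| > 0.1$ and gap
  $< 2000$. The targeted/enzymatic sequencing filters in `target_panel`
  are deliberately *inclusive* ($\ge 10\times$ coverage, difference
  $\ge 0.10$) because the workflows they model state inclusive bounds; the
  asymmetry is intentional and tested.

Direction summaries report integer percentages with round-half-up;
because the two percentages are rounded independently their sum may be
99–101. Percentages below 1% display with one decimal (`"0.3%"`), all
others as integers (`"5%"`), matching the reporting convention for
persistence fractions.

No p-value is attached to DMRs; the rule is effect-size based by design,
and the per-CpG testing alternative is out of scope.

## Coverage masking and missingness

Targeted methyl-seq betas are masked to missing wherever total coverage is
strictly below `coverage_min = 10` reads; a site at exactly 10× is kept.
Missing is a first-class state (`NA`), never zero: all downstream means are
pairwise-complete, a site with a fully-missing group has a missing
$\Delta\beta$, and a missing $\Delta\beta$ breaks DMR runs. Bismark-style
coverage inputs are trusted only for their counts — beta is recomputed as
$M/(M+U)$ and a 0/0 site is retained as missing.

## Coordinates

Everything in memory is 0-based half-open (BED convention); a CpG is the
0-based position of its + strand cytosine. 1-based inputs (Bismark
coverage, array-style site tables) are converted at the read boundary and
back-converted on write; a property test pushes random positions through
both boundaries and recovers them. CpGs are assumed strand-merged upstream
(symmetric CpG methylation); the readers do not merge strands.

## Targeted panel quantification

`locus_profiles()` computes per-CpG group means for the targeting gRNA,
the NTC, and a reference control (typically the catalytically dead
construct), the deltas against the reference, and the net specific effect

$$\text{net} = \Delta\beta_{\text{targeting} - \text{ref}} -
               \Delta\beta_{\text{NTC} - \text{ref}}
             = \bar\beta_{\text{targeting}} - \bar\beta_{\text{NTC}},$$

so the choice of common reference cancels (asserted on random matrices).
CpGs under the gRNA binding footprint are flagged and summarized
separately: the bound dCas9–gRNA complex sterically protects them from
deposition, so their net effect is expected to be *smaller* than at
flanking CpGs — a useful internal signature of genuine on-target binding.
Coverage context is interpreted per CpG (not per amplicon), which is the
resolution the data model carries.

## Expression screening

Counts are filtered by the "at least 5 reads in at least 25% of samples"
rule (the sample threshold is `ceiling(min_frac * n)`), then scaled by the
trimmed mean of M-values (TMM) and expressed as counts per million using
effective library sizes. TMM is delegated to edgeR with the canonical trim
fractions (30% on M, 5% on A); an independently written reference
implementation in the test suite agrees to $10^{-6}$. Differential
expression is screened as $|\log_2 \text{FC}| > 1$ on group-mean CPM with
a pseudocount of 0.5 (finite ratios when a group mean is zero; the value
is configurable).

The screening rule is exposed in two modes because the underlying analysis
convention is ambiguous between a pure fold-change screen and a
fold-change-plus-adjusted-p screen, and no specific test is named for the
latter. The default `test = "off"` is the pure effect-size screen; `test =
"on"` adds a two-sided Welch t-test on $\log_2(\text{CPM} + 0.5)$ with
Benjamini–Hochberg adjustment and requires two replicates per group. We do
not claim either mode is "the" published setting; the package's own
reported quantities use the default.

## Integration

* **CpG–gene correlation.** Spearman (rank-level, the default screen) or
  Pearson (per-CpG linear profiling), pairwise-complete over samples
  matched by id. Spearman p-values use the exact permutation null for
  $n \le 9$ complete pairs — at the 4–12 samples per condition typical
  here the t-approximation is unsafe — and the t-approximation above that.
  Pairs with under 3 complete observations or zero variance are skipped
  with a reason, not silently dropped.
* **DMR–DEG intersection.** A DMR maps to a gene when it overlaps the gene
  body or a promoter window of −1500/+500 bp around the annotated gene
  start. The window is a conventional promoter definition, configurable;
  nothing in the data dictates it, and a DMR overlapping two genes'
  windows yields two candidate mappings, both reported. A DMR-DEG is a
  mapped gene that also passes the DEG screen.
* **Chromatin-state enrichment.** Each query DMR and background element is
  assigned the state at its midpoint — deterministic and tie-free, unlike
  maximal-overlap assignment (a bp-overlap alternative exists for DMR set
  comparison, where the same trade-off arises). Per state, a 2×2 table
  against the caller-supplied background gives the cross-product odds
  ratio and a two-sided Fisher exact p, reporting depletion as well as
  enrichment. The background definition (all probes, all candidate
  regions…) is the caller's choice and is echoed in the result; the
  package does not hard-code one because no canonical background exists
  for this design.
* **Predicted off-target overlap.** Of the in-silico predicted gRNA
  binding loci, the fraction containing any CpG with
  $|\Delta\beta| > 0.05$ and the fraction whose associated gene moves by
  $|\log_2\text{FC}| > 0.05$. These deliberately loose thresholds measure
  *any* response at predicted loci; small fractions argue that off-target
  deposition is not driven by gRNA sequence homology.
* **ORA.** One-sided hypergeometric upper-tail per gene set, BH across
  sets.
* **Sequence preference.** Position frequency matrix over ±5 bp windows
  centered on DMR CpGs (an 11-mer; the window is configurable) and a
  Fisher test of motif-containing windows against background CpG windows,
  default motif `GCGC` — the GC-rich context preferred by DNMT3A-family
  deposition.

## Temporal stability

A DMR persists when it shares at least one member CpG position with a
same-direction DMR at the later timepoint. CpG identity, not bp
intersection, is the default overlap unit because array-derived DMRs are
built from a fixed probe set, making CpG sharing immune to interval-edge
artifacts; `method = "bp"` provides the interval alternative. Direction
must match — a region hyper at day 3 and hypo at day 7 is not "stable".
Pairwise sharedness between conditions is row-normalized
($100 \cdot |A \cap B| / |A|$), hence asymmetric by construction.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates the statistical structure the analysis
assumes, with full ground truth, so every stage is testable without any
external data:

* **Bimodal baseline.** Region baselines are drawn from a two-component
  mixture: promoter-like states (active/bivalent TSS) mostly near
  $\beta \approx 0.05$ (Beta(1.5, 25)), other states mostly near
  $\beta \approx 0.85$ (Beta(20, 3.5)), each with a minority mid-level
  component (Beta(2, 8)); per-CpG baselines jitter around the region value
  on the logit scale (sd 0.15).
* **Region-wise deposition.** Off-target deposition is drawn per region
  with probability `off_target_rate × state_weight` (weights highest for
  promoter-like open chromatin) and magnitude
  `off_target_magnitude(β₀) = 0.3 (1 − β₀)` — a decreasing function of
  baseline, the simplest encoding of the observed bias toward
  low-methylated regions; the functional form is a modeling choice exposed
  in the config. All CpGs of a deposited region shift together with small
  per-CpG jitter (sd 0.02), because the analysis detects coherent
  multi-CpG regions and region-wise truth makes recovery well-defined.
* **On-target editing.** Region 1 is the targeted promoter: its
  unprotected CpGs gain exactly `on_target_delta = 0.5`; CpGs under the
  gRNA footprint are attenuated multiplicatively by
  `footprint_protection = 0.8`. The on-target jitter is zero so the
  all-randomness-off configuration is exactly checkable.
* **Decay.** Each off-target deposit carries one latent uniform; it
  survives to timepoint $t$ iff that uniform is below `persistence[t]`
  (defaults 1 / 0.5 / 0.1 at days 3 / 7 / 30), making survival monotone
  over time with the declared marginals. On-target editing persists
  throughout, reflecting the stability of targeted promoter methylation.
* **Replicate noise** is specified in beta units (`noise_sd = 0.03`) but
  applied on the logit scale with a delta-method rescaling
  $\sigma_{\text{logit}} = \sigma_\beta / \max(\mu(1-\mu), 0.05)$, so
  realized beta noise matches the nominal value away from the boundaries
  while betas stay strictly inside (0, 1) without hard clipping artifacts.
* **Expression.** Negative-binomial counts (log-normal base means,
  dispersion 0.15, log-normal depth factors). A fraction
  `coupling_fraction = 0.2` of deposited promoter-like regions represses
  its gene by `coupling_slope = −5` log2FC per unit mean $\Delta\beta$
  while the deposit persists; the targeted gene is always coupled. The
  NTC additionally perturbs 50 random genes by ±1.5 log2FC at all
  timepoints independently of methylation — the "pervasive
  methylation-independent" transcriptional signature of non-targeting
  guides. The coupling values are chosen so that coupled promoter deposits
  (typical $\Delta\beta \approx 0.28$) clear the $|\log_2\text{FC}| > 1$
  screen while uncoupled ones do not.

What the simulator does **not** emulate — and hence what green tests do
not establish about real data: array probe chemistry and normalization
artifacts; spatial correlation of methylation beyond the region block;
sharing of off-target deposits between guides (deposits are drawn
independently per guide, whereas real early off-target changes are largely
shared); batch and cell-cycle structure in expression; and any genome
sequence realism beyond GC/motif composition of simulated windows.

## Problem sizes and numerical choices

The test suite runs the full parameter-recovery analysis on 2,000 regions
(~13,000 CpGs, 36 samples across three timepoints, 4 replicates per
condition), the caller-versus-enumeration equivalence on 1,000 random
tracks of up to 300 CpGs, footprint protection across 20 simulation seeds
of 300 regions, and null calibrations at 1,000 resampling draws — sizes at
which binomial confidence intervals are tight enough to be informative
while the whole suite stays fast. Null calibration uses large 2×2 margins
(background of 4,000 sites, queries of 300–600) so the discreteness of
exact-test p-values is negligible next to the Kolmogorov–Smirnov
resolution at 1,000 draws; query draws are taken from the background's
generating distribution, keeping the table margins independent as the
Fisher model assumes.

Other numerical details: betas are validated to [0, 1] at construction
with the offending cell named; the EM-seq inclusive difference boundary
carries a $10^{-12}$ float guard so count-ratio differences like
$5/10 - 4/10$ count as exactly 0.10; odds ratios are reported as raw cross
products (11.0 for [[10, 90], [100, 9900]]), with `Inf` possible for empty
cells rather than a continuity correction; DMR intervals span first to
last member cytosine, half-open.

## Limitations

The DMR rule is a screen, not an inference procedure: it controls nothing,
and its counts scale with probe density and sample noise. Percent
summaries are only as comparable as the underlying probe sets.
`test = "on"` uses a gene-wise Welch test, not a dispersion-moderated
count model; for designs with few replicates a dedicated count framework
is more powerful and should be preferred when p-values matter. The
promoter window and enrichment background are conventions; conclusions
sensitive to either should be checked under alternatives. The pipeline
deliberately starts at matrices: alignment, methylation extraction and
array preprocessing are upstream concerns.

## A minimal session

```{r}
library(epieditr)

sim <- simulate_dataset(sim_config(seed = 1))
b <- sim$beta$day3
d <- compute_delta(b,
                   treatment = samples_where(b, guide = "targeting"),
                   control = samples_where(b, construct = "d3A"))
dmrs <- call_dmrs(d)
summarize_dmrs(dmrs)

norm <- tmm_normalize(filter_low_expressed(sim$counts$day3))
degs <- call_degs(norm, samples_where(norm, guide = "targeting"),
                  samples_where(norm, construct = "d3A"))
intersect_dmr_deg(dmrs, degs, sim$regions$gene)

# or the whole thing at once:
res <- run_all(list(sim = sim_config(seed = 1)), out_dir = "run1")
```
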