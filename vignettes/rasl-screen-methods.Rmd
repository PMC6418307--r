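---
title: "Methods: targeted screen analysis with raslscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted screen analysis with raslscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raslscreen)
```

# The assay and the analysis problem

RASL-seq (RNA annealing, selection and ligation sequencing) is a targeted
expression assay: gene-specific probe pairs anneal to transcripts, are
ligated, PCR-amplified with well-specific dual barcodes, pooled and
sequenced. Because only a small panel of genes is measured, hundreds of
chemicals can be screened across concentrations, sexes and replicates on
384-well plates in a single sequencing run. The analysis problem is to turn
the resulting wells x probes count matrix into per-chemical calls: does a
chemical reproduce one of a set of reference transcriptional signatures,
and at which concentrations?

`raslscreen` implements that pipeline end to end: plate design and barcode
bookkeeping, read-count QC, control-gene normalization with Tukey median
polish, and Pearson-correlation classification against reference
signatures, plus a synthetic screen generator so every stage is testable
against known ground truth.

# The processing model, stage by stage

## Quality-control filters

Spike-in (luciferase) probe counts are separated first; they never enter
normalization. Wells are retained when their total reads (including spike
reads) strictly exceed 500; probes are retained when their totals, summed
across **all** wells of the experiment before any well filtering, strictly
exceed 1,000. Strict inequalities are the documented convention; both
filters expose a `strict` switch for the >= variant. The per-well spike
read fraction is reported as a cell-health proxy: the spike input is fixed
per well, so when a toxic chemical kills cells the spike claims a larger
share of the read budget (heatmap display convention 0--0.25).

Whether the 500-read well total should include spike reads is ambiguous;
we total over all probes, matching a plain reading of "total read count
per well", and compute probe totals on the unfiltered matrix. Filters are
idempotent and conserve counts (dropped + retained = input).

## Normalization

For each well, 1 is added to every count (pseudocount), and each probe is
expressed as the log2 ratio to the geometric mean of the well's
control-gene probes (Ascl3, Psmd4, Sdha, Tbp), computed in log space. Two
exact consequences are tested: the mean over control probes of every well
is 0, and the values are invariant to per-well library size (up to the
pseudocount, negligible at screening depths).

Probes then collapse to genes by the per-well median: probe-level
variation is nuisance the median absorbs, which is also why the simulator
partitions a gene's effect equally over its probes.

The gene x well matrix is then normalized by a two-way Tukey median
polish: alternating row (gene) and column (well) median sweeps, rows
first, stopping when the largest absolute change in the residuals is
below `tol = 1e-6` or after `max_iter = 20` sweeps -- ample for exactness
at these matrix sizes (an additive matrix polishes exactly in two
sweeps). The polish runs once, jointly, on the whole screen: single-run
sequencing of the pooled library removes the main batch axis, so
per-plate polishing would discard signal rather than batch effects. The
returned values are residuals **plus the per-gene row effects** -- column
and overall effects are removed while gene-relative structure (what the
heatmaps display) is preserved; `output = "residual"` gives bare
residuals for users who want the other convention.

Biological replicates collapse to chemical-concentration-sex conditions
by the per-gene median. Finally the sex-marker genes (Xist, Ddx3y) are
separated and every remaining gene row is median-centered across
conditions. Missing data are handled by dropping (genes with no surviving
probes, conditions with no surviving wells -- both logged), never by
imputation; no imputation rule is defensible at this panel size.

## Sex inference

The score Xist - Ddx3y calls a column female when positive, male when
negative, `unknown` on an exact tie. At the generator's default marker
separation (4 log2 units per marker, 8 between sexes) ties are
practically impossible and calls recover the true sex of every unfailed
well.

## Classification

Reference cluster signatures are aggregate profiles: per cluster, the
per-gene median across member chemicals. Each condition profile is
Pearson-correlated with each signature over their shared genes (at least
3; the caller can restrict to a platform-shared subset). Zero-variance
profiles give missing values, never 0 -- otherwise vehicle wells would
spuriously match. A chemical is **classified** to a signature when any of
its concentration profiles correlates strictly above 0.65 with exactly
that one signature; chemicals exceeding the threshold for two or more
signatures are `unclassified_ambiguous` and are flagged with all
candidates plus the cell-health covariate when provided -- ambiguity is
reported as data, never auto-resolved, mirroring screening practice where
such chemicals (typically with the worst cell-health scores) are omitted
manually. Chemicals never exceeding the threshold are `unclassified_low`.

By default correlations are computed after averaging the sexes of each
chemical-concentration (the chemical-by-concentration reporting
convention); per-sex classification is available by passing the
uncollapsed matrix.

Hierarchical clustering of condition profiles uses correlation distance
(1 - Pearson r) with average linkage, chosen for consistency with the
correlation-based classifier; both are configurable. Columns are
pre-sorted by label so tied merges are deterministic. Cross-platform
concordance (e.g. against RNA-seq profiles of the same chemicals) is a
Pearson r over shared genes with a two-sided t-distribution p-value and
the paired table for scatter plots.

# The synthetic screen generator

The generator exists so the pipeline can be exercised, with known ground
truth, at the scale the assay runs: 3 biological replicates x (4 male +
4 female) 384-well plates = 9,216 uniquely barcoded wells, a 56-gene /
261-probe panel (3--7 probes per gene) plus luciferase spike probes, four
concentrations (0.01, 0.1, 1, 10 uM) and interspersed vehicle (DMSO-only)
wells. The default layout uses 352 chemical slots, which fills the 24
plates exactly after reserving vehicle wells; barcode pairs are unique by
construction (forward barcode per well position, reverse per plate).

Counts follow a competition model. Per well: library size
`L ~ LogNormal(log 20000, 0.4)`; each gene's cellular mass is a baseline
weight (log-normal across genes, drawn once per simulation) times
`2^(template effect x dose factor)`, split equally over its probes and
scaled by viability; the spike-in contributes a fixed mass calibrated to
a 5% read share at full viability. Expected probe counts are `L` times
each probe's mass share, and observed counts are negative binomial with
shared dispersion 0.05 -- the simplest overdispersed model consistent
with targeted sequencing counts. Because the spike mass is fixed while
cellular mass scales with viability, the spike read fraction rises
monotonically as viability falls, reproducing the cell-health proxy.

Effect templates are hand-authored fixtures for eight classes: six
reference clusters (e.g. the Cluster-2-like electron-transport-inhibitor
template raises Hmox1/Gsta4/Cx3cr1/Fos and lowers Rbfox3/Syt1/Nrxn1; the
Cluster-5-like topoisomerase template lowers long synaptic genes), a
JQ1-like novel template, and a null. Directions follow the published
phenomenology; magnitudes (0.5--2 log2 units) are the package's own
choice of a realistic screening effect size, fixed once. Dose models:
`flat` (full effect at every concentration, pyraclostrobin-like),
`threshold` (top concentration only, bifenthrin-like), `monotone`
(effect proportional to concentration rank). Control genes and sex
markers always carry effect 0 -- they define the normalization scale.
The two sex markers share one baseline weight so the Xist - Ddx3y score
isolates the configured effect. Sporadic failure: wells fail with
probability 0.01 (resampled multinomially to a total under 500 reads,
so they are guaranteed casualties of the well filter) and probes with
probability 0.005 (zeroed everywhere).

What the generator does **not** emulate: sequencing error and fuzzy
barcodes (demultiplexing is exact-match on a fixed-width synthetic read
dialect), PCR amplification bias, plate-edge effects, and shifts in
cell-type composition. Passing recovery tests therefore demonstrates the
pipeline's correctness and its behaviour under the stated statistical
model -- not robustness to artefacts the model excludes.

# Numerical and design choices

- Geometric means are computed as means of log2 values; no overflow and
  exact zero mean over control probes.
- Median polish: row-first sweep order (the classical ordering);
  convergence on the max absolute residual change. Median-polish
  residuals are order-dependent in general, which is why the convention
  is fixed and tested sweep-by-sweep against an independent oracle.
- Ties: sex score 0 is `unknown`; correlation exactly at the threshold is
  *not* retained (strict >); clustering tie-breaks via label-sorted
  columns.
- Degenerate inputs: an all-dropped well set is a warning state, not an
  error; a control gene losing every probe is a hard error (the scale is
  undefined); fewer than 3 shared genes makes a correlation missing.
- Determinism: every stochastic step takes an explicit seed, and the
  pipeline's artifact manifest (MD5 per file) is byte-identical across
  reruns with one seed.

# Problem sizes used in the tests

The packaged tests run the full 9,216-well x 261-probe screen for the
design, determinism and accounting checks, and smaller seeded screens
(one to six plates) for recovery experiments: template recovery uses 38
chemicals (6 per active cluster, dose-model probes, 20 nulls) in
triplicate; sex recovery uses a single-replicate screen; oracle
comparisons use 50--100 small random matrices. These sizes were chosen so
the whole suite exercises every paper-scale property while staying
comfortably reproducible on a laptop.

# Known limitations

- The six signature fixtures are qualitative stand-ins; real reference
  signatures (from RNA-seq of the same chemicals) should be supplied via
  `aggregate_signatures()` for production use.
- The classifier inherits the panel's blind spots: signatures acting
  outside the 56 genes are invisible, and novel-template chemicals are
  only detectable as `unclassified_low` plus their own cluster in the
  tree.
- No dose-response modelling: concentrations are treated as discrete
  conditions; fitting monotone/threshold dose-response curves is a
  separate problem, deliberately out of scope.
- No plate-position or batch correction beyond what the joint median
  polish absorbs.
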