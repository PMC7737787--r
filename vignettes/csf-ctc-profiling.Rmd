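---
title: "Profiling CSF circulating tumor cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CSF circulating tumor cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcprofiler)
```

## The problem

Leptomeningeal metastasis seeds tumor cells into the cerebrospinal fluid.
Because CSF is nearly acellular in health (mostly T cells and monocytes),
full-length single-cell RNA-seq of CSF cells can separate circulating tumor
cells (CSF-CTCs) from the immune background and characterize their states:
proliferation, partial epithelial-to-mesenchymal transition (EMT), cancer
stemness, cancer-testis antigen (CTA) expression, and patient-to-patient
heterogeneity. `ctcprofiler` implements that analysis as a tested pipeline
over gene x cell integer count matrices, together with a simulator that
plants all of those structures and emits ground truth, so every stage can
be validated without access to patient data.

## Data model and quality control

Counts are genes-as-rows, cells-as-columns, with HGNC symbols matched
exactly and case-sensitively; symbols in a gene set but absent from a
matrix are dropped per-analysis with a logged count. Normalization is
counts-per-10,000 followed by natural `log1p` (`scale_factor = 1e4`,
configurable) — the de-facto scRNA-seq convention; the transform is stated
here because published reports often leave it implicit.

QC applies the field's standard filters with boundary semantics taken
literally from how such filters are conventionally quoted:

* genes detected (count > 0) in *fewer than* 10 cells are removed (a gene
  seen in exactly 10 cells survives);
* cells with *fewer than* 600 detected genes **or** *more than* 20%
  mitochondrial counts are removed (a cell at exactly 600 genes and
  exactly 20% survives); mitochondrial load is the count share of `MT-`
  prefixed symbols, overridable by an explicit list;
* for tumor-cell characterization a stricter subset keeps cells with *at
  least* 1000 detected genes (inclusive).

The two cell criteria combine with OR for removal; zero-count cells are
legal at load time and die at QC (the loader validates format, QC enforces
biology). One consequence worth knowing: when a cohort's detected-gene
distribution straddles the 600-gene cut, QC survivors are enriched for
high-complexity cells — on simulated data this visibly inflates the
apparent cycling fraction, because cycling cells express an extra ~100
phase genes. That is a property of threshold QC on shallow libraries, not
of the classifier; the cycling-recovery validation therefore measures on
all generated cells.

## Gene-set scoring

Four scoring procedures are pinned precisely so results do not depend on
any external implementation.

**Module score** (used for cell-cycle phases and marker panels): genes are
binned into 24 quantile bins of dataset-mean expression; for each set gene,
100 control genes are drawn from its bin (set genes excluded; without
replacement when the bin allows, with replacement otherwise); the score is
the per-cell mean of the set minus the mean of the control pool. The draw
is seeded and reproducible; all RNG in the package is Mersenne-Twister
under explicit seeds, restored on exit.

**Single-sample rank enrichment** (the immune score): per cell, genes get
average ranks; the score is the sum over the descending-rank list of the
difference between the exponent-weighted in-set ECDF (default exponent
0.25) and the unweighted out-of-set ECDF. It depends on within-cell ranks
only. At exponent 0 the statistic is exactly mean-zero under random set
assignment; at positive exponents the rank weighting adds a small constant
positive offset, which cancels in the contrasts the score is used for
(immune vs tumor). The bundled immune signature is package-curated (~50
canonical T/NK/B/monocyte/MHC-II genes) and user-overridable via GMT.

**Set-variation (GSVA-style) score** (epithelial, mesenchymal/CSC and ECM
programs): per cell, a weight-1 Kolmogorov-Smirnov walk over the
descending average-rank list steps up `1/m` at set genes and down
`1/(n-m)` otherwise; the raw score is the signed maximum-magnitude
deviation, observed **only at tie-group boundaries**. The tie rule
matters: in a sparse cell most genes tie at zero, and evaluating the walk
inside that block would let the arbitrary order of tied genes manufacture
large spurious deviations. Each set's raw scores are then min-max rescaled
to [0, 1] across the cells of the analysis so that an absolute 0.5 cutoff
is meaningful; the rescaling makes scores cohort-relative, which is the
package's documented interpretation of score-threshold rules whose
original scale is unstated. A set with constant raw scores maps to 0.5.

**Preranked GSEA**: classic weighted running-sum enrichment (weight
exponent 1) with gene-label permutations for the nominal p, sign-matched
mean-normalization for NES, and a pooled permutation FDR. The enrichment
statistic is cross-checked in the test suite against an independent
implementation (`fgsea::calcGseaStat`) to 1e-10.

## Cell typing and states

Heatmap inspection is replaced by an explicit rule over marker panels
(T: CD2/CD3D/CD3E/CD3G; B: CD19/MS4A1/CD79A/CD79B; monocyte:
CD14/CD68/CD163; pan-leukocyte: PTPRC; lung origin:
SFTPA1/SFTPA2/SFTPB/NAPSA; epithelial: EPCAM/CDH1/KRT7/KRT8/KRT18/MUC1;
proliferation: CCND1/TOP2A). A panel is positive when at least
`min_detected = 2` of its genes are detected — capped at the panel size so
the one-gene PTPRC panel can fire — or when its module score exceeds
`score_threshold = 0.1`. Immune positivity has priority over tumor panels;
immune cells are subtyped by the best immune panel, compared first on
detected marker count and then on module score (detection first, because
control-subtracted scores go negative for sparsely detected panels even
when the detected marker is unambiguous). Non-immune cells are CTCs when
the epithelial or lung panel is positive; everything else is unassigned.
All knobs are arguments.

States follow fixed rules: cycling iff `max(G1/S, G2/M) > 0.2` (strict),
intermediate iff the max is in (0, 0.2], non-cycling otherwise; partial
EMT iff both the epithelial and the mesenchymal/CSC (FN1/VIM/CD44)
rescaled set scores strictly exceed 0.5; CSC markers (PROM1, CD44,
ALDH1A1, ALDH1A3, ALDH3A1, ABCG2) and CTA burden use raw count > 0 as
"detectable expression", with the CD44+ALDH1A1+ dual flag and the
stem-like flag (PROM1+ or CD44+) reported alongside. The bundled CTA
catalogue is a 276-symbol curated stand-in assembled from canonical CTA
gene families (file `cta_catalog_synthetic.gmt`; replace it with your own
GMT for real analyses).

On simulated Smart-seq2-like data the partial-EMT caller is highly
specific but only moderately sensitive (~40-50% of planted cells at
default depth): with a 3-gene mesenchymal set and ~60% per-gene detection,
cells missing one marker read-out fall under the 0.5 cutoff. Treat
partial-EMT fractions as lower bounds at this depth.

## Heterogeneity

Pairwise Pearson correlations (Spearman available) between cell expression
profiles over all QC-passing genes, summarized as the mean coefficient
over within-patient pairs versus between-patient pairs, compared by a
two-sided Wilcoxon rank-sum test; lower mean correlation = greater
heterogeneity. The rank-sum test treats pairs as independent although
pairs share cells — the package reproduces that conventional procedure
as stated and offers a cell-level label-permutation p-value
(`n_cell_perm`) as a robustness check. The gene universe is deliberately
all QC-passing genes (no variable-gene selection) for determinism.

## Differential expression and panel selection

The default test is a two-sided Wilcoxon rank-sum on log-normalized
expression per gene (tie-corrected normal approximation with continuity
correction; exact when the smaller group has fewer than 8 cells), with
Benjamini-Hochberg adjustment across genes. A simplified
negative-binomial Wald test (method-of-moments common dispersion,
delta-method standard errors) is provided as an alternative; the method
used is recorded on the result. Fold changes are
`log2((mean_a + 1) / (mean_b + 1))` on CP10K means — the pseudocount
guards division by zero and is configurable. Patient signatures use
one-vs-rest comparisons at raw p < .05 and fold change > 1.5 (raw p, as
such signature screens are conventionally reported); stage-biased genes
use adjusted p < .05 and fold change > 2. Diagnostic panels rank genes
passing four criteria (detection >= 50% in tumor cells, <= 5% in normal
cells, log2 fold change >= 1, adjusted p < .05) by the detection gap,
ties by fold change then gene id, truncated to 20 — all parameterized,
since published criteria tables for such panels are rarely reproducible
verbatim.

A note on power, established by simulation in the test suite: for a 4x
shift at NB dispersion 0.5 and 100 cells per group, detection power
(adjusted p < .05, correct sign) exceeds 95%, but the per-gene log2
fold-change estimate has an intrinsic sampling SD of ~0.3, so demanding
each estimate land in a +/-0.5 window around the truth caps joint
per-gene success near 90%. Validation therefore asserts detection power
and the *mean* fold-change estimate separately.

## The simulator

`generate_synthetic()` draws counts as NB(mean mu, dispersion theta) with
variance `mu + mu^2/theta`, thinned by independent Bernoulli dropout.
Program genes (immune populations, the shared CTC program, cell-cycle
phases, mesenchymal/CSC, patient-private programs) sit at
`baseline * 2^delta` in cells where their program is active and at
`baseline * 2^background_log2` elsewhere. Defaults, fixed as the study
conditions the package emulates: 5 patients, 200-600 cells each, 2000
genes, CTC-dominated composition (80% CTC / 10% T / 8% monocyte / 2% B),
baseline mean 2, dispersion 0.5, dropout 0.3, `delta = 3` (8x),
`background_log2 = -10` (near-silent off-target markers, matching the
specificity of sorted CSF populations), mitochondrial target 5% (means
calibrated per cell), cycling fraction 7.2% of CTCs (split between G1/S
and G2/M), partial-EMT fraction 30% (the observed range across patients
spans ~0-40%), CTA net detection probability 0.02 per catalogue gene and
CTC (drawn post-dropout, so it is the detection rate an analyst measures),
and CSC marker positivity rates of 25% (CD44), 15% (ALDH1A1), 5%
(ALDH1A3/ALDH3A1), 2% (PROM1), 1% (ABCG2). These choices put the median
detected-genes-per-cell inside the 600-2100 window typical of Smart-seq2
CSF libraries.

What the simulator does **not** model: batch effects, ambient RNA,
doublets, gene-length or GC bias, gene-gene correlation beyond the planted
programs, and continuous (rather than binary) program activation. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
what its own generative model plants — necessary, not sufficient, evidence
about behavior on real libraries.

## Numerical and reporting choices

* Percentages are rounded half-up to one decimal and always carried with
  their integer numerator and denominator (`report_proportion()`);
  half-up, not banker's rounding, because 1/16 should report as 6.3%,
  matching how such ratios are conventionally printed.
* Across-patient means of per-patient percentages are unweighted.
* Ties in ranks use average ranks everywhere; no random tie-breaking in
  scoring. Deterministic index-order traversal only affects constructs
  whose value is tie-invariant (see the GSVA tie-boundary rule).
* The 2-D embedding is PCA (first two PCs, deterministic) — a convenience
  view only; no quantitative claim in the package depends on it.
* Test-suite problem sizes — 600-3000 simulated cells, 500-2000 genes,
  200-1000 permutations — were chosen so the full suite exercises every
  recovery property at comfortable margins in about a minute.

## Known limitations

Exact numerical agreement with the specific third-party tools a given
study ran (Seurat, ESTIMATE, DESeq2, GSVA, GSEA) is a non-goal; this
package pins its own documented constructions instead. The bundled immune
signature and CTA catalogue are curated stand-ins for resources that are
not redistributable here; both are single-line GMT swaps. Heterogeneity
p-values inherit the pair-dependence caveat above. The simulator's binary
program model makes classification easier than continuous biology; effect
size `delta` is the honest dial for difficulty, and sensitivity fixtures
at `delta` in {1, 2, 3} are exercised in the tests.
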