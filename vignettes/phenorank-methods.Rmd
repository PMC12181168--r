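---
title: "Methods: paired training transcriptomics and phenotype-correlated GSEA"
author: "phenorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired training transcriptomics and phenotype-correlated GSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`phenorank` analyses paired pre/post intervention bulk RNA-seq of a young
and an older cohort, starting from a gene-level raw count matrix. The
central container is the `PairedCohortExperiment`, a
`SummarizedExperiment` whose validity enforces the design the methods
assume: every subject contributes exactly one pre- and one post-training
sample, belongs to one cohort, and the `counts` assay holds non-negative
integers with unique gene and sample identifiers. Gene identifiers are
opaque, case-sensitive strings; no symbol mapping is attempted, because
any mapping is dataset-specific. All tabular I/O is pinned to TSV
(tab-separated, decimal point, UTF-8, no quoting) so that outputs are
diff-able and byte-reproducible; reals are written in C17 `%.17g`
shortest-round-trip form, which makes every reader/writer pair lossless.

# Normalization

Library depth is removed with the median-of-ratios estimator: for sample
$j$, $s_j = \operatorname{median}_g\, K_{gj}/\mathrm{GM}_g$ over the
reference genes $g$ observed in every sample
($\mathrm{GM}_g = (\prod_j K_{gj})^{1/m} > 0$), and normalized counts are
$K_{gj}/s_j$. We implement the plain median of the ratios. A subtlety
worth recording: the common log-scale variant
$\exp(\operatorname{median}_g \log(K_{gj}/\mathrm{GM}_g))$ agrees with
ours except when the reference-gene count is even, where the sample
median averages the two middle values arithmetically on one scale and
geometrically on the other; the unit tests cross-check against DESeq2 on
an odd reference count, where both are identical. A matrix without any
all-positive gene has no defined reference and is rejected with advice to
filter first. An exact algebraic property is tested rather than a
folklore one: scaling one sample's counts by $k$ scales its size factor
by exactly $k^{(m-1)/m}$ (the geometric-mean reference absorbs
$k^{1/m}$), so the invariant we assert is that counts and the supplied
library scale moving *together* leave the normalized matrix unchanged.

# Paired differential expression

The analysis that motivated this package used a negative-binomial Wald
test; re-implementing its dispersion shrinkage and GLM machinery is out
of scope here, and everything downstream consumes only the
(log2FC, p) columns. The DE engine is therefore a paired t-test on
log-scale differences: per gene and subject,
$\delta_s = \log_2(\mathrm{norm}_{post} + c) - \log_2(\mathrm{norm}_{pre} + c)$
with prior count $c = 0.5$; the reported log2FC is
$\bar{\delta}$, the statistic $t = \bar\delta / (s_\delta/\sqrt{n})$ with
$n-1$ degrees of freedom, and q the Benjamini–Hochberg adjustment across
tested genes. The subject random effect cancels in the pairing, which is
what makes this test well calibrated on the simulator's null (verified
in the acceptance suite at 99% binomial bounds).

Choices a user can tune, with defaults and reasons:

* **Expression filter** `minMeanCount = 5` (cohort mean raw count).
  Low-count genes make the log-scale test degenerate; they are excluded
  before the BH step and flagged, not silently dropped.
* **Prior count** `prior = 0.5`, the common convention that keeps all
  log ratios finite; exposed everywhere it enters.
* **Degenerate genes** follow the t-test's continuity limits:
  zero-variance differences give p = 1 at zero mean and p = 0 (infinite
  statistic) at nonzero mean.
* **Thresholds** default to unadjusted p < 0.05 with |log2FC| > 0.4 for
  the overlap classification; q is always reported alongside, so the
  permissive unadjusted-p convention of the source analysis and the
  rigorous FDR view coexist in one table. Both a p-only and a p-and-lfc
  significance count are exposed (`countSignificant`,
  `thresholdMode`), since published per-cohort totals and figure-panel
  sets may use either.

`classifyDE` partitions the two cohorts' significant genes into six sets
(common/unique × up/down) with outer-join semantics — a gene absent from
one table is non-significant there — and quotes the shared sets as a
percentage of the union of all increased (resp. decreased) genes, the
denominator convention used when such overlaps are reported.
`makeOverlapDETables` builds synthetic DE tables realising any requested
overlap structure, which is how the tests pin the classifier's set
algebra to known answers, including reconstructing published overlap
summaries from their printed counts.

# Subject-specific correlation ranking

The package's distinctive stage treats each participant as their own
control: `subjectLog2FC` forms
$\mathrm{lfc}_{gs} = \log_2\!\big((\mathrm{norm}_{g,post(s)}+c)/(\mathrm{norm}_{g,pre(s)}+c)\big)$,
and `correlateGenes` computes, per gene, Pearson's r between
$\{\mathrm{lfc}_{gs}\}_s$ and the subjects' phenotype change
$d_s = \mathrm{post} - \mathrm{pre}$ (lean mass in kg, isometric leg
extension/flexion strength in Nm, or type-II fiber cross-sectional area
in µm²). Both cohorts are pooled by default, matching the pooled-subject
framing of the correlation analyses this mirrors; per-cohort scoping is a
flag. Subjects lacking a delta are dropped pairwise with a logged count;
fewer than three common subjects is a hard error. Genes with zero
fold-change variance carry an undefined r and never enter the ranking.
The t-transform p-value, $t = r\sqrt{(n-2)/(1-r^2)}$, is reported for
reference only — ranking uses raw r, and since rank order is invariant
under monotone transforms, applying Fisher's z would change nothing
downstream. `rankBy` orders descending by score with exact ties broken by
ascending gene identifier, making the ranked list fully deterministic.

# Pre-ranked GSEA

`enrichmentScore` implements the weighted Kolmogorov–Smirnov running
sum: walking the list, a member gene adds $|score_i|^w/N_R$
($N_R = \sum_{hits}|score|^w$) and a non-member subtracts $1/(N-N_h)$;
the enrichment score is the maximal signed deviation from zero. Weight
$w = 1$ is the default (the standard weighted statistic of the common
tooling); $w = 0$ gives the classic unweighted form, under which the
score depends only on hit positions (property-tested under monotone
transforms).

Numerical decisions:

* **Extreme evaluation.** Between hits the sum decays linearly, so both
  extremes are evaluated analytically at hit boundaries (O(k) per set)
  rather than from the naive cumulative sum. Exact positive/negative
  magnitude ties do occur — e.g. both extremes equal to a multiple of the
  miss step — and resolve deterministically to the positive extreme, with
  a $10^{-12}$ tolerance because the two extremes come from different
  floating-point expressions.
* **Null and p-value.** The null permutes gene labels: same-size random
  subsets with scores held fixed, the only null available to a
  pre-ranked analysis. The one-sided p conditions on the observed ES
  sign — among same-sign null scores, the smoothed fraction at least as
  extreme, $p = (1+\#extreme)/(1+\#samesign)$. Dividing by the total
  permutation count instead would bound p by the same-sign fraction
  (≈ 0.5) and roughly double the null rejection rate, which is
  incompatible with calibration at $\alpha$; the sign-conditioned
  estimator is the standard one and is what the null-calibration
  acceptance test verifies.
* **Exact enumeration.** Whenever $\binom{N}{k}$ does not exceed
  `nPerm`, sampling is replaced by full enumeration and p is the exact
  tail fraction (no smoothing; the observed subset is among those
  enumerated). Tests exploit this to compare the sampled machinery
  against exhaustive oracles.
* **NES and FDR.** NES = ES divided by the mean magnitude of same-sign
  null scores (reported undefined if none exist). The default FDR is
  Benjamini–Hochberg across the tested sets' permutation p-values; the
  GSEA-native sign-matched pooled-null NES FDR is available as
  `fdrMethod = "gsea_style"` for comparability. BH was chosen as default
  because the mirrored analyses report an "FDR < 0.05" cutoff from
  R tooling without specifying the pooled variant.
* **Size filter** defaults 15–500 (the common tooling's defaults; the
  source analyses name none); toy tests override it. Per-set permutation
  streams are derived from the config seed plus the set index, so a
  collection's results are reproducible and sets do not share a stream.
* **Leading edge**: members at or before the running-sum peak for
  positive ES, at or after it for negative.

# The cohort simulator

`simulateCohort` emulates the study conditions the analysis assumes, so
that every downstream stage is testable without access to raw data. In
draw order from one seed: log-normal per-gene baselines (ln-mean 4,
ln-sd 1.5, putting the median gene near 55 counts at typical depth);
per-subject random effects (sd 0.2 on the natural-log scale) applied to
both timepoints; per-cohort phenotype deltas for all four phenotypes
(lean-mass defaults: young N(0.8, 1.2²) kg, old N(1.5, 1.3²) kg — chosen
once to span the −1 to +5 kg heterogeneity reported for such cohorts,
with the older group showing the clearer mean gain); planted training
log2FCs for a fraction `fracDE = 0.1` of genes, magnitudes N(1, 0.25²)
with 75% positive (training responses of this kind skew ~3:1 toward
induction); phenotype-coupled genes disjoint from the DE set, with
subject-specific targets
$b_{gs} = \gamma\, z(d_s) + \varepsilon_{gs}$, where
$\gamma = \rho\tau$, $sd(\varepsilon) = \tau\sqrt{1-\rho^2}$,
$\tau =$ `couplingSd` $= 0.5$ and $z$ the standardized delta — a closed
form giving $corr(b_{gs}, d_s) = \rho$ in expectation (verified by
Monte-Carlo at n = 200 subjects); log-normal library scaling (sd 0.3, so
size factors are non-trivial); and finally counts
$K \sim \mathrm{NB}(m, \phi_g)$ with the two-parameter dispersion trend
$\phi_g = 3/\mu_g + 0.1$. Cohort sizes default to 8 young + 10 older
subjects, the design this package mirrors. An exact target correlation of
magnitude 1 is rejected, since the construction always carries residual
noise for $|\rho| < 1$.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: GC/length bias, batch effects, read-level
artifacts, correlated gene modules (genes are independent given the
subject effect), dropout structure beyond NB sampling, and measurement
error in the phenotypes themselves. Recovery results on simulated
cohorts demonstrate that the machinery finds structure it was built to
find at realistic depth and noise; they are not evidence about any
particular biological dataset. Note also that the measured per-gene
correlation is attenuated relative to the planted $\rho$ by counting
noise (at the defaults, planted $\rho = 0.8$ yields measured r around
0.4), which is exactly the behaviour real data would show; the recovery
criterion is therefore about rank concentration, not about recovering
$\rho$ numerically.

# Pipeline, determinism, problem sizes

`runAll` executes the DE arm and the correlation arm for all four
phenotypes, writing every intermediate (DE tables, classification sets
and summary, ORA tables, correlation tables, RNK ranked lists,
enrichment tables) as TSV plus a JSON manifest with input hashes, seeds,
versions and per-file MD5s. Identical config and seed give byte-identical
outputs; the test suite and the acceptance script both verify this
end-to-end. Stages are re-runnable from their written intermediates
(e.g. a written RNK file re-enters at `gseaPreranked`).

The shipped tests run the statistical checks at deliberately desk-scale
sizes chosen as the package's own test design: null calibration on a
3000-gene cohort, planted-signal recovery at 5000 genes × 18 subjects
with 50 coupled genes and 1000 permutations, oracle equivalence on
hundreds of random instances at N ≤ 50, and determinism on a 400-gene
full pipeline. The planted-recovery enrichment uses nine random
competitor sets alongside the planted one: with 1000 permutations the
smallest attainable permutation p is about $2\times10^{-3}$, so the
number of sets under BH is kept where a genuinely extreme set can still
reach FDR < 0.05 — a resolution constraint inherent to permutation
p-values, not a tuning knob.

# Known limitations

* The DE engine is a paired t-test on log-normalized counts, not an NB
  GLM; it matches NB-based tools in calibration and ranking behaviour on
  the simulator but will not reproduce their p-values gene by gene.
* ORA uses the hypergeometric tail with a user-stated universe and
  ignores GO DAG topology.
* The correlation stage is plain Pearson on n ≈ 18 subjects: single
  influential responders can dominate r; no robust or partial
  correlation variants are provided.
* Supplementary-workbook ingestion (`readSupplementaryXlsx`) is a thin,
  caller-mapped adapter, because published workbook layouts are not
  standardized.
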