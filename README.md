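# phenorank

Paired pre/post intervention bulk RNA-seq analysis with a
subject-specific, phenotype-correlated gene set enrichment stage.

## The problem

Resistance-training studies biopsy the same muscle before and after weeks
of training, in cohorts of young and older adults, and ask two questions:

1. **Which transcripts respond to training in each cohort, and how much
   of the response is shared across age?** Paired differential expression
   per cohort, then set algebra on the thresholded gene lists
   (p < α, |log2FC| > λ) to split the response into commonly and uniquely
   increased/decreased transcripts.
2. **Which transcriptional changes track each individual's physiological
   gain?** Training responses are heterogeneous (lean-mass changes can
   span several kg across participants on the same protocol). For every
   gene *g* and subject *s*, a subject-specific fold-change
   `lfc_gs = log2((norm_post + c) / (norm_pre + c))` is correlated with
   the subject's phenotype change `d_s = post − pre` (lean mass,
   isometric leg extension/flexion strength, type-II fiber CSA) by
   Pearson's
   `r_g = Σ(lfc_gs − l̄fc_g)(d_s − d̄) / √(Σ(lfc_gs − l̄fc_g)² Σ(d_s − d̄)²)`,
   and genes ranked by `r_g` feed a pre-ranked GSEA.

The package implements the whole chain from a raw count matrix:
median-of-ratios normalization (`s_j = median_g K_gj / GM_g`), a paired
t-test on per-subject log2 differences with Benjamini–Hochberg
correction, the two-cohort overlap classification, hypergeometric
over-representation, and a from-scratch pre-ranked GSEA — the weighted
Kolmogorov–Smirnov running sum (hit step `|score|^w / N_R`, miss step
`1/(N − N_h)`; ES is the maximal signed deviation), a gene-label
permutation null with sign-conditioned one-sided p (exact enumeration
whenever the subset count fits the permutation budget), NES against the
sign-matched null mean, FDR across sets, and leading-edge extraction.

Because raw sequencing data for such studies is often not depositable, a
negative-binomial cohort simulator (`simulateCohort`) with per-subject
random effects, a mean–dispersion trend `φ_g = a0/μ_g + a1`, planted
training effects, and genes whose subject-level fold-change is coupled to
a phenotype change at a target correlation ρ (coupling slope and residual
noise solved in closed form) makes every stage testable end to end.

## Worked example

```r
library(phenorank)

cfg <- simConfig(nGenes = 1000, nPhenoGenes = 40, rhoTarget = 0.8, seed = 7)
sim <- simulateCohort(cfg)
sim$experiment
#> PairedCohortExperiment: 1000 genes x 36 samples (18 subjects: 8 young, 10 old)
#> assays: counts

x   <- normalizeCounts(sim$experiment)
deY <- pairedDETest(x, "young")
deO <- pairedDETest(x, "old")
classifyDE(deY, deO)
#> DEClassification (p < 0.05, |log2FC| > 0.4)
#>   young: 58 up / 45 down; old: 74 up / 51 down
#>   common: 38 up (40.4%), 18 down (23.1%)

co      <- correlateGenes(subjectLog2FC(x), sim$phenotypes, "lean_mass_kg")
ranked  <- rankBy(co, "r")
planted <- sim$truth@geneTruth$gene[sim$truth@geneTruth$isCoupled]
set.seed(1)
gsc <- GeneSetCollection(c(list(planted = planted),
    setNames(lapply(1:4, function(i) sample(rownames(x), 40)),
             paste0("random", 1:4))))
gseaPreranked(ranked, gsc, gseaConfig(nPerm = 1000, seed = 7))[, 1:6]
#>       set size_used     es    nes  p_perm     fdr
#> 1 planted        40  0.735  2.834 0.00182 0.00911
#> 2 random2        40  0.376  1.444 0.04936 0.12340
#> 3 random1        40  0.284  1.073 0.35091 0.58485
#> 4 random3        40 -0.179 -0.699 0.94505 0.94505
#> 5 random4        40 -0.179 -0.707 0.93056 0.94505
```

The classification prints each cohort's significant transcripts at the
default thresholds (p < 0.05, |log2FC| > 0.4) and the overlap between
cohorts, with the shared sets quoted as a percentage of the union of all
increased (resp. decreased) genes. In the enrichment table, the 40 genes
planted to track the simulated lean-mass change are recovered as the top
normalized enrichment score (NES 2.8) with a permutation p of 0.002 and
FDR below 0.01, while the random competitor sets land near their null
expectation.

`runAll(pipelineConfig(...))` executes the DE arm plus the correlation
arm for all four phenotypes from either input files (counts/sample/
phenotype TSV + GMT) or a simulation block, writes every intermediate as
TSV, and records a JSON manifest of input hashes, seeds and output MD5s.

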