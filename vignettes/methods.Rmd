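---
title: "Models and methods behind the cross-disorder DNM pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cross-disorder DNM pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmcross)
```

## The problem

De novo mutations (DNMs) — variants present in a child but in neither
parent — are individually rare but collectively a major source of risk for
severe neurodevelopmental and psychiatric disorders. Trio sequencing
ascertains them directly: N trios expose 2N chromosomes per gene. Three
statistical questions follow. Which *classes* of DNMs (loss-of-function,
deleterious missense) are in excess over unaffected controls, and how much
of each disorder do they explain? Which *genes* accumulate more functional
DNMs than their mutation rate allows? And do disorders *share* those genes
more than gene mutability alone predicts? This package implements one
coherent pipeline for all three, across multiple disorders at once, plus
the descriptive network statistics usually reported for the prioritized
genes.

## Variant classes and the count substrate

Records carry a consequence term and, for missense, a deleteriousness
score in [0, 1]. Stopgain, stoploss, canonical splicing and frameshift
calls are LoF; missense with score ≥ `dmis_threshold` is Dmis, below it
Tmis; Pfun = LoF + Dmis is always derived, never stored. The threshold
defaults to 0.7, a published operating point for ReVe-style ensemble
scores, and is configurable because curated tables use different scorers;
the comparison is `≥` so classification is deterministic at the boundary.
An `other` class (in-frame indels, start-loss, …) is tallied but excluded
from burden testing. Per-cohort class counts plus trio counts
(`count_matrix()`) are the substrate of everything in the burden module.

## Burden with synonymous normalization

Raw DNM counts are not comparable across studies: capture kits, depth and
calling pipelines shift the per-trio detection rate. Synonymous DNMs are
assumed phenotype-neutral, so each cohort's synonymous count serves as its
internal denominator. For class *c* the 2×2 table
(case~c~, case~syn~; control~c~, control~syn~) is tested two-tailed with
Fisher's exact test (sum of hypergeometric probabilities not exceeding the
observed table's). Benjamini–Hochberg adjustment runs within each cohort
across its four tested classes (m = 4); that family is the one under which
the published per-disorder adjusted values are internally consistent, and
it is configurable (`bh_family = "all"`). Odds-ratio intervals are Wald on
the log scale with the Haldane–Anscombe 0.5 correction only when a cell is
zero (flagged); the interval method is a reporting convention, not part of
any decision rule here.

The *ascertainment differential* converts excess burden into an
attributable fraction: f = 1 − (control rate ratio)/(case rate ratio),
the fraction of case DNMs of the class implicated in etiology. Multiplied
by the per-trio class count it yields the fraction of probands
attributable to the class. A negative f (depletion) is reported as-is but
clipped to zero before the patient contribution, since a contribution
cannot be negative.

## TADA-Denovo: gamma-Poisson Bayes factors

Gene-level evidence uses the de novo part of the transmitted-and-de-novo
association framework. For gene *i* and class *c*, the count is
Poisson(2Nμ~ic~γ) where μ~ic~ is the per-chromosome mutation rate. In a
non-risk gene γ = 1; in a risk gene γ ~ Gamma(shape = γ̄β, rate = β). The
marginal likelihood ratio is closed-form:

log BF = logΓ(x + γ̄β) − logΓ(γ̄β) + γ̄β·log(β/(β + λ₀)) − x·log(β + λ₀) + λ₀,

with λ₀ = 2Nμ. It is evaluated in log space (finite up to x = 10⁶) and
verified against adaptive quadrature to 10⁻⁶ relative error across a
180-point grid. Classes contribute additively on the log scale; cohorts
pool by summing counts and trios.

Hyperparameters default to the values long used with this model in trio
studies: π = 0.05 risk-gene fraction, γ̄ = 20 (LoF) and 4.7 (Dmis) with
β = 1. Both class modes are supported: the two-class {LoF, Dmis} TADA
convention and a single aggregate Pfun class, whose default γ̄ = 10 is
approximately the mutation-rate-weighted mean of the two (LoF carries
about 38% of the functional rate in the bundled control marginals). None
of these defaults is asserted as what any particular study used; all are
echoed in outputs.

Ranking uses the Bayesian FDR: P0~i~ = (1−π)/((1−π) + π·BF~i~) is the
posterior probability of the null, and the q-value of rank *k* is the
running mean of P0 over the top *k* genes — the expected fraction of nulls
among genes called at that threshold. Ties share the most conservative q
of their block, and tied Bayes factors are ordered by gene id only for
output reproducibility. Candidates (q < 0.05 under the per-disorder or
the combined strategy, union deduplicated) are tiered at q ≤ 10⁻⁴, 10⁻³,
10⁻², < 0.05, and split into shared (Pfun DNMs in ≥ 2 disorders) versus
unique genes. Disorder bias of a shared gene is the exact conditional
test: given the total count, the focal-disorder count is binomial with
probability proportional to its trio share; one-sided p = P(X ≥ x), BH
over all tests.

## Mutability-weighted overlap permutation

The observed statistic for a disorder pair is the number of distinct genes
carrying the class in both. The null reassigns each side's *hit count*
(one per DNM) to genes with probabilities proportional to per-gene class
weights — the stand-in for gene size, structure and trinucleotide
context — by sampling with replacement; a gene drawn twice counts once.
Expected overlap is the permutation mean, O/E the ratio, and
p = (1 + #{perm ≥ obs})/(n_perm + 1), which is never exactly zero.
Adjustment is BH across all pairs × classes of a run; per-pair seeds are
derived from the master seed and the sorted pair labels, so results do not
depend on input order. The default is 10,000 permutations with 100,000
recommended for production runs; the inner loop is compiled (Rcpp) and
draws from R's RNG, so runs are reproducible under `set.seed`.

Two properties of this *resampling* null deserve emphasis. First, it is
exactly calibrated under its own assumptions: when hit sets are drawn from
the weight distribution itself, O/E centres on 1 and p is uniform up to
the discreteness of the integer overlap (the test-suite calibration uses
universes of 400–600 genes and 250–450 hits per side, where the statistic
has enough spread for a 500-sample uniformity check to be meaningful).
Second, it conditions on hit *totals*, not per-gene multiplicities: a
cohort whose hits recur heavily in a few genes presents fewer distinct
genes than the null spreads the same total over, which deflates O/E. On
synthetic data with strong relative risks this conservatism can fully mask
planted cross-disorder sharing, as the overlap driver reports. An
alternative null that relocates genes while preserving each gene's hit
multiplicity would not have this property; the resampling form was chosen
as the direct probabilistic model of the weighted-reassignment idea and
the difference is a known limitation, not a bug.

## Network and expression statistics

Coexpression edges connect gene pairs with |Pearson R| strictly above 0.8
(constant genes are excluded with a warning; at least 3 samples are
required). PPI edges keep combined scores strictly above 400 — following
the "higher than" reading; a flag switches to ≥ — with symmetric
duplicates collapsed to the maximal score and self-edges dropped. The
merged network keeps per-type degrees and retains annotated degree-0
genes, which the in-network versus out-of-network comparisons need.

Degree versus the number of disorders sharing a gene uses Spearman's rank
correlation with mid-rank ties and a large-sample t approximation; for
networks of ≤ 10 nodes an exact null is impractical to enumerate in full,
so a 20,000-draw permutation p replaces the approximation. Module
membership of a gene set is tested per module with a 2×2 Fisher test
inside an explicit background; odds ratios use the Haldane correction on
zero cells. The "shared-disorder trend" is a logistic regression of a
binary gene property on the number of disorders treated as a numeric
score, with a likelihood-ratio p; this resolves the ambiguity of an
"ordered" trend model by the simplest monotone-trend reading. Under
perfect separation the ML fit diverges, so a Firth-penalized fit (bias-
adjusted score with the Jeffreys-prior penalty) supplies the slope and a
penalized LRT p, flagged in the output.

## The synthetic generator

The generator is the package's substitute for curated study data and
defines the conditions under which the pipeline is validated:

* **Scale** — 2,000 genes by default (a desk scale chosen so the whole
  pipeline and its calibration checks run in minutes); 18,000+ genes are
  supported and used by the overlap driver, where gene-level overlap needs
  genome-like sparsity.
* **Cohorts** — the five case cohorts at their curated trio counts (6,511 /
  4,293 / 933 / 1,022 / 1,094) plus 3,391 control trios.
* **Rates** — marginal per-trio class rates equal to the control cohort's
  (411 LoF, 2,257 missense, 932 synonymous per 3,391 trios); per-gene
  mutability is log-normal across genes (σ = 1 by default), a coarse
  stand-in for gene length and trinucleotide effects, rescaled so the
  class totals match exactly. The deleterious fraction of missense is the
  control share, 662/2,257.
* **Risk genes** — π = 0.05 per disorder; half of each disorder's risk
  genes (configurable) come from one shared pool whose size is the largest
  per-disorder risk count, so `shared_pool_fraction = 1` with equal π
  makes the disorders coincide and intermediate values give hypergeometric
  pairwise overlap with mean (s·n_risk)²/pool. Relative risks are sampled
  per risk gene from the same Gamma(γ̄β, β) prior the Bayes factor
  integrates — so the FDR calibration check tests the procedure under its
  own model, which is exactly what a calibration check should do.
* **Records** — counts are Poisson(2Nμγ) per gene and class, expanded to
  per-DNM rows with synthetic sample ids; missense scores are generated on
  the correct side of the classification threshold so classification
  round-trips exactly.
* **Expression and PPI** — module profiles are the near-orthogonal cosine
  basis cos(πk·stage) (module 1 prenatal-high and falling, module 2
  U-shaped, …). Orthogonality matters: exactly mirrored profiles would
  correlate at R = −1 and an |R| threshold would wire the two modules
  together, making module recovery impossible by construction. PPI tables
  are stochastic block graphs with uniform scores.

What the generator does **not** emulate: batch effects across studies
(every cohort shares one detection process — the synonymous normalization
is therefore exercised, not stressed), sample-level structure (multiple
DNMs per proband are independent), sequence context (no FASTA/VCF level),
inherited variation, and any coupling between network degree or module
membership and pleiotropy. Consequently, passing tests demonstrate
correctness and calibration of the statistics under the stated model, not
robustness to the full messiness of curated multi-study data.

## Numerical choices and degenerate inputs

* Bayes factors and posterior null probabilities are computed in log space
  (`plogis` on the log-odds), so BF up to e^700 and beyond cause no
  overflow.
* The Bayesian FDR tie rule (maximal q of a tie block) is conservative.
* Fisher p-values use the standard sum-of-less-probable-tables convention
  with the usual 1 + 10⁻⁷ relative slack for floating-point ties.
* `permutation_null` maps uniforms to genes by binary search on the
  cumulative weight vector; the +1-corrected p cannot be zero.
* Zero cells: Haldane correction (flagged) for odds ratios; two zeros in
  one row return a flagged missing OR. Zero synonymous counts abort burden
  analysis with an explicit error, as normalization is impossible.
* Degenerate networks (all-tied degrees or annotations) return flagged NA
  correlations rather than fabricating a p-value.
* All simulation entry points are deterministic under a seed; the study
  simulator seeds once and the YAML config round-trips at full double
  precision, so a reloaded config reproduces byte-identical tables.

## Problem sizes used in validation

The test suite validates at: 180-point quadrature grid for the Bayes
factor; all 2×2 tables with margins ≤ 20 against enumeration; 50
synthetic studies of 2,000 genes at one-tenth trio counts for FDR
calibration (realized FDP among q < 0.05 calls ≤ 1.5 × nominal); 500
overlap-null runs at 10,000 permutations for O/E and p-uniformity; 100-run
permutation nulls for the type-I error of module enrichment and the trend
test; and 50 planted-signal networks of 200 nodes for the
degree-pleiotropy test. These sizes are the package's chosen validation
conditions; all are parameters, not constants.

## Known limitations

* The resampling overlap null is conservative for recurrence-heavy
  cohorts (see above); O/E values from it are not comparable to nulls that
  preserve per-gene multiplicities.
* Bundled class counts are cohort-level; per-variant curated tables (and
  hence real per-gene results) are inputs the user must supply.
* Gene symbols are matched case-sensitively after whitespace trimming; no
  alias resolution.
* The trend test treats the disorder count as a numeric score; genuinely
  ordinal alternatives (proportional-odds models) are out of scope.
* WGCNA-style module *detection* is out of scope; module labels are inputs
  (synthetic truth or user-supplied), and only the statistics computed on
  given modules are implemented.
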