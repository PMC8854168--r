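# dnmcross

Cross-disorder analysis of de novo mutations (DNMs) from parent-offspring
trio sequencing. The package implements, as reusable and tested functions,
the statistical pipeline used to compare the DNM burden of several
neuropsychiatric disorders (autism spectrum disorder, undiagnosed
developmental disorder, epileptic encephalopathy, intellectual disability,
schizophrenia) against unaffected controls, to prioritize risk genes, and
to characterize the prioritized genes in coexpression/PPI networks:

* **Variant classification** — consequence terms plus a missense
  deleteriousness score map each DNM to LoF, Dmis, Tmis or synonymous;
  LoF + Dmis form the putative functional (Pfun) class.
* **Synonymous-normalized burden** — for class *c* in a case cohort, the
  2×2 table (x_c, x_syn; y_c, y_syn) of case and control counts is tested
  with a two-tailed Fisher exact test; synonymous counts cancel per-study
  differences in DNM detection. The ascertainment differential
  f = 1 − (y_c/y_syn)/(x_c/x_syn) estimates the implicated fraction of
  case DNMs, and f · x_c / N (N trios) the fraction of attributable
  patients.
* **TADA-Denovo gene prioritization** — per gene, the class count follows
  x ~ Poisson(2Nμγ) with relative risk γ ~ Gamma(γ̄β, β) in risk genes and
  γ = 1 otherwise; the closed-form Bayes factor
  BF = Γ(x+γ̄β)/Γ(γ̄β) · (β/(β+2Nμ))^γ̄β · (β+2Nμ)^(−x) · e^{2Nμ}
  accumulates over classes and cohorts, and genes are ranked by a Bayesian
  FDR (running mean of posterior null probabilities), tiered, and split
  into shared/unique by the number of disorders carrying Pfun DNMs, with
  an exact conditional (binomial) test for disorder bias.
* **Mutability-weighted overlap** — observed distinct genes mutated in two
  disorders versus a permutation null that reassigns each side's hit count
  to genes proportionally to per-gene mutation rates (O/E ratio, add-one
  empirical p).
* **Network statistics** — coexpression edges at |R| > 0.8, PPI edges at
  combined score > 400, merged typed-degree networks, degree-vs-pleiotropy
  Spearman correlations, module-membership Fisher enrichment, and a
  logistic trend test (with Firth fallback under separation).
* **Synthetic trio-cohort generator** — the full gamma-Poisson generative
  model with known risk-gene truth, plus toy expression matrices and PPI
  tables, so every stage is testable without access to curated data.

## Worked example

The bundled `npd_class_counts()` table carries the published per-cohort
DNM class counts (six case rows including the pooled NPD row, plus
controls). Burden and contribution reproduce directly:

```r
library(dnmcross)
counts <- npd_class_counts()
bt <- burden_table(counts)
subset(bt, class == "Pfun", c(cohort, or, p, p_adj))
#>    cohort       or            p        p_adj
#> 3     ASD 1.333178 9.805823e-08 1.961165e-07
#> 7     UDD 1.772859 6.153253e-26 2.461301e-25
#> 11     EE 2.451965 1.904639e-22 7.618556e-22
#> 15     ID 2.364113 2.230595e-24 8.922379e-24
#> 19    SCZ 1.272254 1.127015e-02 4.508058e-02
#> 23    NPD 1.613131 1.850124e-22 7.400497e-22

ct <- contribution_table(counts)
round(100 * subset(ct, class == "Pfun")$patient_contribution, 2)
#> [1] 10.98 33.31 34.40 38.11  6.90 21.16
```

Read: every disorder carries a significant excess of putative functional
DNMs over controls after synonymous normalization (odds ratios 1.27–2.45),
and those DNMs account for about 38% of intellectual-disability probands
down to about 7% of schizophrenia probands.

The complete analysis — synthetic study generation, burden, TADA
prioritization, permutation overlap, network statistics — runs as numbered
drivers:

```sh
Rscript analysis/01_simulate.R   # synthetic multi-cohort trio study
Rscript analysis/02_burden.R     # burden + contribution (published & synthetic)
Rscript analysis/03_tada.R       # gene prioritization with truth-based FDP
Rscript analysis/04_overlap.R    # cross-disorder overlap permutation tests
Rscript analysis/05_network.R    # coexpression/PPI network statistics
```

Each driver prints a short summary and writes its tables under `results/`.

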