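# cctcount

P-value combination tests for count data, with the simulation machinery
to study when they can be trusted.

## The problem

Meta-analyses, gene-set tests and microbiome scans all face the same
question: given m individual p-values p_1, ..., p_m testing related null
hypotheses, is the *global* null — all m nulls true at once — rejected?
`cctcount` implements three classical answers:

- **Cauchy combination test (CCT)**:
  Ψ = Σ ω_i · tan{(0.5 − p_i)π} with weights ω_i summing to 1 (equal by
  default). Under the null each transform is standard Cauchy, and the tail
  of the weighted sum is approximately standard Cauchy even under
  dependence, so the combined p-value is 0.5 − arctan(Ψ)/π.
- **Fisher's test**: Ψ = −2 Σ log p_i ~ χ² with 2m degrees of freedom
  under independent uniform nulls.
- **MinP**: the smallest p-value, referred to its Beta(1, m) null law,
  giving 1 − (1 − p_(1))^m.

When the individual p-values come from normal-approximation Z-tests on
negative binomial counts — the canonical over-dispersed count model in
RNA-seq and epidemiology — their null distribution is only approximately
uniform, and correlation between variables breaks Fisher's independence
assumption. The package therefore also provides:

- samplers for multivariate Archimedean copulas (Clayton,
  Gumbel-Hougaard, survival Clayton) by exact frailty constructions,
  with Kendall's τ ↔ θ conversions (Clayton τ = θ/(θ+2), Gumbel
  τ = 1 − 1/θ);
- the negative binomial marginal layer (failures-before-r-th-success
  convention: mean r(1−p)/p, variance r(1−p)/p²), the quantile transform
  from copula uniforms to counts, the Z-test
  Z = (x̄ − μ₀)/√(V₀/n), and the standardized skewness diagnostic
  γ/√n with γ = (2−p)/√((1−p)r) that flags when the normal approximation
  is unsafe;
- vectorized Monte Carlo drivers for type-I error tables, a
  skewness-sensitivity table, an (n, r) heatmap grid, and sparse-signal
  power curves (nine null variables at r = 10 plus one signal at r = 11).

## Worked example

Two GWAS meta-analyses of SNP–depression association p-values ship with
the package. Combining the first set (six studies):

```r
library(cctcount)
run_worked_examples()
#>             study method m statistic  combined_p
#> 1 meta_analysis_1    cct 6  29.53045 0.010774923
#> 2 meta_analysis_1 fisher 6  26.63692 0.008712280
#> 3 meta_analysis_1   minp 6   0.00200 0.011940160
#> 4 meta_analysis_2    cct 5  38.72466 0.008217998
#> 5 meta_analysis_2 fisher 5  14.08214 0.169277980
#> 6 meta_analysis_2   minp 5   0.00150 0.007477534
```

In the first study every method rejects at the 5% level (CCT 0.011,
Fisher 0.009). The second set (0.94, 0.0015, 0.97, 0.79, 0.81) is a
sparse signal — one strong study among four null-looking ones: the CCT
still rejects (0.0082) while Fisher, diluted by the four large
p-values, does not (0.17).

A type-I error cell of the simulation study:

```r
cfg <- scenario_config(m = 50, r = 5, n = 30, M = 10000, alpha = 0.05, seed = 1)
run_type1(cfg)
#> Monte Carlo rejection rates (M = 10000 replicates)
#>  method alpha   rate    mc_se
#>     cct  0.05 0.0241 0.001534
#>  fisher  0.05 0.0549 0.002278
#>    minp  0.05 0.0691 0.002536
```

With m = 50 skewed NB(5, 0.5) variables the CCT is conservative (rate
~0.02 at the nominal 0.05), MinP is liberal, and Fisher holds its size —
the skewness diagnostic `standardized_skewness(nb_params(5, 0.5), 30)`
= 0.17 warns that the normal approximation is strained here.

A command-line wrapper over the same functions (subcommands `combine`,
`sample-copula`, `simulate-counts`, `type1`, `power`, `sensitivity`,
`heatmap`, `worked-examples`) lives at
`system.file("cli", "cctcount.R", package = "cctcount")`; every file-writing
run emits a JSON manifest with the configuration, seed and output
checksums.

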