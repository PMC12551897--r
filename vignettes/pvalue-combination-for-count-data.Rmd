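---
title: "Combining p-values from correlated count data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining p-values from correlated count data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctcount)
```

## The testing problem

Given m hypotheses with p-values $p_1,\dots,p_m$, the global null
$H_0 = \bigcap_i H_{0i}$ is tested from a single combined p-value.
`cctcount` implements three combiners and the simulation layer needed to
study their operating characteristics when the $p_i$ come from
normal-approximation Z-tests on (possibly correlated) negative binomial
counts.

**Cauchy combination test (CCT).** Each p-value is transformed to
$\tan\{(0.5 - p_i)\pi\}$, standard Cauchy under a uniform null; the
statistic is the weighted sum
$\Psi = \sum_i \omega_i \tan\{(0.5-p_i)\pi\}$ with
$\omega_i > 0, \sum_i \omega_i = 1$. The heavy Cauchy tail dominates
the dependence structure, so the tail of $\Psi$ is approximately standard
Cauchy under broad classes of dependence, and the combined p-value is
$0.5 - \arctan(\Psi)/\pi$. This tail robustness — no estimate of the
correlation matrix is needed — plus power against sparse signals is why
the CCT is attractive for meta-analysis and large-scale count-data
screens.

**Fisher.** $\Psi_F = -2\sum_i \log p_i \sim \chi^2_{2m}$ under
*independent* uniform nulls. It is defined unweighted; user-supplied
weights are ignored (and the result records that they were).

**MinP.** The minimum p-value referred to its Beta(1, m) null law:
combined p-value $1 - (1 - p_{(1)})^m$, computed as
`-expm1(m * log1p(-p1))` to keep precision for tiny $p_{(1)}$.

Assumptions worth keeping in view: all three combiners take the
*individual* p-values as given and assume they are (approximately)
Uniform(0,1) under their own nulls. Fisher and MinP additionally calibrate
their null laws under independence; the CCT's Cauchy tail approximation
is what buys robustness to dependence, but it is a *tail* approximation —
it is at its best for small combined p-values.

## The count-data layer

Counts follow the negative binomial in the failures convention:
$X \sim \mathrm{NB}(r, p)$ counts failures before the $r$-th success,
$$f(x) = \binom{x+r-1}{r-1} p^r (1-p)^x,\qquad
E(X) = \frac{r(1-p)}{p},\quad V(X) = \frac{r(1-p)}{p^2},$$
so the variance always exceeds the mean (overdispersion). This is
exactly R's `size`/`prob` parameterization, so the pmf, cdf and quantile
go through `dnbinom`/`pnbinom`/`qnbinom`; `qnbinom` is the
left-continuous generalized inverse (smallest integer x with
CDF(x) ≥ u) that the uniform-to-count transform requires. `r` may be any
positive real.

Each variable is tested with a Z statistic on the sample mean,
$Z = (\bar X - \mu_0)/\sqrt{V_0/n}$, two-sided p-value
$2[1-\Phi(|Z|)]$. The null variance $V_0$ is the *theoretical* variance
implied by the null mean and the known success probability
($V_0 = \mu_0 / p$), not a sample estimate: the simulation scenarios fix
$p$ and specify the null law completely, and using the known variance
keeps the individual tests exactly the intended normal-approximation
tests. With an estimated variance the individual test would acquire
additional $t$-like noise that is not part of the design. This choice
also pins down the power scenario: data from the signal variable
NB(11, 0.5) are tested against the null mean 10 with the null variance
20, so the shift appears only in the numerator of Z.

The quality of the normal approximation is summarized by the
standardized skewness of the sample mean,
$$\gamma_n = \frac{\gamma}{\sqrt n},\qquad
\gamma = \frac{2-p}{\sqrt{(1-p)\,r}},$$
computed by `standardized_skewness()`. Values around 0.05 or below mark
the regime where individual null p-values are close to uniform; at
NB(5, 0.5) with n = 30, $\gamma_n = 0.17$ and the CCT visibly loses
size accuracy (conservative), while at r = 50 ($\gamma_n = 0.05$) it is
essentially nominal.

## Dependence: Archimedean copulas by frailty sampling

Cross-variable dependence is induced on the uniform scale and pushed
through the quantile transform. Two exchangeable one-parameter families
cover the two tail regimes:

- **Clayton** ($\theta > 0$): lower-tail dependence,
  $\tau = \theta/(\theta+2)$;
- **Gumbel-Hougaard** ($\theta \ge 1$): upper-tail dependence,
  $\tau = 1 - 1/\theta$, with $\theta = 1$ exact independence;
- **survival Clayton**: the copula of $1-U$ for Clayton $U$, hence
  upper-tail dependent with the Clayton τ relation.

Sampling uses the Marshall–Olkin frailty construction, which is exact
and O(nm): draw one frailty V per observation and set
$U_i = \psi(E_i/V)$ for i.i.d. standard exponentials $E_i$, where
$\psi$ is the family's generator. For Clayton,
$V \sim \Gamma(1/\theta, 1)$ and $U_i = (1 + E_i/V)^{-1/\theta}$. For
Gumbel, V is positive stable with index $\alpha = 1/\theta$ drawn by the
Chambers–Mallows–Stuck representation and
$U_i = \exp\{-(E_i/V)^{1/\theta}\}$; the stable sampler is singular at
$\alpha = 1$, so $\theta = 1$ branches explicitly to i.i.d. uniforms.
The survival Clayton is generated as the elementwise complement of a
Clayton draw, so with a shared seed the two samples are exact
complements — a property the tests assert bitwise.

No closed-form copula density or cdf is needed (or provided): sampling
is the only operation the study requires. Correctness is asserted
distributionally — marginal uniformity by Kolmogorov–Smirnov,
$\hat\tau$ recovery of the closed-form τ(θ) at n = 5000 within three
standard errors, exchangeability across column pairs, and the
lower-versus-upper tail asymmetry between the families.

## The Monte Carlo studies and their defaults

One scenario (`scenario_config`) is: m variables, per-variable success
parameters r (scalar broadcast), shared p, sample size n, M replicates,
significance levels, an optional copula, and null means. Defaults encode
the study conditions: **p = 0.5** (moderate success probability),
**n = 30** (the classical CLT sample size), **M = 10,000** replicates,
levels **0.05 and 0.01**. M = 10,000 gives a binomial standard error of
about 0.0022 at a rate of 0.05 — small enough to separate the effects of
interest — and every driver exposes M, so larger runs are a parameter,
not a code change.

- `run_type1()`: all-null scenario; per replicate, generate counts,
  compute the m Z-test p-values, combine with all three methods, and
  report rejection proportions per level with binomial standard errors.
  (The rejection *proportion* below each level is the standard size
  estimator.)
- `run_sensitivity()`: analytic $\gamma_n$ next to the simulated CCT
  rate over an (r, n) grid, m = 30 independent variables by default.
- `run_heatmap_grid()`: per (n, r) cell, the mean CCT rate over
  `outer_reps` independent M-replicate studies (`outer_reps = 1`
  reduces exactly to `run_type1`; the averaged grid at
  `outer_reps = 1000` is a command-line scale of run).
- `run_power()`: the sparse-signal design — m − 1 null variables at
  `r_null = 10` and one signal variable at `r_signal = 11`, all tested
  against the null mean 10 (variance 20), so exactly one of ten
  hypotheses is false with a mean shift of 1. Sample sizes sweep
  5…1000; dependence structures: independence, Clayton θ = 3, Gumbel
  θ = 3; α = 0.05 (the level at which the size studies are read).
  Setting `r_signal = r_null` collapses the curve to the type-I rate —
  a built-in null check.

What the generator emulates: over-dispersed counts with a controlled,
exchangeable, tail-asymmetric dependence and a known marginal law — the
setting in which the combiners' size and power can be measured cleanly.
What it does not emulate: real RNA-seq/microbiome features such as
library-size variation, gene-specific dispersions, zero inflation,
non-exchangeable correlation, or estimated (rather than known) null
variances. Passing tests therefore certify the combiners' behaviour
under the stated model, not performance on any particular real dataset.

## Numerical choices

- **Clipping.** Input p-values (and sampled uniforms) are clipped to
  $[10^{-15}, 1-10^{-15}]$ before the tangent/log transforms, so p = 0
  or 1 yields a finite statistic while preserving ordering.
- **CCT tail branch.** The direct form $0.5 - \arctan(\Psi)/\pi$
  cancels catastrophically for large $|\Psi|$ (and underflows to 0 near
  $\Psi \approx 10^{15}$). Above $|\Psi| > 10^8$ the implementation
  switches to the exact identity $\arctan(1/\Psi)/\pi$
  (asymptotically $1/(\pi\Psi)$), mirrored for large negative $\Psi$.
  Both branches agree to better than $10^{-10}$ relative error across
  $\Psi \in [1, 10^6]$.
- **tanpi.** The statistic uses `tanpi(0.5 - p)` rather than
  `tan((0.5 - p) * pi)`, avoiding the error from forming the product
  with π. Near p = 0 the transform is inherently ill-conditioned in
  double precision (relative error in the statistic grows like
  $|\Psi|\cdot\varepsilon$), but the *combined p-value* remains accurate
  to ~$10^{-16}$ absolute, which is the scale that matters; the
  high-precision oracle tests assert $10^{-12}$ absolute agreement.
- **Weights.** Supplied weights are validated (non-negative, not all
  zero) and normalized to sum to one rather than rejected; equal
  weights are the default, and the packaged meta-analysis examples use
  them (they reproduce the published combined values).
- **Vectorization and memory.** Replicates are simulated in blocks
  capped at ~6·10⁶ matrix entries; each block is one
  `(B·n) × m` matrix reduced to B sample means per variable by
  `rowsum`. This keeps the largest scenarios (m = 500) in a few hundred
  MB and makes an M = 10,000 cell take seconds.
- **Reproducibility.** Each driver seeds R's generator once and draws
  sequentially; identical configuration and seed give bit-identical
  tables. The per-replicate substream design that would license
  order-independent parallel execution was deliberately not adopted:
  the blocked vectorized engine is fast enough that parallelism is
  unnecessary, and a single stream keeps the RNG contract trivial to
  audit. Block boundaries never affect results because draws are
  consumed in a fixed order.
- **Degenerate inputs.** M = 1 yields rates in {0, 1}; constant columns
  make Kendall's τ undefined (error); empty p-value vectors, out-of-range
  θ/τ, and dimension mismatches raise immediate validation errors.

## Problem sizes used in the tests

The shipped test suite runs the independent headline type-I cells at the
full M = 10,000, the dependence-ordering checks at M = 2,000, the power
monotonicity sweep at M = 2,000 over n ∈ {5, 10, 30, 50, 100} under
independence, and τ-recovery at n = 5,000 — sizes chosen so the whole
suite completes in about a minute while keeping three-standard-error
bands tight enough to be meaningful. Full grids at larger M are run
through the command-line wrapper.

## Known limitations

- The CCT's Cauchy tail approximation degrades in the *center* of the
  distribution; combined p-values near 0.5 are approximate (harmless in
  practice, since decisions happen in the tail).
- Individual p-values from discrete counts are themselves discrete; for
  small r and n this, not the combiner, dominates size distortion (the
  skewness diagnostic is the guardrail).
- Copula parameter estimation, goodness-of-fit, and non-exchangeable or
  mixed dependence structures are out of scope; the copulas here are
  simulation instruments, not fitted models.
- Discrete marginals do not determine a unique copula; the simulated
  dependence is specified on the latent uniform scale, which is exactly
  what the study design requires but should not be read as an estimable
  property of observed counts.
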