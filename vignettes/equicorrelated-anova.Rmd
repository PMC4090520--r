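---
title: "Comparing group means under equicorrelated repeated measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing group means under equicorrelated repeated measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equianova)
```

## The model

`equianova` is about one question: are the means of $I \ge 2$ groups equal,
when each subject contributes $T$ repeated measurements whose errors are
*equicorrelated* (compound-symmetric) and the error variance differs between
groups? Subject $j$ of group $i$ yields the $T$-vector

$$Y_{ij} = \mu_i 1_T + \alpha_{ij} 1_T + \epsilon_{ij}, \qquad
\alpha_{ij} \sim N(0, \sigma_\alpha^2), \quad
\epsilon_{ij} \sim N(0, \Sigma_{ei}),$$

with $\Sigma_{ei} = \sigma_i^2[(1-\rho) I_T + \rho 1_T 1_T']$. The $\mu_i$
are the targets of inference; $\sigma_i$ (group-specific), $\rho$ and
$\sigma_\alpha$ (shared) are nuisance parameters. This is the classical
heteroscedastic several-means problem (a multi-group Behrens–Fisher
situation), complicated by the within-subject correlation.

Two structural facts drive everything in the package. Writing

$$\phi_i^2 = \sigma_i^2(1-\rho) + T(\rho\sigma_i^2 + \sigma_\alpha^2),$$

the subject means satisfy $\bar Y_{ij\cdot} \sim N(\mu_i,\, \phi_i^2/T)$, and
the between-subject residual sum of squares
$S_i^2 = T\sum_j (\bar Y_{ij\cdot} - \bar Y_{i\cdot\cdot})^2$ satisfies
$S_i^2/\phi_i^2 \sim \chi^2_{n_i-1}$, independent of
$\hat\mu_i = \bar Y_{i\cdot\cdot}$. Consequently every procedure here
depends on the data *only* through the per-group triple
$(n_i, \hat\mu_i, S_i^2)$ and $T$ — the `study_summary` object — and each
group contributes exactly one nuisance scale, $\phi_i^2$. The random effect
is attached to the subject, not the group: that is the reading under which
$S_i^2/\phi_i^2$ has its $\chi^2_{n_i-1}$ law with the subject means
independent across subjects, and it is what the simulator implements.

Note a consequence worth internalizing: $\rho$ and $\sigma_\alpha$ are not
identified separately by these statistics, and the tests never estimate
them. When all $\sigma_i$ are equal, the common $\phi^2$ is a pure scale
factor, so test levels and interval coverage are invariant to
$(\rho, \sigma_\alpha)$ entirely.

## The three tests

All test $H_0: \mu_1 = \cdots = \mu_I$, rephrased as $H\mu = 0$ for the
$(I-1)\times I$ contrast `canonical_contrast(I)`. The common kernel is the
standardized between-group sum of squares

$$\tilde S_B^2(\phi_1^2, \ldots, \phi_I^2)
  = \sum_i w_i \hat\mu_i^2 - \Big(\sum_i w_i \hat\mu_i\Big)^2 \Big/ \sum_i w_i,
  \qquad w_i = \frac{T n_i}{\phi_i^2},$$

which is $\chi^2_{I-1}$ under $H_0$ at the true $\phi_i^2$.

**Generalized F-test** (`gf_test`). The generalized p-value of
$\tilde S_B^2$ treats the unknown $\phi_i^2$ through the pivots
$V_i = S_i^2/\phi_i^2$. We estimate it in Rao–Blackwellized form: draw
$V_i \sim \chi^2_{n_i-1}$, evaluate $\tilde S_B^2$ at the variance
arguments $s_i^2/V_i$, and average the $\chi^2_{I-1}$ upper-tail
probability beyond that value. Conditioning on the $V_i$ and using the
exact $\chi^2$ tail (instead of an indicator against a second simulated
statistic) targets the same quantity with strictly smaller Monte Carlo
variance; the test suite verifies agreement with a brute-force nested
simulation from the model itself.

**Standardization-based test** (`sp_test`). Fiducial generalized pivotal
quantities for the means,
$R_{\mu_i} = \hat\mu_i - Z_i\sqrt{s_i^2/(V_i T n_i)}$ with
$Z_i \sim N(0,1)$ and $V_i \sim \chi^2_{n_i-1}$, induce a fiducial
distribution for $H\mu$ centered at $H\hat\mu$ with
$\mathrm{Cov}^*(HR_\mu) = H\,\mathrm{diag}\{s_i^2/(T n_i(n_i-3))\}\,H'$.
By the standard duality between confidence regions and tests, the p-value
is the fiducial probability that $HR_\mu$ deviates from its center by more
(in the $\mathrm{Cov}^*$ Mahalanobis norm) than the center deviates from
zero. The $n_i - 3$ denominators are the exact second moments of
$1/V_i$; they are also why the test requires $n_i \ge 4$ and why the
refusal for smaller groups is loud rather than silent. The p-value is
algebraically invariant to replacing $H$ by $MH$ for invertible $M$, which
the suite checks numerically.

**Parametric bootstrap test** (`pb_test`). Plug in
$\hat\phi_i^2 = S_i^2/(n_i-1)$, compute
$TS = \tilde S_B^2(\hat\phi^2)$, and approximate its null distribution by
resampling: $\hat\mu_i^B \sim N(0, \hat\phi_i^2/(T n_i))$,
$(\hat\phi_i^B)^2 = \hat\phi_i^2\,\chi^2_{n_i-1}/(n_i-1)$, recompute the
statistic, and report the proportion of bootstrap statistics at or above
$TS$ (non-strict, the conservative tie-break). The p-value is a plain
proportion, with no continuity correction.

Monte Carlo uncertainty is first-class: every result carries `mc_se` (the
draw-level standard deviation for the smooth GF average, the binomial
standard error for the SP/PB proportions), and the suite checks that ten
independent seeds scatter consistently with it. Defaults are 10,000 draws
interactively; use 500,000 when reporting.

In simulation, the three tests divide as the literature for independent
errors leads one to expect: GF is anti-conservative (null rejection around
0.07–0.10 at nominal 0.05, worsening with more groups), SP is mildly
conservative at small $n_i$, PB sits closest to nominal though slightly
above it at very small $n_i$. Those are the behaviors the acceptance
checks pin down numerically.

## Simultaneous intervals for pairwise differences

For all $\binom{I}{2}$ differences $\mu_i - \mu_j$ the package builds
intervals $(\hat\mu_i - \hat\mu_j) \pm q\sqrt{v_{ij}}$ with
$v_{ij} = s_i^2/(T n_i(n_i-3)) + s_j^2/(T n_j(n_j-3))$, calibrating $q$
through the studentized maximum modulus
$M = \max_{i<j} |(\mu_i-\mu_j)-(\hat\mu_i-\hat\mu_j)|/\sqrt{v_{ij}}$:

* `gpq_simultaneous_ci` approximates $M$'s distribution by the GPQ
  deviations $R_{\mu_i} - R_{\mu_j} - (\hat\mu_i - \hat\mu_j)$;
* `pb_simultaneous_ci` approximates it by bootstrap deviations
  $\hat\mu_i^B - \hat\mu_j^B - (\hat\mu_i - \hat\mu_j)$, standardized by
  $v_{ij}$ recomputed from the bootstrap variances. The *halfwidths* still
  use the observed $v_{ij}$; the bootstrap enters only through the
  quantile $q^B$.

The empirical upper-$\alpha$ quantile is the order statistic with index
$\lceil (1-\alpha)\,\mathrm{mc} \rceil$ — the conservative convention, which
matters at small `mc_samples` and is deliberately documented because
"upper quantile" alone underdetermines it.

## The simulator and the study drivers

`generate_dataset` draws full subject-by-repeat data from the model
(per-subject random effects, Cholesky factor of the shared correlation
matrix, group-specific scaling). `type_i_error_study` and `coverage_study`
wrap it: generate, reduce, test (or build intervals), tally. Seeds spawn
deterministically master → replicate → method, so a study is reproducible
bit-for-bit and restricting `methods` never changes the per-method result.

What the generator emulates is exactly the model above: Gaussian errors,
equal $T$ for every subject, no missing measurements, a common $\rho$ and
$\sigma_\alpha$. Real repeated-measures data fail those assumptions in
well-known ways (dropout, unequal visit counts, heavier tails, correlation
decaying with lag rather than constant), so passing simulations certify
the procedures *under the model*, not robustness beyond it. Estimating
$\rho$ or $\sigma_\alpha$ from data is out of scope — the tests never need
them.

Default study sizes are 2,000 replicates with 2,000 inner draws, a
desk-scale compromise whose binomial standard error (about 0.005 on a
rejection rate near 0.05) is adequate for screening; the acceptance script
runs the canonical 5,000 × 5,000 for reported numbers.

## Numerical choices

* **Centered between-SS kernel.** $\tilde S_B^2$ is computed as a weighted
  sum of squared deviations after anchoring the means at the first group,
  never as the catastrophic-cancellation-prone
  $\sum w\hat\mu^2 - (\sum w\hat\mu)^2/\sum w$. This makes the statistic
  nonnegative in floating point and *exactly* zero when all $\hat\mu_i$
  coincide, which in turn makes all three tests return exactly $p = 1$ on
  that degenerate input (the PB comparison $TS^B \ge TS$ would otherwise
  dither on $10^{-16}$-sized noise).
* **Invariances.** All three p-values are location invariant in
  $\hat\mu$ and scale invariant under $(\hat\mu, s^2) \to (c\hat\mu,
  c^2 s^2)$. At a fixed seed these hold bit-exactly whenever the rescaling
  is exact in binary floating point (e.g. $c = 2$); for general $c$ they
  hold to rounding error, and the tests assert both forms.
* **Positive definiteness.** Admissible equicorrelation is
  $-1/(T-1) < \rho < 1$; covariance constructors refuse parameters whose
  compound-symmetry eigenvalues $\sigma^2(1-\rho)$ and
  $\sigma^2(1+(T-1)\rho)$ are not strictly positive.
* **Degenerate inputs.** $s_i^2 = 0$ is refused by every test (the
  pivotal quantities would collapse); $n_i \le 3$ is refused by `sp_test`
  and both interval builders.
* **An RNG footnote.** The default Mersenne–Twister is *super-uniform*:
  averages of its draws fit the normal distribution better than truly
  random samples would, and a single Kolmogorov–Smirnov check on 20,000
  simulated residual sums of squares dips below $p = 0.01$ for a few
  percent of seeds instead of the nominal 1%. The distributional tests in
  the suite therefore judge the median KS p-value across three fixed
  seeds. This is a property of the RNG interacting with large-sample
  goodness-of-fit testing, not of the generator, which is exact.

## Known limitations

* `sp_test`, `gpq_simultaneous_ci` and `pb_simultaneous_ci` need
  $n_i \ge 4$; only `gf_test` and `pb_test` run at $n_i \in \{2, 3\}$.
* The PB test's null rejection rate sits slightly above nominal at very
  small $n_i$ (near 0.05 against 0.041–0.058 across the designs the
  acceptance study covers); none of the three tests is exact.
* All Monte Carlo p-values inherit an $O(\mathrm{mc}^{-1/2})$ error;
  decisions near a threshold should budget for `mc_se`.
* The model assumes a common $\rho$ and $\sigma_\alpha$ across groups and
  equal $T$ within study; neither is checked from data, because the
  sufficient statistics cannot see them separately from $\phi_i^2$.
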