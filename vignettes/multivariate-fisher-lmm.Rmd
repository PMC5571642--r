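---
title: "Testing pleiotropy in related samples: the two-step mixed-model Fisher combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing pleiotropy in related samples: the two-step mixed-model Fisher combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The problem

Complex traits are often measured as several correlated quantitative
phenotypes — for instance, several onset-age and symptom-count measures of
the same underlying liability. A variant that influences that shared
liability (a pleiotropic variant) leaves a moderate signal in each marginal
phenotype, and a test that combines the marginal signals is more powerful
than any single-trait scan. Two obstacles stand in the way in real cohorts:

* **Relatedness and population structure.** Family members and cryptically
  related subjects violate the independence assumption of ordinary
  regression; admixture creates allele-frequency gradients that confound
  naive association tests.
* **Dependence between the marginal tests.** The R per-trait p-values at a
  SNP are not independent, so Fisher's classical chi-square null for their
  combination is wrong.

`pleioscan` addresses both with a two-step design.

## Step one: marginal linear mixed models

Each phenotype $y^r$ ($r = 1, \dots, R$, on $N$ subjects) is modeled as

$$ y^r = \alpha^r + x\,\eta^r + g^s \beta^r + z^r + \varepsilon^r, \qquad
   z^r \sim N(0, \sigma_g^2 K), \quad \varepsilon^r \sim N(0, \sigma^2 I), $$

where $g^s$ holds the dosages (0/1/2 copies of the reference allele) of the
tested SNP, $x$ holds fixed covariates (by default the first ten genotype
principal components, to absorb structure the random effect does not capture
perfectly), and $K$ is the genetic relationship matrix estimated from all
SNPs with the standardized-genotype estimator

$$ K_{ij} = \frac{1}{S'} \sum_s
   \frac{(g_{is} - 2\hat p_s)(g_{js} - 2\hat p_s)}{2 \hat p_s (1 - \hat p_s)}. $$

The variance components are estimated once per trait by REML **under the
null** ($\beta^r = 0$). Writing $\lambda = \sigma_g^2/\sigma^2$ and
eigendecomposing $K = U D U'$, the restricted likelihood profiled over
$\sigma^2$ is a one-dimensional function of $\lambda$; `fit_null()`
maximizes it over $\lambda \in [10^{-6}, 10^{6}]$ on a 33-point log grid
followed by Brent refinement in the bracketing interval, with ties broken
toward the smaller $\lambda$. The decomposition is computed once per cohort
and shared by all traits, all covariate sets and the genome scan, so each
additional trait costs $O(Np^2)$ per likelihood evaluation and each SNP
$O(N)$.

Each SNP is then tested per trait by generalized least squares with the
null-model covariance $\hat V = \hat\sigma_g^2 K + \hat\sigma^2 I$ plugged
in; $(\hat\beta^r/\mathrm{se})^2$ is referred to $\chi^2_1$. This "plug-in"
scheme is the standard fast path for mixed-model GWAS; a property test in
the suite confirms that re-estimating the variance components with the SNP
included changes the rejection decision at $\alpha = 0.05$ for fewer than
5% of null SNPs.

Step one also yields the **conditional residuals**
$\hat\varepsilon^r = y^r - X\hat b^r - \hat z^r$, where
$\hat z^r = \hat\sigma_g^2 K \hat V^{-1}(y^r - X \hat b^r)$ is the BLUP of
the random effect. Their pairwise Pearson correlation estimates the
between-phenotype correlation $\rho_{rr'}$ that exists independently of
relatedness. The raw phenotype correlation (`naive_rho()`) is kept as a
baseline: when relatives share a causal genotype it overestimates
$\rho_{rr'}$, which is exactly what the correlation-accuracy experiment
shows.

## Step two: Fisher combination under dependence

Per SNP the marginal p-values are combined into
$\xi_s = \sum_{r=1}^R -2\log p_{rs}$ (computed in log space, so $p$-values
as small as $10^{-300}$ are safe). Under the null each term is $\chi^2_2$,
but the terms are dependent, so $\xi_s$ is *not* $\chi^2_{2R}$. Its null is
approximated by a gamma distribution matched to the first two moments:

$$ k\theta = 2R, \qquad
   k\theta^2 = 4R + \sum_{r \ne r'} \mathrm{cov}(-2\log p_{rs}, -2\log p_{r's}), $$

with the sum over ordered pairs. The pairwise covariance is evaluated by the
published degree-5 polynomial in $\rho^2$,

$$ \mathrm{cov} \approx \sum_{l=1}^5 c_l \rho_{rr'}^{2l}
   - \frac{c_1}{N}\left(1 - \rho_{rr'}^2\right)^2, $$

with $c = (3.9081, 0.0313, 0.1022, -0.1378, 0.0941)$, at
$\rho_{rr'} = \widehat{\mathrm{cor}}(\hat\varepsilon^r, \hat\varepsilon^{r'})$
and $N$ the number of analyzed subjects. One global gamma null serves all
SNPs, which is what makes step two essentially free. The multivariate
p-value is the gamma upper tail at $\xi_s$.

### The ordered-pair convention

The $\sum_{r \ne r'}$ sum counts each unordered pair twice. The degenerate
check pins this down: for $R = 2$ fully duplicated p-values,
$\xi = 2 \cdot \chi^2_2$, i.e. Gamma(1, 4); the ordered-pair sum gives
$V = 8 + 2 \times 3.9979$ and hence $\theta = 3.99895$, $k = 1.000263$ —
the right limit. Counting each pair once would land halfway to the
independent case.

### The quadrature oracle

`exact_cov_oracle()` recomputes the approximated quantity from first
principles: with $(Z_1, Z_2)$ standard bivariate normal with correlation
$\rho$ and $p_j = 2\Phi(-|Z_j|)$, it integrates
$E[(-2\log p_1)(-2\log p_2)]$ by tensor Gauss-Legendre quadrature on the
folded density (folding $|Z|$ onto $(0, \infty)$ removes the absolute-value
kink, so the rule converges to machine precision; 240 nodes on $(0, 8.5)$
leave the value unchanged at the $10^{-9}$ level when doubled). Subtracting
$E[-2\log p]^2 = 4$ gives the covariance.

The oracle reveals an honest limitation worth stating plainly: the printed
polynomial's maximum absolute error is about $6\times10^{-5}$ for
$\rho \le 0.8$ but grows to about $1.1\times10^{-4}$ by $\rho = 0.9$ and
$2.1\times10^{-3}$ at $\rho \to 1$ (the coefficient sum is 3.9979 where the
degenerate limit is exactly 4). A least-squares refit of the same five
monomials would achieve $2.4\times10^{-5}$ on $[0, 0.9]$; the shipped
constants are nevertheless kept as published — the package validates them,
it does not re-derive them. At any realistic $\rho$ the approximation error
is orders of magnitude below the sampling error of $\hat\rho$ itself.

### What the gamma approximation can and cannot do

Matching two moments makes the test's **size** accurate: across the shipped
null experiments the empirical rejection rate at $\alpha = 0.05$ stays
within the Monte Carlo band of 0.05 for every scenario and correlation.
It does *not* make the whole p-value distribution exactly uniform: at high
correlation ($\rho \ge 0.4$) the true null of $\xi$ is more skewed than any
gamma with the same mean and variance, and a Kolmogorov-Smirnov test on a
few thousand null p-values will detect this even when every practical
operating characteristic is fine. Users calibrating extreme genome-wide
thresholds (e.g. $10^{-6}$ and beyond) should be aware that the
approximation is moment-matched, not tail-exact.

## The simulators

The genotype simulator draws two ancestral allele-frequency panels iid
Uniform(0.1, 0.9), generates parents under within-population HWE, and drops
alleles down one-generation pedigrees (a parent of dosage $d$ transmits the
reference allele with probability $d/2$; SNPs are unlinked, no phase is
tracked). Four cohort designs cross admixture with relatedness: 1000
families × 1 child (independent) or 250 families × 4 full sibs (related),
all with $N = 1000$ children as the analysis sample; admixed designs assign
parent-origin types (both population I, both population II, mixed) in equal
thirds, remainders going deterministically to the first types in that
order. Parents are discarded by default (`include_parents = TRUE` keeps
them, untested against any reference design).

The phenotype simulator draws each subject's $R$-vector from a multivariate
normal with mean $(g_i - 1)e_r$ in trait $r$ — so dosages 0/1/2 shift the
mean by $-e, 0, +e$ — and exchangeable covariance: unit variances,
off-diagonal $\rho$. There is **no polygenic background term**: any
phenotypic resemblance between sibs flows through the shared causal dosage
alone. Consequently the REML $\hat\lambda$ on null traits sits at the lower
search bound, which is the correct answer there, and the recovery experiment
instead generates $y$ with an explicit $N(0, \sigma_g^2 K)$ component to
exercise the variance-component machinery. Negative $\rho$ is accepted by
the code (up to positive definiteness, $\rho > -1/(R-1)$) but excluded from
the shipped experiment grids.

What the simulations do *not* emulate: linkage disequilibrium, minor-allele
spectra below 0.1, genotyping error and missingness, multi-generation
pedigrees, non-normal phenotypes, covariate-driven means. Passing tests
therefore validate the statistical machinery under its stated model, not
robustness to the full mess of real cohort data.

## Experiment scale and numerical choices

The shipped experiments default to a reduced scale: 200 replicates per cell and
$S = 2000$ background SNPs (the study-scale settings, 1000 replicates and
$S = 10{,}000$, are one argument away). Genotype cohorts are redrawn every
20 replicates while phenotypes are redrawn every replicate; phenotype noise
dominates the Monte Carlo variance of every reported summary, so this
spends the simulation budget where it matters while amortizing the $O(N^3)$
eigendecomposition. All experiments are exactly reproducible from
`(grid, seed)`: a single seeded RNG stream drives everything.

Other numerical decisions, in one place:

* $\hat\sigma^2$ is floored at $10^{-12}\,\mathrm{Var}(y)$; $\hat\sigma_g^2 = 0$
  is allowed (boundary REML solutions are legitimate).
* GRM eigenvalues are clipped at zero before use as variances.
* SNPs with MAF $\le$ 0.01 are excluded from the GRM; the tested/causal SNP
  is *included* in the GRM (the estimator uses all passing SNPs).
* The covariance polynomial is evaluated at $\hat\rho$ as estimated (it is
  finite on the whole closed interval, so no clipping is needed, and the
  degenerate $\hat\rho = 1$ case then reproduces the Gamma(1, 4) limit
  exactly); if the implied variance $V$ were non-positive the calibration
  fails loudly rather than silently falling back to $\chi^2_{2R}$.
* Monomorphic SNPs error in the scalar test and return `NA` rows in the
  genome scan; missing dosages are mean-imputed per SNP.
* QC defaults mirror standard GWAS practice: MAF > 0.01, exact HWE test
  p > $10^{-5}$ (Wigginton-style enumeration, not chi-square), per-SNP
  missingness < 0.05.

## A worked null run

```{r null-run}
g  <- simulate_cohort("admixed-related", S = 600, seed = 7, n_subjects = 400)
ph <- simulate_phenotypes(g, R = 4, e = 0, rho = 0.4, seed = 8)
fit <- pleio_gwas(g, ph, n_pcs = 10)
fit
round(fit$rho_hat, 3)
fit$gamma_null
```

With no causal SNP the scan should be quiet; the residual correlations
recover $\rho = 0.4$ and the gamma null sits between the independent
($k = 4, \theta = 2$) and degenerate ($k \approx 1, \theta \approx 4$)
extremes.

```{r qq, fig.width = 5, fig.height = 5}
plot(fit)
```

## Known limitations

* The gamma null is moment-matched, not tail-exact (see above).
* The residual-correlation estimator inherits the known upward bias of all
  three estimators when a strong causal effect is shared across traits and
  $\rho$ is small; the mixed-model residuals reduce but do not remove it.
* One GRM, one random effect: no multi-kernel or leave-one-chromosome-out
  variants.
* The cross-trait genetic correlation induced by relatedness (the $\nu$ in
  the trait-covariance decomposition) is deliberately not estimated; only
  $\rho_{rr'}$ enters the calibration.
* Quantitative, complete phenotypes only; rows with missing traits are
  dropped, not imputed.
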