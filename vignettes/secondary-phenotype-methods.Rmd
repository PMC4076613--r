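---
title: "Models and methods for secondary-phenotype association under case-control ascertainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for secondary-phenotype association under case-control ascertainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control genetic studies sample on disease status $D$. Any quantitative
trait $Y$ measured on those subjects (a *secondary phenotype*) that itself
influences disease risk is then entangled with the sampling: conditioning on
$D$ opens a collider path between the genotype $X$ and $Y$, so a naive
regression of $Y$ on $X$ in the pooled sample (or within a stratum) can show
association where none exists in the population, and can bias effect
estimates where one does.

`secophen` implements two complementary tools:

1. a **proportional-odds likelihood-ratio test** (`proposed_lrt()`) for
   *testing* genotype-trait association while conditioning on disease
   status, and
2. a **retrospective-likelihood maximum-likelihood estimator**
   (`fit_retrospective()`) for *estimating* the genotype effect at the SNPs
   that survive the scan,

together with an ascertainment simulator (`simulate_case_control()`) and a
study harness (`run_study()`) that measure the operating characteristics of
both, plus the standard case-only / control-only / combined OLS comparators.

## The testing model

Factor the retrospective likelihood of each subject as
$P(X_i, Y_i \mid D_i) = P(X_i \mid Y_i, D_i)\, P(Y_i \mid D_i)$. The
$P(Y \mid D)$ factor is common to null and alternative, so the
likelihood-ratio test of "X independent of Y given D (and confounders)"
only needs models for $P(X \mid D)$ and $P(X \mid Y, D)$. For an ordinal
genotype with levels $0, \dots, J$ we use cumulative-logit
(proportional-odds) regression

$$\operatorname{logit} P(X \le j \mid Y, D) = \alpha_{1j} + \delta_{1Y} Y + \delta_{1D} D,
\qquad
\operatorname{logit} P(X \le j \mid D) = \alpha_{0j} + \delta_{0D} D,$$

for $j = 0, \dots, J-1$, and refer twice the log-likelihood difference to
$\chi^2_1$ — one degree of freedom because only $\delta_{1Y}$ is tested,
however many confounders are added to both models via `adjust`. Allele
counts give $J = 2$; imputed dosages give one level per distinct dosage
value (quantized to at most `max_levels` grid points, default 21, because
cumulative-logit thresholds for near-empty categories are poorly
identified; empty levels are dropped and re-indexed).

**Sign convention.** We write thresholds *plus* covariate effects, so our
slopes are the negatives of implementations (such as `MASS::polr`) that
subtract the linear predictor. Likelihood values and the LRT are
convention-invariant; the test suite checks the mapping against `polr`
explicitly.

**Numerics.** Monotone thresholds are enforced by an unconstrained
log-gap reparameterization $(\alpha_0, \log(\alpha_{j+1}-\alpha_j))$.
Optimization is BFGS on the analytic gradient, followed by Newton steps on a
finite-difference Hessian of that gradient, because BFGS's relative-change
stopping rule routinely halts with the gradient just above a strict
tolerance. Convergence requires a gradient max-norm below `1e-6`
(iteration cap 200; cap hits are returned with `converged = FALSE`, never
silently). Slopes exceeding 50 in absolute value are flagged as probable
complete separation and the test reports a missing p-value rather than a
spurious one. Negative LRT values within optimizer tolerance are clamped to
zero with a note.

## The estimation model

For significant SNPs the genotype effect is estimated from the full
retrospective likelihood

$$\prod_i \left\{ \frac{P(D_i \mid X_i, Y_i)\, P(Y_i \mid X_i)\, P(X_i)}{P(D_i)} \right\},$$

with $P(D=1 \mid X, Y) = \operatorname{expit}(\gamma_0 + \gamma_1 X +
\gamma_2 Y)$, $Y \mid X \sim N(\beta_0 + \beta_1 X, \sigma^2)$, and $P(X)$ a
free probability simplex over the observed genotype levels (softmax
parameterized — for a finite, fixed support this is equivalent to profiling
a nonparametric genotype distribution). The marginal
$P(D=1) = \sum_x p_x \int \operatorname{expit}(\gamma_0+\gamma_1 x+\gamma_2 y)\,
\phi(y;\beta_0+\beta_1 x,\sigma^2)\, dy$
is evaluated by Gauss–Hermite quadrature; order 64 by default, at which the
value is stable to well below $10^{-10}$ against orders 32 and 128 at the
parameter scales that occur here (asserted in tests). Maximization is BFGS
with fully analytic gradients (including the quadrature term and, when a
known disease rate is imposed, the implicit-function contribution of the
profiled $\gamma_0$), plus the same Newton polish; the stationarity
tolerance is a gradient max-norm below `1e-5`.

**Flat surfaces are first-class.** Under the null the retrospective surface
is nearly flat in the disease-model parameters — that is precisely the
computational complaint that motivates doing the *testing* step with the
cumulative-logit models instead. The fitter therefore runs a
deterministically jittered multi-start (default 5 starts; no RNG is
consumed, so results do not depend on the caller's seed state), reports
non-convergence as a result rather than an error, and raises a
`flat_surface` flag when two starts agree in log-likelihood to $10^{-4}$
but disagree in parameters by more than $10^{-2}$. `loglik_surface()`
exposes the surface itself over any two scalar parameters, fixed or
profiled, for inspection.

**An exact ridge in the degenerate case.** If the true
$\gamma_1 = \gamma_2 = 0$ (disease independent of genotype and trait), the
ascertainment terms cancel *identically in $\gamma_0$*: every value of
$\gamma_0$ gives the same likelihood, so the unconstrained maximizer is a
ridge, and points on it can differ noticeably in $\hat\beta$ and
$\hat{p}_x$ at identical log-likelihood. The package's check of the
cancellation property therefore fixes the $\gamma$'s at their true zeros
(via the `fixed` argument), under which the retrospective MLE provably
coincides with prospective OLS/MLE and empirical genotype frequencies; the
free-gamma fit remains available but its $\gamma_0$ (and, weakly, the other
parameters) should not be over-interpreted in that regime. Supplying a
known disease rate (`fixed_rate`) removes the indeterminacy by pinning
$P(D=1)$. The same mechanism matters away from the degenerate case: at
$n = 1000$ the near-flat $\gamma_0$ direction measurably attenuates the
unconstrained $\hat\beta_1$ (we observe a mean of about $-0.104$ against a
truth of $-0.12$ across replicates, versus $-0.124$ with the rate fixed),
so the package's estimator-recovery check — and our recommendation for
real use whenever the disease rate is approximately known — is the
`fixed_rate` fit.

The variance matrix is the inverse of the observed information, obtained by
central differences (step $10^{-5}$) of the analytic gradient on the
transformed scale; `wald_test_beta1()` and `lrt_beta1()` provide 1-df tests
of $\beta_1$.

## The simulator: a stated world

`simulate_case_control()` draws genotypes from Hardy–Weinberg proportions
at MAF 0.3 (default), the trait from
$Y \mid X \sim N(\beta_0 + \beta_1 X, \sigma^2)$ with
$\beta_0 = \sigma^2 = 1$, and disease from the logistic model with
$\gamma_2 = \log 2$; $\gamma_0$ is calibrated by root search so the
population prevalence (computed by the same quadrature) hits a 1% or 5%
target to $10^{-8}$. Sampling is retrospective: individuals are drawn in
vectorized blocks from a single seeded Mersenne–Twister stream (genotype
block, then trait block, then disease block) and kept in draw order until
the 500-case and 500-control quotas fill; overflow of a filled class is
discarded, which is distributionally identical to sampling the two classes
as independent streams. Default effect sizes under test are $\beta_1 = 0$
(null) and $\beta_1 = -0.12$ (alternative), with $\gamma_1$ ranging over
$[0, \log 1.5]$ on a six-point grid — the endpoints are the stated design;
the number of interior points is our choice.

What the generator does *not* emulate: covariates/confounders (none are
generated, though the tests accept them), departure from HWE, linkage
between SNPs, missing data, or non-normal traits. A green simulation test
therefore establishes calibration and power ordering *within this world*,
not robustness to proportional-odds violations (for which non-symmetric
links or dispersion parameters would be needed and are out of scope here).

## The study harness

`run_study()` crosses $\beta_1 \times \gamma_1 \times$ disease rate,
calibrates $\gamma_0$ once per cell, and derives per-replicate seeds as
`master + cell_index * 1e6 + replicate` so cells are disjoint and
independently re-runnable. Rejection rates at $\alpha = 0.01$ are computed
among converged replicates (with `n_converged` reported — Lin–Zeng-style
fits may legitimately fail under the null and hiding that would misstate
the comparison) with Wilson 95% intervals (`binomial_ci()`).

## Testing strategy and scale-downs

Every numerical claim in the test suite is anchored to an independent
oracle: per-subject brute-force likelihood summation, adaptive 1-d
`integrate()` for the prevalence integral, refined dense grid search for
maximized likelihoods, `glm`/`MASS::polr` for special cases, closed-form
normal equations for the OLS comparators, and Monte-Carlo draws for
calibration. Two property checks are scaled down for runtime and say so in
place: the quadrature-vs-Monte-Carlo prevalence grid uses $2\times10^5$
draws per cell (criterion recomputed for that sample size), and the
null-uniformity KS check uses 400 replicates. The headline acceptance
checks run at full stated size (2000 null replicates for type-I error,
$10^6$ unascertained draws for rate calibration, 200 replicates for
estimator recovery and coverage, 1000 replicates per power cell).

## Known limitations

- Dichotomous secondary phenotypes and the adjusted score statistic of the
  retrospective framework are not implemented (Wald and LRT only).
- The retrospective model takes no covariates; the testing step does.
- Dosage-level quantization (nearest of at most `max_levels` grid points,
  ties to the lower level) is a pragmatic identifiability device, not part
  of the underlying theory.
- Multiallelic variants and missing-data imputation are out of scope;
  missingness is handled per SNP by complete-case analysis with the drop
  count reported.
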