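---
title: "Skew-t mixture latent state-trait models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skew-t mixture latent state-trait models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewtlst)
```

## The model

A latent state-trait (LST) decomposition writes an observed score for
indicator $i \in \{1,2\}$ at occasion $j$ as trait plus occasion-specific
deviation plus error. The mixture version lets every parameter differ by
latent class $c$:

$$Y_{ijc} = \alpha_{ic} + \lambda_{Tic}\,T_c + \lambda_{Iic}\,IST_{ic} +
O_{jc} + E_{ijc},$$

with membership probability $\pi_c$. $IST_2$ is an indicator-specific trait
residual (the stable part of indicator 2 not shared with indicator 1); the
$O_{jc}$ are mean-zero and uncorrelated across occasions. Identification
fixes $\lambda_{T1c} = \lambda_{I2c} = \lambda_{O1c} = \lambda_{O2c} = 1$
and $\alpha_{1c} = 0$, and strict measurement invariance holds over time
(equal intercepts, loadings and occasion variances), except that the first
occasion has its own error variance — the *Socratic effect* of a larger
first-measurement error. These rules are encoded as a constraint table
(`constraint_map()`), and `count_free_parameters()` counts equality classes
rather than asserting a constant; the two-class design has 10 free
parameters per class plus the mixing logit, 21 in all, for every occasion
count.

Non-normality enters through the trait:
$T_c = \mu_{Tc} + \xi_{Tc}$ with
$\xi_{Tc} \sim rMST(0, \sigma^2_{Tc}, \delta_{Tc}, \nu_c)$, the restricted
multivariate skew-$t$ law defined by

$$Y = \mu + \left(\delta\,|U_0| + U_1\right) W^{-1/2}, \qquad
U_0 \sim N(0,1),\; U_1 \sim N_p(0, \Sigma),\; W \sim
\Gamma(\nu/2, \nu/2),$$

all independent. Positive $\delta$ gives positive (right) skewness — the
sign convention the sampler, the moment formulas and the model-implied
density plots all share, and which the test suite checks empirically.
Setting $\delta = 0$ gives the multivariate $t$; a large $\nu$ (here the
conventional 10000) gives the skew-normal; both together give the normal.

## Density and moments

The closed-form density is not unique to one parameterization in the
skew-$t$ literature, so the package states exactly which one it uses. With
$\Omega = \Sigma + \delta\delta'$, $Q(y) = (y-\mu)'\Omega^{-1}(y-\mu)$ and
$m(y) = \delta'\Omega^{-1}(y-\mu)\big/\sqrt{1 - \delta'\Omega^{-1}\delta}$:

$$f(y) = 2\, t_p(y;\, \mu, \Omega, \nu)\;
T_{\nu+p}\!\left(m(y)\sqrt{\tfrac{\nu+p}{\nu+Q(y)}}\right).$$

Because this formula is easy to get subtly wrong, the tests validate it
against a two-dimensional adaptive quadrature over the mixing variables
$(|U_0|, W)$ of the stochastic representation, against numeric
normalization, and against the $t$/skew-normal/normal special cases.

Moments (needed to translate location/scale/skewness parameters into means,
variances and skewnesses): with
$b_\nu = \sqrt{\nu/\pi}\,\Gamma(\tfrac{\nu-1}{2})/\Gamma(\tfrac{\nu}{2})$,

$$E[Y] = \mu + b_\nu \delta, \qquad
\mathrm{Cov}[Y] = \tfrac{\nu}{\nu-2}(\Sigma + \delta\delta') -
b_\nu^2\,\delta\delta',$$

and the univariate skewness of each margin follows from the exact raw
moments of $(\delta_i |U_0| + U_{1i}) W^{-1/2}$ (finite for $\nu > 3$;
reported as `NA` for $2 < \nu \le 3$). These are verified against
$10^6$-draw Monte Carlo with block-jackknife standard errors — plain
delta-method standard errors for sample skewness are unreliable at
$\nu = 5$ because the sixth moment is infinite.

## Shared t-mixing

The model text treats $O$, $IST$ and $E$ as normal, yet the closed-form
likelihood requires the observed $2j$-vector to be exactly rMST. The package
adopts the standard resolution: within a class, all latent components are
divided by the *same* $\sqrt{W}$ as the trait. Then

$$\mu = \alpha + \Lambda_T \mu_T,\quad
\Sigma = \Lambda\,\mathrm{diag}(\sigma^2_T, Var(IST_2), Var(O), \ldots)
\Lambda' + \Theta,\quad
\delta_{obs} = \Lambda_T\,\delta_T,$$

and the observed vector is $rMST(\mu, \Sigma, \delta_{obs}, \nu)$
(`build_class_moments()`). The symmetric components are then marginally
$t$ rather than normal — identical in the $\nu \to \infty$ limit and close
at $\nu = 5$. `simulate_lst_factors()` exposes both constructions
(`mixing = "shared"` is the generative oracle for the moment structure;
`mixing = "independent"` is the literal independent-normal reading), so the
discrepancy can be examined directly; the generator used by the study
(`simulate_dataset()`) draws from the exact rMST law, keeping generation and
likelihood mutually consistent.

## Synthetic data: what the generator emulates

`enumerate_conditions()` spans the design grid
$N \in \{125, 250, 500, 1000\} \times j \in \{2,\ldots,6\} \times
\delta_T \in \{2.8, 6\}$ — 40 cells, 500 planned replications each (20,000
fits at full scale; desk-scale runs use fewer replications via
`run_config(n_reps = ...)`). Class labels are drawn with
$\pi_1 = \mathrm{logit}^{-1}(1.15) \approx 0.76$; labels are retained for
oracle tests only and never shown to the estimator. Seeds follow
`hash(base_seed, condition index, replication index)` (kept inside 32-bit
range) so any single replication is reproducible in isolation and
parallel/serial execution order cannot change results.

The exact generating values of the original design are not publicly printed,
so `default_truth()` is an **implementer-chosen synthetic fixture** obeying
every stated ordering: class 1 is larger, with lower trait location, larger
trait scale, larger occasion-specific variance and larger error variances;
within both classes the first-occasion error variance exceeds later ones;
$\delta_T$ and $\nu = 5$ are shared across classes (but estimated freely per
class). Consequences for interpretation: qualitative findings (which
parameters are bias-prone, how performance orders across cells) are
comparable with the original study; exact bias magnitudes are not, and the
package nowhere claims they are. The generator also does not emulate
missingness, covariates, or non-invariance over time.

## Estimation

`fit_mixture()` maximizes the observed-data mixture log-likelihood directly
(no EM): with only 21 free parameters, quasi-Newton iteration on a packed
scale is simpler and lets the intricate conditional moments of the
restricted skew-$t$ E-step be avoided. Choices that matter:

* **Packing transforms.** Variances and the trait scale enter as logs;
  degrees of freedom as $\log(\nu - 2.1)$, confining $\nu$ to
  $(2.1, 10000]$ — the moment formulas need $\nu > 2$ and 10000 is the
  skew-normal limit; hitting the cap is reported, not an error. Loadings,
  intercepts, locations, skewness and the logit are untransformed.
* **Optimizer.** Box-constrained L-BFGS (`optim`, `factr = 1e6`) with an
  **analytic gradient** computed in compiled code: every structural
  parameter perturbs $\Omega$ by a low-rank matrix, so the directional
  derivatives of the log-density reduce to a handful of quadratic forms per
  observation; only the two $\nu$ coordinates are differenced numerically
  (the derivative of a $t$ CDF in its order has no closed form). The
  analytic gradient is pinned to a finite-difference gradient of the pure-R
  reference likelihood in the tests. This replaced
  finite-difference-gradient quasi-Newton, which spent 22 likelihood
  evaluations per gradient and dominated study runtime roughly tenfold.
* **Tolerances.** Convergence is declared when the packed-scale gradient
  maximum falls below $10^{-4}$ or the optimizer reports success; the
  iteration cap is 500, mirroring the original study's cap. The original
  study's exact (Mplus) tolerances are not public; these are the documented
  stand-ins.
* **Starting values.** Population values, as in the original design; no
  random multistart by default.
* **Standard errors.** Observed information — the Hessian of the negative
  log-likelihood at the optimum, obtained by central differences *of the
  analytic gradient* — inverted and delta-method-transformed back to the
  reporting scale (the transform is coordinate-wise, so the Jacobian is
  diagonal). Reparameterization invariance of the resulting SEs is verified
  to 5% in the tests.
* **Warning taxonomy.** `boundary_variance` (an estimated variance below
  $10^{-4}$ of its starting value — the analogue of parameters being fixed
  to zero to rescue a singular information matrix), `low_nu`
  ($\hat\nu < 2.5$), `nonpd_information`, `saddle_point`, `se_failure`.
  Optimizer exceptions yield a non-converged fit object, never a crash.

## Label switching and inclusion

Mixture likelihoods are invariant under label permutation, so replications
can return the classes in the wrong order. `detect_label_switch()`
implements the post-hoc rule of the design, using estimates only:
$\hat\pi_1 \in [0.40, 0.60]$ means the classes are not separated enough to
decide and the replication is excluded; for $\hat\pi_1 < 0.40$, labels are
swapped only if *both* criteria agree ($\hat\sigma^2_{T1} <
\hat\sigma^2_{T2}$ and $\hat\mu_{T1} > \hat\mu_{T2}$), a single criterion is
undecidable (excluded), and no criterion leaves labels untouched. The band
is applied to the estimated mixing proportion, not to posterior class
assignments — the source wording is ambiguous, and the mixing weight is the
quantity the rule's logit refers to. Swapping is an involution and leaves
the likelihood unchanged (both tested). `apply_inclusion_filter()` then
keeps only converged, warning-free, unambiguous replications, and
`run_study()` drops cells retaining fewer than `min_included` (default 50)
replications from evaluation summaries.

## Evaluation criteria

Per parameter $p$ and condition, over included replications $r = 1,\ldots,
n_r$:

* parameter estimation bias
  $peb = \tfrac{1}{n_r}\sum_r (\hat\theta_{pr} - \theta_p)/\theta_p$
  (undefined at $\theta_p = 0$; the evaluator refuses rather than silently
  switching to absolute bias — all free parameters of the shipped fixture
  are nonzero);
* standard error bias
  $seb = \tfrac{1}{n_r}\sum_r (SE_{pr} - SD_p)/SD_p$, where $SD_p$ is the
  SD of the estimates over the *included* replications of the same cell;
* $MSE = \tfrac{1}{n_r}\sum_r (\hat\theta_{pr} - \theta_p)^2$ on the raw
  parameter scale (matching the scale of peb and of per-parameter
  comparisons); the decomposition
  $MSE = \text{bias}^2 + \tfrac{n_r - 1}{n_r}\,\mathrm{Var}$ is tested as
  an identity;
* coverage: the share of per-replication Wald intervals
  $\hat\theta \pm z_{0.975} SE$ containing $\theta_p$; replications without
  a usable SE leave the denominator. (The source's phrase "CI around the
  mean of the estimated parameter" is read as the standard per-replication
  CI.)

Thresholds: $|peb|, |seb| \le 0.1$ acceptable, $(0.1, 0.3]$ medium, $> 0.3$
large; coverage acceptable in $[0.91, 0.98]$. A median-based aggregation of
peb/seb is available (`aggregate = "median"`) as the outlier-robust
supplementary variant, but the mean is the headline definition.

## What a green test run establishes — and what it does not

The suite verifies: the kernel against quadrature/sampling oracles; the
likelihood against a naive per-row oracle and its normal-SEM special case;
SEs against expected-information SEM theory and against sampling SDs in a
well-specified single-class normal submodel (400 replications — 200 leaves
roughly 5% Monte Carlo noise in the SD denominator, too much for a ±15%
band); and a scaled-down corner study (cells $\{125, 1000\} \times \{2, 6\}$
at $\delta_T = 2.8$, 50 replications, inclusion threshold lowered to 2 so
small cells still produce rows) reproducing the qualitative signature:
performance improves from the smallest to the largest cell, inclusion rises
with $N$, and in the largest cell the class-2 trait scale is biased upward
while loadings and trait locations stay within ±10%. None of this
establishes agreement with the original study's numeric tables, which
depend on its unpublished population values and its estimation software.

## Known limitations

Two indicators, two classes, at most six occasions; no class-enumeration
tools (likelihood-ratio class tests are out of scope by design); no robust
(sandwich) standard errors; no missing data. The likelihood of a finite
normal/skew-t mixture is unbounded along variance-degenerate ridges —
replications drifting there are caught by the warning screen rather than
prevented, which mirrors the behavior of the software the design emulated.
At small $N$ with $\delta_T = 6$ most replications are excluded; conclusions
for such cells rest on few replications, and the per-cell inclusion tallies
written by `run_study()` should always be read alongside the criteria.
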