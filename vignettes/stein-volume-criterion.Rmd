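---
title: "The Stein volume criterion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Stein volume criterion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steinvc)
```

## The problem and the score

Given N i.i.d. observations in d dimensions and a parametric working model,
data selection asks: onto which subspace of the data (here, which subset of
coordinates) can the data be projected so that the projected model is well
specified? The natural Bayesian answer — model the chosen *foreground*
projection parametrically and everything else with a flexible nonparametric
*background*, then compare marginal likelihoods across choices of foreground
— is statistically and computationally punishing, because the background
model must be fit and integrated in high dimension for every candidate.

`steinvc` implements the Stein volume criterion,

$$\mathcal{K} \;=\; \Big(\tfrac{2\pi}{N}\Big)^{m_B/2} \int
  \exp\!\Big(-\tfrac{N}{T}\,\widehat{\mathrm{NKSD}}\big(p_0(x_F)\,\|\,
  q(x_F\mid\theta)\big)\Big)\,\pi(\theta)\,d\theta,$$

which keeps the *form* of a marginal likelihood but substitutes two pieces.
First, the foreground log likelihood is replaced by an estimate of the
normalized kernelized Stein discrepancy

$$\mathrm{NKSD}(p\|q) = \frac{E_{X,Y\sim p}\big[(s_q-s_p)(X)^\top
  (s_q-s_p)(Y)\,k(X,Y)\big]}{E_{X,Y\sim p}[k(X,Y)]},\qquad
  s_q = \nabla_x \log q,$$

estimated by the ratio of U-statistics over all ordered pairs. Three
properties make this the right divergence for the job: it is estimated
*directly* (not up to a data-dependent constant, which would smuggle the
foreground entropy into cross-dimension comparisons); the estimator
converges at rate $O(1/N)$ when the model is correct, fast enough not to
drown the $\log N$ volume terms that decide nested comparisons; and it is
additive over independent subsystems under a factorized kernel, which makes
scores comparable between foregrounds of different dimension. Second, the
background model appears only through a volume factor $(2\pi/N)^{m_B/2}$ —
the asymptotic footprint a well-specified background of effective dimension
$m_B$ would leave — so no background model is ever specified, fit, or
integrated.

Because only the score $s_q$ of the foreground model enters, additive
constants of the log density cancel: models with intractable normalizers
(the spin glass below) are handled exactly like tractable ones.

## Tunable parameters

**Temperature `T`** (> 0, dimensionless) sharpens or flattens the NKSD
generalized posterior $\pi_N(\theta) \propto
e^{-(N/T)\widehat{\mathrm{NKSD}}}\pi(\theta)$. The package default is 1; the
bivariate toy benchmarks pin `T = 5` and the application-scale benchmarks
pin `T = 0.05`, which `calibrate_temperature()` reproduces in spirit by
matching the frequentist coverage of Laplace-approximate credible intervals
on simulated data (interval width scales as $\sqrt T$, so coverage is
monotone in T and a grid search is well posed). The calibration protocol is
marked experimental: it fixes coverage of per-coordinate 90% intervals at
the minimum-NKSD estimate, one reasonable functional among several.

**Kernel** (`kernel_spec()`): rbf
$\exp(-\|x-y\|^2/2h^2)$ or inverse multiquadric
$(1+\|x-y\|^2/h^2)^{-1/2}$, optionally factorized over coordinate blocks;
both are bounded, strictly positive, integrally strictly positive definite,
and in the Stein class, which the theory requires. The bandwidth default is
the median pairwise distance on a seeded subsample of at most 1000 rows
(deterministic given the seed; degenerate all-identical data is an explicit
error). The toy benchmarks pin `h = 1`. For the pPCA misspecification
benchmarks the package pins the **imq kernel with `h = 2`**: the rbf's
exponential locality makes tail- and scale-mixture misspecification signals
decay faster than the fit-capacity gain of dropping *any* dimension from a
coupled model, and in our simulations no rbf bandwidth separates the
planted dimensions of the harder scale-mixture scenario at N = 2000,
whereas the heavier-tailed imq does so across bandwidths 1–3. General
kernel recommendations for the SVC remain an open design area; the
catalogue here is the package's stand-in.

**Background policy** (`background_policy()`): `m_B` per excluded
dimension. `constant` mode gives $m_B = c\,r_B$ (the toys use $c = 5$);
`per_dim_sqrtN` gives $m_B = c_B r_B \sqrt N$, matching the Pitman–Yor rate
at discount 1/2 — the growth rate with the cleanest nested-selection
asymptotics; `pitman_yor` gives $m_B = r_B\,D\,\Gamma(\nu+1)/(\alpha
\Gamma(\nu+\alpha))\,N^\alpha$, the expected effective dimension of a
Pitman–Yor mixture with discount $\alpha$, concentration $\nu$ and
D-dimensional components (fractional D encodes parameters shared across
components). With $(\alpha,\nu,D) = (0.5, 1, 0.2)$ the per-dimension
allowance crosses 1 at N = 5, crosses 2 (the pPCA per-dimension foreground
cost at k = 2) at N = 20, and is about 20 at N = 2000; with $D = 100$ it
crosses 798 (the spin glass per-gene cost at d = 200) at N = 13. The policy
should be chosen so the background is more generous per dimension than the
foreground, otherwise exclusion is never attractive.

**Decision rule**: a dimension is included iff $\log\mathcal{K}_j -
\log\mathcal{K}_0 < 0$ (excluding it does not improve the score), ties
toward inclusion. The benchmarks phrase results as exclusion decisions, but
no explicit threshold or tie rule accompanies them; the sign rule is this
package's reading, and `loo_scan()` reports the raw log ratios so any other
threshold can be applied downstream.

## Computation backends

For exponential families $q(x\mid\theta) = \lambda(x)\exp(\theta^\top t(x)
- \kappa(\theta))$ the score is affine in $\theta$, so
$\widehat{\mathrm{NKSD}}(\theta) = \theta^\top A\theta + B^\top\theta + C$
exactly; with a Gaussian prior the SVC integral is a closed-form Gaussian
integral (`svc_exact_quadratic()`). The pair sums behind $(A, B, C)$ — and
the analogous statistics for any model whose score is linear in $x$, such
as pPCA — are accumulated once in compiled code with Kahan-compensated
summation, after which every evaluation of the objective at a new $\theta$
costs $O(d^2)$. This is what makes optimizer iterations, finite-difference
Hessians, and candidate scans cheap.

`svc_laplace()` expands around the minimum Stein discrepancy estimator
$\theta_N$ with curvature $\nabla^2\widehat{\mathrm{NKSD}}/T$ and volume
exponent $(m_F + m_B)/2$; `svc_bic()` drops the prior and determinant
terms. `svc_variational()` maximizes the Jensen bound over a mean-field
Gaussian in the unconstrained parameter space; for quadratic objectives the
coordinate maximizers are closed forms, so the ascent is CAVI and the bound
is tight up to the neglected posterior correlations, while for general
models it uses seeded reparameterized sampling with Adam, with optional row
minibatching (flagged as an approximation; pair sums keep the $i \ne j$
convention within each batch). The variational value is a lower bound on
the exact log SVC up to Monte-Carlo noise, initialized at the prior so that
zero steps returns the Jensen-at-prior bound.

`loo_scan()` compares the full foreground against all drop-one candidates.
Since the candidate models of the Gaussian and pPCA families are marginals
of the full model, all candidate objectives share one parameter space, and
the candidate optimum is obtained from the reference optimum by one
implicit-function (Newton) step with the reference Hessian factored once
(`transfer_optimum()`); exact re-optimization is a flag away and agrees
with the transfer to correlation above 0.99 on the Gaussian benchmark. The
kernel bandwidth is resolved once on the full data and reused for every
candidate, so candidates differ only in the quantity being scored, with the
NKSD's normalization handling dimension comparability.

`subset_search()` optimizes per-dimension Bernoulli inclusion logits by
REINFORCE with a leave-one-out control variate (each sampled subset's
advantage is measured against the mean of the *other* samples in the
batch), scoring subsets by the variational SVC plus the background
allowance for excluded dimensions, with a per-subset score cache. Batch
size 4, learning rate 0.1, and 150 steps were fixed on the
four-dimensional Gaussian toy.

## Foreground families

*Gaussian location*: $N(x\mid\theta,\Sigma)$ with fixed $\Sigma$, conjugate
Gaussian prior, full exponential-family structure, and an exact marginal
likelihood (used by the defective baseline `ka`). With `mean_free = FALSE`
it becomes the zero-parameter member used in nested model selection.

*Probabilistic PCA*: $x \sim N(0, H H^\top + v I)$ with $H = U(L - v
I_k)^{1/2}$, $U$ on the Stiefel manifold, spectrum gaps and noise variance
log-transformed, priors uniform-on-Stiefel and inverse-gamma
($\alpha = 0.1$). The effective dimension is the Stiefel quotient count
$m_F = dk - k(k+1)/2 + k + 1$, so each added data dimension costs $k$
parameters. Optimization runs in an unconstrained chart $A \mapsto
\mathrm{qf}(A)$ (sign-fixed thin-QR factor); the chart's
$k(k+1)/2$ gauge directions are flat in every objective, and jittered
solves make Newton steps and transfers well posed along them. The Laplace
backend on this family is approximate for the same gauge reason
(determinant after jitter, no gauge volume in the prior) and the benchmarks
use BIC; the latent rank k is a config input, not inferred.

*Spin glass*: each gene is a softened two-state spin
$z_{j1} = 1/(1+e^{-\tau(x_j-\mu)})$ with fields $H_j \in R^2$, pairwise
couplings $J_{jj'} \in R^{2\times2}$ (stored upper-triangular), and
unnormalized log density $\sum_j H_j^\top z_j + \sum_{j'>j} z_j^\top
J_{jj'} z_{j'}$. The normalizer is unknown and never needed. Priors are
normal on H, Laplace on J (sparsity), normal on $\mu$ and $\log\tau$; the
scales default to 1, the package's choice where the application literature
names only the families. $\Delta E_{jj'} = J_{21}+J_{12}-J_{22}-J_{11}$
summarizes each interaction; under this density convention positive
$\Delta E$ favors *opposed* expression states. A foreground subset of genes
is a different (smaller) glass, so candidate transfer does not apply and
subsets are refit.

## Synthetic benchmarks: what they do and do not show

`gen_toy()` draws bivariate Gaussians: $\Sigma_0 = \mathrm{diag}(1, 1/2)$
makes a unit-covariance location model misspecified on exactly one
coordinate (data selection); $\Sigma_0 = I$ makes it well specified
everywhere (nested data selection, model selection). `gen_ppca_sim()`
plants a rank-2 pPCA structure on dimensions 1–4 (the fixed 4×2 factor
matrix with unit noise) and corrupts dimensions 5–6 either with a
Bernoulli scale mixture (scenario A) or with sign-flipping $\pm 0.99$
correlation at exactly Gaussian margins (scenario B, where only the
dependence is wrong). `gen_glass()` samples the glass by per-coordinate
random-walk Metropolis with acceptance-targeted step adaptation during
burn-in only; because the glass energy is bounded, the density is improper
on $R^d$, so the sampler targets its truncation to $[-6, 6]^d$ (leaving
the score untouched on the support), and the d = 2 oracle tests integrate
the same box on a grid.

These generators emulate the *structure* of the benchmark studies — partial
misspecification with known ground truth — at desk scale. They do not
emulate real scRNA-seq counts: no zero inflation, no library-size
variation, no mean–variance coupling, and Gaussian rather than count
noise. A passing suite therefore certifies the selection machinery
(estimators, scores, decision bookkeeping, consistency regimes), not the
adequacy of any foreground model for real expression data.

Benchmark problem sizes are N up to $10^4$ with 20 seeds for the
consistency-slope and estimator-rate studies, N = 2000 with 5 replicates
per scenario for the pPCA scans, and 20 replicates at N = 2000 for
parameter recovery — sizes at which the measured quantities are stable
while a full run stays comfortable on a laptop.

## Numerical choices

Pair sums use ordered pairs $i \ne j$ only, never the diagonal, with
compensated summation in a single deterministic pass. $N = 1$ returns an
NKSD of 0 by convention with a warning, so selection loops survive tiny
strata. Hessians are symmetrized and, when needed, jittered starting at
$10^{-8}(1 + \max|\mathrm{diag}|)$ with up to three hundredfold
escalations; a Laplace Hessian that stays indefinite falls back to BIC
with a flag on the result. Non-quadratic fits are multi-start BFGS (five
seeded restarts, best kept) with central finite differences — cheap
because objectives are closed forms over precomputed pair statistics —
and convergence is declared below gradient norm $10^{-6}$, otherwise
flagged. The Pitman–Yor coefficient is evaluated through `lgamma`.
Comparisons between results computed under different temperature, kernel,
sample size, or background policy are an error, never a silent number.

## Known limitations

The leave-one-out scan is axis-aligned; general linear projections are
supported in `project()` and `compare()` but not searched over. Uncertainty
on the selected foreground, and inference on $\theta$ *after* selection,
are out of scope. The variational family is a diagonal Gaussian, a poor
fit for strongly coupled glass posteriors. Estimator-level (as opposed to
population-level) additivity of the normalized discrepancy over blocks is
asserted only as the population property in tests. For severely
heavy-tailed data the median-bandwidth heuristic can sit far from the
selection-optimal bandwidth, as the pPCA benchmark experience above
illustrates; bandwidth remains the single most consequential free choice.
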