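---
title: "Dimensionless feature engineering for biofilter performance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensionless feature engineering for biofilter performance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buckpi)
```

## The modelling problem

Granular activated carbon (GAC) biofilters remove organic carbon from
drinking water through a combination of adsorption and microbial activity.
Predicting the effluent organic carbon concentration `EC_org` from operating
conditions is hard: the datasets that exist are sparse compilations of a few
studies run at very different physical scales (bench columns to full-scale
beds), and purely data-driven models trained on one scale transfer poorly to
another.

`buckpi` implements a physics-guided alternative.  Nine measured variables
describe a filter observation: water temperature `T`, pore size `Pz`, filter
age `A`, influent and effluent organic carbon `IC_org` and `EC_org`, empty
bed contact time `Bt`, GAC particle diameter `P`, filter bed diameter
`C_fit`, and ambient temperature `t0`.  Dimensional analysis says that a
system of $n$ variables expressed in $m$ independent base dimensions can be
rewritten in $n - m$ dimensionless products ($\pi$-groups); algebraically,
the $\pi$-group exponent vectors span the null space of the dimensional
matrix (rows = base dimensions, columns = variables, entries = exponents).
For the eight independent biofilter variables over
{mass, length, time, temperature} the dimensional matrix has rank 4, so
there are exactly four independent groups, and the dependent variable is
nondimensionalized by the influent concentration:

$$\frac{EC_{org}}{IC_{org}}
  = e^{\beta_0}
    \left(\frac{P_z}{C_{fit}}\right)^{\beta_1}
    \left(\frac{B_t}{A}\right)^{\beta_2}
    \left(\frac{P}{C_{fit}}\right)^{\beta_3}
    \left(\frac{t_0}{T}\right)^{\beta_4}.$$

Because every feature is a ratio, a model fitted on laboratory columns can
be applied to a full-scale bed without retraining on that scale.

## Exact null-space construction

Floating-point row reduction can turn a structural zero into `1e-16` and
change the rank, so the whole linear-algebra layer uses exact rational
arithmetic (integer numerator/denominator pairs; all magnitudes stay far
below $2^{53}$).  `construct_pi_basis()`:

1. builds the dimensional matrix of the independent variables;
2. computes its reduced row echelon form and right null space exactly;
3. canonicalizes each basis vector to integer exponents with gcd 1 and a
   distinguished (free) variable raised to a positive power;
4. nondimensionalizes the dependent variable by an exact solve against the
   independent columns, preferring a single matching variable — for the
   biofilter system this resolves to `EC_org/IC_org`.

The canonical groups depend on which variables end up as pivots.  We list
the natural *reference* quantities first (`IC_org`, `C_fit`, `A`, `T`) so
that each remaining variable is paired with its physical reference, which
reproduces the familiar ratios:

```{r basis}
basis <- construct_pi_basis(biofilter_variables())
basis
```

Any other ordering yields a basis with the same span (the tests verify span
equality by exact row reduction), but these labels are the interpretable
ones.  Temperatures are converted to kelvin on ingest: `t0/T` must be a
ratio of absolute temperatures — Celsius values near zero would make the
group singular and sign-unstable.

Canonical units are m, s, K, and g/m^3 for concentrations.  g/m^3 is
numerically identical to mg/L, the unit in which biofilter carbon
concentrations are reported, which keeps the fixed hyperparameters of the
baseline regressors (notably the SVR tolerance $\varepsilon = 0.1$) on a
meaningful scale relative to the data.

## Models on the physics-guided path

All physics-guided models work on the logarithmic scale, where the monomial
ansatz is exactly linear:

* **Monomial power law (BP-LR)** — ordinary least squares of
  $\log(EC/IC)$ on the four $\log \pi_i$ with an intercept.
  `predict_monomial()` exponentiates; an all-ones $\pi$ row returns
  $e^{\beta_0}$.
* **Feedforward network (BP-NN)** — two ReLU hidden layers (64 and 32
  units), a linear output, Adam (learning rate $10^{-3}$), an L2 weight
  penalty ($10^{-4}$), minibatches of 32, at most 1000 epochs with early
  stopping (patience 50).  Inputs are the standardized $\log \pi_i$; the
  target is $\log(EC/IC)$.  Training follows a multi-seed, 5-fold
  cross-validation protocol: for each of 7 seeds, each fold in turn serves
  as the early-stopping validation set (producing per-epoch MSE/MAE
  traces), and a final model is refit on all training rows for the median
  best epoch.  Metrics are reported as mean and population SD across
  seeds.
* **Baseline regressors** — ridge (closed form, no separate offset, penalty
  chosen from a log-spaced grid $10^{-3}\dots10^{10}$ by 5-fold CV; the
  target is standardized internally because a no-offset model presumes a
  centered response), gradient boosting (100 trees, learning rate 0.1,
  seed 42), random forest (100 trees, seed 42) and $\varepsilon$-SVR
  (RBF kernel, $C = 1$, $\varepsilon = 0.1$).

Working in $\log \pi$ rather than raw $\pi$ is a deliberate choice.  The
$\pi$-groups of a multi-scale compilation span several decades; on the raw
scale their standardized distribution is degenerately heavy-tailed, a
linear model cannot represent a power law at all, and the network spends
its capacity on a thin sliver of the input range (in our experiments it
plateaus around $R^2 \approx 0.85$ on data whose true law it should match
almost exactly).  The logarithm is the natural scale of power-product
features; standardization is applied there.  Predictions are exponentiated
and multiplied by the known `IC_org` (`back_transform()`) so that all
metrics are computed on the dimensional effluent concentration.

## Data-driven baselines

The comparison harness (`run_comparison()`) mirrors the physics-guided
path with three purely data-driven reducers, each producing four features
from the eight standardized raw variables:

* **PCA** — first four principal components (`stats::prcomp`);
* **kernel PCA** — RBF kernel, bandwidth $\gamma = 1/p$ (the common
  default when only "RBF" is specified), first four kernel components
  (`kernlab::kpca`);
* **autoencoder** — symmetric dense network $8 \to 6 \to 4 \to 6 \to 8$,
  ReLU hidden units, linear output, Adam on mean-squared reconstruction
  error, up to 500 epochs with early stopping on a held-back validation
  slice.  Only the bottleneck width is dictated by the protocol; depth,
  epochs and loss are documented package choices.

These reducers have no access to the dimensional structure, so their
features are not scale-invariant; the regressors on these paths predict
`EC_org` directly.  The same five model families are fitted per reducer,
giving the 4 reducers × 5 families × 2 splits × 2 metrics comparison grid
(`comparison_table()`), with LR realized as the monomial on the
physics-guided path and as ordinary least squares on reduced features
(which may be negative, making a log model undefined).

## The synthetic generator

Real multi-study compilations are not redistributable, so
`generate_observations()` emulates their structure with a known ground
truth: the eight independent variables are sampled log-uniformly within
plausible biofilter magnitudes spanning lab to full scale — pore size
0.1–2 mm, particle diameter 0.5–2 mm, bed diameter 20–2000 mm, age 1–500
days, contact time 0.1–5 h, influent carbon 1–10 mg/L, water temperature
278–298 K, ambient temperature 270–305 K — study labels are assigned
cyclically, and the effluent concentration is constructed by inverting the
monomial law with exponents $(-0.06, -0.30, 0.53, -0.09)$, intercept
$\beta_0 = -0.07$ and multiplicative log-normal noise
$\varepsilon \sim N(0, \sigma^2)$.  Log-uniform sampling spreads the log
$\pi$-groups evenly, which is what makes log-linear fitting stable.

What the generator does *not* emulate: temporal autocorrelation within a
study, correlated operating variables (a real filter's age and contact
time are not independent), measurement error in the predictors, and any
mechanistic adsorption/biofilm dynamics.  Passing tests therefore show
that the pipeline recovers a monomial law from realistic magnitudes and
noise — not that real biofilters obey one.

## Identifiability of the temperature exponent

A parameter-recovery simulation (100 seeded replicates, $n = 300$,
$\sigma = 0.05$) recovers the exponents of `Pz/C_fit`, `Bt/A` and
`P/C_fit` within ±0.05 essentially always.  The `t0/T` exponent is
different: absolute-temperature ratios vary only a few percent under
realistic conditions ($sd(\log t_0/T) \approx 0.04$), so its OLS standard
error is $\sigma / (sd \cdot \sqrt{n}) \approx 0.07$ — wider than the
±0.05 band — and roughly half the replicates miss it.  This is a Fisher
information limit of the design, not an estimation defect: no estimator
can do materially better without wider temperature ranges, lower noise or
more data.  The corresponding test is left failing deliberately, as a
faithful record of that limit; the noiseless check (exact recovery to
1e-10) and the three well-identified exponents pass.

## Numerical and protocol choices

* Standardization uses the population SD (divide by $n$), so the
  transformed training set has exactly unit variance; the across-seed SD
  uses the same convention.  Both are stated conventions, not estimates.
* The study-based split holds out one study entirely and moves a seeded
  random quota of its rows into training (the three-study protocol:
  175 + 26 + 116 rows, quota 54, giving 255 train / 62 test).  Whether the
  quota rows should be random or time-ordered is unknowable from the
  protocol description; random-with-seed is the documented assumption.
* sMAPE uses the form $\frac{100}{n}\sum |y - \hat y| / (|y| + |\hat y|)$
  — without the conventional factor 2 — so it is bounded by 100.
* $R^2$ is $1 - SS_{res}/SS_{tot}$ and may be negative on test data.
* A degenerate SVR fit in which every target lies inside the
  $\varepsilon$-tube of a constant (zero support vectors) returns the
  constant at the median, the $\varepsilon$-insensitive optimum, instead
  of erroring.
* Networks are trained single-threaded with all randomness derived from
  explicit seeds; identical configurations reproduce identical weights,
  traces and predictions bit for bit.
* Problem sizes used by the shipped tests and the acceptance script —
  $n = 300$ recovery replicates, $n_{train} = 250$ / $n_{test} = 60$ for
  the network benchmark, 150 rows per study in the ablation, 7 network
  seeds (3 for the ablation) — were chosen as the smallest sizes at which
  the corresponding effects are stable.

## The ablation: what the π-features buy

`ablation_pi_vs_raw()` makes the cross-scale claim concrete: two synthetic
"studies" differ 10-fold in bed diameter; the identical network is trained
on one study's standardized $\log \pi$ features versus its standardized
raw variables, and evaluated on the other study.  The generating law
depends only on ratios, so the $\pi$-features carry over while the raw
features face a covariate shift the network has never seen.  In a typical
run the $\pi$-network holds $R^2 \approx 0.93$ on the held-out scale while
the raw-variable network drops to $R^2 \approx 0$.  This is by
construction — the synthetic law is scale-free — and is the package's
testable surrogate for the claim that dimensionless features generalize
across filter scales.

## Limitations

* The monomial ansatz is a strong structural assumption; the network on
  $\pi$-features relaxes it only within the span of the four ratios.
* Only the four mechanical/thermal base dimensions are built in; systems
  needing amount-of-substance or electrical dimensions would require a
  config extension.
* The harness treats every row as independent; time series structure in
  real compilations is ignored by design.
* No hyperparameter search is performed beyond the ridge penalty grid;
  the network architecture is a documented fixed choice.
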