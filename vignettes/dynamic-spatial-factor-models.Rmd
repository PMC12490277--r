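---
title: "Dynamic spatial factor models for correlated areal counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic spatial factor models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dsfm)
```

## The model and its assumptions

`dsfm` models $K$ correlated count outcomes observed on $N$ areal units
over $J$ years through one shared latent factor.  For region $i$, year
$j$, outcome $k$:

$$Y_{ij}^{(k)} \sim \mathrm{Poisson}\!\left(E_{ij}^{(k)}\lambda_{ij}^{(k)}\right),
\qquad
\log \lambda_{ij}^{(k)} = \gamma_i^{(k)} f_{ij} + \varepsilon_{ij}^{(k)},
\qquad
\varepsilon_{ij}^{(k)} \sim N(0, \sigma_k^2).$$

The expected counts $E_{ij}^{(k)} = P_{ij}\, r^{(k)}$ standardise each cell
by its population and the baseline-year overall rate of the outcome, so
$\lambda$ is a relative risk against the baseline year and
$\log\lambda = 0$ means "at the baseline-year average rate".
This choice makes the factor comparable across years: the factor trend is
not confounded with population growth or with the outcome's overall level.

The factor field combines ICAR spatial smoothing with an AR(1) temporal
pull: conditional on its neighbours, $f_{ij}$ is centred at the
year-specific mean $\tilde\mu_{ij} = \mu_j + \eta(f_{i,j-1} - \mu_{j-1})$
plus the average deviation of its neighbours, with conditional variance
$\tau_f^2 / w_{i+}$.  Adjacency is binary ($w_{il} \in \{0,1\}$, queen-type
point-touch contiguity for the bundled lattice generator) and isolated
regions are rejected outright, because the conditional divides by the
neighbour total.

Identifiability of a one-factor model requires pinning the factor's scale:
the *reference outcome's* loading is fixed at 1 everywhere.  The remaining
loading fields $\gamma^{(k)}$ are mean-one ICAR fields with a common
variance $\tau_\gamma^2$ (spatially varying mode), or scalars
$\gamma^{(k)} \sim N(1, \tau_\gamma^2)$ (spatially constant mode).  The
mean-one choice encodes the prior view that, on average, every outcome
tracks the factor as strongly as the reference outcome.

Counts may be interval-censored — the small-cell suppression common in
surveillance extracts, where counts of 1–5 are reported only as "1–5".  A
censored cell contributes $\log \sum_{y=a}^{b} \mathrm{Pois}(y; m)$ to the
likelihood (log-sum-exp over log pmf terms; an infinite upper bound uses
the log survival function).  We treat both interval ends as inclusive.
The observation model is plain Poisson with interval censoring; no
generalized-Poisson dispersion parameter is included, since the hierarchy
already carries cell-level overdispersion through $\varepsilon$.

## Marginal covariance of the stacked outcomes

For the Gaussian linear version of the model (one time point, identity
link), the covariance of the stacked vector
$Y = (Y^{(1)}_{1:N}, \ldots, Y^{(K)}_{1:N})$ has closed form.  Writing
$\Sigma^F$ for the factor covariance, $\mu^{(k)}$ and
$\Sigma^{\Gamma(k)}$ for the loading mean and covariance, and $\odot$ for
the elementwise product, the blocks are

$$\mathrm{Cov}(Y^{(k)}, Y^{(k')}) =
\left[\delta_{kk'}\Sigma^{\Gamma(k)} + \mu^{(k)}\mu^{(k')\top}\right]
\odot \Sigma^F + \delta_{kk'}\,\sigma_k^2 I,$$

with $\mu^{(1)} \equiv 1$ and $\Sigma^{\Gamma(1)} \equiv 0$ for the
reference outcome.  Spatially constant loadings are the special case
$\Sigma^{\Gamma(k)} = \tau_{\gamma(k)}^2 \mathbf{1}\mathbf{1}^\top$ and
constant $\mu^{(k)}$, collapsing the diagonal blocks to
$(\tau_{\gamma(k)}^2 + \mu^{(k)2})\Sigma^F + \sigma_k^2 I$: every block is
then proportional to the factor covariance, so spatial heterogeneity in
the outcome covariance can only come from the factor.  With varying
loadings the loading covariance enters the diagonal blocks directly —
that is the structural reason spatially varying loadings give
region-specific interpretations.  Although the derivation is for $K = 3$
outcomes in its usual presentation, the block pattern is fully determined
for any $K$, and the implementation generalises accordingly.  The package
accepts any symmetric PSD $\Sigma^{\Gamma(k)}$ (eigenvalue floor
$\geq -10^{-8}\lambda_{\max}$); ICAR-derived covariances use the
rank-corrected pseudo-inverse $\tau^2 Q^{+}$ of the ICAR precision
$Q = D - W$.  `mc_cov_oracle()` is a brute-force sampling check of the
same quantity and is used as the independent oracle in the tests.

These formulas are for the Gaussian linear model; the package deliberately
does not derive Poisson-scale marginal moments.

## Improper ICAR layers and what identifies the levels

The ICAR prior is improper: its pairwise-difference log density
$-\tfrac{1}{2\tau^2}\sum_{i<l} w_{il}(d_i - d_l)^2$ is invariant to adding
a constant to the whole field.  Three consequences shape the
implementation:

* **Joint form and rank correction.**  The joint density consistent with
  the stated conditionals is the pairwise-difference form above; the
  variance parameter's full conditional uses the exponent $(N - c)/2$ per
  field, with $c$ the number of connected components.
* **Year intercepts.**  Because the likelihood depends on $f$ only and the
  pairwise prior is shift-invariant within each year, a flat prior on
  $\mu_j$ leaves $\mu_j$ with an improper conditional.  We therefore work
  in the equivalent parameterisation in which each year's deviations are
  constrained to sum to zero and the offset is absorbed into $\mu_j$: the
  factor field is sampled under the (mu-free) pairwise conditionals, and
  $\mu_j$ is recovered deterministically by the centering recursion
  $\mu_1 = \bar f_{\cdot 1}$, $\mu_j = \bar f_{\cdot j} -
  \eta(\bar f_{\cdot j-1} - \mu_{j-1})$.  This is a reparameterisation,
  not an approximation; the likelihood and all within-year contrasts are
  untouched.
* **Loading levels.**  The mean-one terms of the loadings conditionals
  cancel in pairwise differences, so the prior alone does not pin each
  loading column's level; the likelihood does, through the factor scale
  fixed by the reference outcome.  The loadings are *not* recentred during
  sampling.  In the synthetic-data generator, by contrast, the mean-one
  anchor is exact: loading deviations are drawn jointly from
  $N(0, \tau_\gamma^2 Q^{+})$ (which lives in the sum-to-zero subspace)
  and shifted by 1.  This asymmetry — exact anchor in simulation,
  likelihood-identified level in inference — is deliberate and is the main
  reason posterior intervals for loadings are slightly conservative in
  weak-signal regimes (see *Calibration* below).

## The sampler

`fit_dsfm()` runs a Metropolis-within-Gibbs sweep (compiled in C++):

1. each latent log rate by adaptive random-walk Metropolis against the
   (possibly censored) Poisson likelihood plus its Gaussian layer; cells
   with missing observations are drawn exactly from the Gaussian layer;
2. the factor field site-by-site by exact Gaussian full conditionals
   (ICAR terms of the current year, AR(1) feedback from the next year,
   and the Gaussian error layer are all quadratic in $f_{ij}$);
3. loading fields (or scalars) by exact Gaussian full conditionals;
4. $\sigma_k^2$, $\tau_f^2$, $\tau_\gamma^2$ by conjugate updates —
   inverse-gamma on variances, equivalently Gamma on precisions, so the
   default IG(0.5, 0.5) and the Gamma(5, 2) sensitivity prior share one
   code path;
5. year intercepts by the centering recursion;
6. $\eta$ by adaptive random-walk Metropolis restricted to its uniform
   support (default $(-1, 1)$, configurable; the AR coefficient's prior is
   not standard in this literature, and uniform on the stationary-ish
   range is the weakly informative choice).

Proposal scales adapt in batches of 50 iterations toward 0.44 acceptance
and freeze at the end of burn-in, preserving the stationary distribution.
Initialisation: $\log\lambda$ at $\log((y + 0.5)/E)$ (censored cells at
the interval midpoint), $f = 0$, loadings at 1, variances at 1,
$\eta = 0$.  Chains are bit-reproducible given the seed; chain $c$ uses
`seed + c - 1`.

Correctness is tested three ways: a prior-sampling run (likelihood
disabled) whose variance chains must reproduce the IG(0.5, 0.5) marginals;
an MH-only reference chain driven solely by the independent R-level
`log_posterior()` on a two-region model, compared on posterior medians;
and the calibration study below.

## The synthetic-data generator and the study conditions

`simulate_dataset()` draws from exactly the hierarchy above: year-wise
ICAR factor deviations (sum-to-zero, joint draw via the eigendecomposition
of $Q$) propagated by the AR(1) recursion; mean-one loading fields; the
Gaussian error layer; Poisson counts against $E = P r$; and interval
censoring of one outcome.  It emulates the *structure* of county-level
syndemic surveillance — a connected areal graph, a handful of years, a mix
of common and rare outcomes, small-cell suppression — at desk scale
(default tests use a $5 \times 6$ queen lattice, $J = 5$, $K = 3$,
standing in for a 100-county, 5-year, 6-outcome study).  It does not
emulate real county geography or populations, reporting artefacts,
outcome-specific surveillance biases, or loadings that drift over time; a
passing recovery study therefore demonstrates internal consistency of
model and sampler, not robustness to the ways real surveillance data
violate the model.

The recovery study ("calibration") conditions are fixed at: year
intercepts rising from 0 to 1 on the log relative-risk scale (epidemic
growth strong enough that the factor and loadings are data-identified),
$\eta = 0.5$, $\tau_f^2 = \tau_\gamma^2 = 0.3$, $\sigma_k^2 = 0.1$,
populations $2 \times 10^4$, baseline rates $(2, 0.5, 0.15) \times
10^{-3}$ (expected counts per cell of roughly 40, 10 and 3, the last
outcome censored on $[1,5]$, touching about a fifth of its cells).
Hyperparameters are fixed rather than drawn from the IG(0.5, 0.5)
hyperprior because that prior has no finite moments: draws from it
routinely produce degenerate or astronomically large counts, and no
finite-replication coverage statement survives that.  The cost of fixing
them is that Bayesian intervals need not be exactly frequentist-calibrated
cell by cell: in weak-signal regimes the heavy-tailed variance priors pull
$\sigma_k^2$ upward for sparsely informed outcomes and widen the loading
intervals (conservative coverage), which is visible if the factor trend is
made small.  Under the stated conditions the test suite checks that the
empirical coverage of 90% intervals for the loading fields over 20
replicates ($20\,000$ iterations each) is statistically consistent with
0.90; hyperparameter intervals ($\sigma_k^2$ in particular) are *not*
expected to be exactly calibrated at fixed truth and are not part of that
check.

## Numerical and design choices

* PSD validation tolerates eigenvalues down to $-10^{-8}\lambda_{\max}$;
  matrix square roots clip tiny negative eigenvalues to zero.
* Censoring bounds are inclusive on both ends ("counts between one and
  five" read inclusively, matching how suppressed small cells are coded).
* $\tau_\gamma^2$ is shared across the non-reference loading fields,
  matching the single symbol used for it in this model family.
* Scaled loadings (`scale_loadings()`) divide each loading by the sum of
  the $K$ loadings at the same region — baseline $1/K$ for equal
  contribution — and are computed per posterior draw, then averaged, so
  the nonlinearity propagates uncertainty; a region whose loading sum is
  numerically zero is flagged undefined rather than dropped.
* Variance-explained ratios use posterior means of $\gamma$, $f$ and
  $\sigma_k^2$ with the empirical variance taken over the $J$ years:
  $\mathrm{Var}_j(\hat\gamma_i^{(k)}\hat f_{ij}) /
  (\mathrm{Var}_j(\hat\gamma_i^{(k)}\hat f_{ij}) + \hat\sigma_k^2)$.
  A draw-wise construction would also be defensible; the plug-in version
  is reported because it matches how such maps are usually thresholded
  (at 0.50) for display.
* Gelman-Rubin uses the classic PSRF
  $\sqrt{((n-1)/n \cdot W + B/n)/W}$; parameters with zero within-chain
  variance (the pinned reference loading) are reported as `NA`, and the
  working convergence threshold is 1.1 with two chains.
* Default production settings mirror large surveillance fits ($10^6$
  iterations, half burn-in, thin 50); tests and examples run at desk scale
  ($10^3$–$2\times10^4$ iterations on $N \leq 30$), which the suite
  completes in about two minutes.

## Known limitations

Single factor only; loadings constant over time; no covariates,
zero-inflation or explicit overdispersion parameter; no shapefile
processing (adjacency is an input, via edge-list CSV or GAL); no
choropleth rendering — postprocessed tibbles are designed to be joined to
geometry in the user's GIS tool of choice.  The marginal covariance
theory applies to the Gaussian linear model, not to the Poisson scale.
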