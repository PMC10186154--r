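---
title: "Modelling temporal and spatial counts with Gaussian processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temporal and spatial counts with Gaussian processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

RNA-seq counts measured along time, pseudotime or 2-D tissue coordinates
are over-dispersed and heteroscedastic, with substantial probability mass
at zero. `countgp` models one gene's counts $y_1,\dots,y_N$ at locations
$x_1,\dots,x_N$ through a latent Gaussian process on the log-mean:

$$ f \sim \mathcal{GP}(0, k), \qquad
   y_i \mid f \sim \mathrm{NB}\!\big(k_i\, e^{f(x_i)},\, r\big), $$

where $k(x, x')$ is a covariance function (isotropic RBF by default,
linear and periodic alternatives available), $k_i$ is an optional
per-sample scale factor and $r = 1/\alpha$ the NB size, so that
$\mathrm{Var}[y] = \mu + \alpha\mu^2$. Zero-inflated NB (dropout
probability $\psi(\mu) = \kappa/(\kappa+\mu)$, a Michaelis–Menten
function of the mean), Poisson and Gaussian-on-transformed-counts
observation models are drop-in replacements. Hyper-parameters —
lengthscale $\ell$, amplitude $\sigma_f^2$, dispersion $\alpha$, and
family-specific extras — are fitted per gene by maximising the (bound on
the) log marginal likelihood.

In addition to the zero-mean GP, the count-family models carry a plug-in
constant latent mean, the average of $\log\max(y_i, 0.5) - \log k_i$.
This costs no optimized parameter and has two effects we rely on: the
dynamic and constant models pay symmetric amplitude penalties (the Occam
factor of the amplitude no longer depends on how far the data sit from
zero), and the test statistic below becomes exactly invariant to
rescaling counts together with their scale factors.

## Inference

For the Gaussian observation model the marginal likelihood is available
in closed form, and sparse inference uses the collapsed variational
(Titsias) bound. For count models the marginal likelihood is intractable
and we maximise an evidence lower bound (ELBO) over a Gaussian
variational posterior:

* **Full inference** uses the structured family
  $q(\mathbf f) = \mathcal N\!\big(\mu, (K^{-1} + \Lambda)^{-1}\big)$
  with $\Lambda$ diagonal and nonnegative. For log-concave site
  likelihoods (NB, Poisson and ZINB away from extreme dropout) the
  optimal Gaussian variational posterior has exactly this form, so the
  restriction to $2N$ free parameters loses nothing while keeping the
  optimization compact. The mean is parameterised in whitened
  coordinates ($\mu = L a$ with $K = LL^\top$), which keeps the problem
  well-conditioned even when $K$ is nearly singular (e.g. replicated
  coordinates).
* **Sparse inference** places $M$ inducing points (default
  $\lceil 0.05N\rceil$) selected by greedy maximisation of the kernel
  submatrix determinant (a greedy MAP of an $M$-determinantal point
  process, with a determinant-increment stopping tolerance) or by
  k-means, and optimizes a whitened inducing-point posterior
  $q(u) = \mathcal N(m, CC^\top)$ in the Titsias/Hensman form.

Expected log-likelihoods and their derivatives are evaluated by
Gauss–Hermite quadrature (order 20 by default; the order-20 vs order-200
agreement is part of the test suite). The joint objective over
variational parameters and log hyper-parameters is maximised with
L-BFGS-B (gradient tolerance $10^{-6}$, up to 1000 iterations);
variational gradients are analytic and the few hyper-parameter partials
use central differences on the bound. Cholesky factorizations add a
relative jitter of $10^{-6}\sigma_f^2$, escalating tenfold up to
$10^{-2}$ before a fit is declared failed.

Default bounds: $\ell \in [0.01, 100] \times$ coordinate range,
$\sigma_f^2 \in [10^{-6}, 10^6]$, $\alpha \in [10^{-4}, 100]$; the
periodic kernel's period is bounded to $[0.1, 10] \times$ range and is
deliberately configurable, as no canonical choice exists.
Initialisation: $\ell_0 = \mathrm{range}/3$ (half the median pairwise
distance for the spatial pipeline), $\sigma_{f,0}^2 =
\mathrm{var}(\log(1+y))$, $\alpha_0 = 1$; the variational state starts
from ridge-smoothed log counts with Laplace-style precision sites.
Replicates at identical coordinates are kept as separate observations.

A *safe mode* (off by default, as restarts cost time) detects numerical
failure, optimizer non-convergence, or a suspected local optimum — the
posterior predictive median sitting strictly on one side of at least
90% of the observations — and restarts the optimization from
hyper-parameters drawn log-uniformly within their bounds, keeping the
best bound found.

## Tests and error control

The one-sample test compares the dynamic GP against a constant-latent
null (a constant kernel — the infinite-lengthscale limit of the RBF, so
the models are nested) under the same observation model:
$\mathrm{LLR} = \hat L_{\text{dyn}} - \hat L_{\text{const}}$. p-values
are upper-tail $\chi^2$ on $2\,\mathrm{LLR}$ — the corrected statistic;
using the LLR itself, as in one published spatial method, halves the
statistic. The default degrees of freedom equal the difference in
optimized hyper-parameter count between the two models (one, for
RBF-vs-constant), configurable via the `df` argument. The two-sample
test fits each condition and a shared model,
$\mathrm{LLR} = (\hat L_A + \hat L_B) - \hat L_{\text{shared}}$, with
`df` defaulting to the per-fit hyper-parameter count.

Two caveats are documented rather than hidden. First, under the null the
LLR sits at a boundary of the parameter space ($\ell \to \infty$,
amplitude $\to 0$), so $2\,\mathrm{LLR}$ follows a
$\chi^2_0/\chi^2_1$-type mixture: roughly half the null mass lands at
$p = 1$ and the $\chi^2$ p-values are *conservative*, not uniform. The
test suite therefore checks validity (the empirical null CDF never
materially exceeds the nominal level) rather than strict uniformity.
Second, for exactly duplicated two-sample data the shared model is
*favoured* (consistent replicates raise its marginal likelihood), so the
LLR is negative and clamped — the gene is correctly not flagged.

FDR control uses Storey q-values with $\hat\pi_0$ from the
$\lambda$-grid smoother (for fewer than 50 usable p-values the estimate
falls back to $\pi_0 = 1$, i.e. Benjamini–Hochberg behaviour); genes
whose fits do not converge are excluded from the FDR computation and
reported with `NA`. A permutation test is provided for better
calibration: coordinates are rearranged (one permutation per round
shared by all genes; the constant model is permutation-invariant and is
not refitted), null statistics are pooled across genes, and p-values use
the add-one estimator.

## Spatial pipeline

`sv_pipeline()` filters genes with total count below 3 and then
locations below 10 (each filter applied once, genes first — the
operation is idempotent), learns per-gene location scale factors
$k_i = \beta T_i$ by zero-intercept identity-link NB regression against
the location totals $T_i$ (with $\beta > 0$ via log-parameterization,
$r$ fitted jointly), and runs the one-sample test with a 2-D isotropic
RBF kernel. The normalization matters: a spatially smooth cell-size
factor otherwise makes nearly every flat gene look spatially variable,
which the test suite reproduces directionally on synthetic data.

## Branching

For two lineages sharing a trunk, the joint covariance of $f$ (trunk)
and $g$ (branch) constrained to cross at $x_b$ has within-function
blocks $k(x,x')$ and the rank-one cross block
$k(x, x_b)k(x', x_b)^\top / k(x_b, x_b)$. Trunk cells always follow
$f$; branch cells follow $f$ before the candidate $x_b$ and $g$ after.
The posterior over $x_b$ is the normalized likelihood on a uniform grid
(spacing $\delta = \mathrm{range}/50$ by default). Kernel and likelihood
parameters are fitted first on the two lineages separately and then
frozen; only the variational distribution is re-optimized at each grid
point (warm-started from the neighbouring point). Two robustness choices
matter here: the per-lineage fits keep $\ell \ge 0.1\times$ range —
below the cell spacing the crossing constraint carries no information
and short-lengthscale noise-chasing optima poison the frozen hypers —
and the shared amplitude is the larger of the two fitted amplitudes, so
the branch function can actually reach the diverged regime. Lengthscale
and dispersion are combined by geometric mean.

## Synthetic data

`simulate_timecourse()` reproduces the benchmark design this package is
tested against: 600 genes (default) at 11 equally spaced timepoints on
$[0,1]$ with two replicates, half dynamic. Dynamic latents are sines
$f(x) = a\sin(xb + d) + c$ with $b \sim U[\pi/4, 2\pi]$,
$d \sim U[0, 2\pi]$, or natural cubic splines through two interior
control points (plus drawn endpoint values — natural boundary conditions
through two points alone would degenerate to a line). Non-dynamic genes
are constant at the median of a dynamic latent on the grid; a
zero-amplitude draw is reclassified as constant. Dispersion regimes:
$\alpha_{\text{low}} \sim U[0.01, 0.1]$,
$\alpha_{\text{high}} \sim U[1, 3]$. The amplitude and offset ranges are
not canonical; we fix $a \sim U[0.5, 2.5]$ and $c \sim U[0.5, 2]$ (low
expression) or $U[3, 6]$ (high), recorded in the output metadata.
Counts are NB draws with mean $e^{f(x)}$.

`simulate_spatial()` places locations on a jittered grid with
Gaussian-bump latent surfaces for patterned genes and an optional shared
smooth size factor for total-count confounding. `simulate_branching()`
draws two lineages sharing a sine trunk with a linear post-$x_b$
divergence ramp — linear rather than smooth, so the labelled $x_b$ is
where divergence actually starts. All generators take an integer seed,
restore the caller's RNG state, and return truth labels.

What these generators deliberately do not emulate: UMI/ambient noise,
gene–gene correlation, pseudotime estimation error (coordinates are
treated as known; published benchmark comparisons show how inferred
pseudotime can distort gene rankings), multi-batch
structure, and spatial anisotropy. Passing tests therefore demonstrate
correctness of the inference machinery under the stated generative
conditions, not robustness to these real-data complications.

## Problem sizes used in the checks

The automated checks run on one CPU and use reduced but fixed sizes,
chosen once: likelihood ranking (AUROC) on 60 genes at high dispersion
and 40 at low; sparse-vs-full concordance on 30 genes at $N = 120$,
$M = 5\%N$; branching recovery over 25 seeds at 50 cells; null
calibration on 60 constant genes plus a 20-gene permutation run
($B = 12$) and 30-gene flat/confounded spatial runs at 36 locations.
`scripts/acceptance.R` recomputes the same quantities end-to-end at
similar sizes.

## Known limitations

* The ELBO is a lower bound; "log marginal likelihood" everywhere means
  this bound for count models (exact only for the Gaussian family), and
  separately optimized bounds can order sparse above full by a small
  optimization slop (the nestedness tolerance used throughout is 0.01).
* Posterior-predictive credible bands use plug-in hyper-parameters and a
  variational posterior, so their empirical coverage sits a few points
  below nominal (~86% for the [5, 95] band in the coverage test); band
  edges are LOWESS-smoothed with a deliberately small span (0.15), since
  heavier smoothing visibly shrinks the band peaks.
* Dispersion is per-gene, shared across samples; sample-specific
  dispersion, kernel composition, Matérn kernels, ARD lengthscales and
  multi-branch (>2 lineage) trees are out of scope.
* The $\chi^2$ calibration caveat above: prefer the permutation test
  when calibrated p-values matter.
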