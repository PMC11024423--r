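---
title: "Simulating plot data in multi-environment field trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating plot data in multi-environment field trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldtrialsim)
```

## The model

Field trials in plant breeding are laid out as two-dimensional lattices of
plots, and the non-genetic variation observed on such lattices is far from
independent noise: fertility and moisture gradients produce *global trend*,
correlated soil variation between neighbouring plots produces *local
trend*, and trial management (serpentine harvesting and spraying,
multi-plot seeders, inaccurate trimming) produces *extraneous variation*
aligned with the columns or rows. Analyses of real trials routinely have to
model all of these, so a simulator that is used to compare such analyses
must be able to generate them at a controlled, known ratio.

`fieldtrialsim` composes the plot-error vector of each environment $j$
(serialised rows-within-columns) as the sum of three mutually independent
terms,

$$\varepsilon_j = s_j + r_j + e_j,$$

with spatial ($s_j$), random ($r_j$), and extraneous ($e_j$) components and
total variance $\sigma^2_{\varepsilon_j} = \sigma^2_{s_j} + \sigma^2_{r_j} +
\sigma^2_{e_j}$. The user chooses the total variance per trait-environment
pair (`varR`) and the proportions `prop.spatial` and `prop.ext`; the
remaining proportion is random error. The defaults are 0.5 spatial, 0
extraneous, hence 0.5 random.

### Spatial trend

Two generators are available.

**Bivariate interpolation** (`spatial.model = "bivariate"`). Standard-normal
z-values are attached to a set of knots: four placed just outside the
corners of the continuous field array (offset by half a plot length/width;
the offset is configurable through `corner.mult`), plus `complexity`
interior knots placed uniformly at random over the field rectangle. A
piecewise-linear surface is interpolated between the knots (barycentric
interpolation on a Delaunay triangulation — the same interpolant classical
bivariate-interpolation routines produce), each plot receives the average
of the surface over a centred `grid.res` × `grid.res` subgrid of its
rectangle, and the plot values are scaled to the requested variance. Few
knots give smooth, field-wide gradients (global trend); many knots give
increasingly local structure, and eventually near-noise. The default
complexity is half the larger lattice dimension, rounded up —
`default_complexity(10, 20)` is 10 — which gives a reasonable balance of
global to local trend. Users wanting explicit control can sum two
independently generated components (one low-, one high-complexity) and
rescale. Note the interpolated surface is a deterministic function of the
knots; the knot z-values are the random variables of this model.

**Separable AR1 process** (`spatial.model = "AR1"`). The spatial errors are
drawn from $N(0, \sigma^2_s\, \Sigma_c(\rho_c) \otimes \Sigma_r(\rho_r))$
with first-order autoregressive correlation in the column and row
dimensions, realised through the factor-wise Cholesky transform (which we
verify is exactly the Cholesky factor of the Kronecker product). Plot
dimensions play no role here; distance is implicit in the
autocorrelations, so estimates of $\rho_c$, $\rho_r$ from empirical
analyses can be plugged in directly. Lower autocorrelations behave like
higher complexity: more local trend, down to pure noise at zero.

### Random and extraneous error

Random error is iid normal per plot. Extraneous error is built from
column- and/or row-level deviates expanded through the design matrices
$Z_c = I_c \otimes 1_r$ and $Z_r = 1_c \otimes I_r$, so it is constant
within each column and/or row. With `ext.ord = "zig-zag"` the deviates are
arranged so positive values sit in odd and negative values in even
columns/rows — the alternating non-stationary pattern that systematic
management practices leave in real data, and the pattern a sample
variogram shows as higher semivariances at odd than at even displacements.
With `ext.ord = "random"` the deviates keep their random order. When both
directions are requested the variance is split equally between them.

Because normal draws need not split evenly into positive and negative
values, a strict sign-by-parity pattern is only achievable when the sign
counts are balanced; any surplus of one sign is placed on the remaining
positions at random. The implementation centres the column/row deviates
*before* the sign-ordering so that the subsequent variance scaling (a
positive multiplier) can never flip signs and break the pattern.

### Exact variance scaling

Every component is centred and rescaled so that its *sample* variance over
the plots of an environment equals its prescribed share exactly, for every
realisation — e.g. with `varR = 0.20` and proportions 0.4/0.2, the
spatial, random, and extraneous components of each realisation have sample
variances exactly 0.08, 0.08, and 0.04, and the variance decomposition is
auditable in each simulated data set. The total error is the sum of the
three scaled components; its sample variance fluctuates around `varR`
through the (zero-mean) sample cross-covariances, and matches `varR` on
average. Two consequences of this choice are worth knowing:

* the draws are no longer exactly multivariate normal — conditioning a
  Gaussian vector on its sample variance matters little on hundreds of
  plots but is a real distortion on tiny lattices (we therefore test the
  distributional shape of the AR1 generator on its unscaled sampling
  route, and the scaling contract separately);
* correlations are unaffected (scaling is affine), so autocorrelation and
  cross-trait/environment correlation targets remain meaningful.

### Multiple traits and environments

Trait correlation matrices can be set separately for the three components
(`R.spatial`, `R.random`, `R.ext`). Correlation is always imposed on the
underlying standard-normal draws via the lower-triangular Cholesky factor,
before any variance scaling; for the interpolation model this means the
knot z-values, which all traits share one knot set for — plot-level
spatial correlation between traits is then emergent rather than
prescribed. For the extraneous component the correlation is imposed on the
raw column/row deviates and the zig-zag ordering is applied per trait, so
the parity signature is preserved for every trait; under zig-zag the
realised cross-trait correlation is attenuated by the per-trait
reordering.

Environments are independent by default. An optional environment
correlation matrix `R.env` imposes a separable environment-by-trait
structure on the underlying draws (knot positions are then also shared
across environments); this requires identical lattice dimensions in all
environments.

All randomness is consumed through per-(environment, trait, component)
substreams derived from one root seed, so enlarging a simulation — adding
a trait, or requesting an extraneous component that was previously zero —
never perturbs the draws of existing components.

### Genetic values and phenotypes

`simulate_gv()` draws genotype effects over the (environment × trait) grid
from a zero-mean multivariate normal with separable correlation
`R.gtrait` ⊗ `R.env`, where the environment structure comes from one of
three GxE models: *unstructured* (any valid correlation matrix),
*compound symmetry* (one common correlation), or *multiplicative* (a
one-factor structure with loadings $\lambda$, implied off-diagonal
$\lambda_j \lambda_k$; we sample from the implied correlation matrix,
which is identical in law to the explicit factor-plus-specific
construction). Per-environment variances are scaled exactly, like the
error components, and environment means added. Users can equally supply
their own genetic-value table in the same long layout (`genotype`, `env`,
`gv.Trait1`, ...).

`make_phenotypes()` allocates the genotypes to plots by an RCBD — an
independent uniform permutation of the genotype set within every
environment × block — and sets `y = gv + e_total` per trait, joining on
plot coordinates rather than row order. Setting the genetic variance to
$h^2/(1-h^2)$ times the total error variance yields data with plot-level
heritability $h^2$; this is the construction behind the worked example
(yield: $h^2 = 0.3$, height: $h^2 = 0.5$).

## Evaluation metrics

`sample_variogram()` computes, for each absolute displacement pair, the
mean of half the squared differences over all plot pairs at that
displacement (folding the two diagonal directions), with pair counts and
the customary "more than 30 pairs" display filter. `expected_accuracy()`
gives the correlation between a genotype's true value and its `b`-replicate
mean under the balanced model, $\sqrt{b h^2 / (1 + (b-1) h^2)}$ — 0.68 at
$h^2 = 0.3$, $b = 2$ — and `shrunken_genotype_means()` provides the
corresponding minimal predictor (centred genotype means shrunk by
$b\sigma^2_g/(b\sigma^2_g + \sigma^2_\varepsilon)$) so that realised
accuracies can be computed without a mixed-model engine. We validated the
closed form against the Monte-Carlo accuracy of this predictor on the
worked example configuration (500 replicates agree within ±0.02).
`prediction_accuracy()`, `variance_bias()` (estimated minus true), and
`plot_level_heritability()` complete the metric set. Full spatial
mixed-model fitting (AR1/spline REML, model selection) is deliberately out
of scope: the simulator's role is to provide data with known truth to
whatever analysis engine the user prefers.

## Worked example

The package's running example evaluates 100 maize hybrids for grain yield
(t/ha) and plant height (cm) in three environments. Environments 1 and 2
are 10 × 20 fields with two side-by-side column blocks of 5 × 20 plots;
environment 3 is 15 × 20 with three such blocks; plots are 8 m × 2 m, so
environment 1 spans 80 m × 40 m.

```{r example, eval = FALSE}
err <- field_trial_error(
  ntraits = 2, nenvs = 3, nblocks = c(2, 2, 3),
  ncols = c(10, 10, 15), nrows = 20, block.dir = "col",
  varR = c(0.20, 0.28, 0.14, 15.1, 8.5, 11.7),
  spatial.model = "bivariate", complexity = 10,
  plot.length = 8, plot.width = 2,
  prop.spatial = 0.4, prop.ext = 0.2,
  ext.ord = "zig-zag", ext.dir = "row", seed = 42)

gv <- simulate_gv(
  ngenos = 100, ntraits = 2, nenvs = 3,
  mean = c(4.0, 4.4, 4.2, 230, 240, 235),
  var = c(0.0857, 0.12, 0.06, 15.1, 8.5, 11.7),
  model = "unstructured",
  env.cor = matrix(c(1, .6, .4, .6, 1, .5, .4, .5, 1), 3), seed = 42)

pheno <- make_phenotypes(gv, err, randomise = TRUE, seed = 42)
plot_effects(pheno, "y.Trait1", env = 1)
```

The same run is available declaratively: the YAML config shipped at
`system.file("extdata", "example_trial.yaml", package = "fieldtrialsim")`
reproduces it via `run_simulation()`, writing the error, genetic-value and
phenotype CSVs, per-environment variograms, heatmaps, a metrics report,
and a manifest with the config hash and seed.

## Numerical choices and degenerate inputs

* Knot sets are triangulated with an incremental Delaunay construction;
  collinear/degenerate sets (possible in principle, vanishing probability
  under uniform sampling) and flat interpolated surfaces trigger knot
  resampling, capped at 10 attempts.
* Plot averaging uses a `grid.res = 5` centred subgrid (25 points per
  plot) by default; `grid.res = 1` evaluates at the plot centre. A
  symmetric subgrid reproduces planar surfaces exactly at the plot centre,
  which is what the tests exploit.
* Zero-variance components short-circuit to zero vectors; no division by
  zero can occur in the scaling.
* Correlation matrices are validated (symmetry, unit diagonal, PSD with
  tolerance 1e-8); matrices on the PSD boundary (e.g. a compound-symmetry
  correlation of exactly 1) receive a 1e-8 diagonal jitter before
  factorisation, so "no GxE" holds to ~1e-4 rather than exactly.
* CSV writers print doubles with 17 significant digits, making write/read
  round trips lossless.

## What the simulation does and does not establish

The generator emulates the spatial structure of real trials — smooth
trend surfaces, autoregressive neighbour correlation, column/row-aligned
management stripes, and GxE-correlated genetic values — under exactly
known variances. It does not emulate heavy-tailed or skewed errors,
missing plots or non-rectangular fields, interplot competition (a
negative neighbour correlation users can approximate by negating
alternate row errors), time trends within the harvest order, or
marker-level genetics. Conclusions drawn from it about analysis methods
therefore concern their behaviour under Gaussian, variance-exact
conditions; robustness questions need different generators. Default test
and acceptance problem sizes (a 200-plot environment; 100–500 replicates
for Monte-Carlo recoveries) were chosen so the full suite runs in a few
minutes while keeping Monte-Carlo error well inside the stated
tolerances.
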