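# fieldtrialsim

Simulation of realistic plot data for single- and multi-environment
plant-breeding field trials, for anyone who needs trial data with *known
truth*: breeders and biometricians comparing experimental designs, spatial
analysis models, or multi-environment testing strategies, and teachers of
spatial modelling.

Field-trial phenotypes carry strong non-genetic structure. `fieldtrialsim`
generates the plot errors of each environment *j* (plots serialised rows
within columns) as the sum of three mutually independent components,

    ε_j = s_j + r_j + e_j

* **s_j — spatial trend**: either a piecewise-linear surface interpolated
  over random knots (4 corner knots outside the field plus a `complexity`
  number of interior knots; few knots → global trend, many → local trend),
  averaged within each plot; or a separable first-order autoregressive
  process with covariance `σ²_s · Σ_col(ρ_c) ⊗ Σ_row(ρ_r)`.
* **r_j — random error**: iid plot-level noise.
* **e_j — extraneous variation**: column/row-aligned effects expanded
  through `Z_c = I_c ⊗ 1_r` and `Z_r = 1_c ⊗ I_r`, optionally with zig-zag
  ordering (positive values in odd, negative in even rows/columns — the
  signature of serpentine harvesting and similar practices).

The user sets the total error variance `varR` per trait-environment pair
and the proportions `prop.spatial` and `prop.ext`; the remainder is random
error (defaults 0.5 / 0 / 0.5). Every component is rescaled so its sample
variance per environment equals its share *exactly* in each realisation.
Genetic values with genotype-by-environment interaction (unstructured,
compound-symmetry, or multiplicative one-factor models, plus optional
trait correlation) are simulated separately, and phenotypes are assembled
under a randomised complete block design as `y = gv + ε`. Evaluation
helpers cover the sample variogram, plot-level heritability
`h² = σ²_g / (σ²_g + σ²_ε)`, expected accuracy
`√(b·h² / (1 + (b−1)·h²))` of b-replicate genotype means, realised
prediction accuracy, and genetic-variance bias.

## Worked example

100 maize hybrids, grain yield (t/ha), one environment: a 10 × 20 field
(8 m × 2 m plots, so 80 m × 40 m) with two side-by-side column blocks of
100 plots. Total error variance 0.20, of which 40% spatial (interpolation,
complexity 10), 20% extraneous (zig-zag rows), 40% random; genetic
variance set to `0.3/0.7 × 0.20 ≈ 0.0857` for a plot-level heritability
of 0.3.

```r
library(fieldtrialsim)

err <- field_trial_error(ntraits = 1, nenvs = 1, nblocks = 2,
  ncols = 10, nrows = 20, varR = 0.20,
  spatial.model = "bivariate", complexity = 10,
  plot.length = 8, plot.width = 2,
  prop.spatial = 0.4, prop.ext = 0.2,
  ext.ord = "zig-zag", ext.dir = "row", seed = 42)
var(err$e.spatial.Trait1)  # 0.08 -- exactly 0.4 * 0.20, every run

var_g <- genetic_variance_for_h2(0.3, 0.20)
gv <- simulate_gv(100, mean = 4, var = var_g, seed = 42)
ph <- make_phenotypes(gv, err, seed = 42)
head(ph, 3)
#>   env block col row genotype gv.Trait1 e.Trait1 y.Trait1
#> 1   1     1   1   1       57      4.03   -0.220     3.81
#> 2   1     1   1   2       46      3.83   -0.342     3.49
#> 3   1     1   1   3       86      4.15    0.979     5.13

pred <- shrunken_genotype_means(ph$y.Trait1, ph$genotype, var_g, 0.20)
tg <- gv[order(gv$genotype), ]
prediction_accuracy(tg$gv.Trait1, as.numeric(pred))  # 0.697
expected_accuracy(0.3, 2)                            # 0.679
```

The realised accuracy of the shrunken genotype means (0.697 for this
seed) scatters around the analytic expectation 0.68. The zig-zag
extraneous rows show up in the variogram as higher semivariance at odd
than at adjacent even row displacements:

```r
vg <- sample_variogram(err, "e.total.Trait1")
vg[vg$col.disp == 0 & vg$row.disp %in% 1:4, ]
#>    col.disp row.disp semivariance n.pairs filtered
#>           0        1        0.159     190    FALSE
#>           0        2        0.130     180    FALSE
#>           0        3        0.173     170    FALSE
#>           0        4        0.162     160    FALSE
```

`plot_effects(ph, "y.Trait1")` renders any per-plot column as a field
heatmap. For scripted use, a YAML config
(`inst/extdata/example_trial.yaml` holds the full three-environment,
two-trait example) drives the whole pipeline:

```sh
Rscript exec/fieldtrialsim run --config inst/extdata/example_trial.yaml --out out/
```

writing plot errors, genetic values, phenotypes, variograms, heatmaps, a
metrics report, and a manifest (seed + config hash) — byte-identical when
re-run with the same seed.

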