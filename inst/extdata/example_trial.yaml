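# Worked example: 100 maize hybrids, two traits (grain yield t/ha, plant
# height cm), three environments; total error variances chosen so that
# plot-level h2 is 0.3 for yield and 0.5 for height in every environment.
seed: 42
error:
  ntraits: 2
  nenvs: 3
  nblocks: [2, 2, 3]
  ncols: [10, 10, 15]
  nrows: 20
  block.dir: col
  varR: [0.20, 0.28, 0.14, 15.1, 8.5, 11.7]
  spatial.model: bivariate
  complexity: 10
  plot.length: 8
  plot.width: 2
  prop.spatial: 0.4
  prop.ext: 0.2
  ext.ord: zig-zag
  ext.dir: row
genetics:
  ngenos: 100
  model: unstructured
  mean: [4.0, 4.4, 4.2, 230, 240, 235]
  # genetic variances h2/(1-h2) * varR per environment-within-trait
  var: [0.0857, 0.12, 0.06, 15.1, 8.5, 11.7]
  env.cor:
    - [1.0, 0.6, 0.4]
    - [0.6, 1.0, 0.5]
    - [0.4, 0.5, 1.0]
  trait.cor:
    - [1.0, 0.3]
    - [0.3, 1.0]
phenotypes:
  randomise: true
evaluation:
  variogram: [y.Trait1]
  heatmaps: [e.total.Trait1]
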