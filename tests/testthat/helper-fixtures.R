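# Shared fixtures: the worked example used throughout the package docs is a
# maize trial with 100 hybrids, 2 traits, 3 environments; environment 1 is a
# 10 x 20 field with two side-by-side column blocks of 5 x 20 plots.

example_layout <- function() {
  field_layout(nenvs = 3, ncols = c(10, 10, 15), nrows = 20,
               nblocks = c(2, 2, 3), block.dir = "col",
               plot.length = 8, plot.width = 2)
}

env1_layout <- function() {
  field_layout(nenvs = 1, ncols = 10, nrows = 20, nblocks = 2,
               block.dir = "col", plot.length = 8, plot.width = 2)
}

# single-environment version of the example error configuration
# (trait 1: total error variance 0.20, 40% spatial / 20% extraneous)
env1_error <- function(seed, ...) {
  field_trial_error(ntraits = 1, nenvs = 1, nblocks = 2, ncols = 10,
                    nrows = 20, varR = 0.20, spatial.model = "bivariate",
                    complexity = 10, plot.length = 8, plot.width = 2,
                    prop.spatial = 0.4, prop.ext = 0.2,
                    ext.ord = "zig-zag", ext.dir = "row", seed = seed, ...)
}

# brute-force Delaunay validity: every triangle's circumcircle must be
# empty of the remaining points (the defining property, checked directly)
expect_delaunay <- function(pts, tris) {
  for (i in seq_len(nrow(tris))) {
    tri <- tris[i, ]
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    expect_gt(abs(d), 1e-12)
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    others <- setdiff(seq_len(nrow(pts)), tri)
    dist2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    expect_true(all(dist2 >= r2 * (1 - 1e-9)),
                label = sprintf("circumcircle of triangle %d is empty", i))
  }
}
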