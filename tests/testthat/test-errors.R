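test_that("random errors hit the requested variance exactly", {
  lay <- env1_layout()
  set.seed(1)
  r <- random_error(lay, 1, var.r = 0.08)
  expect_equal(var(r[, 1]), 0.08, tolerance = 1e-14)
  expect_equal(mean(r[, 1]), 0, tolerance = 1e-14)
  r0 <- random_error(lay, 1, var.r = 0)
  expect_equal(unname(r0[, 1]), rep(0, 200))
  r2 <- random_error(lay, 1, var.r = 0.08)
  expect_false(isTRUE(all.equal(r[, 1], r2[, 1])))  # fresh draw
})

test_that("variance proportions are honoured exactly per component", {
  err <- env1_error(seed = 42)
  expect_equal(var(err$e.spatial.Trait1), 0.4 * 0.20, tolerance = 1e-12)
  expect_equal(var(err$e.random.Trait1), 0.4 * 0.20, tolerance = 1e-12)
  expect_equal(var(err$e.ext.Trait1), 0.2 * 0.20, tolerance = 1e-12)
  # additivity is exact per record
  expect_equal(err$e.total.Trait1,
               err$e.spatial.Trait1 + err$e.random.Trait1 + err$e.ext.Trait1)
})

test_that("default proportions are half spatial, no extraneous", {
  err <- field_trial_error(nenvs = 1, ncols = 6, nrows = 8, nblocks = 2,
                           varR = 1, seed = 7)
  p <- attr(err, "params")
  expect_equal(p$prop.spatial, 0.5)
  expect_equal(p$prop.ext, 0)
  expect_equal(p$prop.random, 0.5)
  expect_equal(var(err$e.spatial.Trait1), 0.5, tolerance = 1e-12)
  expect_equal(unname(err$e.ext.Trait1), rep(0, 48))
})

test_that("degenerate proportions zero out the other components", {
  err <- field_trial_error(nenvs = 1, ncols = 6, nrows = 8, nblocks = 2,
                           varR = 1, prop.spatial = 1, prop.ext = 0, seed = 8)
  expect_equal(unname(err$e.random.Trait1), rep(0, 48))
  expect_equal(unname(err$e.ext.Trait1), rep(0, 48))
  expect_equal(err$e.total.Trait1, err$e.spatial.Trait1)
  expect_error(
    field_trial_error(nenvs = 1, varR = 1, prop.spatial = 0.7, prop.ext = 0.4),
    "prop")
})

test_that("varR is flattened trait-major across environments", {
  err <- field_trial_error(ntraits = 2, nenvs = 3, nblocks = c(2, 2, 3),
                           ncols = c(10, 10, 15), nrows = 20,
                           varR = c(0.20, 0.28, 0.14, 15.1, 8.5, 11.7),
                           prop.spatial = 0.4, prop.ext = 0.2, seed = 9)
  targets <- matrix(c(0.20, 0.28, 0.14, 15.1, 8.5, 11.7), 2, 3, byrow = TRUE)
  for (t in 1:2) for (j in 1:3) {
    tot <- err[err$env == j, paste0("e.spatial.Trait", t)]
    expect_equal(var(tot), 0.4 * targets[t, j], tolerance = 1e-10)
  }
  expect_error(field_trial_error(ntraits = 2, nenvs = 3, varR = c(1, 2, 3, 4)),
               "varR")
})

test_that("variance bookkeeping identity holds for the total error", {
  err <- env1_error(seed = 10)
  s <- err$e.spatial.Trait1; r <- err$e.random.Trait1; x <- err$e.ext.Trait1
  lhs <- var(s + r + x)
  rhs <- var(s) + var(r) + var(x) +
    2 * (cov(s, r) + cov(s, x) + cov(r, x))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("mean total error variance is close to varR across replicates", {
  vars <- vapply(1:60, function(i) var(env1_error(seed = 1000 + i)$e.total.Trait1),
                 numeric(1))
  expect_lt(abs(mean(vars) - 0.20) / 0.20, 0.05)
})

test_that("trait correlations are imposed on the right random variables", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  # random component: plot-level correlation is direct
  err <- field_trial_error(ntraits = 2, nenvs = 1, ncols = 50, nrows = 200,
                           nblocks = 2, varR = 1, prop.spatial = 0,
                           prop.ext = 0, R.random = R, seed = 11)
  expect_lt(abs(cor(err$e.random.Trait1, err$e.random.Trait2) - 0.8), 0.03)
  # interpolation spatial component: correlation applies to the knot
  # z-values on a shared knot set; plot-level correlation is emergent
  err <- field_trial_error(ntraits = 2, nenvs = 1, ncols = 10, nrows = 20,
                           nblocks = 2, varR = 1, prop.spatial = 1,
                           prop.ext = 0, complexity = 200, R.spatial = R,
                           seed = 12)
  kn <- attr(err, "knots")[[1]]
  expect_equal(ncol(kn$z), 2L)  # both traits share one knot set
  expect_lt(abs(cor(kn$z[, 1], kn$z[, 2]) - 0.8), 0.05)
  expect_gt(cor(err$e.spatial.Trait1, err$e.spatial.Trait2), 0)
  # identity correlation leaves draws untouched
  e_id <- field_trial_error(ntraits = 2, nenvs = 1, ncols = 6, nrows = 8,
                            varR = 1, prop.spatial = 0, R.random = diag(2),
                            seed = 13)
  e_no <- field_trial_error(ntraits = 2, nenvs = 1, ncols = 6, nrows = 8,
                            varR = 1, prop.spatial = 0, seed = 13)
  expect_equal(e_id$e.random.Trait2, e_no$e.random.Trait2)
  expect_error(
    field_trial_error(ntraits = 2, nenvs = 1, varR = 1,
                      R.random = matrix(c(1, 2, 2, 1), 2)),
    "R.random")
})

test_that("environments are independent and adding a trait is stable", {
  # same trait, different environments: pooled correlation near zero
  set.seed(14)
  pairs <- vapply(1:300, function(i) {
    err <- field_trial_error(ntraits = 1, nenvs = 2, ncols = 4, nrows = 5,
                             nblocks = 1, varR = 1, prop.spatial = 0,
                             seed = 20000 + i)
    c(err$e.total.Trait1[err$env == 1][1], err$e.total.Trait1[err$env == 2][1])
  }, numeric(2))
  expect_lt(abs(cor(pairs[1, ], pairs[2, ])), 0.1)

  # substream contract: trait 1 errors identical with 1 or 2 traits
  e1 <- env1_error(seed = 77)
  e2 <- field_trial_error(ntraits = 2, nenvs = 1, nblocks = 2, ncols = 10,
                          nrows = 20, varR = c(0.20, 15.1),
                          spatial.model = "bivariate", complexity = 10,
                          prop.spatial = 0.4, prop.ext = 0.2,
                          ext.ord = "zig-zag", ext.dir = "row", seed = 77)
  expect_equal(e1$e.total.Trait1, e2$e.total.Trait1)
})

test_that("environment correlation induces cross-environment dependence", {
  Re <- matrix(c(1, 0.9, 0.9, 1), 2)
  err <- field_trial_error(ntraits = 1, nenvs = 2, ncols = 20, nrows = 50,
                           nblocks = 2, varR = 1, prop.spatial = 0,
                           prop.ext = 0, R.env = Re, seed = 15)
  r <- cor(err$e.random.Trait1[err$env == 1],
           err$e.random.Trait1[err$env == 2])
  expect_gt(r, 0.8)
  expect_error(
    field_trial_error(ntraits = 1, nenvs = 2, ncols = c(4, 5), nrows = 5,
                      nblocks = 1, varR = 1, R.env = Re),
    "identical lattice")
})
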