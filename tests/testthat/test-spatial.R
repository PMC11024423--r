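test_that("default complexity is half the larger lattice dimension, rounded up", {
  expect_identical(default_complexity(10, 20), 10L)
  expect_identical(default_complexity(1, 1), 1L)
  expect_identical(default_complexity(6, 6), 3L)
  expect_identical(default_complexity(20, 10), 10L)
  expect_identical(default_complexity(7, 3), 4L)
})

test_that("knot sampling places 4 corners outside and interior knots inside", {
  lay <- env1_layout()
  set.seed(11)
  kn <- sample_knots(lay, 1, complexity = 0)
  expect_equal(nrow(kn$positions), 4L)
  kn <- sample_knots(lay, 1)  # default complexity for 10 x 20 is 10
  expect_equal(nrow(kn$positions), 14L)
  # corners strictly outside the 80 x 40 rectangle
  corners <- kn$positions[1:4, ]
  expect_true(all(corners[, 1] < 0 | corners[, 1] > 80 |
                    corners[, 2] < 0 | corners[, 2] > 40))
  # interior positions always within the field over many draws
  for (i in 1:200) {
    kn <- sample_knots(lay, 1, complexity = 25)
    inner <- kn$positions[-(1:4), ]
    expect_true(all(inner[, 1] >= 0 & inner[, 1] <= 80 &
                      inner[, 2] >= 0 & inner[, 2] <= 40))
  }
})

test_that("the triangulation satisfies the empty-circumcircle property", {
  lay <- env1_layout()
  for (seed in 1:5) {
    set.seed(seed)
    kn <- sample_knots(lay, 1, complexity = 12)
    expect_delaunay(kn$positions, kn$triangles)
  }
})

test_that("interpolation is exact at knots, for constants, and for planes", {
  lay <- env1_layout()
  set.seed(4)
  kn <- sample_knots(lay, 1, complexity = 8)
  # constant surface
  kn$z[, 1] <- 3.5
  v <- interpolate_surface(kn, runif(50, 0, 80), runif(50, 0, 40))
  expect_equal(unname(v[, 1]), rep(3.5, 50))
  # planar surface reproduced to machine precision
  kn$z[, 1] <- 0.7 + 0.03 * kn$positions[, 1] - 0.11 * kn$positions[, 2]
  qx <- runif(100, 0, 80); qy <- runif(100, 0, 40)
  expect_equal(unname(v <- interpolate_surface(kn, qx, qy)[, 1]),
               0.7 + 0.03 * qx - 0.11 * qy, tolerance = 1e-12)
  # exact at the knot locations themselves
  at_knots <- interpolate_surface(kn, kn$positions[, 1], kn$positions[, 2])
  expect_equal(unname(at_knots[, 1]), unname(kn$z[, 1]), tolerance = 1e-12)
})

test_that("plot averaging integrates the surface over each plot", {
  lay <- env1_layout()
  set.seed(5)
  kn <- sample_knots(lay, 1, complexity = 6)
  idx <- plot_index(lay, 1)
  # constant surface -> every plot equal
  kn$z[, 1] <- -1.25
  expect_equal(unname(plot_average(kn, lay, 1)[, 1]), rep(-1.25, 200))
  # planar surface -> plot average equals the plane at the plot centre,
  # for any resolution (symmetric quadrature of a linear function)
  kn$z[, 1] <- 2 - 0.05 * kn$positions[, 1] + 0.02 * kn$positions[, 2]
  plane_at_centre <- 2 - 0.05 * idx$x_centre + 0.02 * idx$y_centre
  for (res in c(1, 2, 5)) {
    expect_equal(unname(plot_average(kn, lay, 1, grid.res = res)[, 1]),
                 plane_at_centre, tolerance = 1e-10)
  }
})

test_that("interpolated spatial errors hit the requested variance exactly", {
  lay <- env1_layout()
  set.seed(21)
  s <- spatial_error_interp(lay, 1, var.s = 0.08, complexity = 10)
  expect_equal(nrow(s), 200L)
  expect_equal(var(s[, 1]), 0.08, tolerance = 1e-12)
  expect_equal(mean(s[, 1]), 0, tolerance = 1e-12)
  # zero variance short-circuits to zeros
  s0 <- spatial_error_interp(lay, 1, var.s = 0)
  expect_equal(unname(s0[, 1]), rep(0, 200))
})

test_that("higher complexity yields more local trend", {
  lay <- env1_layout()
  idx <- plot_index(lay, 1)
  # mean |difference| between row-neighbours within a column
  neighbour_diff <- function(s) {
    m <- matrix(s[order(idx$ordinal)], nrow = 20)
    mean(abs(diff(m)))
  }
  set.seed(31)
  lo <- replicate(100, neighbour_diff(
    spatial_error_interp(lay, 1, var.s = 1, complexity = 0, grid.res = 2)[, 1]))
  hi <- replicate(100, neighbour_diff(
    spatial_error_interp(lay, 1, var.s = 1, complexity = 50, grid.res = 2)[, 1]))
  expect_gt(mean(hi), mean(lo))
})

test_that("AR1 correlation matrices have the power structure and are PD", {
  expect_equal(ar1_cor(3, 0), diag(3))
  expect_equal(ar1_cor(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  for (n in 2:8) for (rho in c(-0.9, -0.3, 0.4, 0.95)) {
    ev <- eigen(ar1_cor(n, rho), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(ar1_cor(3, 1), "rho")
})

test_that("factorised AR1 sampling equals explicit full-covariance Cholesky", {
  for (dims in list(c(3, 3), c(4, 4), c(2, 4))) {
    nc <- dims[1]; nr <- dims[2]
    set.seed(nc * 10 + nr)
    z <- rnorm(nc * nr)
    fact <- fieldtrialsim:::.ar1_draw(nc, nr, 0.45, 0.7, z)[, 1]
    Sc <- ar1_cor(nc, 0.45); Sr <- ar1_cor(nr, 0.7)
    full <- as.vector(t(chol(Sc %x% Sr)) %*% z)
    expect_equal(fact, full, tolerance = 1e-12)
  }
})

test_that("unscaled AR1 draws reproduce the separable covariance", {
  # empirical covariance of the raw sampling route on a 3 x 3 lattice
  nc <- 3L; nr <- 3L; ndraw <- 200000L
  set.seed(99)
  Z <- matrix(rnorm(nc * nr * ndraw), nrow = nc * nr)
  S <- fieldtrialsim:::.ar1_draw(nc, nr, 0.4, 0.6, Z)
  emp <- tcrossprod(S) / ndraw
  target <- ar1_cor(nc, 0.4) %x% ar1_cor(nr, 0.6)
  expect_lt(max(abs(emp - target)), 0.01)
})

test_that("scaled AR1 errors keep exact variance and recover autocorrelation", {
  lay <- env1_layout()
  set.seed(17)
  s <- spatial_error_ar1(lay, 1, var.s = 0.08, rho.col = 0.7, rho.row = 0.9)
  expect_equal(var(s[, 1]), 0.08, tolerance = 1e-12)

  lag1_row <- function(s) {
    m <- matrix(s, nrow = 20)
    cor(as.vector(m[-20, ]), as.vector(m[-1, ]))
  }
  set.seed(18)
  # autocorrelation is invariant to the variance rescaling
  r_high <- mean(replicate(500, lag1_row(
    spatial_error_ar1(lay, 1, 1, rho.col = 0.7, rho.row = 0.9)[, 1])))
  expect_lt(abs(r_high - 0.9), 0.05)
  r_zero <- mean(replicate(200, lag1_row(
    spatial_error_ar1(lay, 1, 1, rho.col = 0, rho.row = 0)[, 1])))
  expect_lt(abs(r_zero), 0.05)
})
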