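test_that("variogram semivariances match hand enumeration", {
  # constant field: all zero
  df <- expand.grid(col = 1:3, row = 1:4)
  df$v <- 5
  vg <- sample_variogram(df, "v")
  expect_true(all(vg$semivariance == 0))

  # 2 x 2 field, values 1..4 rows-within-columns:
  # (0,1) pairs are (1,2) and (3,4): 0.5 * mean(1, 1) = 0.5
  df <- data.frame(col = c(1, 1, 2, 2), row = c(1, 2, 1, 2), v = 1:4)
  vg <- sample_variogram(df, "v")
  g <- function(dc, dr) vg$semivariance[vg$col.disp == dc & vg$row.disp == dr]
  expect_equal(g(0, 1), 0.5)
  expect_equal(g(1, 0), 2)      # pairs (1,3), (2,4): 0.5 * mean(4, 4)
  expect_equal(g(1, 1), 2.5)    # both diagonals: 0.5 * mean(9, 1)
  expect_equal(g(0, 0), 0)
})

test_that("alternating row pattern produces the zig-zag signature", {
  df <- expand.grid(col = 1:6, row = 1:10)
  a <- 0.37
  df$v <- ifelse(df$row %% 2 == 1, a, -a)
  vg <- sample_variogram(df, "v")
  odd <- vg$semivariance[vg$col.disp == 0 & vg$row.disp %in% c(1, 3, 5)]
  even <- vg$semivariance[vg$col.disp == 0 & vg$row.disp %in% c(2, 4, 6)]
  expect_equal(odd, rep(2 * a^2, 3))  # closed form: half of (2a)^2
  expect_equal(even, rep(0, 3))
})

test_that("pair counts follow lattice combinatorics and the 30-pair filter", {
  for (dims in list(c(3, 3), c(4, 3), c(4, 4))) {
    nc <- dims[1]; nr <- dims[2]
    df <- expand.grid(col = seq_len(nc), row = seq_len(nr))
    set.seed(nc + 10 * nr)
    df$v <- rnorm(nrow(df))
    vg <- sample_variogram(df, "v")
    # brute-force pair enumeration
    n <- nrow(df)
    brute <- array(0L, dim = c(nc, nr))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dc <- abs(df$col[i] - df$col[j]); dr <- abs(df$row[i] - df$row[j])
      brute[dc + 1, dr + 1] <- brute[dc + 1, dr + 1] + 1L
    }
    for (k in seq_len(nrow(vg))) {
      if (vg$col.disp[k] == 0 && vg$row.disp[k] == 0) next
      expect_equal(vg$n.pairs[k], brute[vg$col.disp[k] + 1, vg$row.disp[k] + 1])
    }
    # totals: all unordered pairs plus the n self-pairs at (0,0)
    expect_equal(sum(vg$n.pairs), n * (n - 1) / 2 + n)
  }
  df <- expand.grid(col = 1:10, row = 1:20)
  df$v <- seq_len(200)
  vg <- sample_variogram(df, "v")
  expect_true(all(vg$filtered == (vg$n.pairs <= 30)))
})

test_that("variogram of the transposed lattice swaps displacement axes", {
  df <- expand.grid(col = 1:5, row = 1:7)
  set.seed(3)
  df$v <- rnorm(35)
  vg <- sample_variogram(df, "v")
  tdf <- data.frame(col = df$row, row = df$col, v = df$v)
  tvg <- sample_variogram(tdf, "v")
  key <- function(x) x[order(x$col.disp, x$row.disp), ]
  a <- key(vg)
  b <- tvg[, c("row.disp", "col.disp", "semivariance", "n.pairs")]
  names(b)[1:2] <- c("col.disp", "row.disp")
  b <- key(b)
  expect_equal(a$semivariance, b$semivariance)
  expect_equal(a$n.pairs, b$n.pairs)
})

test_that("expected accuracy has the closed form and is monotone", {
  expect_equal(round(expected_accuracy(0.3, 2), 2), 0.68)
  expect_equal(expected_accuracy(1, 5), 1)
  expect_equal(expected_accuracy(0.5, 1), sqrt(0.5))
  h <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(expected_accuracy(h, 3)) > 0))
  expect_true(all(diff(vapply(1:6, expected_accuracy, numeric(1),
                              h2 = 0.3)) > 0))
})

test_that("shrunken genotype means behave at the variance extremes", {
  set.seed(4)
  y <- rnorm(30)
  g <- rep(1:10, each = 3)
  # no error: predictions are the centred genotype means
  pred <- shrunken_genotype_means(y, g, var.g = 1, var.e = 0)
  expect_equal(as.numeric(pred),
               as.numeric(tapply(y, g, mean)) - mean(y))
  # no genetic variance: all predictions zero
  pred0 <- shrunken_genotype_means(y, g, var.g = 0, var.e = 1)
  expect_equal(as.numeric(pred0), rep(0, 10))
  expect_error(shrunken_genotype_means(y[-1], g[-30], 1, 1), "unbalanced")
})

test_that("prediction accuracy is Pearson correlation with guard rails", {
  expect_equal(prediction_accuracy(1:5, 1:5), 1)
  expect_equal(prediction_accuracy(1:5, -(1:5)), -1)
  expect_equal(prediction_accuracy(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_error(prediction_accuracy(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("bias and heritability helpers use the reporting conventions", {
  expect_equal(variance_bias(0.061, 0.087), -0.026)
  expect_equal(variance_bias(0.084, 0.087), -0.003)
  expect_equal(variance_bias(2, 2), 0)
  expect_equal(plot_level_heritability(0.087, 0.20), 0.303, tolerance = 0.002)
  expect_equal(plot_level_heritability(3, 0), 1)
  expect_error(plot_level_heritability(0, 0), "undefined")
  expect_equal(genetic_variance_for_h2(0.5, 15.1), 15.1)
  expect_equal(genetic_variance_for_h2(0.3, 0.20), 0.3 / 0.7 * 0.20)
})
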