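#' Default spatial-trend complexity
#'
#' The number of interior knot points used by the interpolation spatial
#' model defaults to half the maximum of the column and row counts, rounded
#' up, e.g. 10 knots for a 10 x 20 field. More knots shift the simulated
#' trend from global (field-wide gradients) towards local (plot-to-plot)
#' variation.
#'
#' @param ncols,nrows Lattice dimensions.
#' @return Integer knot count, `ceiling(max(ncols, nrows) / 2)`.
#' @examples
#' default_complexity(10, 20)  # 10
#' @export
default_complexity <- function(ncols, nrows) {
  stopifnot(ncols >= 1, nrows >= 1)
  as.integer(ceiling(max(ncols, nrows) / 2))
}

#' Sample interpolation knots for one environment
#'
#' Places four knots just outside the corners of the continuous field array
#' (offset by half a plot length/width, preventing boundary artefacts in the
#' interpolated surface) plus `complexity` interior knots sampled uniformly
#' over the field rectangle. Each knot carries one standard-normal z-value
#' per trait; when `R.spatial` is given, trait correlation is imposed on
#' these z-values (the interpolated surface itself is a deterministic
#' function of the knots, so the knots are the random variables).
#'
#' @param layout A [field_layout()].
#' @param env Environment number.
#' @param complexity Interior knot count; `NULL` uses
#'   [default_complexity()].
#' @param ntraits Number of traits.
#' @param R.spatial Optional trait correlation matrix applied to the knot
#'   z-values.
#' @param corner.mult Corner offset in units of half a plot
#'   length/width (default 1).
#' @return An object of class `knot_set`: list with `positions`
#'   ((4 + complexity) x 2 matrix, corners first), `z`
#'   (knots x traits matrix), `triangles` (Delaunay triangle vertex
#'   indices), and the field extent.
#' @export
sample_knots <- function(layout, env = 1, complexity = NULL, ntraits = 1,
                         R.spatial = NULL, corner.mult = 1) {
  e <- .layout_env(layout, env)
  if (is.null(complexity)) complexity <- default_complexity(e$ncols, e$nrows)
  stopifnot(complexity >= 0, ntraits >= 1)
  pos <- .knot_positions(e, complexity, corner.mult)
  z <- matrix(stats::rnorm(nrow(pos) * ntraits), ncol = ntraits)
  if (!is.null(R.spatial)) z <- z %*% t(.chol_lower(R.spatial, "R.spatial"))
  .knot_set(pos, z, e)
}

.knot_positions <- function(e, complexity, corner.mult = 1) {
  dx <- corner.mult * e$plot.length / 2
  dy <- corner.mult * e$plot.width / 2
  corners <- rbind(
    c(-dx, -dy), c(e$length + dx, -dy),
    c(e$length + dx, e$width + dy), c(-dx, e$width + dy))
  inner <- if (complexity > 0) {
    cbind(stats::runif(complexity, 0, e$length),
          stats::runif(complexity, 0, e$width))
  }
  pos <- rbind(corners, inner)
  colnames(pos) <- c("x", "y")
  pos
}

.knot_set <- function(pos, z, e) {
  z <- as.matrix(z)
  colnames(z) <- paste0("Trait", seq_len(ncol(z)))
  structure(list(positions = pos, z = z, ncorner = 4L,
                 triangles = .delaunay(pos),
                 length = e$length, width = e$width),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat(sprintf("Knot set: %d knots (4 corner + %d interior), %d trait(s), field %g m x %g m\n",
              nrow(x$positions), nrow(x$positions) - 4L, ncol(x$z),
              x$length, x$width))
  invisible(x)
}

#' Evaluate the interpolated trend surface
#'
#' Piecewise-linear (barycentric) interpolation of the knot z-values on a
#' Delaunay triangulation of the knot positions, evaluated at arbitrary
#' field coordinates. The surface is continuous, exact at the knots, and
#' reproduces planar fields exactly.
#'
#' @param knots A [sample_knots()] object.
#' @param x,y Query coordinates in metres (equal length).
#' @return Matrix `length(x)` x ntraits of surface values.
#' @export
interpolate_surface <- function(knots, x, y) {
  stopifnot(inherits(knots, "knot_set"), length(x) == length(y))
  bw <- .bary_weights(knots$positions, knots$triangles, x, y)
  v <- .bary_eval(bw, knots$z)
  colnames(v) <- colnames(knots$z)
  v
}

#' Average a trend surface within each plot
#'
#' Assigns a single value per plot by averaging the interpolated surface
#' over a centred `grid.res` x `grid.res` subgrid inside each plot
#' rectangle (`grid.res = 1` evaluates at the plot centre). Plots are
#' returned in rows-within-columns order.
#'
#' @param knots A [sample_knots()] object.
#' @param layout A [field_layout()].
#' @param env Environment number.
#' @param grid.res Subgrid resolution per plot side (default 5, i.e. a
#'   25-point quadrature).
#' @return Matrix nplots x ntraits of per-plot averages.
#' @export
plot_average <- function(knots, layout, env = 1, grid.res = 5) {
  e <- .layout_env(layout, env)
  stopifnot(grid.res >= 1)
  idx <- plot_index(layout, env)
  off_x <- ((seq_len(grid.res) - 0.5) / grid.res - 0.5) * e$plot.length
  off_y <- ((seq_len(grid.res) - 0.5) / grid.res - 0.5) * e$plot.width
  # query points grouped by plot: grid.res^2 consecutive points per plot
  gx <- rep(off_x, each = grid.res)
  gy <- rep(off_y, times = grid.res)
  qx <- rep(idx$x_centre, each = grid.res^2) + rep(gx, times = nrow(idx))
  qy <- rep(idx$y_centre, each = grid.res^2) + rep(gy, times = nrow(idx))
  v <- interpolate_surface(knots, qx, qy)
  out <- apply(v, 2L, function(col) {
    colMeans(matrix(col, nrow = grid.res^2))
  })
  out <- matrix(out, ncol = ncol(v), dimnames = list(NULL, colnames(v)))
  out
}

# exact sample-variance scaling: centre to mean 0 and rescale so that
# var(x) == v (denominator n - 1). Returns NULL when the input carries no
# signal (degenerate), which callers treat as "resample".
.scale_exact <- function(x, v) {
  if (v < 0) stop("variance must be >= 0", call. = FALSE)
  if (v == 0) return(rep(0, length(x)))
  x <- x - mean(x)
  sv <- stats::var(x)
  if (!is.finite(sv) || sv < .Machine$double.eps) return(NULL)
  x * sqrt(v / sv)
}

#' Spatial error by bivariate interpolation
#'
#' Simulates the spatial (global/local trend) error vector for one
#' environment: knots are sampled, the piecewise-linear surface is
#' interpolated and averaged within plots, and the plot values are centred
#' and rescaled so their sample variance equals `var.s` exactly. Degenerate
#' knot sets (a flat surface) trigger resampling, up to `max.tries`.
#'
#' @inheritParams sample_knots
#' @param var.s Spatial error variance per trait (recycled).
#' @param grid.res Per-plot quadrature resolution, see [plot_average()].
#' @param max.tries Resampling cap for degenerate surfaces.
#' @return Matrix nplots x ntraits in rows-within-columns order, with the
#'   accepted `knot_set` attached as attribute `"knots"`.
#' @export
spatial_error_interp <- function(layout, env = 1, var.s = 1, complexity = NULL,
                                 ntraits = 1, R.spatial = NULL, grid.res = 5,
                                 max.tries = 10) {
  var.s <- rep_len(var.s, ntraits)
  for (try in seq_len(max.tries)) {
    knots <- sample_knots(layout, env, complexity, ntraits, R.spatial)
    vals <- plot_average(knots, layout, env, grid.res)
    scaled <- .scale_columns(vals, var.s)
    if (!is.null(scaled)) {
      attr(scaled, "knots") <- knots
      return(scaled)
    }
  }
  stop(sprintf("degenerate interpolation surface after %d attempts", max.tries),
       call. = FALSE)
}

# scale each column to its target variance; NULL if any column degenerate
.scale_columns <- function(vals, v) {
  out <- vals
  for (k in seq_len(ncol(vals))) {
    s <- .scale_exact(vals[, k], v[k])
    if (is.null(s)) return(NULL)
    out[, k] <- s
  }
  out
}

#' First-order autoregressive correlation matrix
#'
#' @param n Dimension.
#' @param rho Autocorrelation, `abs(rho) < 1`.
#' @return n x n matrix with entries `rho^|i - k|`.
#' @examples
#' ar1_cor(3, 0.5)
#' @export
ar1_cor <- function(n, rho) {
  stopifnot(n >= 1)
  if (abs(rho) >= 1) stop("autocorrelation must satisfy |rho| < 1", call. = FALSE)
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

# Separable AR1 transform of pre-drawn standard normals.
# z: nplots-vector or nplots x k matrix in rows-within-columns order;
# returns the correlated field(s) vec(L_r Z L_c') with covariance
# Sigma_c (x) Sigma_r (row index fastest).
.ar1_draw <- function(ncols, nrows, rho.col, rho.row, z) {
  Lc <- t(chol(ar1_cor(ncols, rho.col)))
  Lr <- t(chol(ar1_cor(nrows, rho.row)))
  z <- as.matrix(z)
  out <- apply(z, 2L, function(col) {
    as.vector(Lr %*% matrix(col, nrow = nrows) %*% t(Lc))
  })
  matrix(out, ncol = ncol(z), dimnames = dimnames(z))
}

#' Spatial error by a separable AR1 process
#'
#' Simulates the spatial error vector for one environment as a draw from a
#' zero-mean Gaussian field with separable correlation
#' `Sigma_col(rho.col) %x% Sigma_row(rho.row)` (row index fastest,
#' matching the rows-within-columns plot ordering), realised through the
#' factor-wise Cholesky transform. The draw is then centred and rescaled to
#' sample variance `var.s` exactly, consistent with the interpolation
#' model. Plot dimensions are not used: distance enters only through the
#' lattice autocorrelations.
#'
#' @inheritParams spatial_error_interp
#' @param rho.col,rho.row Column and row autocorrelations, `|rho| < 1`.
#' @return Matrix nplots x ntraits in rows-within-columns order.
#' @export
spatial_error_ar1 <- function(layout, env = 1, var.s = 1,
                              rho.col = 0.5, rho.row = 0.5,
                              ntraits = 1, R.spatial = NULL) {
  e <- .layout_env(layout, env)
  var.s <- rep_len(var.s, ntraits)
  z <- matrix(stats::rnorm(e$nplots * ntraits), ncol = ntraits)
  if (!is.null(R.spatial)) z <- z %*% t(.chol_lower(R.spatial, "R.spatial"))
  vals <- .ar1_draw(e$ncols, e$nrows, rho.col, rho.row, z)
  scaled <- .scale_columns(vals, var.s)
  if (is.null(scaled))
    stop("degenerate AR1 draw (zero variance)", call. = FALSE)
  colnames(scaled) <- paste0("Trait", seq_len(ntraits))
  scaled
}

# lower-triangular Cholesky factor of a correlation matrix, with validation
.chol_lower <- function(R, name) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || any(abs(R - t(R)) > 1e-8) ||
      any(abs(diag(R) - 1) > 1e-8))
    stop(sprintf("`%s` must be a symmetric correlation matrix with unit diagonal",
                 name), call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("`%s` is not positive semi-definite", name), call. = FALSE)
  if (min(ev) < 1e-10) R <- R + diag(1e-8, nrow(R))  # PSD boundary
  t(chol(R))
}
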