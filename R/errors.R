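#' Random (plot-level noise) error for one environment
#'
#' Independent normal noise per plot, centred and rescaled so the sample
#' variance equals `var.r` exactly.
#'
#' @param layout A [field_layout()].
#' @param env Environment number.
#' @param var.r Random error variance per trait (recycled).
#' @param ntraits Number of traits.
#' @param R.random Optional trait correlation matrix.
#' @return Matrix nplots x ntraits in rows-within-columns order.
#' @export
random_error <- function(layout, env = 1, var.r = 1, ntraits = 1,
                         R.random = NULL) {
  e <- .layout_env(layout, env)
  var.r <- rep_len(var.r, ntraits)
  z <- matrix(stats::rnorm(e$nplots * ntraits), ncol = ntraits)
  if (!is.null(R.random)) z <- correlate_traits(z, R.random, "R.random")
  scaled <- .scale_columns(z, var.r)
  if (is.null(scaled))
    stop("degenerate random draw (zero variance)", call. = FALSE)
  colnames(scaled) <- paste0("Trait", seq_len(ntraits))
  scaled
}

#' Impose a trait correlation on independent draws
#'
#' Applies the lower-triangular Cholesky factor of a trait correlation
#' matrix to columns of independent standard-normal draws. Because the
#' factor is lower triangular, appending a trait never alters the mixed
#' values of the existing traits.
#'
#' @param z Matrix of draws, one column per trait.
#' @param R Trait correlation matrix (symmetric, unit diagonal, PSD).
#' @param name Matrix name used in error messages.
#' @return Matrix of correlated draws, same shape as `z`.
#' @export
correlate_traits <- function(z, R, name = "R") {
  z <- as.matrix(z)
  L <- .chol_lower(R, name)
  if (ncol(z) != nrow(L))
    stop(sprintf("`%s` has order %d but there are %d traits",
                 name, nrow(L), ncol(z)), call. = FALSE)
  out <- z %*% t(L)
  dimnames(out) <- dimnames(z)
  out
}

# varR argument -> ntraits x nenvs matrix (trait-major flattening:
# trait 1's environments first, matching the documented argument order)
.varR_matrix <- function(varR, ntraits, nenvs) {
  if (is.list(varR)) varR <- as.numeric(unlist(varR))
  if (any(varR < 0)) stop("`varR` must be >= 0", call. = FALSE)
  if (length(varR) == 1L) {
    m <- matrix(varR, ntraits, nenvs)
  } else if (length(varR) == ntraits) {
    m <- matrix(rep(varR, each = nenvs), ntraits, nenvs, byrow = TRUE)
  } else if (length(varR) == ntraits * nenvs) {
    m <- matrix(varR, ntraits, nenvs, byrow = TRUE)
  } else {
    stop(sprintf(
      "`varR` must have length 1, ntraits (%d), or ntraits * nenvs (%d), got %d",
      ntraits, ntraits * nenvs, length(varR)), call. = FALSE)
  }
  m
}

#' Simulate plot errors for a multi-environment trial
#'
#' The core simulator: composes, for every environment and trait, a total
#' plot error `e_total = e_spatial + e_random + e_ext` from
#' \itemize{
#'   \item a spatial trend component (bivariate interpolation over random
#'     knots, or a separable AR1 process),
#'   \item independent random noise, and
#'   \item extraneous column/row-aligned variation,
#' }
#' at user-defined variance proportions. With total error variance
#' `varR` for a trait-environment pair, the spatial component receives
#' `prop.spatial * varR`, the extraneous component `prop.ext * varR`, and
#' the random component the remaining proportion
#' `1 - prop.spatial - prop.ext`. By default half the variance is spatial
#' and none is extraneous. Each component's plot-level sample variance is
#' scaled exactly to its share, so the realised variance decomposition
#' matches the prescription in every run.
#'
#' `varR` is flattened trait-major: for 2 traits in 3 environments,
#' `c(t1e1, t1e2, t1e3, t2e1, t2e2, t2e3)`.
#'
#' Trait correlation matrices can be supplied separately for the three
#' components. For the interpolation spatial model the correlation is
#' imposed on the knot z-values (the random variables of that model), on a
#' knot set shared between traits; plot-level spatial correlation is then
#' emergent. When `R.env` is supplied, a separable environment-by-trait
#' correlation structure is used; this requires all environments to share
#' the same lattice dimensions, and under the interpolation model the knot
#' positions are then also shared across environments.
#'
#' Randomness is consumed through per-(environment, trait, component)
#' substreams derived from `seed`, so e.g. adding a second trait does not
#' perturb the first trait's errors.
#'
#' @param ntraits,nenvs Numbers of traits and environments.
#' @param nblocks,ncols,nrows,block.dir,plot.length,plot.width Field
#'   geometry, see [field_layout()]. Ignored when `layout` is given.
#' @param varR Total plot error variance(s), trait-major (length 1,
#'   ntraits, or ntraits * nenvs).
#' @param spatial.model `"bivariate"` (interpolation) or `"AR1"`.
#' @param complexity Interior knot count for the interpolation model;
#'   `NULL` uses [default_complexity()] per environment.
#' @param rho.col,rho.row AR1 autocorrelations (AR1 model only).
#' @param prop.spatial,prop.ext Proportions of `varR` assigned to the
#'   spatial and extraneous components (scalar or per environment);
#'   their sum must not exceed 1.
#' @param ext.ord Extraneous ordering, `"zig-zag"` or `"random"`.
#' @param ext.dir Extraneous direction, `"row"`, `"col"`, or `"both"`.
#' @param R.spatial,R.random,R.ext Optional trait correlation matrices per
#'   component (default: independent traits).
#' @param R.env Optional environment correlation matrix (default:
#'   independent environments).
#' @param grid.res Per-plot quadrature resolution for the interpolation
#'   model, see [plot_average()].
#' @param layout Optional pre-built [field_layout()].
#' @param seed Integer seed; `NULL` draws one from the session RNG.
#'
#' @return A data.frame of class `plot_error_df` with one row per
#'   environment x plot: `env`, `block`, `col`, `row`, then per trait `k`
#'   the columns `e.spatial.Traitk`, `e.random.Traitk`, `e.ext.Traitk`,
#'   `e.total.Traitk`. The generating parameters are attached as attribute
#'   `"params"` and the accepted knot sets (interpolation model) as
#'   attribute `"knots"`.
#'
#' @examples
#' err <- field_trial_error(ntraits = 2, nenvs = 3, nblocks = c(2, 2, 3),
#'                          ncols = c(10, 10, 15), nrows = 20,
#'                          varR = c(0.20, 0.28, 0.14, 15.1, 8.5, 11.7),
#'                          spatial.model = "bivariate", complexity = 10,
#'                          plot.length = 8, plot.width = 2,
#'                          prop.spatial = 0.4, prop.ext = 0.2,
#'                          ext.ord = "zig-zag", ext.dir = "row", seed = 1)
#' nrow(err)  # 200 + 200 + 300 plots
#' var(err$e.spatial.Trait1[err$env == 1])  # exactly 0.4 * 0.20
#' @export
field_trial_error <- function(ntraits = 1, nenvs = 1, nblocks = 2,
                              ncols = 10, nrows = 20,
                              block.dir = c("col", "row"), varR = 1,
                              spatial.model = c("bivariate", "AR1"),
                              complexity = NULL,
                              plot.length = 8, plot.width = 2,
                              rho.col = 0.5, rho.row = 0.5,
                              prop.spatial = 0.5, prop.ext = 0,
                              ext.ord = c("zig-zag", "random"),
                              ext.dir = c("row", "col", "both"),
                              R.spatial = NULL, R.random = NULL,
                              R.ext = NULL, R.env = NULL,
                              grid.res = 5, layout = NULL, seed = NULL) {
  spatial.model <- match.arg(tolower(spatial.model[1L]), c("bivariate", "ar1"))
  ext.ord <- match.arg(ext.ord)
  ext.dir <- match.arg(ext.dir)
  if (is.null(layout)) {
    block.dir <- match.arg(block.dir)
    layout <- field_layout(nenvs, ncols, nrows, nblocks, block.dir,
                           plot.length, plot.width)
  }
  nenvs <- layout$nenvs
  ntraits <- as.integer(ntraits)
  stopifnot(ntraits >= 1)

  vr <- .varR_matrix(varR, ntraits, nenvs)
  prop.spatial <- rep_len(prop.spatial, nenvs)
  prop.ext <- rep_len(prop.ext, nenvs)
  if (any(prop.spatial < 0) || any(prop.ext < 0) ||
      any(prop.spatial + prop.ext > 1 + 1e-12))
    stop("`prop.spatial` + `prop.ext` must lie in [0, 1]", call. = FALSE)
  prop.random <- 1 - prop.spatial - prop.ext

  seed <- .resolve_seed(seed)
  shared_env <- !is.null(R.env)
  if (shared_env) {
    dims <- vapply(layout$envs, function(e) c(e$ncols, e$nrows), numeric(2))
    if (any(dims != dims[, 1L]))
      stop("`R.env` requires identical lattice dimensions in all environments",
           call. = FALSE)
    L_env <- .chol_lower(R.env, "R.env")
    if (nrow(L_env) != nenvs)
      stop(sprintf("`R.env` has order %d but there are %d environments",
                   nrow(L_env), nenvs), call. = FALSE)
  }

  # draw a units x (env x trait) matrix of standard normals, one substream
  # per (env, trait) column, then impose the separable correlation
  draw_block <- function(n_units, comp, Rt) {
    z <- matrix(0, n_units, nenvs * ntraits)
    for (t in seq_len(ntraits)) {
      for (j in seq_len(nenvs)) {
        z[, (t - 1L) * nenvs + j] <- .with_seed(
          .substream_seed(seed, j, .COMP[[comp]], t), stats::rnorm(n_units))
      }
    }
    Lt <- if (!is.null(Rt)) .chol_lower(Rt, paste0("R.", comp)) else diag(ntraits)
    Le <- if (shared_env) L_env else diag(nenvs)
    z %*% t(Lt %x% Le)  # columns trait-major: (t1 e1..ep, t2 e1..ep, ...)
  }
  col_of <- function(t, j) (t - 1L) * nenvs + j

  env_tables <- vector("list", nenvs)
  knot_sets <- vector("list", nenvs)

  # ---- spatial component ------------------------------------------------
  spat <- vector("list", nenvs)  # nplots x ntraits matrices
  if (spatial.model == "bivariate") {
    Lt <- if (!is.null(R.spatial)) .chol_lower(R.spatial, "R.spatial")
    for (try in 0:9) {
      ok <- TRUE
      for (j in seq_len(nenvs)) {
        e <- layout$envs[[j]]
        cx <- if (is.null(complexity)) default_complexity(e$ncols, e$nrows)
              else complexity
        pos_env <- if (shared_env) 0L else j
        pos <- .with_seed(.substream_seed(seed, pos_env, .COMP[["knot_pos"]],
                                          0L, try),
                          .knot_positions(e, cx))
        nk <- nrow(pos)
        z <- matrix(0, nk, ntraits)
        for (t in seq_len(ntraits))
          z[, t] <- .with_seed(.substream_seed(seed, j, .COMP[["knot_z"]],
                                               t, try),
                               stats::rnorm(nk))
        if (shared_env) {
          # redraw all env x trait z-values on the shared knots and mix
          zz <- matrix(0, nk, nenvs * ntraits)
          for (t in seq_len(ntraits)) for (jj in seq_len(nenvs))
            zz[, col_of(t, jj)] <- .with_seed(
              .substream_seed(seed, jj, .COMP[["knot_z"]], t, try),
              stats::rnorm(nk))
          Ltm <- if (is.null(Lt)) diag(ntraits) else Lt
          zz <- zz %*% t(Ltm %x% L_env)
          z <- zz[, col_of(seq_len(ntraits), j), drop = FALSE]
        } else if (!is.null(Lt)) {
          z <- z %*% t(Lt)
        }
        knots <- .knot_set(pos, z, e)
        vals <- plot_average(knots, layout, j, grid.res)
        scaled <- .scale_columns(vals, prop.spatial[j] * vr[, j])
        if (is.null(scaled)) { ok <- FALSE; break }
        spat[[j]] <- scaled
        knot_sets[[j]] <- knots
      }
      if (ok) break
      if (try == 9L)
        stop("degenerate interpolation surface after 10 attempts",
             call. = FALSE)
    }
  } else {  # AR1
    nplots <- vapply(layout$envs, `[[`, integer(1), "nplots")
    if (shared_env) {
      z <- draw_block(nplots[1L], "ar1", R.spatial)
    }
    for (j in seq_len(nenvs)) {
      e <- layout$envs[[j]]
      if (shared_env) {
        zj <- z[, col_of(seq_len(ntraits), j), drop = FALSE]
      } else {
        zj <- matrix(0, e$nplots, ntraits)
        for (t in seq_len(ntraits))
          zj[, t] <- .with_seed(.substream_seed(seed, j, .COMP[["ar1"]], t),
                                stats::rnorm(e$nplots))
        if (!is.null(R.spatial)) zj <- correlate_traits(zj, R.spatial, "R.spatial")
      }
      vals <- .ar1_draw(e$ncols, e$nrows, rho.col, rho.row, zj)
      scaled <- .scale_columns(vals, prop.spatial[j] * vr[, j])
      if (is.null(scaled))
        stop("degenerate AR1 draw (zero variance)", call. = FALSE)
      spat[[j]] <- scaled
    }
  }

  # ---- random component -------------------------------------------------
  rand <- vector("list", nenvs)
  if (shared_env && length(unique(vapply(layout$envs, `[[`, integer(1),
                                         "nplots"))) == 1L) {
    z <- draw_block(layout$envs[[1L]]$nplots, "random", R.random)
    for (j in seq_len(nenvs))
      rand[[j]] <- .scale_columns(z[, col_of(seq_len(ntraits), j),
                                    drop = FALSE],
                                  prop.random[j] * vr[, j])
  } else {
    for (j in seq_len(nenvs)) {
      e <- layout$envs[[j]]
      zj <- matrix(0, e$nplots, ntraits)
      for (t in seq_len(ntraits))
        zj[, t] <- .with_seed(.substream_seed(seed, j, .COMP[["random"]], t),
                              stats::rnorm(e$nplots))
      if (!is.null(R.random)) zj <- correlate_traits(zj, R.random, "R.random")
      rand[[j]] <- .scale_columns(zj, prop.random[j] * vr[, j])
    }
  }

  # ---- extraneous component ----------------------------------------------
  ext <- vector("list", nenvs)
  Lx <- if (!is.null(R.ext)) .chol_lower(R.ext, "R.ext")
  for (j in seq_len(nenvs)) {
    e <- layout$envs[[j]]
    var_e <- prop.ext[j] * vr[, j]
    if (all(var_e == 0)) {
      ext[[j]] <- matrix(0, e$nplots, ntraits)
      next
    }
    if (ext.dir == "both" && (e$ncols < 2L || e$nrows < 2L))
      stop(sprintf(
        "environment %d: ext.dir = \"both\" needs at least 2 columns and 2 rows",
        j), call. = FALSE)
    draw_dim <- function(n, comp) {
      zz <- matrix(0, n, ntraits)
      for (t in seq_len(ntraits))
        zz[, t] <- .with_seed(.substream_seed(seed, j, .COMP[[comp]], t),
                              stats::rnorm(n))
      if (!is.null(Lx)) zz <- zz %*% t(Lx)
      zz
    }
    ec <- if (ext.dir %in% c("col", "both")) draw_dim(e$ncols, "ext_col")
    er <- if (ext.dir %in% c("row", "both")) draw_dim(e$nrows, "ext_row")
    out <- matrix(0, e$nplots, ntraits)
    for (t in seq_len(ntraits)) {
      out[, t] <- .with_seed(
        .substream_seed(seed, j, .COMP[["ext_order"]], t),
        .ext_assemble(e, if (!is.null(ec)) ec[, t, drop = FALSE],
                      if (!is.null(er)) er[, t, drop = FALSE],
                      ext.ord, var_e[t]))
    }
    ext[[j]] <- out
  }

  # ---- assemble ----------------------------------------------------------
  for (j in seq_len(nenvs)) {
    idx <- plot_index(layout, j)
    tab <- idx[, c("env", "block", "col", "row")]
    for (t in seq_len(ntraits)) {
      s <- spat[[j]][, t]; r <- rand[[j]][, t]; x <- ext[[j]][, t]
      tab[[paste0("e.spatial.Trait", t)]] <- s
      tab[[paste0("e.random.Trait", t)]] <- r
      tab[[paste0("e.ext.Trait", t)]] <- x
      tab[[paste0("e.total.Trait", t)]] <- s + r + x
    }
    env_tables[[j]] <- tab
  }
  out <- do.call(rbind, env_tables)
  rownames(out) <- NULL
  attr(out, "params") <- list(
    ntraits = ntraits, nenvs = nenvs, varR = vr,
    spatial.model = spatial.model, complexity = complexity,
    rho.col = rho.col, rho.row = rho.row,
    prop.spatial = prop.spatial, prop.ext = prop.ext,
    prop.random = prop.random,
    ext.ord = ext.ord, ext.dir = ext.dir, grid.res = grid.res, seed = seed)
  attr(out, "knots") <- knot_sets
  class(out) <- c("plot_error_df", "data.frame")
  out
}
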