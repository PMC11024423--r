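#' Implied genetic correlation between environments
#'
#' The three genotype-by-environment (GxE) models used by [simulate_gv()]
#' all reduce to a p x p genetic correlation matrix between environments:
#' \describe{
#'   \item{unstructured}{the user-supplied matrix itself;}
#'   \item{compound_symmetry}{a common correlation on all off-diagonals;}
#'   \item{multiplicative}{a one-factor structure with loadings
#'     `lambda`: off-diagonal (j, k) equals `lambda[j] * lambda[k]`, the
#'     unit diagonal being completed by environment-specific variance.}
#' }
#'
#' @param model `"unstructured"`, `"compound_symmetry"`, or
#'   `"multiplicative"`.
#' @param nenvs Number of environments p.
#' @param env.cor Correlation matrix (unstructured) or scalar common
#'   correlation (compound symmetry).
#' @param loadings Length-p loading vector in `[-1, 1]` (multiplicative).
#' @return p x p correlation matrix.
#' @examples
#' implied_env_correlation("multiplicative", 2, loadings = c(0.9, 0.6))
#' @export
implied_env_correlation <- function(model = c("unstructured",
                                              "compound_symmetry",
                                              "multiplicative"),
                                    nenvs, env.cor = NULL, loadings = NULL) {
  model <- match.arg(model)
  nenvs <- as.integer(nenvs)
  switch(model,
    unstructured = {
      if (is.null(env.cor)) stop("unstructured model needs `env.cor`",
                                 call. = FALSE)
      R <- as.matrix(env.cor)
      if (nrow(R) != nenvs)
        stop(sprintf("`env.cor` has order %d but nenvs = %d", nrow(R), nenvs),
             call. = FALSE)
      R
    },
    compound_symmetry = {
      if (is.null(env.cor) || length(env.cor) != 1L)
        stop("compound symmetry needs a scalar `env.cor`", call. = FALSE)
      if (abs(env.cor) > 1) stop("|env.cor| must be <= 1", call. = FALSE)
      R <- matrix(env.cor, nenvs, nenvs)
      diag(R) <- 1
      R
    },
    multiplicative = {
      if (is.null(loadings) || length(loadings) != nenvs)
        stop("multiplicative model needs length-p `loadings`", call. = FALSE)
      if (any(abs(loadings) > 1))
        stop("|loadings| must be <= 1", call. = FALSE)
      R <- tcrossprod(loadings)
      diag(R) <- 1
      R
    })
}

#' Simulate true genetic values across environments and traits
#'
#' Draws genotype effects from a zero-mean multivariate normal over the
#' (environment x trait) grid with the separable covariance
#' `R_trait %x% R_env` implied by the chosen GxE model, scales each
#' environment-within-trait column so its sample variance over genotypes
#' equals `var` exactly (consistent with the plot-error scaling contract),
#' and shifts by the environment means. Cross-environment and cross-trait
#' correlations are unaffected by the scaling and are recovered only in
#' expectation.
#'
#' With perfect environment correlation and equal variances the model
#' degenerates to "no GxE": every genotype takes the same value in every
#' environment.
#'
#' @param ngenos Number of genotypes.
#' @param ntraits,nenvs Numbers of traits and environments.
#' @param mean Genetic means, trait-major (length 1, ntraits, or
#'   ntraits * nenvs).
#' @param var Genetic variances per environment-within-trait, trait-major
#'   (length 1, ntraits, or ntraits * nenvs).
#' @param model GxE model, see [implied_env_correlation()].
#' @param env.cor,loadings Parameters of the GxE model.
#' @param R.gtrait Optional trait correlation matrix (default independent).
#' @param seed Integer seed; `NULL` draws one from the session RNG.
#' @return A data.frame with one row per genotype x environment:
#'   `genotype`, `env`, and `gv.Trait1` ... `gv.TraitK` (the long layout
#'   consumed by [make_phenotypes()]).
#' @examples
#' gv <- simulate_gv(ngenos = 100, ntraits = 2, nenvs = 3,
#'                   mean = c(4, 4.2, 4.1, 230, 240, 235),
#'                   var = c(0.086, 0.12, 0.06, 15.1, 8.5, 11.7),
#'                   model = "unstructured",
#'                   env.cor = matrix(c(1, .5, .4, .5, 1, .6, .4, .6, 1), 3),
#'                   seed = 42)
#' head(gv)
#' @export
simulate_gv <- function(ngenos, ntraits = 1, nenvs = 1, mean = 0, var = 1,
                        model = c("unstructured", "compound_symmetry",
                                  "multiplicative"),
                        env.cor = NULL, loadings = NULL, R.gtrait = NULL,
                        seed = NULL) {
  model <- match.arg(model)
  ngenos <- as.integer(ngenos)
  stopifnot(ngenos >= 1, ntraits >= 1, nenvs >= 1)
  if (nenvs == 1L && is.null(env.cor) && is.null(loadings)) {
    R_env <- matrix(1, 1, 1)
  } else {
    R_env <- implied_env_correlation(model, nenvs, env.cor, loadings)
  }
  mu <- matrix(.flatten_tm(mean, ntraits, nenvs), ntraits, nenvs, byrow = TRUE)
  vg <- .varR_matrix(.flatten_tm(var, ntraits, nenvs), ntraits, nenvs)

  seed <- .resolve_seed(seed)
  L_env <- .chol_lower(R_env, "env.cor")
  L_trait <- if (!is.null(R.gtrait)) .chol_lower(R.gtrait, "R.gtrait")
             else diag(ntraits)

  # columns trait-major: (t1 e1..ep, t2 e1..ep, ...)
  z <- matrix(0, ngenos, ntraits * nenvs)
  for (t in seq_len(ntraits)) for (j in seq_len(nenvs))
    z[, (t - 1L) * nenvs + j] <- .with_seed(
      .substream_seed(seed, j, .COMP[["gv"]], t), stats::rnorm(ngenos))
  g <- z %*% t(L_trait %x% L_env)

  out <- data.frame(
    genotype = rep(seq_len(ngenos), times = nenvs),
    env = rep(seq_len(nenvs), each = ngenos))
  for (t in seq_len(ntraits)) {
    col <- rep(NA_real_, ngenos * nenvs)
    for (j in seq_len(nenvs)) {
      gj <- g[, (t - 1L) * nenvs + j]
      if (ngenos >= 2L) {
        s <- .scale_exact(gj, vg[t, j])
        if (is.null(s)) s <- rep(0, ngenos)  # vg == 0 handled in .scale_exact
      } else {
        s <- rep(0, ngenos)
      }
      col[(j - 1L) * ngenos + seq_len(ngenos)] <- s + mu[t, j]
    }
    out[[paste0("gv.Trait", t)]] <- col
  }
  attr(out, "params") <- list(ngenos = ngenos, ntraits = ntraits,
                              nenvs = nenvs, mean = mu, var = vg,
                              model = model, R.env = R_env, seed = seed)
  class(out) <- c("gv_df", "data.frame")
  out
}

# trait-major flattening of a scalar / per-trait / full-length vector
.flatten_tm <- function(x, ntraits, nenvs) {
  if (is.list(x)) x <- as.numeric(unlist(x))
  if (length(x) == 1L) rep(x, ntraits * nenvs)
  else if (length(x) == ntraits) rep(x, each = nenvs)
  else if (length(x) == ntraits * nenvs) x
  else stop(sprintf(
    "expected length 1, ntraits (%d), or ntraits * nenvs (%d), got %d",
    ntraits, ntraits * nenvs, length(x)), call. = FALSE)
}
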