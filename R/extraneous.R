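#' Zig-zag ordering of simulated values
#'
#' Reorders a vector so that positive values sit at odd positions and
#' negative values at even positions, as far as the sign counts allow; any
#' surplus of either sign fills the remaining positions at random, and the
#' order within each sign is randomised. Applied to column or row errors,
#' this mimics the systematic alternating pattern induced by management
#' practices such as serpentine harvesting or spraying. The output is always
#' a permutation of the input, so the value multiset (and hence variance) is
#' unchanged.
#'
#' @param x Numeric vector.
#' @return A permutation of `x`.
#' @export
zigzag_order <- function(x) {
  n <- length(x)
  stopifnot(n >= 1)
  pos <- x[x > 0]
  neg <- x[x <= 0]
  if (length(pos) > 1) pos <- sample(pos)
  if (length(neg) > 1) neg <- sample(neg)
  odd <- seq(1L, n, by = 2L)
  even <- if (n >= 2L) seq(2L, n, by = 2L) else integer(0)
  out <- rep(NA_real_, n)
  npos <- min(length(pos), length(odd))
  nneg <- min(length(neg), length(even))
  if (npos > 0) out[odd[seq_len(npos)]] <- pos[seq_len(npos)]
  if (nneg > 0) out[even[seq_len(nneg)]] <- neg[seq_len(nneg)]
  left <- c(pos[seq_len(length(pos)) > npos], neg[seq_len(length(neg)) > nneg])
  slots <- which(is.na(out))
  if (length(slots)) {
    if (length(slots) > 1) left <- sample(left)
    out[slots] <- left
  }
  out
}

# expand column/row-level errors to the plot vector
# (rows-within-columns order): Z_c = I_c (x) 1_r, Z_r = 1_c (x) I_r
.expand_col <- function(ec, nrows) rep(ec, each = nrows)
.expand_row <- function(er, ncols) rep(er, times = ncols)

# Assemble one environment's extraneous errors from pre-drawn standard
# normals. ec/er: ncols x k / nrows x k matrices (or NULL). Each dimension's
# draws are mean-centred before ordering so that variance scaling (which is
# multiplicative after centring) cannot flip the sign-by-parity pattern.
# When both dimensions are present the total variance is split equally:
# each expanded component is scaled to var.e/2 before summing, and the sum
# is then rescaled to total sample variance var.e exactly. Returns an
# nplots x k matrix.
.ext_assemble <- function(e, ec, er, ordering, var.e) {
  k <- if (!is.null(ec)) ncol(ec) else ncol(er)
  both <- !is.null(ec) && !is.null(er)
  out <- matrix(0, e$nplots, k)
  for (t in seq_len(k)) {
    share <- if (both) var.e[t] / 2 else var.e[t]
    v <- rep(0, e$nplots)
    if (!is.null(ec)) {
      x <- ec[, t] - mean(ec[, t])
      if (ordering == "zig-zag") x <- zigzag_order(x)
      comp <- .scale_exact(.expand_col(x, e$nrows), share)
      if (is.null(comp))
        stop("degenerate extraneous column draw (zero variance)", call. = FALSE)
      v <- v + comp
    }
    if (!is.null(er)) {
      x <- er[, t] - mean(er[, t])
      if (ordering == "zig-zag") x <- zigzag_order(x)
      comp <- .scale_exact(.expand_row(x, e$ncols), share)
      if (is.null(comp))
        stop("degenerate extraneous row draw (zero variance)", call. = FALSE)
      v <- v + comp
    }
    s <- .scale_exact(v, var.e[t])
    if (is.null(s))
      stop("degenerate extraneous draw (zero variance)", call. = FALSE)
    out[, t] <- s
  }
  colnames(out) <- paste0("Trait", seq_len(k))
  out
}

#' Extraneous (column/row-aligned) error for one environment
#'
#' Simulates errors constant within columns and/or rows of the lattice:
#' column- and row-level normal deviates are expanded to plots through the
#' design matrices `I_c %x% 1_r` and `1_c %x% I_r`, optionally arranged in a
#' zig-zag (sign alternating with column/row parity) or left in random
#' order, and finally centred and rescaled so the plot-level sample variance
#' equals `var.e` exactly. With `direction = "both"` the total variance is
#' split equally between the column and row components.
#'
#' @param layout A [field_layout()].
#' @param env Environment number.
#' @param var.e Total extraneous error variance per trait (recycled).
#' @param direction `"col"`, `"row"`, or `"both"`.
#' @param ordering `"zig-zag"` or `"random"`.
#' @param ntraits Number of traits.
#' @param R.ext Optional trait correlation matrix applied to the underlying
#'   column/row draws (before ordering).
#' @return Matrix nplots x ntraits in rows-within-columns order.
#' @export
extraneous_error <- function(layout, env = 1, var.e = 1,
                             direction = c("row", "col", "both"),
                             ordering = c("zig-zag", "random"),
                             ntraits = 1, R.ext = NULL) {
  direction <- match.arg(direction)
  ordering <- match.arg(ordering)
  e <- .layout_env(layout, env)
  var.e <- rep_len(var.e, ntraits)
  if (direction == "both" && (e$ncols < 2L || e$nrows < 2L))
    stop("direction = \"both\" needs at least 2 columns and 2 rows",
         call. = FALSE)
  if (all(var.e == 0)) {
    out <- matrix(0, e$nplots, ntraits,
                  dimnames = list(NULL, paste0("Trait", seq_len(ntraits))))
    return(out)
  }
  L <- if (!is.null(R.ext)) .chol_lower(R.ext, "R.ext")
  draw <- function(n) {
    z <- matrix(stats::rnorm(n * ntraits), ncol = ntraits)
    if (!is.null(L)) z <- z %*% t(L)
    z
  }
  ec <- if (direction %in% c("col", "both")) draw(e$ncols)
  er <- if (direction %in% c("row", "both")) draw(e$nrows)
  .ext_assemble(e, ec, er, ordering, var.e)
}
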