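#' Construct a multi-environment field layout
#'
#' Defines the two-dimensional plot lattice of each environment in a
#' multi-environment trial: number of columns and rows, the block structure,
#' and the physical plot dimensions. Each environment `j` is a complete
#' rectangular lattice of `ncols[j] * nrows[j]` plots, partitioned into
#' `nblocks[j]` contiguous equal-sized blocks aligned side-by-side in the
#' column direction (`block.dir = "col"`) or stacked in the row direction
#' (`block.dir = "row"`).
#'
#' Scalar arguments are recycled across environments, so heterogeneous
#' layouts such as `nblocks = c(2, 2, 3)` with `ncols = c(10, 10, 15)` and a
#' common `nrows = 20` are expressed directly.
#'
#' Plot dimensions are only required by the interpolation-based spatial
#' model, which works on the continuous field array; the separable AR1 model
#' ignores them because distance enters only through the lattice
#' autocorrelations.
#'
#' @param nenvs Number of environments (p).
#' @param ncols,nrows Columns and rows per environment (scalar or length-p).
#' @param nblocks Complete blocks per environment (scalar or length-p).
#' @param block.dir `"col"` for side-by-side blocks along the column
#'   direction (the blocked dimension is then the columns), `"row"` for
#'   blocks stacked along the row direction.
#' @param plot.length Plot length in metres, measured in the column
#'   direction.
#' @param plot.width Plot width in metres, measured in the row direction.
#'
#' @return An object of class `field_layout`: a list with one entry per
#'   environment holding `ncols`, `nrows`, `nblocks`, `nplots`,
#'   `block.dir`, `plot.length`, `plot.width`, and the field extent in
#'   metres (`length = ncols * plot.length`, `width = nrows * plot.width`).
#'
#' @examples
#' lay <- field_layout(nenvs = 3, ncols = c(10, 10, 15), nrows = 20,
#'                     nblocks = c(2, 2, 3), plot.length = 8, plot.width = 2)
#' lay
#' head(plot_index(lay, env = 1))
#' @export
field_layout <- function(nenvs = 1, ncols = 10, nrows = 20, nblocks = 2,
                         block.dir = c("col", "row"),
                         plot.length = 8, plot.width = 2) {
  block.dir <- match.arg(block.dir)
  nenvs <- as.integer(nenvs)
  if (length(nenvs) != 1L || is.na(nenvs) || nenvs < 1L)
    stop("`nenvs` must be a single integer >= 1", call. = FALSE)
  ncols <- .recycle_int(ncols, nenvs, "ncols")
  nrows <- .recycle_int(nrows, nenvs, "nrows")
  nblocks <- .recycle_int(nblocks, nenvs, "nblocks")
  if (!is.numeric(plot.length) || plot.length <= 0 ||
      !is.numeric(plot.width) || plot.width <= 0)
    stop("`plot.length` and `plot.width` must be positive", call. = FALSE)

  envs <- vector("list", nenvs)
  for (j in seq_len(nenvs)) {
    blocked <- if (block.dir == "col") ncols[j] else nrows[j]
    if (blocked %% nblocks[j] != 0L)
      stop(sprintf(
        "environment %d: %s (%d) not divisible by nblocks (%d)",
        j, if (block.dir == "col") "ncols" else "nrows", blocked, nblocks[j]),
        call. = FALSE)
    envs[[j]] <- list(
      env = j,
      ncols = ncols[j], nrows = nrows[j], nblocks = nblocks[j],
      nplots = ncols[j] * nrows[j],
      block.dir = block.dir,
      plot.length = plot.length, plot.width = plot.width,
      length = ncols[j] * plot.length,
      width = nrows[j] * plot.width
    )
  }
  structure(list(nenvs = nenvs, envs = envs, block.dir = block.dir,
                 plot.length = plot.length, plot.width = plot.width),
            class = "field_layout")
}

.recycle_int <- function(x, n, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 1) || any(x != round(x)))
    stop(sprintf("`%s` must contain positive integers", name), call. = FALSE)
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n)
    stop(sprintf("`%s` must have length 1 or nenvs (%d)", name, n),
         call. = FALSE)
  as.integer(x)
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("Field layout: %d environment(s), blocks along the %s direction\n",
              x$nenvs, if (x$block.dir == "col") "column" else "row"))
  for (e in x$envs) {
    cat(sprintf(
      "  env %d: %d cols x %d rows = %d plots, %d block(s); field %g m x %g m\n",
      e$env, e$ncols, e$nrows, e$nplots, e$nblocks, e$length, e$width))
  }
  invisible(x)
}

.layout_env <- function(layout, env) {
  stopifnot(inherits(layout, "field_layout"))
  env <- as.integer(env)
  if (length(env) != 1L || is.na(env) || env < 1L || env > layout$nenvs)
    stop(sprintf("unknown environment %s (layout has %d)", env, layout$nenvs),
         call. = FALSE)
  layout$envs[[env]]
}

#' Enumerate the plots of one environment
#'
#' Serialises one environment's lattice in rows-within-columns order (row
#' varies fastest), which is the ordering used by every simulated error
#' vector in the package. Block labels follow contiguous slabs: columns
#' `1..ncols/nblocks` are block 1 and so on for column-direction blocks
#' (left to right), analogously bottom-to-top for row-direction blocks.
#' Physical plot-centre coordinates are reported with the origin at the
#' field's lower-left corner.
#'
#' @param layout A [field_layout()].
#' @param env Environment number.
#' @return A data.frame with columns `env`, `block`, `col`, `row`,
#'   `ordinal`, `x_centre`, `y_centre`; `ordinal = (col - 1) * nrows + row`.
#' @export
plot_index <- function(layout, env = 1) {
  e <- .layout_env(layout, env)
  col <- rep(seq_len(e$ncols), each = e$nrows)
  row <- rep(seq_len(e$nrows), times = e$ncols)
  if (e$block.dir == "col") {
    per <- e$ncols %/% e$nblocks
    block <- (col - 1L) %/% per + 1L
  } else {
    per <- e$nrows %/% e$nblocks
    block <- (row - 1L) %/% per + 1L
  }
  data.frame(
    env = e$env,
    block = as.integer(block),
    col = col,
    row = row,
    ordinal = (col - 1L) * e$nrows + row,
    x_centre = (col - 0.5) * e$plot.length,
    y_centre = (row - 0.5) * e$plot.width
  )
}

#' Full plot index across environments
#'
#' Row-binds [plot_index()] over all environments.
#' @param layout A [field_layout()].
#' @return A data.frame as in [plot_index()], all environments stacked.
#' @export
plot_index_all <- function(layout) {
  do.call(rbind, lapply(seq_len(layout$nenvs), plot_index, layout = layout))
}
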