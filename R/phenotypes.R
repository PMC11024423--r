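#' Randomise genotypes to plots under an RCBD
#'
#' Draws an independent uniform permutation of the genotype set within
#' every environment x block combination of a randomised complete block
#' design, so that each genotype occupies exactly one plot per block. The
#' number of plots per block must equal the number of genotypes in every
#' environment.
#'
#' @param layout A [field_layout()].
#' @param genotypes Vector of genotype identifiers.
#' @param seed Integer seed; `NULL` draws one from the session RNG.
#' @return A data.frame `env`, `block`, `col`, `row`, `genotype` covering
#'   every plot, in rows-within-columns order per environment.
#' @export
randomise_rcbd <- function(layout, genotypes, seed = NULL) {
  stopifnot(inherits(layout, "field_layout"))
  ng <- length(genotypes)
  seed <- .resolve_seed(seed)
  out <- vector("list", layout$nenvs)
  for (j in seq_len(layout$nenvs)) {
    e <- layout$envs[[j]]
    per_block <- e$nplots %/% e$nblocks
    if (per_block != ng)
      stop(sprintf(
        "environment %d: block size %d does not match %d genotype(s)",
        j, per_block, ng), call. = FALSE)
    idx <- plot_index(layout, j)
    idx$genotype <- NA
    for (b in seq_len(e$nblocks)) {
      sel <- idx$block == b
      perm <- .with_seed(.substream_seed(seed, j, .COMP[["rcbd"]],
                                         trait = b %% 256L),
                         sample.int(ng))
      idx$genotype[sel] <- genotypes[perm]
    }
    out[[j]] <- idx[, c("env", "block", "col", "row", "genotype")]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble phenotypes from genetic values and plot errors
#'
#' Joins a genetic-value table with a plot-error table and computes the
#' phenotype of every plot as `y = gv + e_total` per trait. Genotypes are
#' placed on plots either through a supplied allocation or, with
#' `randomise = TRUE`, by drawing a fresh RCBD allocation (each genotype
#' once per environment x block). The join is keyed on plot coordinates
#' (`env`, `col`, `row`) and genotype, so the row order of the inputs is
#' irrelevant.
#'
#' @param gv.df Genetic values as returned by [simulate_gv()]: columns
#'   `genotype`, `env`, `gv.Trait1`, ...
#' @param error.df Plot errors as returned by [field_trial_error()]:
#'   columns `env`, `block`, `col`, `row`, and per trait at least
#'   `e.total.Traitk`.
#' @param allocation Optional data.frame `env`, `block`, `col`, `row`,
#'   `genotype` (e.g. from [randomise_rcbd()]); ignored when
#'   `randomise = TRUE`.
#' @param randomise Draw a fresh RCBD allocation.
#' @param layout Optional [field_layout()] used for the randomisation;
#'   reconstructed from `error.df` when omitted.
#' @param seed Integer seed for the randomisation.
#' @return A data.frame with one row per environment x plot: `env`,
#'   `block`, `col`, `row`, `genotype`, then per trait `gv.Traitk`,
#'   `e.Traitk`, `y.Traitk` with `y = gv + e` exactly.
#' @export
make_phenotypes <- function(gv.df, error.df, allocation = NULL,
                            randomise = is.null(allocation),
                            layout = NULL, seed = NULL) {
  gv_traits <- grep("^gv\\.Trait[0-9]+$", names(gv.df), value = TRUE)
  err_traits <- grep("^e\\.total\\.Trait[0-9]+$", names(error.df), value = TRUE)
  if (!length(gv_traits))
    stop("`gv.df` has no gv.TraitK columns", call. = FALSE)
  ntraits <- length(gv_traits)
  if (length(err_traits) != ntraits)
    stop(sprintf("trait mismatch: %d gv trait(s) vs %d error trait(s)",
                 ntraits, length(err_traits)), call. = FALSE)
  envs_gv <- sort(unique(gv.df$env))
  envs_err <- sort(unique(error.df$env))
  if (!identical(as.integer(envs_gv), as.integer(envs_err)))
    stop("`gv.df` and `error.df` cover different environments", call. = FALSE)

  if (randomise || is.null(allocation)) {
    if (is.null(layout)) layout <- .layout_from_table(error.df)
    genotypes <- sort(unique(gv.df$genotype))
    allocation <- randomise_rcbd(layout, genotypes, seed = seed)
  }
  need <- c("env", "block", "col", "row", "genotype")
  if (!all(need %in% names(allocation)))
    stop("`allocation` must have columns env, block, col, row, genotype",
         call. = FALSE)

  err <- error.df[, c("env", "col", "row", err_traits)]
  tab <- merge(allocation, err, by = c("env", "col", "row"), all.x = TRUE)
  if (anyNA(tab[, err_traits]))
    stop("allocation refers to plots missing from `error.df`", call. = FALSE)
  tab <- merge(tab, gv.df[, c("genotype", "env", gv_traits)],
               by = c("genotype", "env"), all.x = TRUE)
  if (anyNA(tab[, gv_traits]))
    stop("genotype missing from `gv.df` for at least one plot", call. = FALSE)

  tab <- tab[order(tab$env, tab$col, tab$row), ]
  out <- tab[, c("env", "block", "col", "row", "genotype")]
  for (t in seq_len(ntraits)) {
    g <- tab[[paste0("gv.Trait", t)]]
    e <- tab[[paste0("e.total.Trait", t)]]
    out[[paste0("gv.Trait", t)]] <- g
    out[[paste0("e.Trait", t)]] <- e
    out[[paste0("y.Trait", t)]] <- g + e
  }
  rownames(out) <- NULL
  class(out) <- c("pheno_df", "data.frame")
  out
}

# reconstruct the lattice geometry implied by a plot table
.layout_from_table <- function(df) {
  envs <- sort(unique(df$env))
  ncols <- integer(length(envs))
  nrows <- integer(length(envs))
  nblocks <- integer(length(envs))
  for (i in seq_along(envs)) {
    d <- df[df$env == envs[i], ]
    ncols[i] <- max(d$col)
    nrows[i] <- max(d$row)
    nblocks[i] <- max(d$block)
    if (nrow(d) != ncols[i] * nrows[i])
      stop(sprintf("environment %s is not a complete lattice", envs[i]),
           call. = FALSE)
  }
  # block direction: do blocks change along columns or rows?
  d1 <- df[df$env == envs[1L], ]
  dir <- if (length(unique(d1$block[d1$row == 1L])) > 1L) "col" else "row"
  field_layout(length(envs), ncols, nrows, nblocks, dir)
}
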