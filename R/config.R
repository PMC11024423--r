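# YAML-driven simulation runner. A config maps one-to-one onto the
# programmatic API: an `error` block with the field_trial_error() arguments,
# an optional `genetics` block for simulate_gv(), plus phenotype and
# evaluation options. Unknown keys anywhere are rejected.

.CONFIG_KEYS <- list(
  top = c("seed", "output_dir", "error", "genetics", "phenotypes",
          "evaluation"),
  error = c("ntraits", "nenvs", "nblocks", "ncols", "nrows", "block.dir",
            "varR", "spatial.model", "complexity", "plot.length",
            "plot.width", "rho.col", "rho.row", "prop.spatial", "prop.ext",
            "ext.ord", "ext.dir", "R.spatial", "R.random", "R.ext", "R.env",
            "grid.res"),
  genetics = c("ngenos", "model", "mean", "var", "env.cor", "loadings",
               "trait.cor"),
  phenotypes = c("randomise"),
  evaluation = c("variogram", "heatmaps")
)

.check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible())
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in config %s: %s",
                 where, paste(unknown, collapse = ", ")), call. = FALSE)
  invisible()
}

# YAML represents matrices as lists of rows
.as_matrix <- function(x) {
  if (is.null(x) || is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  if (is.numeric(x) && length(x) == 1L) return(x)  # scalar (CS correlation)
  stop("expected a scalar or a list of matrix rows", call. = FALSE)
}

#' Read a simulation configuration
#'
#' Parses and validates a YAML simulation config (or an equivalent R
#' list). The `error` block maps one-to-one onto the
#' [field_trial_error()] arguments; the optional `genetics` block onto
#' [simulate_gv()] (inheriting `ntraits`/`nenvs`); `phenotypes$randomise`
#' requests a fresh RCBD; `evaluation$variogram` and
#' `evaluation$heatmaps` list effect columns to export. Unknown keys are
#' rejected with their names.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return The validated config as a list.
#' @export
read_sim_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  .check_keys(config, .CONFIG_KEYS$top, "top level")
  if (is.null(config$error)) stop("config needs an `error` block",
                                  call. = FALSE)
  .check_keys(config$error, .CONFIG_KEYS$error, "`error` block")
  .check_keys(config$genetics, .CONFIG_KEYS$genetics, "`genetics` block")
  .check_keys(config$phenotypes, .CONFIG_KEYS$phenotypes,
              "`phenotypes` block")
  .check_keys(config$evaluation, .CONFIG_KEYS$evaluation,
              "`evaluation` block")
  for (nm in c("R.spatial", "R.random", "R.ext", "R.env"))
    config$error[[nm]] <- .as_matrix(config$error[[nm]])
  if (!is.null(config$genetics)) {
    config$genetics$env.cor <- .as_matrix(config$genetics$env.cor)
    config$genetics$trait.cor <- .as_matrix(config$genetics$trait.cor)
  }
  config
}

#' Run a configured simulation end to end
#'
#' Executes the three simulation steps (plot errors, genetic values,
#' phenotypes) plus the evaluation outputs for a validated config, writing
#' all artifacts to the output directory: `layout.csv`,
#' `plot_errors.csv`, `genetic_values.csv`, `phenotypes.csv`, a variogram
#' CSV per requested effect and environment, heatmap PNGs, a plain-text
#' `metrics.txt`, and a `manifest.json` recording the package version,
#' seed, config hash, and written files. Outputs are deterministic given
#' (config, seed).
#'
#' @param config Path to a YAML config or an equivalent list, see
#'   [read_sim_config()].
#' @param out.dir Output directory (created if needed); defaults to the
#'   config's `output_dir`.
#' @param seed Overrides the config's `seed`.
#' @param stages Subset of `c("errors", "gv", "phenotypes", "evaluate",
#'   "plot")` to run; later stages pull in the earlier ones they need.
#' @return Invisibly, a list with the simulated tables, computed metrics,
#'   and written file paths.
#' @export
run_simulation <- function(config, out.dir = NULL, seed = NULL,
                           stages = c("errors", "gv", "phenotypes",
                                      "evaluate", "plot")) {
  config <- read_sim_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c("phenotypes", "evaluate", "plot") %in% stages))
    stages <- union(stages, c("errors", "gv"))
  out.dir <- out.dir %||% config$output_dir
  if (is.null(out.dir)) stop("no output directory given", call. = FALSE)
  dir.create(out.dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("config needs a `seed`", call. = FALSE)
  seed <- as.integer(seed)

  files <- character(0)
  add_file <- function(p) files[[length(files) + 1L]] <<- p
  res <- list()

  # echo the config (it doubles as the hash source for the manifest);
  # the output path is environment-specific and is not part of the echo
  cfg_path <- file.path(out.dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "output_dir")], cfg_path)
  add_file(cfg_path)

  err_args <- config$error
  err_args$seed <- seed
  error_df <- do.call(field_trial_error, err_args)
  res$errors <- error_df
  params <- attr(error_df, "params")
  layout <- field_layout(
    nenvs = params$nenvs,
    ncols = vapply(seq_len(params$nenvs),
                   function(j) max(error_df$col[error_df$env == j]), numeric(1)),
    nrows = vapply(seq_len(params$nenvs),
                   function(j) max(error_df$row[error_df$env == j]), numeric(1)),
    nblocks = vapply(seq_len(params$nenvs),
                     function(j) max(error_df$block[error_df$env == j]),
                     numeric(1)),
    block.dir = err_args$block.dir %||% "col",
    plot.length = err_args$plot.length %||% 8,
    plot.width = err_args$plot.width %||% 2)

  if ("errors" %in% stages) {
    p <- file.path(out.dir, "plot_errors.csv")
    write_plot_errors(error_df, p); add_file(p)
    p <- file.path(out.dir, "layout.csv")
    write_layout(plot_index_all(layout), p); add_file(p)
  }

  gv_df <- NULL
  if (!is.null(config$genetics) && "gv" %in% stages) {
    g <- config$genetics
    gv_df <- simulate_gv(
      ngenos = g$ngenos, ntraits = params$ntraits, nenvs = params$nenvs,
      mean = g$mean %||% 0, var = g$var %||% 1,
      model = g$model %||% "unstructured",
      env.cor = g$env.cor, loadings = g$loadings,
      R.gtrait = g$trait.cor, seed = seed)
    res$genetic_values <- gv_df
    p <- file.path(out.dir, "genetic_values.csv")
    write_genetic_values(gv_df, p); add_file(p)
  }

  pheno_df <- NULL
  if (!is.null(gv_df) && any(c("phenotypes", "evaluate", "plot") %in% stages)) {
    randomise <- config$phenotypes$randomise %||% TRUE
    pheno_df <- make_phenotypes(gv_df, error_df, randomise = randomise,
                                layout = layout, seed = seed)
    res$phenotypes <- pheno_df
    if ("phenotypes" %in% stages) {
      p <- file.path(out.dir, "phenotypes.csv")
      write_phenotypes(pheno_df, p); add_file(p)
    }
  }

  if ("evaluate" %in% stages) {
    effects <- config$evaluation$variogram %||% "e.total.Trait1"
    for (eff in effects) {
      src <- if (!is.null(pheno_df) && eff %in% names(pheno_df)) pheno_df
             else error_df
      for (j in seq_len(params$nenvs)) {
        vg <- sample_variogram(src, eff, env = j)
        p <- file.path(out.dir, sprintf("variogram_%s_env%d.csv", eff, j))
        write_variogram(vg, p); add_file(p)
      }
    }
    p <- file.path(out.dir, "metrics.txt")
    writeLines(.metrics_report(config, params, gv_df, pheno_df), p)
    add_file(p)
    res$metrics_file <- p
  }

  if ("plot" %in% stages) {
    effects <- config$evaluation$heatmaps %||% character(0)
    for (eff in effects) {
      src <- if (!is.null(pheno_df) && eff %in% names(pheno_df)) pheno_df
             else error_df
      p <- file.path(out.dir, sprintf("heatmap_%s.png", eff))
      ggplot2::ggsave(p, plot_effects(src, eff), width = 8, height = 6,
                      dpi = 120)
      add_file(p)
    }
  }

  manifest <- list(
    package = "fieldtrialsim",
    version = as.character(utils::packageVersion("fieldtrialsim")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = basename(unlist(files)))
  mp <- file.path(out.dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  res$files <- c(unlist(files), mp)
  invisible(res)
}

# plain-text per-environment x trait metrics from the configured true
# variances: error decomposition, plot-level h2, expected accuracy, and
# (when phenotypes exist) realised accuracy of shrunken genotype means
.metrics_report <- function(config, params, gv_df, pheno_df) {
  lines <- c("Simulation metrics", "==================", "")
  nb <- rep_len(config$error$nblocks %||% 2, params$nenvs)
  gvar <- if (!is.null(config$genetics))
    .varR_matrix(.flatten_tm(config$genetics$var %||% 1,
                             params$ntraits, params$nenvs),
                 params$ntraits, params$nenvs)
  for (t in seq_len(params$ntraits)) {
    for (j in seq_len(params$nenvs)) {
      ve <- params$varR[t, j]
      lines <- c(lines, sprintf("Trait %d, environment %d:", t, j))
      lines <- c(lines, sprintf(
        "  error variance %.4g = spatial %.4g + random %.4g + extraneous %.4g",
        ve, params$prop.spatial[j] * ve, params$prop.random[j] * ve,
        params$prop.ext[j] * ve))
      if (!is.null(gvar)) {
        vg <- gvar[t, j]
        h2 <- plot_level_heritability(vg, ve)
        lines <- c(lines, sprintf(
          "  genetic variance %.4g, plot-level h2 %.3f", vg, h2))
        lines <- c(lines, sprintf(
          "  expected accuracy (b = %d): %.3f", nb[j],
          expected_accuracy(h2, nb[j])))
        if (!is.null(pheno_df)) {
          d <- pheno_df[pheno_df$env == j, ]
          pred <- shrunken_genotype_means(d[[paste0("y.Trait", t)]],
                                          d$genotype, vg, ve)
          tg <- gv_df[gv_df$env == j, ]
          tg <- tg[order(tg$genotype), ]
          acc <- prediction_accuracy(tg[[paste0("gv.Trait", t)]],
                                     as.numeric(pred))
          lines <- c(lines, sprintf("  realised accuracy: %.3f", acc))
        }
      }
      lines <- c(lines, "")
    }
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
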