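# CSV schemas for the three core tables. Readers validate the header
# exactly (unknown or missing columns are named in the error) and writers
# print floats with %.17g so a write -> read round trip is lossless.

.SCHEMAS <- list(
  plot_errors = list(
    fixed = c("env", "block", "col", "row"),
    per_trait = c("e.spatial.Trait%d", "e.random.Trait%d",
                  "e.ext.Trait%d", "e.total.Trait%d")),
  genetic_values = list(
    fixed = c("genotype", "env"),
    per_trait = "gv.Trait%d"),
  phenotypes = list(
    fixed = c("env", "block", "col", "row", "genotype"),
    per_trait = c("gv.Trait%d", "e.Trait%d", "y.Trait%d")),
  layout = list(
    fixed = c("env", "block", "col", "row", "ordinal",
              "x_centre", "y_centre"),
    per_trait = character(0)),
  variogram = list(
    fixed = c("col.disp", "row.disp", "semivariance", "n.pairs", "filtered"),
    per_trait = character(0))
)

.schema_columns <- function(schema, ntraits) {
  c(schema$fixed,
    unlist(lapply(seq_len(ntraits),
                  function(t) sprintf(schema$per_trait, t))))
}

# infer trait count from a header, given the schema
.infer_ntraits <- function(cols, schema) {
  if (!length(schema$per_trait)) return(0L)
  pat <- sub("%d", "([0-9]+)", schema$per_trait[1L], fixed = TRUE)
  hits <- regmatches(cols, regexec(paste0("^", pat, "$"), cols))
  ks <- as.integer(unlist(lapply(hits, function(h) if (length(h)) h[2L])))
  if (!length(ks)) 0L else max(ks)
}

.check_schema <- function(df, what) {
  schema <- .SCHEMAS[[what]]
  ntraits <- .infer_ntraits(names(df), schema)
  if (length(schema$per_trait) && ntraits == 0L)
    stop(sprintf("`%s` table has no trait columns (expected e.g. %s)",
                 what, sprintf(schema$per_trait[1L], 1L)), call. = FALSE)
  want <- .schema_columns(schema, ntraits)
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop(sprintf("unexpected column(s) in %s table: %s",
                 what, paste(extra, collapse = ", ")), call. = FALSE)
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop(sprintf("missing column(s) in %s table: %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  df[, want]
}

.write_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table <- function(path, what) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("filtered" %in% names(df)) df$filtered <- as.logical(df$filtered)
  .check_schema(df, what)
}

#' Write / read the simulated tables as CSV
#'
#' Schema-checked CSV round trips for the plot-error, genetic-value,
#' phenotype, layout, and variogram tables. Floats are written with 17
#' significant digits, so reading a written table reproduces the numbers
#' exactly; unexpected or missing columns raise an error naming them.
#'
#' @param df Table to write (with the schema of the corresponding
#'   simulator output).
#' @param path CSV file path.
#' @return Writers return `path` invisibly; readers return the validated
#'   data.frame.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
write_plot_errors <- function(df, path) .write_table(.check_schema(df, "plot_errors"), path)
#' @rdname trial_io
#' @export
read_plot_errors <- function(path) .read_table(path, "plot_errors")
#' @rdname trial_io
#' @export
write_genetic_values <- function(df, path) .write_table(.check_schema(df, "genetic_values"), path)
#' @rdname trial_io
#' @export
read_genetic_values <- function(path) .read_table(path, "genetic_values")
#' @rdname trial_io
#' @export
write_phenotypes <- function(df, path) .write_table(.check_schema(df, "phenotypes"), path)
#' @rdname trial_io
#' @export
read_phenotypes <- function(path) .read_table(path, "phenotypes")
#' @rdname trial_io
#' @export
write_layout <- function(df, path) .write_table(.check_schema(df, "layout"), path)
#' @rdname trial_io
#' @export
write_variogram <- function(df, path) .write_table(.check_schema(df, "variogram"), path)
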