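# Expression container: a TPM-scale gene x sample matrix plus the sample
# sheet and the binary trait indicators derived from it.  Kept as a light
# S3 object so the numeric work can stay on matrices while user-facing
# functions speak tibbles.

#' Construct an expression set
#'
#' @param values numeric gene x sample matrix, nonnegative, TPM scale, with
#'   row and column names.
#' @param samples tibble with one row per sample: `sample_id`, `tissue`,
#'   `stress`, `timepoint`, `replicate`.
#' @return object of class `expression_set` with elements `values`,
#'   `samples` and `traits` (samples x conditions 0/1 indicator matrix, one
#'   column per observed `(tissue, stress, timepoint)` combination).
#' @export
expression_set <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene row names and sample column names")
  }
  if (any(values < 0)) abort("expression values must be nonnegative")
  req <- c("sample_id", "tissue", "stress", "timepoint", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0L) {
    abort(glue("sample sheet lacks columns: {paste(missing_cols, collapse = ', ')}"))
  }
  extra <- symdiff_msg(colnames(values), samples$sample_id)
  if (!is.null(extra)) abort(glue("matrix and sample sheet disagree on samples: {extra}"))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  structure(
    list(
      values = values,
      samples = as_tibble(samples),
      traits = build_trait_matrix(samples)
    ),
    class = "expression_set"
  )
}

# binary indicator matrix, one column per (tissue, stress, timepoint) combo
build_trait_matrix <- function(samples) {
  combo <- paste(samples$tissue, samples$stress, samples$timepoint, sep = "_")
  levels <- unique(combo)
  m <- vapply(levels, function(l) as.integer(combo == l), integer(nrow(samples)))
  rownames(m) <- samples$sample_id
  m
}

symdiff_msg <- function(a, b) {
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) == 0L && length(only_b) == 0L) return(NULL)
  paste(c(
    if (length(only_a)) glue("only in matrix: {paste(only_a, collapse = ', ')}"),
    if (length(only_b)) glue("only in sheet: {paste(only_b, collapse = ', ')}")
  ), collapse = "; ")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(glue(
    "<expression_set> {nrow(x$values)} genes x {ncol(x$values)} samples, ",
    "{ncol(x$traits)} trait indicators\n\n"
  ))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Tidy an expression set into long format
#'
#' @param x an `expression_set`.
#' @param ... unused.
#' @return tibble with one row per gene x sample measurement.
#' @export
tidy.expression_set <- function(x, ...) {
  as_tibble(x$values, rownames = "gene_id") |>
    pivot_longer(-"gene_id", names_to = "sample_id", values_to = "tpm") |>
    left_join(x$samples, by = "sample_id")
}

#' Read an expression matrix and its sample sheet
#'
#' @param matrix_path TSV with gene ids in the first column and one column
#'   per sample (TPM scale).
#' @param sample_sheet_path TSV with columns `sample_id`, `tissue`,
#'   `stress`, `timepoint`, `replicate`.
#' @return an [expression_set()].
#' @export
read_expression_matrix <- function(matrix_path, sample_sheet_path) {
  mat_tbl <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(mat_tbl[, -1, drop = FALSE])
  rownames(values) <- as.character(mat_tbl[[1]])
  if (any(is.na(values))) abort("expression matrix contains missing values")
  if (any(values < 0)) abort("expression matrix contains negative values")
  expression_set(values, samples)
}

#' Write an expression set to TSV files
#'
#' @param x an `expression_set`.
#' @param matrix_path,sample_sheet_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_matrix <- function(x, matrix_path, sample_sheet_path) {
  as_tibble(x$values, rownames = "gene_id") |>
    readr::write_tsv(matrix_path, progress = FALSE)
  readr::write_tsv(x$samples, sample_sheet_path, progress = FALSE)
  invisible(matrix_path)
}

# log2 transform used by the correlation machinery; pseudocount = 1 is the
# conventional guard against zeros, pseudocount = 0 gives the exact inverse
# of the generator's log2-scale model
log2_expr <- function(x, pseudocount = 1) {
  values <- if (inherits(x, "expression_set")) x$values else x
  log2(values + pseudocount)
}
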