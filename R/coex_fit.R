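# One-call wrapper chaining soft threshold -> adjacency -> TOM ->
# clustering -> static cut -> eigengene merge, returning a fit object with
# broom-style tidiers.

#' Detect co-expression modules in one call
#'
#' Runs the full module-detection chain: soft-threshold selection (unless
#' `beta` is given), unsigned adjacency, topological overlap, average
#' linkage clustering on `1 - TOM`, a static cut with size filter, and
#' eigengene-based module merging.
#'
#' @param expr an [expression_set()] or gene x sample matrix (TPM scale).
#' @param beta soft-threshold exponent; `NULL` picks it by
#'   [pick_soft_threshold()].
#' @param min_module_size minimum genes per module.
#' @param merge_cut_height eigengene dissimilarity below which modules are
#'   merged.
#' @param cut_height_frac static-cut fraction of the maximum merge height.
#' @param transform expression transform, see [pick_soft_threshold()].
#' @param keep_tom keep the TOM matrix in the returned object.
#' @return object of class `coex_fit`: `assignment` (tibble `gene_id`,
#'   `module`), `eigengenes` (sample x module matrix), `beta`,
#'   `soft_threshold` diagnostics (when selected), `dendrogram`, `params`,
#'   optional `tom`.
#' @export
coexpression_modules <- function(expr, beta = NULL, min_module_size = 10,
                                 merge_cut_height = 0.2,
                                 cut_height_frac = 0.90,
                                 transform = "log2p1", keep_tom = FALSE) {
  m <- expr_input_matrix(expr, transform)
  st <- NULL
  if (is.null(beta)) {
    st <- pick_soft_threshold(m, transform = "none")
    beta <- st$beta
  }
  adj <- adjacency_matrix(m, beta = beta, transform = "none")
  tom <- tom_similarity(adj)
  diss <- 1 - tom
  diag(diss) <- 0
  tree <- average_linkage_cluster(diss)
  assignment <- cut_modules(tree, min_module_size = min_module_size,
                            cut_height_frac = cut_height_frac)
  if (any(assignment$module != "unassigned")) {
    assignment <- merge_modules(assignment, m, merge_cut_height = merge_cut_height,
                                transform = "none")
    eigengenes <- module_eigengenes(m, assignment, transform = "none")
  } else {
    eigengenes <- matrix(numeric(0), nrow = ncol(m), ncol = 0,
                         dimnames = list(colnames(m), NULL))
  }
  structure(
    list(
      assignment = assignment,
      eigengenes = eigengenes,
      beta = beta,
      soft_threshold = st,
      dendrogram = tree,
      tom = if (keep_tom) tom,
      params = list(min_module_size = min_module_size,
                    merge_cut_height = merge_cut_height,
                    cut_height_frac = cut_height_frac,
                    transform = transform)
    ),
    class = "coex_fit"
  )
}

#' @export
print.coex_fit <- function(x, ...) {
  nmod <- length(setdiff(unique(x$assignment$module), "unassigned"))
  cat(glue(
    "<coex_fit> {nrow(x$assignment)} genes, {nmod} modules ",
    "(beta = {x$beta}, min size = {x$params$min_module_size}, ",
    "merge cut = {x$params$merge_cut_height})\n\n"
  ))
  invisible(x)
}

#' Tidy a co-expression fit into per-gene rows
#'
#' @param x a `coex_fit`.
#' @param ... unused.
#' @return tibble `gene_id`, `module`.
#' @export
tidy.coex_fit <- function(x, ...) x$assignment

#' One-row summary of a co-expression fit
#'
#' @param x a `coex_fit`.
#' @param ... unused.
#' @return tibble `n_genes`, `n_modules`, `n_unassigned`, `beta`,
#'   `largest_module`.
#' @export
glance.coex_fit <- function(x, ...) {
  mods <- x$assignment$module
  sizes <- table(mods[mods != "unassigned"])
  tibble(
    n_genes = length(mods),
    n_modules = length(sizes),
    n_unassigned = sum(mods == "unassigned"),
    beta = x$beta,
    largest_module = if (length(sizes) > 0) max(sizes) else 0L
  )
}

#' Module sizes of a co-expression fit, largest first
#'
#' @param fit a `coex_fit`.
#' @return tibble `module`, `n_genes`.
#' @export
module_sizes <- function(fit) {
  fit$assignment |>
    filter(.data$module != "unassigned") |>
    group_by(.data$module) |>
    summarise(n_genes = n(), .groups = "drop") |>
    arrange(desc(.data$n_genes))
}
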