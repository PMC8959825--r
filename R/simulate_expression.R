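# Synthetic expression with planted, trait-linked co-expression modules.
#
# Each planted module follows the binary indicator of its condition: for a
# member gene i in sample s,
#   log2(expr) = baseline_i + direction * loading_i * amplitude * I(s) +
#                N(0, noise_sd)
# and the matrix is exponentiated to a TPM-like scale.  Genes outside all
# modules are baseline + noise.  The log2-scale construction makes planted
# correlation structure analytically controllable.

#' Simulate an expression matrix with planted modules
#'
#' @param config a [sim_config()].
#' @return list: `expr` (an [expression_set()]), `module_truth` (tibble
#'   `gene_id`, `module`, `trait`, `loading`, `direction`; one row per
#'   planted member), `deg_truth` (tibble `gene_id`, `tissue`, `stress`,
#'   `timepoint`, `true_log2fc` for every stress condition vs control).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  design <- config$design
  n_s <- nrow(design)
  combo <- paste(design$tissue, design$stress, design$timepoint, sep = "_")
  baseline <- runif(config$n_genes, config$baseline_range[1], config$baseline_range[2])
  log2m <- matrix(rep(baseline, n_s), nrow = config$n_genes,
                  dimnames = list(config$gene_ids, design$sample_id))
  module_truth <- vector("list", length(config$modules))
  for (mi in seq_along(config$modules)) {
    mod <- config$modules[[mi]]
    loading <- runif(length(mod$genes), mod$loading_range[1], mod$loading_range[2])
    indicator <- as.numeric(combo == mod$trait)
    log2m[mod$genes, ] <- log2m[mod$genes, ] +
      outer(mod$direction * loading * config$amplitude, indicator)
    module_truth[[mi]] <- tibble(
      gene_id = mod$genes, module = paste0("planted-", mi),
      trait = mod$trait, loading = loading, direction = mod$direction
    )
  }
  module_truth <- bind_rows(module_truth)
  if (nrow(module_truth) == 0L) {
    module_truth <- tibble(gene_id = character(), module = character(),
                           trait = character(), loading = numeric(),
                           direction = numeric())
  }
  log2m <- log2m + matrix(rnorm(length(log2m), sd = config$noise_sd),
                          nrow = nrow(log2m))
  expr <- expression_set(2^log2m, design)

  conditions <- design |>
    filter(.data$stress != "control") |>
    distinct(.data$tissue, .data$stress, .data$timepoint)
  deg_truth <- expand_grid(gene_id = config$gene_ids, conditions) |>
    left_join(module_truth, by = "gene_id") |>
    mutate(
      hit = !is.na(.data$trait) &
        .data$trait == paste(.data$tissue, .data$stress, .data$timepoint, sep = "_"),
      true_log2fc = ifelse(.data$hit, .data$direction * .data$loading * config$amplitude, 0)
    ) |>
    select("gene_id", "tissue", "stress", "timepoint", "true_log2fc")
  list(expr = expr, module_truth = module_truth, deg_truth = deg_truth)
}

#' Simulate per-method DEG result tables from a truth table
#'
#' Emulates the inputs of the consensus DEG rule: for each method,
#' replicate-level log2 expression is drawn around `baseline` (control)
#' and `baseline + true_log2fc` (treatment) with independent noise, and
#' the method reports the observed log2 fold change with a two-sample
#' t-test p, BH-adjusted across genes.  Methods differ only by their noise
#' draws.  Uses the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param truth tibble with `gene_id` and `true_log2fc` (one row per gene).
#' @param methods method names (one table each).
#' @param n_replicates replicates per group.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param baseline log2 baseline expression.
#' @return named list of tibbles (`gene_id`, `log2fc`, `padj`).
#' @export
simulate_deg_tables <- function(truth, methods = c("edger", "deseq2", "ballgown"),
                                n_replicates = 3, noise_sd = 0.25, baseline = 5) {
  stopifnot(all(c("gene_id", "true_log2fc") %in% names(truth)))
  if (anyDuplicated(truth$gene_id)) abort("truth must have one row per gene")
  if (n_replicates < 2) abort("need at least 2 replicates")
  out <- map(methods, function(m) {
    res <- map(seq_len(nrow(truth)), function(i) {
      ctrl <- baseline + rnorm(n_replicates, sd = noise_sd)
      trt <- baseline + truth$true_log2fc[i] + rnorm(n_replicates, sd = noise_sd)
      tt <- t.test(trt, ctrl, var.equal = TRUE)
      tibble(gene_id = truth$gene_id[i],
             log2fc = mean(trt) - mean(ctrl),
             p = tt$p.value)
    }) |> bind_rows()
    mutate(res, padj = bh_adjust(.data$p)) |> select("gene_id", "log2fc", "padj")
  })
  setNames(out, methods)
}
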