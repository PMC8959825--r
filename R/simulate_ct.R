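# Synthetic qPCR Ct tables with known fold changes.
#
# Ct = baseline_gene - log2(relative abundance) + N(0, sigma_ct); reference
# genes have condition-invariant abundance, so ddCt recovers the planted
# fold change exactly at sigma_ct = 0.

#' Simulate a Ct table with truth fold changes
#'
#' @param config a [sim_config()]; uses the `ct` spec (targets with
#'   per-group fold changes, reference genes, control group, replicate
#'   count, `sigma_ct`).
#' @return list: `ct_table` (tibble `sample_id`, `group`, `gene_id`,
#'   `replicate`, `ct`), `truth` (tibble `gene_id`, `group`,
#'   `true_fold_change`).
#' @export
simulate_ct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$ct
  if (length(spec$reference_genes) < 1L) abort("need at least one reference gene")
  if (spec$n_replicates < 3L) abort("need at least 3 biological replicates")
  if (spec$sigma_ct < 0) abort("sigma_ct must be nonnegative")
  set.seed(config$seed + 4L)
  groups <- unique(c(spec$control_group, spec$targets$group))
  target_genes <- unique(spec$targets$gene_id)
  genes <- c(target_genes, spec$reference_genes)
  baseline <- setNames(runif(length(genes), 18, 26), genes)
  truth <- expand_grid(gene_id = genes, group = groups) |>
    left_join(spec$targets, by = c("gene_id", "group")) |>
    mutate(true_fold_change = ifelse(is.na(.data$fold_change), 1, .data$fold_change)) |>
    select("gene_id", "group", "true_fold_change")
  rows <- expand_grid(group = groups, replicate = seq_len(spec$n_replicates),
                      gene_id = genes) |>
    left_join(truth, by = c("gene_id", "group")) |>
    mutate(
      sample_id = paste(.data$group, paste0("r", .data$replicate), sep = "_"),
      ct = baseline[.data$gene_id] - log2(.data$true_fold_change) +
        rnorm(n(), sd = spec$sigma_ct)
    ) |>
    select("sample_id", "group", "gene_id", "replicate", "ct")
  list(ct_table = rows, truth = truth)
}
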