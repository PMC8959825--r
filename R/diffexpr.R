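# Consensus differential-expression calling over per-method result tables.
#
# A gene is a DEG when at least `min_methods` methods report
# padj < padj_max and |log2fc| >= log2(min_abs_linear_fc), and the
# supporting methods agree in sign (the direction requirement can be
# switched off).

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment: sort ascending, `adj_i = min_{j >= i} p_j * m / j`,
#' capped at 1, original order restored.  This is the same procedure as
#' `stats::p.adjust(method = "BH")`; it is exposed here with input
#' validation so raw-p method tables can be adjusted before consensus
#' calling.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must be numeric in [0, 1] with no missing values")
  }
  p.adjust(pvalues, method = "BH")
}

#' Signed log2 fold change with pseudocount
#'
#' `log2((mean_treatment + c) / (mean_control + c))`.
#'
#' @param mean_treatment,mean_control nonnegative group means.
#' @param pseudocount added to both means before the ratio.
#' @return signed log2 ratio (vectorised).
#' @export
log2_fold_change <- function(mean_treatment, mean_control, pseudocount = 1) {
  if (any(mean_treatment < 0) || any(mean_control < 0)) {
    abort("group means must be nonnegative")
  }
  log2((mean_treatment + pseudocount) / (mean_control + pseudocount))
}

#' Consensus DEG calls across methods
#'
#' @param tables named list of per-method tibbles, each with columns
#'   `gene_id`, `log2fc`, `padj`.
#' @param padj_max adjusted-p threshold (strict `<`).
#' @param min_abs_linear_fc linear fold-change threshold; applied as
#'   `|log2fc| >= log2(min_abs_linear_fc)`.
#' @param min_methods minimum number of supporting methods.
#' @param require_direction_agreement when `TRUE` (default) the supporting
#'   methods must share the sign of `log2fc`.
#' @return tibble with one row per called gene: `gene_id`,
#'   `n_supporting_methods`, `direction` (`"up"`/`"down"`), `mean_log2fc`
#'   (over supporting methods), plus per-method `log2fc_*` and `padj_*`
#'   columns; sorted by `gene_id`.
#' @export
consensus_degs <- function(tables, padj_max = 0.05, min_abs_linear_fc = 2,
                           min_methods = 2, require_direction_agreement = TRUE) {
  if (!is.list(tables) || length(tables) < min_methods) {
    abort(glue("need at least {min_methods} method tables"))
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("method", seq_along(tables))
  }
  for (nm in names(tables)) {
    missing_cols <- setdiff(c("gene_id", "log2fc", "padj"), names(tables[[nm]]))
    if (length(missing_cols) > 0L) {
      abort(glue("table '{nm}' lacks columns: {paste(missing_cols, collapse = ', ')}"))
    }
    if (anyDuplicated(tables[[nm]]$gene_id)) {
      abort(glue("table '{nm}' has duplicated gene ids"))
    }
  }
  lfc_min <- log2(min_abs_linear_fc)
  long <- imap(tables, function(tb, nm) {
    mutate(as_tibble(tb)[c("gene_id", "log2fc", "padj")], method = nm)
  }) |> bind_rows()
  per_gene <- long |>
    mutate(pass = .data$padj < padj_max & abs(.data$log2fc) >= lfc_min) |>
    group_by(.data$gene_id)
  calls <- per_gene |>
    summarise(
      n_up = sum(.data$pass & .data$log2fc > 0),
      n_down = sum(.data$pass & .data$log2fc < 0),
      mean_up = mean(.data$log2fc[.data$pass & .data$log2fc > 0]),
      mean_down = mean(.data$log2fc[.data$pass & .data$log2fc < 0]),
      .groups = "drop"
    )
  if (require_direction_agreement) {
    calls <- calls |>
      mutate(
        direction = dplyr::case_when(
          .data$n_up >= min_methods ~ "up",
          .data$n_down >= min_methods ~ "down",
          TRUE ~ NA_character_
        ),
        n_supporting_methods = ifelse(.data$direction == "up", .data$n_up, .data$n_down),
        mean_log2fc = ifelse(.data$direction == "up", .data$mean_up, .data$mean_down)
      )
  } else {
    calls <- calls |>
      mutate(
        n_pass = .data$n_up + .data$n_down,
        direction = dplyr::case_when(
          .data$n_pass < min_methods ~ NA_character_,
          .data$n_up >= .data$n_down ~ "up",
          TRUE ~ "down"
        ),
        n_supporting_methods = .data$n_pass,
        mean_log2fc = ifelse(
          .data$direction == "up", .data$mean_up,
          ifelse(is.nan(.data$mean_down), .data$mean_up, .data$mean_down)
        )
      )
  }
  calls <- calls |>
    filter(!is.na(.data$direction)) |>
    select("gene_id", "n_supporting_methods", "direction", "mean_log2fc")
  wide <- long |>
    pivot_wider(
      names_from = "method", values_from = c("log2fc", "padj"),
      names_sep = "_"
    )
  calls |>
    left_join(wide, by = "gene_id") |>
    arrange(.data$gene_id)
}

#' Summarise DEG calls
#'
#' @param calls output of [consensus_degs()].
#' @return one-row tibble with `n_deg`, `n_up`, `n_down`.
#' @export
deg_summary <- function(calls) {
  tibble(
    n_deg = nrow(calls),
    n_up = sum(calls$direction == "up"),
    n_down = sum(calls$direction == "down")
  )
}
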