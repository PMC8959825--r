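# qPCR relative quantification by the 2^-ddCt method (multiple reference
# genes aggregated by the arithmetic mean of their Ct, i.e. the geometric
# mean on the expression scale) and simple phenotype statistics.

#' Relative quantification by 2^-ddCt
#'
#' Per biological replicate, `dCt = Ct_target - mean(Ct of reference
#' genes)` (technical replicates of a gene are averaged first);
#' `ddCt = dCt - mean(dCt of the control group)`; `rq = 2^-ddCt`.  By
#' construction the control group's rq values have geometric mean 1.
#'
#' @param ct_table tibble with columns `sample_id`, `group`, `gene_id`,
#'   `replicate`, `ct` (one row per technical replicate measurement;
#'   `sample_id` identifies the biological replicate).
#' @param target target gene id.
#' @param reference_genes character vector of reference gene ids; each must
#'   be measured in every sample.
#' @param control_group group label used as calibrator.
#' @return tibble of class `rq_tbl` with per-replicate rows: `group`,
#'   `sample_id`, `delta_ct`, `delta_delta_ct`, `rq`.  Group summaries via
#'   [rq_summary()].
#' @export
delta_delta_ct <- function(ct_table, target, reference_genes, control_group = "control") {
  req <- c("sample_id", "group", "gene_id", "replicate", "ct")
  missing_cols <- setdiff(req, names(ct_table))
  if (length(missing_cols) > 0L) {
    abort(glue("ct_table lacks columns: {paste(missing_cols, collapse = ', ')}"))
  }
  if (any(ct_table$ct <= 0)) abort("Ct values must be positive")
  if (length(reference_genes) < 1L) abort("need at least one reference gene")
  if (!control_group %in% ct_table$group) {
    abort(glue("control group '{control_group}' absent from table"))
  }
  # mean Ct per (sample, gene) over technical replicates
  per_gene <- ct_table |>
    group_by(.data$sample_id, .data$group, .data$gene_id) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  samples <- distinct(per_gene, .data$sample_id, .data$group)
  for (rg in reference_genes) {
    missing_in <- setdiff(samples$sample_id,
                          per_gene$sample_id[per_gene$gene_id == rg])
    if (length(missing_in) > 0L) {
      abort(glue("reference gene '{rg}' missing in sample(s): {paste(missing_in, collapse = ', ')}"))
    }
  }
  missing_target <- setdiff(samples$sample_id,
                            per_gene$sample_id[per_gene$gene_id == target])
  if (length(missing_target) > 0L) {
    abort(glue("target '{target}' missing in sample(s): {paste(missing_target, collapse = ', ')}"))
  }
  ref_ct <- per_gene |>
    filter(.data$gene_id %in% reference_genes) |>
    group_by(.data$sample_id) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  dct <- per_gene |>
    filter(.data$gene_id == target) |>
    left_join(ref_ct, by = "sample_id") |>
    mutate(delta_ct = .data$ct - .data$ref_ct)
  control_mean <- mean(dct$delta_ct[dct$group == control_group])
  out <- dct |>
    mutate(
      delta_delta_ct = .data$delta_ct - control_mean,
      rq = 2^(-.data$delta_delta_ct)
    ) |>
    select("group", "sample_id", "delta_ct", "delta_delta_ct", "rq") |>
    arrange(.data$group, .data$sample_id)
  attr(out, "target") <- target
  attr(out, "control_group") <- control_group
  class(out) <- c("rq_tbl", class(out))
  out
}

#' Group summaries of relative quantities, with t-tests against control
#'
#' @param rq a `rq_tbl` from [delta_delta_ct()].
#' @param equal_var pooled-variance Student's t (default) or Welch.
#' @return tibble: `group`, `n`, `mean_rq`, `sd_rq`, `t`, `p`, `stars`
#'   (`*` p < 0.05, `**` p < 0.01; control row has `NA` test columns).
#' @export
rq_summary <- function(rq, equal_var = TRUE) {
  control_group <- attr(rq, "control_group")
  ctrl <- rq$rq[rq$group == control_group]
  rq |>
    group_by(.data$group) |>
    summarise(n = n(), mean_rq = mean(.data$rq), sd_rq = sd(.data$rq),
              .groups = "drop") |>
    mutate(
      test = map(.data$group, function(g) {
        if (g == control_group) return(tibble(t = NA_real_, p = NA_real_))
        # degenerate (noise-free) groups cannot be tested; report NA
        tt <- tryCatch(
          two_sample_ttest(rq$rq[rq$group == g], ctrl, equal_var = equal_var),
          error = function(e) tibble(t = NA_real_, p = NA_real_)
        )
        tibble(t = tt$t, p = tt$p)
      })
    ) |>
    unnest("test") |>
    mutate(stars = dplyr::case_when(
      is.na(.data$p) ~ "",
      .data$p < 0.01 ~ "**",
      .data$p < 0.05 ~ "*",
      TRUE ~ ""
    ))
}

#' Two-sample t-test
#'
#' Student's pooled-variance t by default, Welch when `equal_var = FALSE`;
#' two-sided p.  Degenerate inputs follow the convention: zero pooled
#' variance with equal means gives `t = 0, p = 1`; zero pooled variance
#' with unequal means is an error (infinite t).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param equal_var pooled (TRUE) or Welch (FALSE).
#' @return one-row tibble: `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b, equal_var = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) abort("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    abort("zero variance in both groups with unequal means: t is infinite")
  }
  tt <- t.test(a, b, var.equal = equal_var)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Event rate (survival / germination proportion)
#'
#' @param events number of events (e.g. surviving plants), `0 <= events <=
#'   total`.
#' @param total number of individuals, `> 0`.
#' @return `events / total` (vectorised).
#' @export
event_rate <- function(events, total) {
  if (any(total <= 0)) abort("total must be positive")
  if (any(events < 0 | events > total)) abort("events must lie in [0, total]")
  events / total
}

#' Bar plot of relative quantities by group
#'
#' @param object a `rq_tbl` from [delta_delta_ct()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rq_tbl <- function(object, ...) {
  summ <- rq_summary(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean_rq)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rq - .data$sd_rq,
                                        ymax = .data$mean_rq + .data$sd_rq),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean_rq + .data$sd_rq,
                                    label = .data$stars), vjust = -0.4) +
    ggplot2::labs(x = NULL,
                  y = glue("relative expression of {attr(object, 'target')} (2^-ddCt)")) +
    ggplot2::theme_classic()
}
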