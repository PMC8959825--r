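# Focal-TF regulatory network: co-expression partner selection by
# |r| > min_abs_r and p < max_p (strict, matching the thresholds as
# published for this kind of screen), intersection with promoter site
# counts, and export as edge-list TSV or GraphML.

#' Co-expression partners of a focal gene
#'
#' Pearson correlation (with exact t-based p) of the focal gene against
#' every other gene over the selected samples; partners must satisfy the
#' strict inequalities `|r| > min_abs_r` and `p < max_p`.  Genes with zero
#' variance over the selected samples cannot be tested and are skipped
#' (reported in the `n_skipped_constant` attribute); a constant focal gene
#' is an error.
#'
#' @param expr an [expression_set()] or gene x sample matrix.
#' @param focal focal gene id.
#' @param min_abs_r correlation threshold (strict `>`).
#' @param max_p p-value threshold (strict `<`).
#' @param sample_filter optional character vector of sample ids (or column
#'   names) to correlate over; default all samples.
#' @param transform see [pick_soft_threshold()].
#' @return object of class `coexpression_set`: tibble `gene_id`, `r`, `p`
#'   of the partners (focal excluded), with attributes `focal`,
#'   `thresholds`, `samples_used`, `n_tested`, `n_skipped_constant`.
#' @export
coexpressed_genes <- function(expr, focal, min_abs_r = 0.7, max_p = 1e-4,
                              sample_filter = NULL, transform = "log2p1") {
  m <- expr_input_matrix(expr, transform)
  if (!focal %in% rownames(m)) abort(glue("focal gene '{focal}' not in matrix"))
  if (!is.null(sample_filter)) {
    missing_s <- setdiff(sample_filter, colnames(m))
    if (length(missing_s) > 0L) {
      abort(glue("samples not in matrix: {paste(missing_s, collapse = ', ')}"))
    }
    m <- m[, sample_filter, drop = FALSE]
  }
  if (ncol(m) < 3L) abort("need at least 3 samples after filtering")
  x <- m[focal, ]
  if (sd(x) == 0) abort(glue("focal gene '{focal}' is constant over the selected samples"))
  others <- setdiff(rownames(m), focal)
  sds <- apply(m[others, , drop = FALSE], 1, sd)
  testable <- others[sds > 0]
  r <- as.numeric(cor(x, t(m[testable, , drop = FALSE])))
  p <- cor_p_value(r, ncol(m))
  members <- tibble(gene_id = testable, r = r, p = p) |>
    filter(abs(.data$r) > min_abs_r, .data$p < max_p) |>
    arrange(.data$gene_id)
  structure(
    members,
    class = c("coexpression_set", class(members)),
    focal = focal,
    thresholds = list(min_abs_r = min_abs_r, max_p = max_p),
    samples_used = colnames(m),
    n_tested = length(testable),
    n_skipped_constant = length(others) - length(testable)
  )
}

#' Build the focal-TF regulatory network
#'
#' Targets are co-expression partners whose promoter carries at least
#' `min_sites` consensus sites; whitelisted partners (curated
#' stress-relevant genes) qualify with a single site.  Edges are directed
#' focal -> target and signed by the correlation (`activating` for r > 0,
#' `repressing` for r < 0).
#'
#' @param coexpr a `coexpression_set` from [coexpressed_genes()].
#' @param site_counts tibble `gene_id`, `site_count` (see [count_sites()]).
#'   Members missing from it are treated as having 0 sites (a note is
#'   emitted).
#' @param min_sites minimum promoter sites for a non-whitelist target.
#' @param whitelist character vector of gene ids admitted with >= 1 site.
#' @return object of class `regulatory_network`: list with `focal`,
#'   `edges` tibble (`source`, `target`, `r`, `p`, `site_count`,
#'   `whitelist`, `sign`), `members`, `site_counts`, `stats` (member count,
#'   motif-positive count and fraction, >= `min_sites` count), `params`.
#' @export
build_network <- function(coexpr, site_counts, min_sites = 2, whitelist = character()) {
  stopifnot(inherits(coexpr, "coexpression_set"))
  focal <- attr(coexpr, "focal")
  members <- as_tibble(coexpr)
  missing_counts <- setdiff(members$gene_id, site_counts$gene_id)
  if (length(missing_counts) > 0L) {
    inform(glue(
      "{length(missing_counts)} member(s) absent from site_counts treated as 0 sites"
    ))
  }
  absent_wl <- setdiff(whitelist, members$gene_id)
  if (length(absent_wl) > 0L) {
    inform(glue(
      "whitelist gene(s) not co-expressed, excluded: {paste(absent_wl, collapse = ', ')}"
    ))
  }
  annotated <- members |>
    left_join(site_counts, by = "gene_id") |>
    mutate(
      site_count = ifelse(is.na(.data$site_count), 0L, .data$site_count),
      whitelist = .data$gene_id %in% whitelist
    )
  edges <- annotated |>
    filter(.data$site_count >= min_sites |
             (.data$whitelist & .data$site_count >= 1)) |>
    mutate(
      source = focal,
      target = .data$gene_id,
      sign = ifelse(.data$r > 0, "activating", "repressing")
    ) |>
    select("source", "target", "r", "p", "site_count", "whitelist", "sign") |>
    arrange(.data$target)
  n_members <- nrow(members)
  n_motif_pos <- sum(annotated$site_count >= 1)
  structure(
    list(
      focal = focal,
      edges = edges,
      members = annotated,
      stats = tibble(
        member_count = n_members,
        motif_positive_count = n_motif_pos,
        motif_positive_fraction = if (n_members > 0) n_motif_pos / n_members else NA_real_,
        min_sites_count = sum(annotated$site_count >= min_sites),
        target_count = nrow(edges)
      ),
      params = list(min_sites = min_sites, whitelist = whitelist,
                    thresholds = attr(coexpr, "thresholds"),
                    samples_used = attr(coexpr, "samples_used"))
    ),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- x$stats
  cat(glue(
    "<regulatory_network> focal {x$focal}: {s$member_count} co-expressed, ",
    "{s$motif_positive_count} motif-positive ",
    "({round(100 * s$motif_positive_fraction, 1)}%), ",
    "{s$target_count} targets\n\n"
  ))
  invisible(x)
}

#' Tidy a regulatory network into its edge list
#'
#' @param x a `regulatory_network`.
#' @param ... unused.
#' @return the edge tibble.
#' @export
tidy.regulatory_network <- function(x, ...) x$edges

#' One-row summary of a regulatory network
#'
#' @param x a `regulatory_network`.
#' @param ... unused.
#' @return the `stats` tibble (member / motif-positive / target counts).
#' @export
glance.regulatory_network <- function(x, ...) x$stats

#' Export a regulatory network
#'
#' @param net a `regulatory_network`.
#' @param path output file path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "regulatory_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(net$edges, path, progress = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a regulatory network to an igraph object
#'
#' @param net a `regulatory_network`.
#' @return a directed igraph graph; the focal node is present even when
#'   there are no edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  vertices <- tibble(
    name = c(net$focal, net$edges$target),
    role = c("focal", rep("target", nrow(net$edges))),
    site_count = c(NA_integer_, net$edges$site_count),
    whitelist = c(NA, net$edges$whitelist)
  )
  igraph::graph_from_data_frame(net$edges, directed = TRUE, vertices = vertices)
}

#' Plot a regulatory network
#'
#' Star layout around the focal gene; edge colour encodes the correlation
#' sign, point size the promoter site count.
#'
#' @param object a `regulatory_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.regulatory_network <- function(object, ...) {
  e <- object$edges
  if (nrow(e) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = glue("{object$focal}: no targets")) +
             ggplot2::theme_void())
  }
  theta <- seq(0, 2 * pi, length.out = nrow(e) + 1L)[-1L]
  nodes <- tibble(
    gene_id = e$target, x = cos(theta), y = sin(theta),
    site_count = e$site_count, whitelist = e$whitelist, sign = e$sign
  )
  ggplot2::ggplot(nodes) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y, colour = .data$sign)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$site_count,
                                     shape = .data$whitelist)) +
    ggplot2::geom_text(ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$gene_id), size = 2.5) +
    ggplot2::annotate("point", 0, 0, size = 4) +
    ggplot2::annotate("text", 0, -0.12, label = object$focal, fontface = "bold") +
    ggplot2::scale_colour_manual(values = c(activating = "#c0392b",
                                            repressing = "#2980b9")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
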