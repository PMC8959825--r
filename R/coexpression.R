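# Weighted gene co-expression network analysis, written from scratch:
# soft-thresholded correlation adjacency, topological overlap (TOM),
# average-linkage clustering, module detection by a static cut with a
# minimum module size, eigengene-based module merging, and module-trait
# correlation.
#
# Everything is deterministic given the input order: ties break on the
# lowest gene index and the eigengene sign is fixed by an orientation rule.

#' Pearson correlation with a two-sided p-value
#'
#' p is computed from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom;
#' `r = +/-1` gives `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return one-row tibble: `r`, `n`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input: correlation undefined")
  r <- cor(x, y)
  tibble(r = r, n = n, p = cor_p_value(r, n))
}

# two-sided p for a Pearson r at sample size n (vectorised)
cor_p_value <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t <- abs(r[!exact]) * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  p
}

#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate exponent `beta` the unsigned adjacency
#' `a_ij = |r_ij|^beta` is formed, connectivities `k_i = sum_j a_ij` are
#' binned, and the fit R^2 of `log10 p(k)` on `log10 k` is recorded.  The
#' chosen `beta` is the smallest whose R^2 reaches `r2_target`; if none
#' does, the `beta` maximising R^2.  Candidates whose connectivity is
#' degenerate (constant `k` or fewer than 3 usable bins) get `NA` R^2 and
#' are excluded from selection.
#'
#' @param expr an [expression_set()] or a gene x sample numeric matrix.
#' @param betas candidate exponents.
#' @param r2_target scale-free fit target.
#' @param n_bins connectivity bins for the fit.
#' @param transform `"log2p1"` (default, `log2(x + 1)`), `"log2"` or
#'   `"none"`; how expression is transformed before correlation.
#' @return list of class `soft_threshold`: `beta` (chosen), `diagnostics`
#'   tibble (`beta`, `r2`, `mean_k`, `median_k`, `max_k`, `degenerate`).
#' @export
pick_soft_threshold <- function(expr, betas = 1:20, r2_target = 0.8,
                                n_bins = 10, transform = "log2p1") {
  m <- expr_input_matrix(expr, transform)
  if (nrow(m) < 50) warn("fewer than 50 genes: scale-free fit is unreliable")
  r <- abs(gene_cor(m))
  diag(r) <- 0
  diagnostics <- map(betas, function(b) {
    a <- r^b
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins)
    tibble(
      beta = b, r2 = fit$r2, mean_k = mean(k), median_k = stats::median(k),
      max_k = max(k), degenerate = fit$degenerate
    )
  }) |> bind_rows()
  usable <- which(!diagnostics$degenerate)
  if (length(usable) == 0L) {
    warn("scale-free fit undefined for every candidate beta; defaulting to beta = 6")
    chosen <- 6
  } else {
    hit <- usable[diagnostics$r2[usable] >= r2_target]
    chosen <- if (length(hit) > 0L) diagnostics$beta[hit[1]] else
      diagnostics$beta[usable[which.max(diagnostics$r2[usable])]]
  }
  structure(
    list(beta = chosen, r2_target = r2_target, diagnostics = diagnostics),
    class = "soft_threshold"
  )
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(glue("<soft_threshold> chosen beta = {x$beta} (target R2 = {x$r2_target})\n\n"))
  print(x$diagnostics, n = 5)
  invisible(x)
}

# R^2 of the log10 p(k) ~ log10 k regression over connectivity bins
scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2L || any(!is.finite(k))) {
    return(list(r2 = NA_real_, degenerate = TRUE))
  }
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(ok) < 3L) return(list(r2 = NA_real_, degenerate = TRUE))
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  list(r2 = summary(fit)$r.squared, degenerate = FALSE)
}

# correlation between genes (rows) across samples
gene_cor <- function(m) {
  keep_sd <- apply(m, 1, sd)
  if (any(keep_sd == 0)) {
    abort(glue(
      "constant genes (zero variance) are not allowed here: ",
      "{paste(utils::head(rownames(m)[keep_sd == 0], 5), collapse = ', ')}"
    ))
  }
  cor(t(m))
}

# resolve user input (expression_set or matrix) to a transformed matrix
expr_input_matrix <- function(expr, transform = "log2p1") {
  m <- if (inherits(expr, "expression_set")) expr$values else expr
  stopifnot(is.matrix(m), is.numeric(m))
  switch(transform,
    log2p1 = log2(m + 1),
    log2 = log2(m),
    none = m,
    abort(glue("unknown transform '{transform}'"))
  )
}

#' Unsigned soft-thresholded adjacency
#'
#' @param expr an [expression_set()] or gene x sample matrix.
#' @param beta soft-threshold exponent.
#' @param transform see [pick_soft_threshold()].
#' @return gene x gene adjacency matrix `|r|^beta`, diagonal 1.
#' @export
adjacency_matrix <- function(expr, beta, transform = "log2p1") {
  check_number(beta, min = 0)
  m <- expr_input_matrix(expr, transform)
  a <- abs(gene_cor(m))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k_i = sum_{j != i} a_ij`; the diagonal is 1.
#'
#' @param adjacency symmetric gene x gene matrix with values in `[0, 1]`
#'   (the diagonal is ignored and treated as 0 internally).
#' @return symmetric matrix of class `matrix` with values in `[0, 1]` and
#'   unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency), is.numeric(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-10) {
    abort("adjacency must be symmetric (tolerance 1e-10)")
  }
  if (min(adjacency) < 0 || max(adjacency) > 1 + 1e-12) {
    abort("adjacency values must lie in [0, 1]")
  }
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2  # symmetrise away float asymmetry
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param dissimilarity symmetric matrix with zero diagonal, typically
#'   `1 - TOM`.
#' @return an [stats::hclust] tree (method `"average"`).
#' @export
average_linkage_cluster <- function(dissimilarity) {
  stopifnot(is.matrix(dissimilarity))
  if (max(abs(dissimilarity - t(dissimilarity))) > 1e-10) {
    abort("dissimilarity must be symmetric")
  }
  if (max(abs(diag(dissimilarity))) > 1e-12) {
    abort("dissimilarity must have a zero diagonal")
  }
  hclust(as.dist(dissimilarity), method = "average")
}

#' Cut a dendrogram into modules
#'
#' A static cut at `cut_height_frac` of the maximum merge height produces
#' candidate clusters; clusters smaller than `min_module_size` become
#' `"unassigned"`.  Because TOM dissimilarity of unrelated genes sits
#' essentially at 1, cutting just below the top of the tree keeps cohesive
#' branches together while leaving null genes as singletons.  Surviving
#' clusters are labelled `module-1 ... module-k` by decreasing size (ties:
#' lowest member index first).
#'
#' @param dendrogram an [stats::hclust] tree from
#'   [average_linkage_cluster()].
#' @param min_module_size minimum genes per retained module.
#' @param cut_height_frac fraction of the maximum merge height at which the
#'   tree is cut.
#' @return tibble `gene_id`, `module`; parameters in attribute `params`.
#' @export
cut_modules <- function(dendrogram, min_module_size = 10, cut_height_frac = 0.90) {
  stopifnot(inherits(dendrogram, "hclust"))
  check_number(min_module_size, min = 1)
  check_number(cut_height_frac, min = 0, max = 1)
  h <- cut_height_frac * max(dendrogram$height)
  raw <- cutree(dendrogram, h = h)
  assignment_from_clusters(names(raw) %||% as.character(seq_along(raw)),
                           raw, min_module_size,
                           params = list(min_module_size = min_module_size,
                                         cut_height_frac = cut_height_frac))
}

# turn integer cluster ids into size-ranked module labels with a size filter
assignment_from_clusters <- function(gene_ids, cluster, min_module_size, params) {
  sizes <- table(cluster)
  keep <- names(sizes)[sizes >= min_module_size]
  # order kept clusters by decreasing size, ties by lowest member position
  first_idx <- vapply(keep, function(cl) min(which(cluster == cl)), integer(1))
  keep <- keep[order(-as.integer(sizes[keep]), first_idx)]
  label <- setNames(rep("unassigned", length(sizes)), names(sizes))
  label[keep] <- paste0("module-", seq_along(keep))
  out <- tibble(gene_id = gene_ids, module = unname(label[as.character(cluster)]))
  attr(out, "params") <- params
  out
}

#' Module eigengene
#'
#' First principal component of the gene-standardised (zero mean, unit
#' variance per gene) expression submatrix of the module, as a unit-norm
#' per-sample profile, sign-oriented so that the mean correlation with the
#' member genes is nonnegative.
#'
#' @param expr an [expression_set()] or gene x sample matrix.
#' @param genes character vector of member gene ids (>= 2).
#' @param transform see [pick_soft_threshold()].
#' @return named numeric vector (one value per sample) with attributes
#'   `var_explained` and `n_genes`.
#' @export
module_eigengene <- function(expr, genes, transform = "log2p1") {
  m <- expr_input_matrix(expr, transform)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0L) {
    abort(glue("genes not in matrix: {paste(utils::head(missing_genes, 5), collapse = ', ')}"))
  }
  if (length(genes) < 2L) abort("a module needs at least 2 genes")
  sub <- m[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    abort(glue(
      "constant genes make the module submatrix singular: ",
      "{paste(utils::head(genes[sds == 0], 5), collapse = ', ')}"
    ))
  }
  z <- (sub - rowMeans(sub)) / sds
  sv <- svd(z)
  profile <- sv$v[, 1]
  profile <- profile / sqrt(sum(profile^2))
  # orientation: mean correlation with members must be >= 0
  mean_cor <- mean(cor(profile, t(z)))
  if (mean_cor < 0) profile <- -profile
  names(profile) <- colnames(m)
  attr(profile, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  attr(profile, "n_genes") <- length(genes)
  profile
}

#' Eigengenes for every module of an assignment
#'
#' @param expr an [expression_set()] or gene x sample matrix.
#' @param assignment tibble `gene_id`, `module` (from [cut_modules()] or
#'   [merge_modules()]); `"unassigned"` is skipped.
#' @param transform see [pick_soft_threshold()].
#' @return sample x module numeric matrix.
#' @export
module_eigengenes <- function(expr, assignment, transform = "log2p1") {
  mods <- setdiff(unique(assignment$module), "unassigned")
  if (length(mods) == 0L) abort("no modules in assignment")
  m <- expr_input_matrix(expr, transform)
  me <- vapply(mods, function(mod) {
    module_eigengene(m, assignment$gene_id[assignment$module == mod], transform = "none")
  }, numeric(ncol(m)))
  rownames(me) <- colnames(m)
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules while their eigengene
#' dissimilarity `1 - cor(ME_a, ME_b)` is below `merge_cut_height`
#' (equivalently eigengene correlation above `1 - merge_cut_height`);
#' eigengenes are recomputed after every merge.  Final modules are
#' relabelled by decreasing size.
#'
#' @param assignment tibble `gene_id`, `module`.
#' @param expr an [expression_set()] or gene x sample matrix.
#' @param merge_cut_height eigengene dissimilarity below which modules are
#'   merged.
#' @param transform see [pick_soft_threshold()].
#' @return tibble `gene_id`, `module`.
#' @export
merge_modules <- function(assignment, expr, merge_cut_height = 0.2,
                          transform = "log2p1") {
  check_number(merge_cut_height, min = 0, max = 2)
  m <- expr_input_matrix(expr, transform)
  groups <- split(assignment$gene_id[assignment$module != "unassigned"],
                  assignment$module[assignment$module != "unassigned"])
  if (length(groups) == 0L) abort("no modules to merge")
  repeat {
    if (length(groups) < 2L) break
    me <- vapply(groups, function(g) module_eigengene(m, g, transform = "none"),
                 numeric(ncol(m)))
    d <- 1 - cor(me)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[idx[1], idx[2]] >= merge_cut_height) break
    i <- min(idx); j <- max(idx)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups[[j]] <- NULL
  }
  # relabel merged groups by decreasing size (ties: lowest member position)
  first_idx <- vapply(groups, function(g) min(match(g, assignment$gene_id)), integer(1))
  ord <- order(-lengths(groups), first_idx)
  label <- rep("unassigned", nrow(assignment))
  names(label) <- assignment$gene_id
  for (gi in seq_along(ord)) {
    label[groups[[ord[gi]]]] <- paste0("module-", gi)
  }
  out <- tibble(gene_id = assignment$gene_id, module = unname(label))
  attr(out, "params") <- list(merge_cut_height = merge_cut_height)
  out
}

#' Module-trait correlations
#'
#' Pearson correlation with p-value between each module eigengene and each
#' trait column.
#'
#' @param eigengenes sample x module matrix (see [module_eigengenes()]).
#' @param traits sample x trait numeric matrix (binary indicators or
#'   continuous covariates), same row order as `eigengenes`.
#' @return tibble of class `module_trait_cor`: `module`, `trait`, `r`,
#'   `n`, `p`, ordered by module then trait.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  stopifnot(is.matrix(eigengenes), nrow(eigengenes) == nrow(traits))
  traits <- as.matrix(traits)
  const <- apply(traits, 2, function(v) sd(v) == 0)
  if (any(const)) {
    abort(glue("constant trait column(s): {paste(colnames(traits)[const], collapse = ', ')}"))
  }
  out <- expand_grid(module = colnames(eigengenes), trait = colnames(traits)) |>
    mutate(
      r = map2_dbl_(.data$module, .data$trait,
                    function(mo, tr) cor(eigengenes[, mo], traits[, tr])),
      n = nrow(eigengenes),
      p = cor_p_value(.data$r, nrow(eigengenes))
    ) |>
    arrange(.data$module, .data$trait)
  class(out) <- c("module_trait_cor", class(out))
  out
}

map2_dbl_ <- function(x, y, f) vapply(seq_along(x), function(i) f(x[i], y[i]), numeric(1))

#' Heatmap of module-trait correlations
#'
#' @param object a `module_trait_cor` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.module_trait_cor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trait, y = .data$module,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1g)", .data$r, .data$p)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
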