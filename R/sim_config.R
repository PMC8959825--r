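# Simulation configuration: the study conditions every generator draws
# from.  Defaults emulate a 3-tissue x (control + 3 stresses) x 24 h
# design with 2 replicates (24 samples), three planted trait-linked
# modules, class II TCP consensus sites planted in a subset of promoters,
# and duplicate-pair divergence times spanning the three WGD epochs of the
# Populus lineage (14 recent-WGD, 7 gamma-triplication, 9 ancient pairs).

#' Define a planted co-expression module
#'
#' @param genes member gene ids.
#' @param trait name of the condition indicator the module follows, in
#'   `tissue_stress_timepoint` form (e.g. `"leaf_cold_24h"`).
#' @param loading_range interval in `(0, 1]` from which per-gene loadings
#'   are drawn.
#' @param direction `+1` (induced) or `-1` (repressed).
#' @return list of class `planted_module`.
#' @export
planted_module <- function(genes, trait, loading_range = c(0.8, 1), direction = 1) {
  stopifnot(length(genes) >= 2, direction %in% c(-1, 1))
  if (loading_range[1] <= 0 || loading_range[2] > 1 ||
      loading_range[1] > loading_range[2]) {
    abort("loading_range must be an interval within (0, 1]")
  }
  structure(list(genes = genes, trait = trait,
                 loading_range = loading_range, direction = direction),
            class = "planted_module")
}

#' Default sample design
#'
#' 3 tissues x stresses (control, cold, heat, salt) x 24 h x 2 replicates
#' = 24 samples.  Drought and the 7 d timepoint of the emulated study can
#' be added by passing a larger grid to [sim_config()].
#'
#' @param tissues,stresses,timepoints,replicates design factors.
#' @return tibble: `sample_id`, `tissue`, `stress`, `timepoint`,
#'   `replicate`.
#' @export
default_design <- function(tissues = c("leaf", "stem", "root"),
                           stresses = c("control", "cold", "heat", "salt"),
                           timepoints = "24h",
                           replicates = 2) {
  expand_grid(tissue = tissues, stress = stresses, timepoint = timepoints,
              replicate = seq_len(replicates)) |>
    mutate(sample_id = paste(.data$tissue, .data$stress, .data$timepoint,
                             paste0("r", .data$replicate), sep = "_")) |>
    select("sample_id", "tissue", "stress", "timepoint", "replicate")
}

default_modules <- function(gene_ids) {
  list(
    planted_module(gene_ids[1:30], "leaf_cold_24h", direction = 1),
    planted_module(gene_ids[31:55], "root_salt_24h", direction = 1),
    planted_module(gene_ids[56:75], "stem_heat_24h", direction = -1)
  )
}

# sites concentrated in the cold module (whose first gene is the focal TF
# in the end-to-end network demonstration) plus a few background genes
default_planted_sites <- function(gene_ids) {
  m1 <- gene_ids[1:30]
  bg <- gene_ids[76:80]
  tibble(
    gene_id = c(m1[2:13], m1[14:19], bg),
    site_count = c(rep(2L, 12), rep(1L, 6), rep(1L, 5)),
    strand = rep(c("plus", "minus", "both"), length.out = 23),
    mismatches_per_site = rep(c(0L, 1L), length.out = 23)
  )
}

default_ks_targets <- function() {
  c(rep(0.25, 14), rep(1.5, 7), rep(4.0, 9))
}

default_ct_spec <- function() {
  list(
    targets = tibble(
      gene_id = c("target_1", "target_1", "target_2", "target_2"),
      group = c("cold_24h", "salt_24h", "cold_24h", "salt_24h"),
      fold_change = c(4, 2, 0.5, 1)
    ),
    reference_genes = c("ref_his", "ref_60s", "ref_actin", "ref_actin2"),
    control_group = "control",
    n_replicates = 3,
    sigma_ct = 0.2
  )
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators and validates
#' their joint constraints.  Given a fixed `seed` all four generators are
#' byte-reproducible.
#'
#' @param seed integer RNG seed; each generator derives its own stream
#'   from it.
#' @param n_genes number of genes (must cover all module members).
#' @param n_chromosomes chromosomes the genes are spread over.
#' @param promoter_length promoter window in bp.
#' @param design sample sheet tibble (see [default_design()]).
#' @param modules list of [planted_module()]s with disjoint members; gene
#'   ids may be given as indices into the generated id set.
#' @param planted_sites tibble `gene_id`, `site_count`, `strand`
#'   (`plus`/`minus`/`both`), `mismatches_per_site` (0 or 1).
#' @param ks_targets true synonymous divergences, one per codon pair.
#' @param n_codons codons per simulated coding sequence.
#' @param noise_sd residual noise sd on the log2 expression scale.
#' @param amplitude module eigenprofile amplitude in log2 units (3 =
#'   8-fold induction for a loading of 1).
#' @param baseline_range interval of per-gene baseline log2 expression.
#' @param consensus,max_mismatch motif planted and scrubbed against.
#' @param body_length gene-body length in bp (multiple of 3).
#' @param spacer_length intergenic spacer in bp.
#' @param ct qPCR simulation spec (see [default_ct_spec()]).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 200,
                       n_chromosomes = 2,
                       promoter_length = 1000,
                       design = default_design(),
                       modules = NULL,
                       planted_sites = NULL,
                       ks_targets = default_ks_targets(),
                       n_codons = 300,
                       noise_sd = 0.25,
                       amplitude = 3,
                       baseline_range = c(3, 8),
                       consensus = "GTGGNCCC",
                       max_mismatch = 1,
                       body_length = 300,
                       spacer_length = 100,
                       ct = default_ct_spec()) {
  check_number(seed)
  check_number(n_genes, min = 2)
  check_number(noise_sd, min = 0)
  check_number(amplitude, min = 0)
  if (body_length %% 3 != 0) abort("body_length must be a multiple of 3")
  gene_ids <- make_gene_ids(n_genes)
  if (is.null(modules)) modules <- default_modules(gene_ids)
  modules <- map(modules, function(m) {
    if (is.numeric(m$genes)) m$genes <- gene_ids[m$genes]
    m
  })
  members <- unlist(map(modules, "genes"))
  if (anyDuplicated(members)) abort("module member lists must be disjoint")
  if (length(members) > n_genes) abort("n_genes must cover all module members")
  if (!all(members %in% gene_ids)) abort("module members outside the gene id set")
  traits <- unique(paste(design$tissue, design$stress, design$timepoint, sep = "_"))
  bad_traits <- setdiff(map_chr(modules, "trait"), traits)
  if (length(bad_traits) > 0L) {
    abort(glue("module trait(s) not in the design: {paste(bad_traits, collapse = ', ')}"))
  }
  if (is.null(planted_sites)) planted_sites <- default_planted_sites(gene_ids)
  motif <- motif_consensus(consensus, max_mismatch)
  L <- nchar(motif$iupac)
  cap <- floor((promoter_length + 1) / (2 * L))  # non-overlap with gaps
  if (any(planted_sites$site_count > cap)) {
    abort(glue("planted site count exceeds promoter capacity ({cap} sites)"))
  }
  if (!all(planted_sites$strand %in% c("plus", "minus", "both"))) {
    abort("planted_sites$strand must be plus/minus/both")
  }
  if (!all(planted_sites$mismatches_per_site %in% c(0L, 1L))) {
    abort("mismatches_per_site must be 0 or 1")
  }
  if (!all(planted_sites$gene_id %in% gene_ids)) {
    abort("planted_sites refers to unknown genes")
  }
  if (any(ks_targets < 0)) abort("ks_targets must be nonnegative")
  if (min(table(paste(design$tissue, design$stress, design$timepoint))) < 2) {
    abort("design needs at least 2 replicates per condition")
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_chromosomes = as.integer(n_chromosomes),
      promoter_length = as.integer(promoter_length),
      design = design, modules = modules, planted_sites = planted_sites,
      ks_targets = ks_targets, n_codons = as.integer(n_codons),
      noise_sd = noise_sd, amplitude = amplitude,
      baseline_range = baseline_range, consensus = motif,
      body_length = as.integer(body_length),
      spacer_length = as.integer(spacer_length),
      ct = ct, gene_ids = gene_ids
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(glue(
    "<sim_config> seed {x$seed}: {x$n_genes} genes on {x$n_chromosomes} ",
    "chromosomes, {nrow(x$design)} samples, {length(x$modules)} planted ",
    "modules, {nrow(x$planted_sites)} genes with planted sites, ",
    "{length(x$ks_targets)} codon pairs\n\n"
  ))
  invisible(x)
}
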