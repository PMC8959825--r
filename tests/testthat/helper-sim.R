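# Small configurations used across tests: quick to generate, still
# carrying the planted structure each stage needs.

tiny_site_spec <- function(gene_ids = c("g0002", "g0003", "g0004")) {
  tibble::tibble(
    gene_id = gene_ids,
    site_count = c(2L, 1L, 0L),
    strand = c("plus", "minus", "plus"),
    mismatches_per_site = c(0L, 1L, 0L)
  )
}

tiny_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_genes = 40, promoter_length = 300,
    modules = list(planted_module(1:15, "leaf_cold_24h")),
    planted_sites = tiny_site_spec(),
    ks_targets = c(0, 0.2),
    n_codons = 100,
    ...
  )
}

no_structure_config <- function(seed = 1, n_genes = 200, ...) {
  sim_config(
    seed = seed, n_genes = n_genes,
    modules = list(),
    planted_sites = tibble::tibble(
      gene_id = character(), site_count = integer(),
      strand = character(), mismatches_per_site = integer()
    ),
    ks_targets = numeric(),
    ...
  )
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
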