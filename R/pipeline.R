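# Stage orchestration: one config, eight stages, deterministic outputs.
#
# Stages write into their own subdirectory of `out_dir` (staged into a
# temporary directory first, then renamed, so a failed stage never leaves
# partial primary outputs).  All randomness flows from the single config
# seed.  The stage functions are thin wrappers over the exported module
# functions; scripting those functions directly is equally supported.

PIPELINE_STAGES <- c("simulate", "promoters", "ks", "deg", "wgcna",
                     "scan", "network", "qpcr")

PIPELINE_DEFAULTS <- list(
  seed = 1,
  out_dir = "coexreg_run",
  promoter_window = 1000,
  consensus = "GTGGNCCC",
  max_mismatch = 1,
  min_abs_r = 0.7,
  max_p = 1e-4,
  min_sites = 2,
  whitelist = character(),
  focal_gene = NULL,
  padj_max = 0.05,
  min_linear_fc = 2,
  min_methods = 2,
  beta = NULL,
  min_module_size = 10,
  merge_cut_height = 0.2,
  cut_height_frac = 0.90,
  epoch_labels = c("rWGD", "gamma-WGT", "ancient-WGD"),
  epoch_ks_low = c(0.10, 0.90, 3.00),
  epoch_ks_high = c(0.50, 2.20, 5.00),
  sim = list()
)

#' Build a pipeline configuration
#'
#' Starts from the package defaults (the parameter values of the emulated
#' workflow: promoter window 1000 bp, consensus GTGGNCCC with 1 mismatch,
#' |r| > 0.7 and p < 1e-4, >= 2 sites, padj < 0.05 and fold change >= 2 in
#' >= 2 methods, minimum module size 10, merge cut height 0.2) and
#' overrides them with `...` or with a YAML file.  Unknown keys are
#' rejected.
#'
#' @param ... named overrides of the defaults.
#' @param file optional YAML file of overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  overrides <- list(...)
  if (!is.null(file)) {
    overrides <- modifyList(yaml::read_yaml(file), overrides)
  }
  unknown <- setdiff(names(overrides), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    abort(glue("unknown pipeline config key(s): {paste(unknown, collapse = ', ')}"))
  }
  cfg <- modifyList(PIPELINE_DEFAULTS, overrides)
  unknown_sim <- setdiff(names(cfg$sim), setdiff(names(formals(sim_config)), "..."))
  if (length(unknown_sim) > 0L) {
    abort(glue("unknown sim config key(s): {paste(unknown_sim, collapse = ', ')}"))
  }
  structure(cfg, class = "pipeline_config")
}

resolve_sim_config <- function(config) {
  do.call(sim_config, modifyList(
    list(seed = config$seed, promoter_length = config$promoter_window,
         consensus = config$consensus, max_mismatch = config$max_mismatch),
    config$sim
  ))
}

stage_path <- function(config, stage, ...) {
  file.path(config$out_dir, stage, ...)
}

# write stage outputs atomically: fill a temp dir, then swap it in
with_stage_dir <- function(config, stage, writer) {
  tmp <- file.path(config$out_dir, paste0(".", stage, ".tmp"))
  final <- file.path(config$out_dir, stage)
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  info <- writer(tmp)
  log <- c(
    list(stage = stage, time = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("coexreg")),
         seed = config$seed),
    info
  )
  jsonlite::write_json(log, file.path(tmp, "log.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  unlink(final, recursive = TRUE)
  if (!file.rename(tmp, final)) abort(glue("could not finalize stage '{stage}'"))
  invisible(final)
}

require_inputs <- function(paths) {
  missing_in <- paths[!file.exists(paths)]
  if (length(missing_in) > 0L) {
    abort(glue(
      "missing stage input(s): {paste(missing_in, collapse = ', ')} ",
      "(run the producing stage first)"
    ))
  }
  invisible(paths)
}

read_tsv_q <- function(path) readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)

#' Run one pipeline stage
#'
#' Stage names: `simulate` (generate all synthetic inputs), `promoters`,
#' `ks`, `deg`, `wgcna`, `scan`, `network`, `qpcr`.  Inputs are taken from
#' the earlier stages' subdirectories of `out_dir`; missing inputs abort
#' before anything is written.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the stage output directory, invisibly.
#' @export
run_stage <- function(name, config = pipeline_config()) {
  if (length(name) != 1L || !name %in% PIPELINE_STAGES) {
    abort(glue("unknown stage '{name}'; stages: {paste(PIPELINE_STAGES, collapse = ', ')}"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config)[setdiff(names(config), "sim")],
                   file.path(config$out_dir, "config.yaml"))
  switch(name,
    simulate = stage_simulate(config),
    promoters = stage_promoters(config),
    ks = stage_ks(config),
    deg = stage_deg(config),
    wgcna = stage_wgcna(config),
    scan = stage_scan(config),
    network = stage_network(config),
    qpcr = stage_qpcr(config)
  )
}

stage_simulate <- function(config) {
  sc <- resolve_sim_config(config)
  with_stage_dir(config, "simulate", function(dir) {
    gen <- simulate_genome(sc)
    write_fasta(gen$genome, file.path(dir, "genome.fasta"))
    write_gff_genes(gen$genes, file.path(dir, "genes.gff3"))
    readr::write_tsv(gen$site_truth, file.path(dir, "site_truth.tsv"), progress = FALSE)
    ex <- simulate_expression(sc)
    write_expression_matrix(ex$expr, file.path(dir, "expression.tsv"),
                            file.path(dir, "samples.tsv"))
    readr::write_tsv(ex$module_truth, file.path(dir, "module_truth.tsv"), progress = FALSE)
    readr::write_tsv(ex$deg_truth, file.path(dir, "deg_truth.tsv"), progress = FALSE)
    # per-method DEG tables for the first planted module's condition
    tr <- ex$module_truth$trait[1]
    parts <- strsplit(tr, "_")[[1]]
    contrast <- ex$deg_truth |>
      filter(.data$tissue == parts[1], .data$stress == parts[2],
             .data$timepoint == parts[3]) |>
      select("gene_id", "true_log2fc")
    set.seed(sc$seed + 5L)
    tabs <- simulate_deg_tables(contrast, noise_sd = sc$noise_sd)
    for (m in names(tabs)) {
      readr::write_tsv(tabs[[m]], file.path(dir, glue("deg_method_{m}.tsv")),
                       progress = FALSE)
    }
    cp <- simulate_codon_pairs(sc)
    write_codon_pairs(cp$pairs, file.path(dir, "codon_pairs.fasta"))
    readr::write_tsv(cp$truth, file.path(dir, "codon_truth.tsv"), progress = FALSE)
    ct <- simulate_ct_table(sc)
    readr::write_tsv(ct$ct_table, file.path(dir, "ct_table.tsv"), progress = FALSE)
    readr::write_tsv(ct$truth, file.path(dir, "ct_truth.tsv"), progress = FALSE)
    list(n_genes = sc$n_genes, n_samples = nrow(sc$design),
         n_codon_pairs = length(sc$ks_targets),
         deg_contrast = tr)
  })
}

stage_promoters <- function(config) {
  inputs <- stage_path(config, "simulate", c("genome.fasta", "genes.gff3"))
  require_inputs(inputs)
  genome <- read_fasta(inputs[1])
  genes <- read_gff_genes(inputs[2])
  with_stage_dir(config, "promoters", function(dir) {
    prom <- extract_promoters(genome, genes, window = config$promoter_window)
    readr::write_tsv(prom, file.path(dir, "promoters.tsv"), progress = FALSE)
    list(n_promoters = nrow(prom), window = config$promoter_window,
         n_truncated = sum(prom$truncated))
  })
}

stage_ks <- function(config) {
  input <- stage_path(config, "simulate", "codon_pairs.fasta")
  require_inputs(input)
  pairs <- read_codon_pairs(input)
  bins <- epoch_bins(config$epoch_labels, config$epoch_ks_low, config$epoch_ks_high)
  with_stage_dir(config, "ks", function(dir) {
    est <- classify_epochs(ks_estimate(pairs), bins)
    readr::write_tsv(est, file.path(dir, "ks.tsv"), progress = FALSE)
    readr::write_tsv(epoch_summary(est), file.path(dir, "epoch_summary.tsv"),
                     progress = FALSE)
    list(n_pairs = nrow(est), n_saturated = sum(est$saturated))
  })
}

stage_deg <- function(config) {
  sim_dir <- stage_path(config, "simulate")
  require_inputs(sim_dir)
  files <- list.files(sim_dir, pattern = "^deg_method_.*\\.tsv$", full.names = TRUE)
  if (length(files) < config$min_methods) {
    abort(glue("need >= {config$min_methods} method tables under {sim_dir}"))
  }
  tables <- setNames(map(files, read_tsv_q),
                     sub("^deg_method_(.*)\\.tsv$", "\\1", basename(files)))
  with_stage_dir(config, "deg", function(dir) {
    calls <- consensus_degs(tables, padj_max = config$padj_max,
                            min_abs_linear_fc = config$min_linear_fc,
                            min_methods = config$min_methods)
    readr::write_tsv(calls, file.path(dir, "degs.tsv"), progress = FALSE)
    readr::write_tsv(deg_summary(calls), file.path(dir, "deg_summary.tsv"),
                     progress = FALSE)
    as.list(deg_summary(calls))
  })
}

stage_wgcna <- function(config) {
  inputs <- stage_path(config, "simulate", c("expression.tsv", "samples.tsv"))
  require_inputs(inputs)
  expr <- read_expression_matrix(inputs[1], inputs[2])
  with_stage_dir(config, "wgcna", function(dir) {
    fit <- coexpression_modules(expr, beta = config$beta,
                                min_module_size = config$min_module_size,
                                merge_cut_height = config$merge_cut_height,
                                cut_height_frac = config$cut_height_frac)
    readr::write_tsv(tidy(fit), file.path(dir, "modules.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(fit$eigengenes, rownames = "sample_id"),
                     file.path(dir, "eigengenes.tsv"), progress = FALSE)
    mt <- module_trait_correlation(fit$eigengenes, expr$traits)
    readr::write_tsv(mt, file.path(dir, "module_trait.tsv"), progress = FALSE)
    c(as.list(glance(fit)), list(n_traits = ncol(expr$traits)))
  })
}

stage_scan <- function(config) {
  input <- stage_path(config, "promoters", "promoters.tsv")
  require_inputs(input)
  prom <- read_tsv_q(input)
  motif <- motif_consensus(config$consensus, config$max_mismatch)
  with_stage_dir(config, "scan", function(dir) {
    hits <- scan_promoters(prom, motif)
    counts <- count_sites(prom, motif)
    readr::write_tsv(hits, file.path(dir, "hits.tsv"), progress = FALSE)
    readr::write_tsv(counts, file.path(dir, "site_counts.tsv"), progress = FALSE)
    list(n_hits = nrow(hits), n_genes_with_sites = sum(counts$site_count > 0),
         consensus = motif$iupac, max_mismatch = motif$max_mismatch)
  })
}

stage_network <- function(config) {
  inputs <- c(stage_path(config, "simulate", c("expression.tsv", "samples.tsv")),
              stage_path(config, "scan", "site_counts.tsv"))
  require_inputs(inputs)
  expr <- read_expression_matrix(inputs[1], inputs[2])
  counts <- read_tsv_q(inputs[3])
  focal <- config$focal_gene %||% rownames(expr$values)[1]
  with_stage_dir(config, "network", function(dir) {
    coexpr <- coexpressed_genes(expr, focal, min_abs_r = config$min_abs_r,
                                max_p = config$max_p)
    net <- build_network(coexpr, counts, min_sites = config$min_sites,
                         whitelist = config$whitelist)
    export_network(net, file.path(dir, "edges.tsv"), "tsv")
    export_network(net, file.path(dir, "network.graphml"), "graphml")
    jsonlite::write_json(as.list(glance(net)), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    as.list(glance(net))
  })
}

stage_qpcr <- function(config) {
  input <- stage_path(config, "simulate", "ct_table.tsv")
  require_inputs(input)
  ct <- read_tsv_q(input)
  sc <- resolve_sim_config(config)
  with_stage_dir(config, "qpcr", function(dir) {
    targets <- unique(sc$ct$targets$gene_id)
    summaries <- map(targets, function(tg) {
      rq <- delta_delta_ct(ct, tg, sc$ct$reference_genes, sc$ct$control_group)
      readr::write_tsv(rq, file.path(dir, glue("rq_{tg}.tsv")), progress = FALSE)
      summ <- rq_summary(rq)
      readr::write_tsv(summ, file.path(dir, glue("rq_summary_{tg}.tsv")),
                       progress = FALSE)
      summ
    })
    list(targets = targets,
         n_significant = sum(map_dbl(summaries, ~ sum(.x$p < 0.05, na.rm = TRUE))))
  })
}

#' Run every pipeline stage and aggregate a run report
#'
#' @param config a [pipeline_config()].
#' @return the report as a list (also written to
#'   `out_dir/run_report.json`): per-stage logs plus the headline
#'   quantities (module-trait table, DEG counts, epoch counts, network
#'   member / motif-positive / target counts, qPCR summaries).
#' @export
run_all <- function(config = pipeline_config()) {
  for (stage in PIPELINE_STAGES) run_stage(stage, config)
  report <- list(
    seed = config$seed,
    stages = setNames(map(PIPELINE_STAGES, function(s) {
      jsonlite::read_json(stage_path(config, s, "log.json"))
    }), PIPELINE_STAGES),
    epoch_counts = read_tsv_q(stage_path(config, "ks", "epoch_summary.tsv")),
    deg_summary = read_tsv_q(stage_path(config, "deg", "deg_summary.tsv")),
    module_trait = read_tsv_q(stage_path(config, "wgcna", "module_trait.tsv")),
    network = jsonlite::read_json(stage_path(config, "network", "report.json"))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  report
}
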