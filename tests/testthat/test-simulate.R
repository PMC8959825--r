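# Synthetic-data generators: determinism, planted-truth exactness, and
# distributional sanity.

test_that("identical config and seed give byte-identical outputs", {
  cfg_a <- tiny_config(seed = 7)
  cfg_b <- tiny_config(seed = 7)
  gen_a <- simulate_genome(cfg_a)
  gen_b <- simulate_genome(cfg_b)
  fa_a <- withr::local_tempfile(fileext = ".fa")
  fa_b <- withr::local_tempfile(fileext = ".fa")
  write_fasta(gen_a$genome, fa_a)
  write_fasta(gen_b$genome, fa_b)
  expect_identical(readBin(fa_a, "raw", file.size(fa_a)),
                   readBin(fa_b, "raw", file.size(fa_b)))
  gff_a <- withr::local_tempfile(); gff_b <- withr::local_tempfile()
  write_gff_genes(gen_a$genes, gff_a)
  write_gff_genes(gen_b$genes, gff_b)
  expect_identical(readLines(gff_a), readLines(gff_b))
  expect_identical(simulate_expression(cfg_a)$expr$values,
                   simulate_expression(cfg_b)$expr$values)
  expect_identical(simulate_codon_pairs(cfg_a)$pairs,
                   simulate_codon_pairs(cfg_b)$pairs)
  expect_identical(simulate_ct_table(cfg_a)$ct_table$ct,
                   simulate_ct_table(cfg_b)$ct_table$ct)
  # a different seed changes the sequence content
  gen_c <- simulate_genome(tiny_config(seed = 8))
  expect_false(identical(gen_a$genome, gen_c$genome))
})

test_that("planted promoter sites are recovered exactly by the scanner", {
  cfg <- tiny_config(seed = 2)
  gen <- simulate_genome(cfg)
  counts <- count_sites(gen$promoters, cfg$consensus)
  # the planted spec: g0002 has 2 sites, g0003 has 1 (1 mismatch), others 0
  expect_equal(counts$site_count[counts$gene_id == "g0002"], 2L)
  expect_equal(counts$site_count[counts$gene_id == "g0003"], 1L)
  expect_equal(sum(counts$site_count), 3L)
  # per-hit truth: offsets, strands and mismatch counts all line up
  hits <- scan_promoters(gen$promoters, cfg$consensus)
  truth <- dplyr::arrange(gen$site_truth, gene_id, offset, strand)
  hits <- dplyr::arrange(hits, gene_id, offset, strand)
  expect_equal(hits$gene_id, truth$gene_id)
  expect_equal(hits$offset, truth$offset)
  expect_equal(hits$strand, truth$strand)
  expect_equal(hits$mismatches, truth$mismatches)
})

test_that("a site-free configuration yields zero hits genome-wide", {
  cfg <- no_structure_config(seed = 5, n_genes = 30)
  gen <- simulate_genome(cfg)
  hits <- scan_promoters(gen$promoters, cfg$consensus)
  expect_equal(nrow(hits), 0L)
  # and the whole chromosomes are clean on both strands
  for (chr in gen$genome) {
    expect_equal(nrow(scan_sequence(chr, cfg$consensus)), 0L)
  }
})

test_that("genome generation respects promoter capacity limits", {
  expect_error(
    sim_config(n_genes = 10, promoter_length = 20,
               modules = list(planted_module(1:5, "leaf_cold_24h")),
               planted_sites = tibble::tibble(
                 gene_id = "g0001", site_count = 5L, strand = "plus",
                 mismatches_per_site = 0L)),
    "capacity"
  )
})

test_that("noiseless module members are perfectly correlated", {
  cfg <- tiny_config(seed = 3, noise_sd = 0)
  ex <- simulate_expression(cfg)
  members <- ex$module_truth$gene_id
  lg <- log2(ex$expr$values[members, ])
  cc <- cor(t(lg))
  expect_true(all(abs(cc - 1) < 1e-12))
  expect_error(tiny_config(noise_sd = -1), "noise_sd")
})

test_that("planted module tracks its trait indicator at default noise", {
  ok <- logical(20)
  for (s in 1:20) {
    cfg <- sim_config(seed = s)
    ex <- simulate_expression(cfg)
    cold <- ex$module_truth$gene_id[ex$module_truth$module == "planted-1"]
    me <- module_eigengene(ex$expr, cold)
    ind <- ex$expr$traits[, "leaf_cold_24h"]
    ok[s] <- abs(cor(me, ind)) >= 0.9
  }
  expect_gte(mean(ok), 0.9)
})

test_that("genes outside all modules are uncorrelated on average", {
  cfg <- sim_config(seed = 41)
  ex <- simulate_expression(cfg)
  bg <- setdiff(rownames(ex$expr$values), ex$module_truth$gene_id)[1:50]
  cc <- cor(t(log2(ex$expr$values[bg, ] + 1)))
  mean_abs_r <- mean(abs(cc[upper.tri(cc)]))
  expect_lt(mean_abs_r, 0.2)
})

test_that("codon pair simulation respects its construction invariants", {
  cfg <- tiny_config(seed = 9)
  cp <- simulate_codon_pairs(cfg)
  # ks_target 0: the two sequences are identical
  expect_identical(cp$pairs$seq_a[1], cp$pairs$seq_b[1])
  # multiples of 3 and stop-free throughout
  for (s in c(cp$pairs$seq_a, cp$pairs$seq_b)) {
    expect_equal(nchar(s) %% 3, 0)
    n <- nchar(s) / 3
    cods <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
    expect_false(any(cods %in% oracle_stops))
  }
  # realized divergence is close to its target
  expect_equal(cp$truth$realized_ks[2], 0.2, tolerance = 0.15)
})

test_that("ct simulation recovers fold changes in the noiseless limit", {
  cfg <- tiny_config(seed = 6)
  cfg$ct$sigma_ct <- 0
  sim <- simulate_ct_table(cfg)
  rq <- delta_delta_ct(sim$ct_table, "target_1", cfg$ct$reference_genes)
  summ <- rq_summary(rq)
  truth <- sim$truth[sim$truth$gene_id == "target_1", ]
  for (g in summ$group) {
    expect_equal(summ$mean_rq[summ$group == g],
                 truth$true_fold_change[truth$group == g], tolerance = 1e-12)
  }
})

test_that("noisy ct simulation recovers a 4-fold change on average", {
  rqs <- numeric(100)
  for (s in 1:100) {
    cfg <- tiny_config(seed = s)
    sim <- simulate_ct_table(cfg)   # sigma_ct 0.2, n = 3
    rq <- delta_delta_ct(sim$ct_table, "target_1", cfg$ct$reference_genes)
    summ <- rq_summary(rq)
    rqs[s] <- summ$mean_rq[summ$group == "cold_24h"]
  }
  expect_gte(mean(rqs), 3)
  expect_lte(mean(rqs), 5)
})

test_that("reference-only quantification is flat at 1", {
  cfg <- tiny_config(seed = 10)
  cfg$ct$sigma_ct <- 0
  sim <- simulate_ct_table(cfg)
  # quantify a reference gene against the other references
  rq <- delta_delta_ct(sim$ct_table, "ref_his",
                       setdiff(cfg$ct$reference_genes, "ref_his"))
  expect_true(all(abs(rq$rq - 1) < 1e-12))
})
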