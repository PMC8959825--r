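# Correlation inference, soft threshold, TOM, clustering, module cutting
# and merging, eigengenes and module-trait correlation.

test_that("pearson_with_p matches its closed-form limits and quadrature", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10, 12, 11)
  res <- pearson_with_p(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  # orthogonalized pair: r = 0 => p = 1
  y <- rnorm(12)
  y_orth <- residuals(lm(y ~ x))
  res0 <- pearson_with_p(x, y_orth)
  expect_equal(res0$r, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  # fixed n = 20 vectors against the t-density quadrature oracle
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(20); b <- 0.4 * a + rnorm(20)
    res <- pearson_with_p(a, b)
    expect_equal(res$p, oracle_cor_p(res$r, 20), tolerance = 1e-10)
  }
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("TOM matches the formula and the triple-loop oracle", {
  # 3-gene toy: a_12 = a_13 = a_23 = 0.5 -> TOM_12 = (0.25 + 0.5) / (1.5)
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(diag(tom), rep(1, 3))
  # zero adjacency -> zero overlap off the diagonal
  z <- diag(3)
  expect_true(all(tom_similarity(z)[upper.tri(z)] == 0))
  # random matrices against the brute-force evaluation
  set.seed(8)
  for (i in 1:5) {
    n <- sample(15:25, 1)
    r <- matrix(runif(n * n), n)
    adj <- (r + t(r)) / 2
    diag(adj) <- 1
    tom <- tom_similarity(adj)
    expect_equal(max(abs(tom - oracle_tom(adj))), 0, tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_identical(tom, t(tom))
  }
  bad <- matrix(runif(16), 4); bad[1, 2] <- bad[2, 1] + 1e-3
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("adjacency shrinks monotonically in beta", {
  set.seed(4)
  m <- matrix(rnorm(30 * 10), 30)
  rownames(m) <- paste0("g", 1:30); colnames(m) <- paste0("s", 1:10)
  a2 <- adjacency_matrix(m, 2, transform = "none")
  a5 <- adjacency_matrix(m, 5, transform = "none")
  expect_true(all(a5 <= a2 + 1e-15))
})

test_that("soft threshold selection is reproducible from its diagnostics", {
  cfg <- sim_config(seed = 2)
  ex <- simulate_expression(cfg)
  st <- pick_soft_threshold(ex$expr)
  d <- st$diagnostics[!st$diagnostics$degenerate, ]
  hit <- d$beta[d$r2 >= st$r2_target]
  expected <- if (length(hit) > 0) hit[1] else d$beta[which.max(d$r2)]
  expect_equal(st$beta, expected)
  expect_true(st$beta %in% 1:20)
})

test_that("degenerate correlation structure falls back with a flag", {
  # perfectly correlated genes: connectivity is constant at every beta
  base <- seq_len(12)
  m <- outer(rep(1, 20), base) + outer(seq(0, 1.9, by = 0.1), rep(0, 12))
  rownames(m) <- paste0("g", 1:20); colnames(m) <- paste0("s", 1:12)
  st <- suppressWarnings(pick_soft_threshold(m, transform = "none"))
  expect_true(all(st$diagnostics$degenerate))
  expect_equal(st$beta, 6)
})

test_that("average linkage reproduces a hand-worked UPGMA trace", {
  # two tight pairs, one outlier:
  # {1,2} at 0.1; {3,4} at 0.2; pairs join at 0.9 (mean of 4 cross
  # distances); 5 joins last at 1.0 (mean of its 4 distances)
  d <- matrix(1, 5, 5)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  d[1, 3] <- d[3, 1] <- d[1, 4] <- d[4, 1] <- 0.9
  d[2, 3] <- d[3, 2] <- d[2, 4] <- d[4, 2] <- 0.9
  dimnames(d) <- list(paste0("g", 1:5), paste0("g", 1:5))
  tree <- average_linkage_cluster(d)
  expect_equal(tree$height, c(0.1, 0.2, 0.9, 1.0))
  # identical genes merge first at height 0
  d0 <- matrix(0.5, 3, 3); diag(d0) <- 0; d0[1, 2] <- d0[2, 1] <- 0
  tree0 <- average_linkage_cluster(d0)
  expect_equal(tree0$height[1], 0)
  expect_setequal(-tree0$merge[1, ], 1:2)
})

test_that("static cut assigns tight blocks and leaves noise unassigned", {
  # all mutually dissimilar -> everything unassigned
  n <- 30
  d1 <- matrix(1, n, n); diag(d1) <- 0
  dimnames(d1) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a1 <- cut_modules(average_linkage_cluster(d1), min_module_size = 10)
  expect_true(all(a1$module == "unassigned"))
  # two planted blocks of 15 -> exactly two perfect modules
  d2 <- matrix(1, n, n)
  d2[1:15, 1:15] <- 0.05
  d2[16:30, 16:30] <- 0.1
  diag(d2) <- 0
  dimnames(d2) <- dimnames(d1)
  a2 <- cut_modules(average_linkage_cluster(d2), min_module_size = 10)
  expect_equal(length(unique(a2$module[1:15])), 1L)
  expect_equal(length(unique(a2$module[16:30])), 1L)
  expect_false(a2$module[1] == a2$module[16])
  expect_false(any(a2$module == "unassigned"))
  # a block of 5 below min_module_size ends up unassigned
  d3 <- matrix(1, 20, 20)
  d3[1:5, 1:5] <- 0.05
  diag(d3) <- 0
  dimnames(d3) <- list(paste0("g", 1:20), paste0("g", 1:20))
  a3 <- cut_modules(average_linkage_cluster(d3), min_module_size = 10)
  expect_true(all(a3$module == "unassigned"))
})

# expression matrix with block-structured profiles for merge tests
block_expr <- function(profiles, size = 6, noise = 0, seed = 1) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    matrix(rep(profiles[[i]], each = size), nrow = size) +
      matrix(rnorm(size * length(profiles[[i]]), sd = noise), nrow = size)
  }))
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("modules with near-identical eigengenes are merged", {
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  m <- block_expr(list(base, base + 0.1, rev(base)), size = 6, noise = 0.05)
  assignment <- tibble::tibble(
    gene_id = rownames(m),
    module = rep(c("module-1", "module-2", "module-3"), each = 6)
  )
  merged <- merge_modules(assignment, m, merge_cut_height = 0.2, transform = "none")
  # the two parallel blocks merge; the reversed block stays separate
  expect_equal(length(setdiff(unique(merged$module), "unassigned")), 2L)
  expect_equal(length(unique(merged$module[1:12])), 1L)
  expect_false(merged$module[1] == merged$module[13])
  # at cut 0: nothing merges
  none <- merge_modules(assignment, m, merge_cut_height = 0, transform = "none")
  expect_equal(length(setdiff(unique(none$module), "unassigned")), 3L)
})

test_that("three mutually similar modules collapse into one", {
  set.seed(9)
  base <- rnorm(16)
  m <- block_expr(list(base, base + rnorm(16, sd = 0.25),
                       base + rnorm(16, sd = 0.25)), size = 5, noise = 0.02)
  assignment <- tibble::tibble(
    gene_id = rownames(m),
    module = rep(paste0("module-", 1:3), each = 5)
  )
  me <- module_eigengenes(m, assignment, transform = "none")
  cors <- cor(me)[upper.tri(diag(3))]
  expect_true(all(cors > 0.8))  # construction: pairwise ME correlation high
  merged <- merge_modules(assignment, m, merge_cut_height = 0.2, transform = "none")
  expect_equal(length(setdiff(unique(merged$module), "unassigned")), 1L)
})

test_that("module eigengene is the oriented first PC", {
  # identical genes: eigengene proportional to the standardized profile
  prof <- c(2, 4, 1, 5, 3, 6, 2, 7)
  m <- block_expr(list(prof), size = 4, noise = 0)
  me <- module_eigengene(m, rownames(m), transform = "none")
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(abs(cor(me, z)), 1, tolerance = 1e-12)
  expect_gte(mean(cor(me, t(m))), 0)
  expect_equal(attr(me, "var_explained"), 1, tolerance = 1e-12)
  # 2-gene anticorrelated module: the standardized rows span one axis
  # (PC1 takes essentially all variance) and the orientation rule still
  # gives nonnegative mean member correlation
  m2 <- rbind(g1 = z, g2 = -z + rnorm(8, sd = 0.01))
  colnames(m2) <- paste0("s", 1:8)
  me2 <- module_eigengene(m2, c("g1", "g2"), transform = "none")
  expect_gte(attr(me2, "var_explained"), 0.9)
  expect_gte(mean(cor(me2, t((m2 - rowMeans(m2)) / apply(m2, 1, sd)))), 0)
  # permutation invariance up to sign
  set.seed(12)
  m3 <- matrix(rnorm(6 * 10), 6, dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  me_a <- module_eigengene(m3, paste0("g", 1:6), transform = "none")
  me_b <- module_eigengene(m3[sample(6), ], paste0("g", 1:6), transform = "none")
  expect_equal(abs(cor(me_a, me_b)), 1, tolerance = 1e-10)
  # constant member genes are an error
  m4 <- rbind(g1 = rep(1, 5), g2 = rnorm(5))
  colnames(m4) <- paste0("s", 1:5)
  expect_error(module_eigengene(m4, c("g1", "g2"), transform = "none"), "singular|constant")
})

test_that("module-trait correlation handles exact and degenerate traits", {
  cfg <- sim_config(seed = 6)
  ex <- simulate_expression(cfg)
  fit <- coexpression_modules(ex$expr)
  traits <- ex$expr$traits
  mt <- module_trait_correlation(fit$eigengenes, traits)
  expect_true(all(c("module", "trait", "r", "n", "p") %in% names(mt)))
  expect_true(all(abs(mt$r) <= 1))
  # a trait equal to an eigengene correlates at exactly 1
  t2 <- cbind(traits, me_copy = fit$eigengenes[, 1])
  mt2 <- module_trait_correlation(fit$eigengenes, t2)
  expect_equal(mt2$r[mt2$module == colnames(fit$eigengenes)[1] &
                       mt2$trait == "me_copy"], 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(fit$eigengenes,
                                        cbind(traits, flat = 1)), "flat")
})

test_that("gene order only permutes labels, never the partition", {
  cfg <- sim_config(seed = 14)
  ex <- simulate_expression(cfg)
  fit1 <- coexpression_modules(ex$expr, beta = 6)
  set.seed(99)
  perm <- sample(nrow(ex$expr$values))
  fit2 <- coexpression_modules(ex$expr$values[perm, ], beta = 6)
  m2 <- fit2$assignment$module[match(fit1$assignment$gene_id,
                                     fit2$assignment$gene_id)]
  expect_equal(mclust::adjustedRandIndex(fit1$assignment$module, m2), 1)
})
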