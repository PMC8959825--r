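# FASTA/GFF parsing, promoter extraction conventions, expression matrix IO.

test_that("read_fasta takes the first header token and uppercases", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "acgt", ">c2", "AC", "GT", "TT"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs, c(c1 = "ACGT", c2 = "ACGTTT"))
  # duplicate identifiers are an error
  writeLines(c(">c1", "AAAA", ">c1", "CCCC"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")
})

test_that("fasta round trip preserves sequences through wrapping", {
  path <- withr::local_tempfile(fileext = ".fasta")
  set.seed(3)
  seqs <- c(a = random_dna_string(250), b = random_dna_string(10))
  write_fasta(seqs, path, width = 60)
  expect_equal(read_fasta(path), seqs)
})

test_that("read_gff_genes anchors the TIS by strand", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t400\t.\t+\t.\tID=gp",
    "chr1\tx\tgene\t101\t400\t.\t-\t.\tID=gm"
  ), path)
  genes <- read_gff_genes(path)
  expect_equal(genes$tis[genes$gene_id == "gp"], 101)
  expect_equal(genes$tis[genes$gene_id == "gm"], 400)
  # CDS rows are preferred over the gene row when present
  writeLines(c(
    "chr1\tx\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tx\tCDS\t120\t260\t.\t+\t.\tParent=g1"
  ), path)
  expect_equal(read_gff_genes(path)$tis, 120)
})

test_that("gff parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tx\tgene\t1\t10\t.\t+\t."), path)
  expect_error(read_gff_genes(path), "line 2.*9 tab-separated")
  writeLines(c("chr1\tx\tgene\t1\t10\t.\t*\t.\tID=a"), path)
  expect_error(read_gff_genes(path), "strand.*line 1")
  writeLines(c("chr1\tx\tgene\t10\t1\t.\t+\t.\tID=a"), path)
  expect_error(read_gff_genes(path), "coordinates.*line 1")
})

test_that("promoter extraction follows the stated strand conventions", {
  genome <- c(chr = "AAAACGTTTT")  # positions 1..10
  genes <- tibble::tibble(
    gene_id = c("plus", "minus", "edge"),
    chromosome = "chr", strand = c("+", "-", "+"),
    start = c(6, 1, 2), end = c(10, 5, 9),
    tis = c(6, 5, 2)
  )
  prom <- extract_promoters(genome, genes, window = 3)
  # + strand, tis 6: bases 3..5 of AAAACGTTTT
  expect_equal(prom$sequence[1], "AAC")
  # - strand, tis 5: revcomp of bases 6..8 ("GTT")
  expect_equal(prom$sequence[2], "AAC")
  # truncation at the chromosome start: only base 1 remains
  prom_big <- extract_promoters(genome, genes, window = 1000)
  expect_equal(prom_big$sequence[3], "A")
  expect_equal(prom_big$length[3], 1L)
  expect_true(prom_big$truncated[3])
  expect_error(extract_promoters(genome, dplyr::mutate(genes, chromosome = "nope")),
               "plus.*minus.*edge")
})

test_that("promoters are invariant under genome reverse complementation", {
  set.seed(17)
  for (i in 1:5) {
    len <- 400
    genome <- c(chrA = random_dna_string(len))
    genes <- tibble::tibble(
      gene_id = c("f", "r"),
      chromosome = "chrA",
      strand = c("+", "-"),
      start = c(201, 101), end = c(300, 180),
      tis = c(201, 180)
    )
    fwd <- extract_promoters(genome, genes, window = 50)
    flipped_genome <- c(chrA = reverse_complement(genome[["chrA"]]))
    flipped_genes <- dplyr::mutate(
      genes,
      strand = ifelse(strand == "+", "-", "+"),
      tis = len - tis + 1,
      start2 = len - end + 1, end = len - start + 1, start = start2
    )[, names(genes)]
    rev <- extract_promoters(flipped_genome, flipped_genes, window = 50)
    expect_equal(rev$sequence, fwd$sequence)
  }
})

test_that("expression matrix IO validates and aligns the sample sheet", {
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  sheet_path <- withr::local_tempfile(fileext = ".tsv")
  mat <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        s1 = c(1, 2, 3), s2 = c(4, 5, 6),
                        s3 = c(0, 0, 1), s4 = c(2, 2, 2))
  sheet <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    tissue = c("leaf", "leaf", "root", "root"),
    stress = c("control", "cold", "control", "cold"),
    timepoint = "24h", replicate = 1L
  )
  readr::write_tsv(mat, mat_path)
  readr::write_tsv(sheet, sheet_path)
  es <- read_expression_matrix(mat_path, sheet_path)
  expect_equal(dim(es), c(3L, 4L))
  # one binary trait per (tissue, stress, timepoint) combination
  expect_equal(ncol(es$traits), 4L)
  expect_true(all(es$traits %in% 0:1))
  expect_equal(unname(es$traits[, "leaf_cold_24h"]), c(0L, 1L, 0L, 0L))
  # mismatched sample sets name the symmetric difference
  readr::write_tsv(sheet[sheet$sample_id != "s2", ], sheet_path)
  expect_error(read_expression_matrix(mat_path, sheet_path), "s2")
  # negative values rejected
  mat$s1[1] <- -5
  readr::write_tsv(mat, mat_path)
  readr::write_tsv(sheet, sheet_path)
  expect_error(read_expression_matrix(mat_path, sheet_path), "negative")
})

test_that("expression set round-trips through TSV", {
  cfg <- tiny_config(seed = 8)
  ex <- simulate_expression(cfg)
  m_path <- withr::local_tempfile(fileext = ".tsv")
  s_path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ex$expr, m_path, s_path)
  back <- read_expression_matrix(m_path, s_path)
  expect_equal(back$values, ex$expr$values, tolerance = 1e-12)
  expect_equal(back$samples$sample_id, ex$expr$samples$sample_id)
  # tidy() gives one row per measurement with metadata attached
  td <- tidy(back)
  expect_equal(nrow(td), prod(dim(back)))
  expect_true(all(c("tissue", "stress", "tpm") %in% names(td)))
})
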