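# NG86 site/difference counting, Jukes-Cantor correction and epoch
# binning, checked against direct enumeration oracles.

test_that("site counts match neighbour enumeration for single codons", {
  # TTT (Phe): only TTT->TTC is synonymous among the 9 neighbours
  expect_equal(unname(ng86_site_counts("TTT")["s"]), 1 / 3)
  expect_equal(unname(ng86_site_counts("TTT")["n"]), 8 / 3)
  # ATG (Met) is a singleton family
  expect_equal(unname(ng86_site_counts("ATG")["s"]), 0)
  expect_error(ng86_site_counts("TAA"), "stop")
  expect_error(ng86_site_counts("AXG"), "codon")
  # every sense codon: s + n = 3 exactly, and s matches the oracle
  sense <- setdiff(names(oracle_code), oracle_stops)
  for (cd in sense) {
    sc <- ng86_site_counts(cd)
    expect_equal(unname(sc["s"] + sc["n"]), 3)
    expect_equal(unname(sc["s"]), oracle_codon_s(cd))
  }
})

test_that("jc_correct has the closed form and a saturation domain", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.3), -0.75 * log(0.6))
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.9)))
  # monotone and >= p on its domain
  p <- seq(0, 0.7, by = 0.05)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("ng86_pair handles identity, symmetry, and the saturating toy", {
  s <- "ATGTTTGGA"
  est <- ng86_pair(s, s)
  expect_equal(est$Sd, 0)
  expect_equal(est$Nd, 0)
  expect_equal(est$Ks, 0)
  expect_equal(est$Ka, 0)
  # single-codon synonymous pair: pS = 1 / (1/3) = 3 -> saturated flag
  toy <- ng86_pair("TTT", "TTC")
  expect_equal(toy$Sd, 1)
  expect_equal(toy$Nd, 0)
  expect_equal(toy$S, 1 / 3)
  expect_true(toy$saturated)
  expect_true(is.na(toy$Ks))
  # symmetry
  set.seed(5)
  for (i in 1:10) {
    a <- random_sense_codons(20)
    b <- mutate_coding(a, 6)
    expect_equal(ng86_pair(a, b)[-1], ng86_pair(b, a)[-1], tolerance = 1e-12)
  }
})

test_that("ng86_pair validates its contract", {
  expect_error(ng86_pair("ATG", "ATGATG"), "length")
  expect_error(ng86_pair("ATGA", "ATGC"), "multiple of 3")
  expect_error(ng86_pair("TAAATG", "TAAATG"), "stop")
  expect_error(ng86_pair("ATGNNN", "ATGAAA"), "non-ACGT")
})

test_that("ng86_pair equals the pathway-enumeration oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    a <- random_sense_codons(n)
    b <- mutate_coding(a, sample(1:(2 * n), 1))
    got <- ng86_pair(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    if (!got$saturated) {
      expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
      expect_equal(got$Ka, want$Ka, tolerance = 1e-12)
    }
  }
})

test_that("an extra synonymous difference never decreases Ks", {
  set.seed(13)
  for (i in 1:15) {
    a <- random_sense_codons(60)
    b <- mutate_coding(a, 10)
    base <- ng86_pair(a, b)
    # find a codon where the sequences agree and a synonymous 1-nt variant
    n <- nchar(b) / 3
    cods_a <- substring(a, 3 * seq_len(n) - 2, 3 * seq_len(n))
    cods_b <- substring(b, 3 * seq_len(n) - 2, 3 * seq_len(n))
    done <- FALSE
    for (ci in sample(which(cods_a == cods_b))) {
      cd <- cods_b[ci]
      chars <- strsplit(cd, "")[[1]]
      for (pos in 1:3) {
        for (bs in setdiff(c("A", "C", "G", "T"), chars[pos])) {
          mut <- chars; mut[pos] <- bs
          mc <- paste(mut, collapse = "")
          if (!(mc %in% oracle_stops) && oracle_code[[mc]] == oracle_code[[cd]]) {
            cods_b2 <- cods_b; cods_b2[ci] <- mc
            more <- ng86_pair(a, paste(cods_b2, collapse = ""))
            if (!base$saturated && !more$saturated) {
              expect_gte(more$Ks, base$Ks)
            }
            done <- TRUE
          }
          if (done) break
        }
        if (done) break
      }
      if (done) break
    }
  }
})

test_that("epoch classification uses half-open bins and an unassigned label", {
  est <- tibble::tibble(
    pair_id = c("a", "b", "c", "d", "e"),
    Ks = c(0.25, 4.0, 10.0, 1.5, NA),
    saturated = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  out <- classify_epochs(est, epoch_bins())
  expect_equal(out$epoch, c("rWGD", "ancient-WGD", "unassigned",
                            "gamma-WGT", "unassigned"))
  # boundary: half-open [low, high)
  b <- epoch_bins(labels = "x", ks_low = 0.1, ks_high = 0.5)
  edge <- classify_epochs(tibble::tibble(pair_id = c("p", "q"),
                                         Ks = c(0.1, 0.5),
                                         saturated = c(FALSE, FALSE)), b)
  expect_equal(edge$epoch, c("x", "unassigned"))
  expect_error(epoch_bins(ks_low = c(0, 0.2), ks_high = c(0.3, 0.4),
                          labels = c("a", "b")), "overlap")
})

test_that("codon pairs round-trip through paired FASTA", {
  cfg <- tiny_config(seed = 4)
  cp <- simulate_codon_pairs(cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_pairs(cp$pairs, path)
  back <- read_codon_pairs(path)
  expect_equal(back$pair_id, cp$pairs$pair_id)
  expect_equal(back$seq_a, cp$pairs$seq_a)
  expect_equal(back$seq_b, cp$pairs$seq_b)
  # and the table interface reproduces the single-pair estimates
  est <- ks_estimate(back)
  expect_equal(est$Ks[1], 0)
})
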