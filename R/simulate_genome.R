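# Synthetic genome with planted promoter motif sites.
#
# Background sequence is i.i.d. uniform over {A,C,G,T}; every window that
# accidentally matches the configured consensus within its mismatch budget
# (either strand) is rejection-resampled, so the emitted site truth table
# is exact.  Genes sit on both strands; each gene region is
# promoter + body laid 5'->3' on the coding strand and reverse-complemented
# into the genome for minus-strand genes.

#' Simulate a genome, gene models and promoter site truth
#'
#' @param config a [sim_config()].
#' @return list: `genome` (named chromosome sequences), `genes` (gene-model
#'   tibble as from [read_gff_genes()]), `site_truth` (tibble `gene_id`,
#'   `offset` 0-based in the promoter, `strand` promoter-relative,
#'   `mismatches`), `promoters` (the planted promoter tibble, identical to
#'   what [extract_promoters()] recovers from `genome` + `genes`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  motif <- config$consensus
  P <- config$promoter_length
  site_spec <- config$planted_sites
  promoters <- character(config$n_genes)
  truth <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    gid <- config$gene_ids[i]
    spec_row <- site_spec[site_spec$gene_id == gid, ]
    n_sites <- if (nrow(spec_row) == 1L) spec_row$site_count else 0L
    res <- build_promoter(
      P, motif, n_sites,
      strand = if (nrow(spec_row) == 1L) spec_row$strand else "plus",
      mism = if (nrow(spec_row) == 1L) spec_row$mismatches_per_site else 0L
    )
    promoters[i] <- res$sequence
    truth[[i]] <- if (nrow(res$truth) > 0L) mutate(res$truth, gene_id = gid) else NULL
  }
  site_truth <- bind_rows(truth)
  if (nrow(site_truth) == 0L) {
    site_truth <- tibble(gene_id = character(), offset = integer(),
                         strand = character(), mismatches = integer())
  } else {
    site_truth <- select(site_truth, "gene_id", "offset", "strand", "mismatches")
  }

  # gene bodies and layout
  B <- config$body_length
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  bodies <- vapply(seq_len(config$n_genes), function(i) {
    paste0("ATG", scrub_matches(random_dna(B - 3L), motif))
  }, character(1))
  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = config$n_genes)
  chrom_of <- sort(chrom_of)
  genome <- character(config$n_chromosomes)
  gene_rows <- vector("list", config$n_genes)
  for (chr in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == chr)
    pos <- 1L
    parts <- character(0)
    for (i in idx) {
      spacer <- scrub_matches(random_dna(config$spacer_length), motif)
      parts <- c(parts, spacer)
      pos <- pos + config$spacer_length
      region <- paste0(promoters[i], bodies[i])
      seg_start <- pos
      if (strands[i] == "+") {
        start <- seg_start + P
        end <- seg_start + P + B - 1L
        tis <- start
        parts <- c(parts, region)
      } else {
        start <- seg_start
        end <- seg_start + B - 1L
        tis <- end
        parts <- c(parts, reverse_complement(region))
      }
      pos <- pos + P + B
      gene_rows[[i]] <- tibble(
        gene_id = config$gene_ids[i], chromosome = paste0("chr", chr),
        strand = strands[i], start = start, end = end, tis = tis
      )
    }
    parts <- c(parts, scrub_matches(random_dna(config$spacer_length), motif))
    genome[chr] <- paste(parts, collapse = "")
  }
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  genes <- bind_rows(gene_rows)

  # junction scrub: windows spanning spacer/promoter/body boundaries can
  # still match; resample any hit whose bases lie outside planted windows
  protected <- planted_windows(genes, site_truth, P, B, nchar(motif$iupac))
  for (chr in names(genome)) {
    genome[chr] <- scrub_matches(genome[chr], motif,
                                 protected = protected[[chr]] %||% integer(0))
  }

  prom_tbl <- extract_promoters(genome, genes, window = P)
  verify_site_truth(prom_tbl, site_truth, motif)
  list(genome = genome, genes = genes, site_truth = site_truth,
       promoters = prom_tbl)
}

# genomic base positions (per chromosome) belonging to planted site windows
planted_windows <- function(genes, site_truth, P, B, L) {
  if (nrow(site_truth) == 0L) return(list())
  tr <- left_join(site_truth, genes, by = "gene_id", suffix = c("", ".g"))
  out <- list()
  for (i in seq_len(nrow(tr))) {
    o <- tr$offset[i]
    if (tr$strand.g[i] == "+") {
      seg_start <- tr$start[i] - P
      gpos <- (seg_start + o):(seg_start + o + L - 1L)
    } else {
      seg_start <- tr$start[i]
      gpos <- (seg_start + P + B - o - L):(seg_start + P + B - 1L - o)
    }
    out[[tr$chromosome[i]]] <- c(out[[tr$chromosome[i]]], gpos)
  }
  out
}

# resample every consensus match (both strands, within budget) whose
# window touches at least one unprotected base, until none remain
scrub_matches <- function(seq, motif, protected = integer(0), max_iter = 200L) {
  L <- nchar(motif$iupac)
  n <- nchar(seq)
  if (n < L) return(seq)
  prot <- logical(n)
  prot[protected] <- TRUE
  chars <- seq_chars(seq)
  for (iter in seq_len(max_iter)) {
    s <- paste(chars, collapse = "")
    mmP <- mismatch_profile(s, motif$iupac)
    mmM <- rev(mismatch_profile(reverse_complement(s), motif$iupac))
    hit_off <- which(mmP <= motif$max_mismatch | mmM <= motif$max_mismatch)
    if (length(hit_off) == 0L) return(s)
    changed <- FALSE
    for (o in hit_off) {
      span <- o:(o + L - 1L)
      free <- span[!prot[span]]
      if (length(free) == 0L) next  # fully planted window
      chars[free] <- sample(DNA_BASES, length(free), replace = TRUE)
      changed <- TRUE
    }
    if (!changed) return(paste(chars, collapse = ""))
  }
  abort("scrub_matches failed to converge; consensus too permissive for the background")
}

# one promoter: scrubbed background + n_sites planted occurrences,
# verified by a full two-strand scan against the intended truth
build_promoter <- function(P, motif, n_sites, strand = "plus", mism = 0L,
                           max_tries = 100L) {
  L <- nchar(motif$iupac)
  for (try in seq_len(max_tries)) {
    bg <- scrub_matches(random_dna(P), motif)
    if (n_sites == 0L) {
      return(list(sequence = bg,
                  truth = tibble(offset = integer(), strand = character(),
                                 mismatches = integer())))
    }
    offs <- sample_site_offsets(P, L, n_sites)
    strands <- switch(strand,
      plus = rep("+", n_sites),
      minus = rep("-", n_sites),
      both = rep(c("+", "-"), length.out = n_sites)
    )
    chars <- seq_chars(bg)
    for (k in seq_len(n_sites)) {
      inst <- motif_instance(motif, mism)
      if (strands[k] == "-") inst <- reverse_complement(inst)
      chars[(offs[k] + 1L):(offs[k] + L)] <- seq_chars(inst)
    }
    seq <- paste(chars, collapse = "")
    want <- tibble(offset = offs, strand = strands,
                   mismatches = rep(as.integer(mism), n_sites)) |>
      arrange(.data$offset, .data$strand)
    got <- scan_sequence(seq, motif, both_strands = TRUE)
    if (nrow(got) == nrow(want) &&
        all(got$offset == want$offset) && all(got$strand == want$strand) &&
        all(got$mismatches == want$mismatches)) {
      return(list(sequence = seq, truth = want))
    }
  }
  abort("could not plant sites without creating spurious matches; relax the configuration")
}

# non-overlapping 0-based offsets with at least one spacer base between
# sites
sample_site_offsets <- function(P, L, n_sites, max_tries = 1000L) {
  stopifnot(P >= n_sites * L)
  for (try in seq_len(max_tries)) {
    offs <- sort(sample(0:(P - L), n_sites))
    if (n_sites == 1L || all(diff(offs) > L)) return(offs)
  }
  abort("could not place non-overlapping sites; promoter too crowded")
}

# concrete site instance: degenerate positions filled at random, then
# `mism` constrained positions mutated outside their allowed set
motif_instance <- function(motif, mism = 0L) {
  cc <- seq_chars(motif$iupac)
  inst <- vapply(cc, function(code) {
    allowed <- intersect(IUPAC_SETS[[code]], DNA_BASES)
    allowed[sample.int(length(allowed), 1L)]
  }, character(1))
  if (mism > 0L) {
    constrained <- which(lengths(IUPAC_SETS[cc]) < 4L)
    pos <- sample(constrained, mism)
    for (p in pos) {
      forbidden <- setdiff(DNA_BASES, IUPAC_SETS[[cc[p]]])
      inst[p] <- forbidden[sample.int(length(forbidden), 1L)]
    }
  }
  paste(inst, collapse = "")
}

# internal consistency check: the promoters recovered from the genome must
# carry exactly the planted sites
verify_site_truth <- function(prom_tbl, site_truth, motif) {
  hits <- scan_promoters(prom_tbl, motif)
  truth_counts <- table(site_truth$gene_id)
  hit_counts <- table(hits$gene_id)
  all_ids <- prom_tbl$gene_id
  t_n <- as.integer(ifelse(is.na(truth_counts[all_ids]), 0L, truth_counts[all_ids]))
  h_n <- as.integer(ifelse(is.na(hit_counts[all_ids]), 0L, hit_counts[all_ids]))
  if (!all(t_n == h_n)) {
    abort("internal error: recovered promoter sites deviate from the planted truth")
  }
  invisible(TRUE)
}
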