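# Degenerate IUPAC consensus scanning with a mismatch budget.
#
# The default consensus GTGGNCCC is the class II TCP binding site; the
# engine is generic over any IUPAC string.  N (and other degenerate codes)
# in the consensus are true wildcards for their nucleotide set and never
# consume the mismatch budget; an N in the *sequence* at a constrained
# consensus position counts as a mismatch (conservative).  Both strands
# are scanned by default and overlapping occurrences are all counted.

# N in the consensus accepts any base including an N in the sequence; an N
# in the sequence at any constrained position is a mismatch
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

#' Define a degenerate consensus motif
#'
#' @param iupac consensus string over the IUPAC nucleotide alphabet,
#'   length >= 4.
#' @param max_mismatch mismatch budget, `0 <= max_mismatch < nchar(iupac)`.
#' @return list of class `motif_consensus`.
#' @export
motif_consensus <- function(iupac = "GTGGNCCC", max_mismatch = 1) {
  check_string(iupac)
  iupac <- toupper(iupac)
  if (nchar(iupac) < 4) abort("consensus must be at least 4 bases long")
  bad <- setdiff(seq_chars(iupac), names(IUPAC_SETS))
  if (length(bad) > 0L) abort(glue("invalid IUPAC code(s): {paste(bad, collapse = ', ')}"))
  check_number(max_mismatch, min = 0, max = nchar(iupac) - 1)
  structure(list(iupac = iupac, max_mismatch = as.integer(max_mismatch)),
            class = "motif_consensus")
}

as_motif <- function(x) {
  if (inherits(x, "motif_consensus")) x else motif_consensus(x)
}

#' Mismatch count of a window against a consensus
#'
#' @param window sequence of the same length as the consensus.
#' @param consensus a [motif_consensus()] (or IUPAC string, budget 1).
#' @return the mismatch count, or `NA_integer_` when it exceeds the budget
#'   (no match).
#' @export
match_mismatches <- function(window, consensus = motif_consensus()) {
  consensus <- as_motif(consensus)
  check_string(window)
  window <- toupper(window)
  if (nchar(window) != nchar(consensus$iupac)) {
    abort(glue("window length {nchar(window)} != consensus length {nchar(consensus$iupac)}"))
  }
  wc <- seq_chars(window)
  cc <- seq_chars(consensus$iupac)
  mm <- sum(vapply(seq_along(cc), function(i) !(wc[i] %in% IUPAC_SETS[[cc[i]]]),
                   logical(1)))
  if (mm > consensus$max_mismatch) NA_integer_ else as.integer(mm)
}

# vectorised mismatch profile: mismatch count at every offset of seq
# (returns integer vector of length nchar(seq) - L + 1, or length 0)
mismatch_profile <- function(seq, iupac) {
  L <- nchar(iupac)
  n <- nchar(seq)
  if (n < L) return(integer(0))
  chars <- seq_chars(seq)
  cc <- seq_chars(iupac)
  n_off <- n - L + 1L
  mm <- integer(n_off)
  for (j in seq_len(L)) {
    mm <- mm + !(chars[j:(j + n_off - 1L)] %in% IUPAC_SETS[[cc[j]]])
  }
  mm
}

#' Scan one sequence for consensus hits
#'
#' Every offset is tested (overlaps allowed).  Minus-strand hits are found
#' by scanning the reverse complement and mapping back to the coordinates
#' of the input sequence.  Hits are sorted by offset then strand.
#'
#' @param seq sequence over `{A,C,G,T,N}`.
#' @param consensus a [motif_consensus()] or IUPAC string.
#' @param both_strands scan the minus strand too (default `TRUE`).
#' @return tibble: `offset` (0-based within `seq`), `strand` (`"+"`/`"-"`),
#'   `mismatches`, `matched` (the plus-strand sequence of the window).
#' @export
scan_sequence <- function(seq, consensus = motif_consensus(), both_strands = TRUE) {
  consensus <- as_motif(consensus)
  check_string(seq)
  seq <- toupper(seq)
  L <- nchar(consensus$iupac)
  hit_rows <- function(mm, strand, total_len) {
    off <- which(mm <= consensus$max_mismatch) - 1L
    if (strand == "-") off <- (total_len - L) - off
    tibble(offset = off, strand = strand, mismatches = mm[mm <= consensus$max_mismatch])
  }
  plus <- hit_rows(mismatch_profile(seq, consensus$iupac), "+", nchar(seq))
  out <- if (both_strands && nchar(seq) >= L) {
    minus <- hit_rows(mismatch_profile(reverse_complement(seq), consensus$iupac),
                      "-", nchar(seq))
    bind_rows(plus, minus)
  } else {
    plus
  }
  out <- distinct(out, .data$offset, .data$strand, .keep_all = TRUE)
  if (nrow(out) == 0L) {
    return(tibble(offset = integer(), strand = character(),
                  mismatches = integer(), matched = character()))
  }
  out |>
    mutate(matched = substring(seq, .data$offset + 1L, .data$offset + L)) |>
    arrange(.data$offset, .data$strand)
}

#' Scan a promoter set and tabulate all hits
#'
#' @param promoters tibble with `gene_id` and `sequence` columns (see
#'   [extract_promoters()]).
#' @param consensus a [motif_consensus()] or IUPAC string.
#' @param both_strands scan the minus strand too.
#' @return tibble: `gene_id`, `offset`, `strand`, `mismatches`, `matched`.
#' @export
scan_promoters <- function(promoters, consensus = motif_consensus(),
                           both_strands = TRUE) {
  stopifnot(all(c("gene_id", "sequence") %in% names(promoters)))
  consensus <- as_motif(consensus)
  out <- map2(promoters$gene_id, promoters$sequence, function(id, s) {
    hits <- scan_sequence(s, consensus, both_strands)
    if (nrow(hits) > 0) mutate(hits, gene_id = id) else NULL
  }) |>
    bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(), offset = integer(),
                  strand = character(), mismatches = integer(),
                  matched = character()))
  }
  select(out, "gene_id", "offset", "strand", "mismatches", "matched")
}

#' Per-gene site counts
#'
#' @param promoters tibble with `gene_id` and `sequence`.
#' @param consensus a [motif_consensus()] or IUPAC string.
#' @param both_strands scan the minus strand too.
#' @return tibble `gene_id`, `site_count` (0 for promoters with no hits,
#'   including promoters shorter than the motif).
#' @export
count_sites <- function(promoters, consensus = motif_consensus(),
                        both_strands = TRUE) {
  hits <- scan_promoters(promoters, consensus, both_strands)
  counts <- table(hits$gene_id)
  tibble(
    gene_id = promoters$gene_id,
    site_count = as.integer(ifelse(is.na(counts[promoters$gene_id]), 0L,
                                   counts[promoters$gene_id]))
  )
}

#' Genes with at least k sites
#'
#' @param counts tibble `gene_id`, `site_count` (see [count_sites()]).
#' @param k minimum site count, `k >= 1`.
#' @return character vector of gene ids.
#' @export
genes_with_min_sites <- function(counts, k = 2) {
  check_number(k, min = 1)
  counts$gene_id[counts$site_count >= k]
}
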