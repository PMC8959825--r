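# Synonymous / nonsynonymous divergence for duplicate gene pairs by the
# Nei-Gojobori (1986) counting method with Jukes-Cantor correction.
#
# Conventions made explicit because implementations differ:
#   * in site counting, a single-nucleotide neighbour that is a stop codon
#     counts as a nonsynonymous change;
#   * in difference counting, substitution pathways that pass through a stop
#     codon are excluded from the average over orderings; if every ordering
#     is blocked, the average is taken over all orderings without the
#     exclusion.

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- genetic_code()[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

# cache for codon site fractions and pairwise difference contributions
.ks_cache <- new.env(parent = emptyenv())

all_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-nucleotide changes that preserve the amino acid is accumulated;
#' changes creating a stop codon count as nonsynonymous.  `s + n == 3`
#' exactly for every sense codon.
#'
#' @param codon a single sense codon (string of 3 bases).
#' @return named numeric vector `c(s = ..., n = ...)`.
#' @export
#' @examples
#' ng86_site_counts("TTT") # s = 1/3: only TTT -> TTC is synonymous
ng86_site_counts <- function(codon) {
  check_string(codon)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !all(seq_chars(codon) %in% DNA_BASES)) {
    abort(glue("not a codon: '{codon}'"))
  }
  if (codon %in% STOP_CODONS) abort(glue("stop codon '{codon}' has no site counts"))
  tab <- codon_site_table()
  c(s = tab[codon], n = 3 - tab[codon]) |> setNames(c("s", "n"))
}

codon_site_table <- function() {
  if (!is.null(.ks_cache$sites)) return(.ks_cache$sites)
  code <- genetic_code()
  sense <- setdiff(all_codons(), STOP_CODONS)
  s <- vapply(sense, function(cd) {
    chars <- seq_chars(cd)
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, chars[pos])) {
        mut <- chars
        mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (!(mutc %in% STOP_CODONS) && code[mutc] == code[cd]) syn <- syn + 1
      }
    }
    syn / 3
  }, numeric(1))
  .ks_cache$sites <- s
  s
}

# pathway-averaged (sd, nd) contributions for every ordered codon pair,
# stored as two 64 x 64 matrices indexed by codon string
codon_diff_tables <- function() {
  if (!is.null(.ks_cache$sd)) return(list(sd = .ks_cache$sd, nd = .ks_cache$nd))
  codons <- all_codons()
  nsense <- setdiff(codons, STOP_CODONS)
  sd <- nd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  for (a in nsense) {
    for (b in nsense) {
      d <- pathway_diffs(a, b)
      sd[a, b] <- d[["sd"]]
      nd[a, b] <- d[["nd"]]
    }
  }
  .ks_cache$sd <- sd
  .ks_cache$nd <- nd
  list(sd = sd, nd = nd)
}

# average syn/nonsyn step counts over substitution orderings between two
# codons, excluding orderings that pass through a stop codon (with the
# all-blocked fallback)
pathway_diffs <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  diff_pos <- which(ca != cb)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- perms(diff_pos)
  code <- genetic_code()
  aa_of <- function(cd) if (cd %in% STOP_CODONS) "*" else unname(code[cd])
  walk_one <- function(ord) {
    cur <- ca
    syn <- non <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      cur_c <- paste(cur, collapse = "")
      nxt_c <- paste(nxt, collapse = "")
      if (aa_of(cur_c) == aa_of(nxt_c)) syn <- syn + 1 else non <- non + 1
      if (nxt_c %in% STOP_CODONS && nxt_c != b) blocked <- TRUE
      cur <- nxt
    }
    c(syn = syn, non = non, blocked = as.numeric(blocked))
  }
  res <- vapply(orders, walk_one, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(sd = mean(res["syn", ok]), nd = mean(res["non", ok]))
}

# all permutations of a small vector (k <= 3 here)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`.  Returns `NA` (saturation) when
#' `p >= 3/4`, where the correction is undefined.
#'
#' @param p proportion of differing sites, in `[0, 1]`.
#' @return corrected distance, or `NA_real_` when saturated.
#' @export
jc_correct <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  ifelse(p >= 3 / 4, NA_real_, -(3 / 4) * log(1 - 4 * p / 3))
}

validate_codon_pair <- function(seq_a, seq_b, pair_id = "pair") {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort(glue("{pair_id}: sequences differ in length ({nchar(seq_a)} vs {nchar(seq_b)})"))
  }
  if (nchar(seq_a) %% 3 != 0) abort(glue("{pair_id}: length not a multiple of 3"))
  if (nchar(seq_a) == 0L) abort(glue("{pair_id}: empty sequence"))
  for (s in list(seq_a, seq_b)) {
    if (!all(seq_chars(s) %in% DNA_BASES)) abort(glue("{pair_id}: non-ACGT character"))
    cods <- codon_split(s)
    if (any(cods %in% STOP_CODONS)) abort(glue("{pair_id}: internal stop codon"))
  }
  list(a = seq_a, b = seq_b)
}

codon_split <- function(s) {
  n <- nchar(s) / 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' NG86 divergence estimate for one coding-sequence pair
#'
#' Site totals `S` and `N` are averaged over the two sequences; per-codon
#' synonymous/nonsynonymous differences are averaged over all substitution
#' orderings (stop-blocked orderings excluded, see package details); `Ks`
#' and `Ka` are the Jukes-Cantor corrections of `pS = Sd/S` and
#' `pN = Nd/N`.  When the correction is undefined the `saturated` flag is
#' set and the corresponding distance is `NA`.
#'
#' @param seq_a,seq_b gap-free coding sequences of equal length, length a
#'   multiple of 3, no internal stop codons.
#' @param pair_id identifier carried into the output.
#' @return one-row tibble: `pair_id`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ka`, `Ks`, `saturated`.
#' @export
ng86_pair <- function(seq_a, seq_b, pair_id = "pair") {
  sq <- validate_codon_pair(seq_a, seq_b, pair_id)
  cods_a <- codon_split(sq$a)
  cods_b <- codon_split(sq$b)
  sites <- codon_site_table()
  S <- (sum(sites[cods_a]) + sum(sites[cods_b])) / 2
  N <- 3 * length(cods_a) - S
  dt <- codon_diff_tables()
  idx <- cbind(match(cods_a, rownames(dt$sd)), match(cods_b, colnames(dt$sd)))
  Sd <- sum(dt$sd[idx])
  Nd <- sum(dt$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(min(pS, 1))
  Ka <- jc_correct(min(pN, 1))
  tibble(
    pair_id = pair_id, S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, Ka = Ka, Ks = Ks,
    saturated = is.na(Ks) | is.na(Ka)
  )
}

#' NG86 divergence estimates for a table of coding-sequence pairs
#'
#' @param pairs tibble with columns `pair_id`, `seq_a`, `seq_b`.
#' @return tibble with one [ng86_pair()] row per pair, class `ks_tbl`.
#' @export
ks_estimate <- function(pairs) {
  req <- c("pair_id", "seq_a", "seq_b")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols) > 0L) {
    abort(glue("`pairs` lacks columns: {paste(missing_cols, collapse = ', ')}"))
  }
  out <- pmap(
    list(pairs$seq_a, pairs$seq_b, as.character(pairs$pair_id)),
    function(a, b, id) ng86_pair(a, b, id)
  ) |> bind_rows()
  class(out) <- c("ks_tbl", class(out))
  out
}

#' Read codon pairs from a paired FASTA file
#'
#' Records are matched into pairs by a shared prefix before the last `_`
#' separator (e.g. `pair07_a` / `pair07_b`); every prefix must occur
#' exactly twice.
#'
#' @param path FASTA path.
#' @return tibble with `pair_id`, `seq_a`, `seq_b`.
#' @export
read_codon_pairs <- function(path) {
  seqs <- read_fasta(path)
  prefix <- sub("_[^_]+$", "", names(seqs))
  counts <- table(prefix)
  if (any(counts != 2L)) {
    abort(glue(
      "each pair_id prefix must occur exactly twice; offending: ",
      "{paste(names(counts)[counts != 2], collapse = ', ')}"
    ))
  }
  split_seqs <- split(unname(seqs), prefix)
  tibble(
    pair_id = names(split_seqs),
    seq_a = unname(map_chr(split_seqs, 1L)),
    seq_b = unname(map_chr(split_seqs, 2L))
  )
}
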