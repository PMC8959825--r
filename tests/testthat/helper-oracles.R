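# Independent brute-force oracles.  These deliberately share no code with
# the package implementation: naive loops, explicit enumeration, and
# quadrature, so agreement is evidence rather than tautology.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_iupac <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# mismatches of one window vs a consensus, position by position
oracle_window_mm <- function(window, iupac) {
  w <- strsplit(window, "")[[1]]
  cc <- strsplit(iupac, "")[[1]]
  mm <- 0L
  for (i in seq_along(cc)) {
    allowed <- strsplit(oracle_iupac[[cc[i]]], "")[[1]]
    if (!(w[i] %in% allowed)) mm <- mm + 1L
  }
  mm
}

# naive per-offset Hamming scanner over both strands
oracle_scan <- function(seq, iupac, budget, both_strands = TRUE) {
  L <- nchar(iupac)
  n <- nchar(seq)
  rows <- list()
  if (n >= L) {
    for (off in 0:(n - L)) {
      w <- substr(seq, off + 1, off + L)
      mm <- oracle_window_mm(w, iupac)
      if (mm <= budget) {
        rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "+",
                                               mismatches = mm)
      }
      if (both_strands) {
        mm2 <- oracle_window_mm(oracle_revcomp(w), iupac)
        if (mm2 <= budget) {
          rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "-",
                                                 mismatches = mm2)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# number of distinct k-mers accepted by the consensus at <= budget
oracle_count_accepted_kmers <- function(iupac, budget) {
  L <- nchar(iupac)
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
  kmers <- do.call(paste0, grid)
  sum(vapply(kmers, function(k) oracle_window_mm(k, iupac) <= budget, logical(1)))
}

# ---- NG86 oracle: direct enumeration of neighbours and pathway orderings

oracle_code <- Biostrings::GENETIC_CODE
oracle_stops <- names(oracle_code)[oracle_code == "*"]

oracle_codon_s <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[pos]) next
      mut <- chars; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (!(mutc %in% oracle_stops) && oracle_code[[mutc]] == oracle_code[[codon]]) {
        syn <- syn + 1
      }
    }
  }
  syn / 3
}

oracle_perm <- function(v) {
  if (length(v) <= 1) return(list(v))
  res <- list()
  for (i in seq_along(v)) {
    rest <- oracle_perm(v[-i])
    for (r in rest) res[[length(res) + 1]] <- c(v[i], r)
  }
  res
}

oracle_pair_codon_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (length(dpos) == 0) return(c(0, 0))
  paths <- oracle_perm(dpos)
  keep <- list()
  for (p in paths) {
    cur <- a
    blocked <- FALSE
    steps <- character(0)
    for (pos in p) {
      nxt <- cur; nxt[pos] <- b[pos]
      steps <- c(steps, paste(paste(cur, collapse = ""), paste(nxt, collapse = ""),
                              sep = ">"))
      nc <- paste(nxt, collapse = "")
      if (nc %in% oracle_stops && nc != c2) blocked <- TRUE
      cur <- nxt
    }
    keep[[length(keep) + 1]] <- list(steps = steps, blocked = blocked)
  }
  usable <- Filter(function(x) !x$blocked, keep)
  if (length(usable) == 0) usable <- keep
  aa <- function(cd) if (cd %in% oracle_stops) "*" else oracle_code[[cd]]
  sdnd <- sapply(usable, function(x) {
    syn <- 0; non <- 0
    for (st in x$steps) {
      cs <- strsplit(st, ">")[[1]]
      if (aa(cs[1]) == aa(cs[2])) syn <- syn + 1 else non <- non + 1
    }
    c(syn, non)
  })
  rowMeans(matrix(sdnd, nrow = 2))
}

oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  ca <- substring(seq_a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(seq_b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  S <- (sum(vapply(ca, oracle_codon_s, numeric(1))) +
          sum(vapply(cb, oracle_codon_s, numeric(1)))) / 2
  N <- 3 * n - S
  d <- mapply(function(x, y) oracle_pair_codon_diffs(x, y), ca, cb)
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(min(pS, 1)), Ka = jc(min(pN, 1)))
}

random_sense_codons <- function(n) {
  sense <- setdiff(names(oracle_code), oracle_stops)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# mutate a fraction of random positions of a coding sequence, avoiding
# in-frame stops
mutate_coding <- function(seq, n_mut) {
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      pos <- sample(length(chars), 1)
      old <- chars[pos]
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      ci <- (pos - 1) %/% 3
      codon <- paste(chars[(3 * ci + 1):(3 * ci + 3)], collapse = "")
      if (!(codon %in% oracle_stops)) break
      chars[pos] <- old
    }
  }
  paste(chars, collapse = "")
}

# ---- TOM oracle: literal triple loop

oracle_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  out <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      num <- a[i, j]
      for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# ---- probability oracles: quadrature of the t density

oracle_t_p <- function(t, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf,
                       rel.tol = 1e-12)$value
}

oracle_cor_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  oracle_t_p(r * sqrt((n - 2) / (1 - r^2)), n - 2)
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = oracle_t_p(t, na + nb - 2))
}

# ---- consensus DEG rule oracle: explicit per-gene loop

oracle_consensus <- function(tables, padj_max, min_lfc_log2, min_methods) {
  genes <- sort(unique(unlist(lapply(tables, function(t) t$gene_id))))
  called <- character(0)
  dir <- character(0)
  for (g in genes) {
    up <- 0; down <- 0
    for (tb in tables) {
      row <- tb[tb$gene_id == g, ]
      if (nrow(row) == 0) next
      if (row$padj < padj_max && abs(row$log2fc) >= min_lfc_log2) {
        if (row$log2fc > 0) up <- up + 1 else if (row$log2fc < 0) down <- down + 1
      }
    }
    if (up >= min_methods) { called <- c(called, g); dir <- c(dir, "up") }
    else if (down >= min_methods) { called <- c(called, g); dir <- c(dir, "down") }
  }
  data.frame(gene_id = called, direction = dir)
}
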