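# FASTA and GFF3 reading/writing plus strand-aware promoter extraction.
#
# Coordinates: GFF3 is 1-based inclusive; everything returned to the user
# keeps that convention.  Sequences are stored as uppercase character
# vectors named by their identifier.

#' Read a FASTA file into a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased.  Wrapped (multi-line) records are concatenated.
#' Gzip-compressed files are handled transparently.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  check_string(path)
  if (!file.exists(path)) abort(glue("FASTA file not found: {path}"))
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0L) abort(glue("FASTA file is empty: {path}"))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(glue("duplicate FASTA identifiers: {paste(dup, collapse = ', ')}"))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Returns one row per gene with the genomic coordinate of the translation
#' initiation site (TIS).  The TIS is taken from annotation coordinates:
#' feature start on the `+` strand, feature end on the `-` strand.  When CDS
#' records are present for a gene the CDS span is used (the span of all its
#' CDS segments); otherwise the `gene` record itself.
#'
#' @param path path to a GFF3 file (optionally `.gz`).
#' @param feature_types feature types considered, in order of preference.
#' @return tibble with columns `gene_id`, `chromosome`, `strand`, `start`,
#'   `end`, `tis` (all coordinates 1-based inclusive).
#' @export
read_gff_genes <- function(path, feature_types = c("CDS", "gene")) {
  check_string(path)
  if (!file.exists(path)) abort(glue("GFF file not found: {path}"))
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    abort(glue("malformed GFF line {lineno[bad[1]]}: expected 9 tab-separated columns, found {length(fields[[bad[1]]])}"))
  }
  gff <- tibble(
    chromosome = map_chr(fields, 1L),
    type       = map_chr(fields, 3L),
    start      = suppressWarnings(as.integer(map_chr(fields, 4L))),
    end        = suppressWarnings(as.integer(map_chr(fields, 5L))),
    strand     = map_chr(fields, 7L),
    attributes = map_chr(fields, 9L),
    line       = lineno
  )
  gff <- filter(gff, .data$type %in% feature_types)
  if (nrow(gff) == 0L) abort(glue("no features of type {paste(feature_types, collapse = '/')} in {path}"))
  bad_coord <- which(is.na(gff$start) | is.na(gff$end) | gff$end < gff$start)
  if (length(bad_coord) > 0L) {
    abort(glue("invalid coordinates on GFF line {gff$line[bad_coord[1]]}"))
  }
  bad_strand <- which(!gff$strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    abort(glue("strand must be '+' or '-' on GFF line {gff$line[bad_strand[1]]}"))
  }
  gff$gene_id <- gff_attribute_id(gff$attributes)
  if (anyNA(gff$gene_id)) {
    abort(glue("GFF line {gff$line[which(is.na(gff$gene_id))[1]]} has no ID= or Parent= attribute"))
  }
  # prefer the first listed feature type that a gene has (CDS over gene)
  gff$pref <- match(gff$type, feature_types)
  gff <- gff |>
    group_by(.data$gene_id) |>
    filter(.data$pref == min(.data$pref)) |>
    summarise(
      chromosome = .data$chromosome[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
  gff |>
    mutate(tis = ifelse(.data$strand == "+", .data$start, .data$end)) |>
    select("gene_id", "chromosome", "strand", "start", "end", "tis") |>
    arrange(.data$gene_id)
}

# first of ID= / Parent= in a GFF attribute string, NA when absent
gff_attribute_id <- function(attrs) {
  id <- sub('.*?ID=([^;]+).*', "\\1", attrs)
  id[!grepl("ID=", attrs)] <- NA_character_
  par <- sub('.*?Parent=([^;]+).*', "\\1", attrs)
  par[!grepl("Parent=", attrs)] <- NA_character_
  dplyr::coalesce(id, par)
}

#' Write gene models as GFF3
#'
#' @param genes tibble as returned by [read_gff_genes()].
#' @param path output path.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path, source = "coexreg") {
  stopifnot(all(c("gene_id", "chromosome", "strand", "start", "end") %in% names(genes)))
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chromosome, source, genes$start, genes$end, genes$strand, genes$gene_id
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Extract strand-aware promoter sequences
#'
#' The promoter is the `window` bases immediately upstream of the translation
#' initiation site, read 5'->3' on the gene's coding strand; the TIS base
#' itself is excluded.  On the `+` strand this is genomic
#' `[tis - window, tis - 1]`; on the `-` strand the reverse complement of
#' `[tis + 1, tis + window]`.  Promoters running off a chromosome end are
#' truncated, never padded.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes tibble of gene models (see [read_gff_genes()]).
#' @param window promoter length in bp upstream of the TIS.
#' @return tibble with columns `gene_id`, `sequence`, `length`, `truncated`.
#' @export
extract_promoters <- function(genome, genes, window = 1000L) {
  check_number(window, min = 1)
  missing_chr <- unique(genes$gene_id[!genes$chromosome %in% names(genome)])
  if (length(missing_chr) > 0L) {
    abort(glue(
      "chromosome missing from genome for genes: {paste(missing_chr, collapse = ', ')}"
    ))
  }
  chrlen <- nchar(genome)[genes$chromosome]
  plus <- genes$strand == "+"
  from <- ifelse(plus, pmax(1L, genes$tis - window), genes$tis + 1L)
  to <- ifelse(plus, genes$tis - 1L, pmin(chrlen, genes$tis + window))
  empty <- from > to
  seqs <- character(nrow(genes))
  seqs[!empty] <- substr(genome[genes$chromosome[!empty]], from[!empty], to[!empty])
  seqs[!plus & !empty] <- reverse_complement(seqs[!plus & !empty])
  tibble(
    gene_id = genes$gene_id,
    sequence = toupper(seqs),
    length = nchar(seqs),
    truncated = nchar(seqs) < window
  )
}
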