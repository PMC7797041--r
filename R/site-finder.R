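SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
# specificity order used when several types share a seed-match core
SITE_PRIORITY <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)

#' Canonical seed-match patterns of a miRNA on the target strand
#'
#' A canonical site is the Watson-Crick match to the miRNA seed on the
#' target mRNA (written 5'->3' as sense-strand DNA):
#' * `6mer` - reverse complement of miRNA positions 2-7,
#' * `7mer-m8` - reverse complement of positions 2-8,
#' * `7mer-A1` - the 6mer followed by an A opposite miRNA position 1,
#' * `8mer` - the 7mer-m8 followed by that A.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3' (RNA or DNA letters; at
#'   least 8 nt).
#' @return named character vector with one DNA match string per site type.
#' @export
#' @examples
#' seed_patterns("UGGCAGUGUCUUAGCUGGUUGU") # miR-34a-5p
seed_patterns <- function(mirna_seq) {
  stopifnot(length(mirna_seq) == 1)
  seq <- normalize_rna(mirna_seq)
  if (nchar(seq) < 8) {
    abort(sprintf("miRNA must be at least 8 nt (got %d)", nchar(seq)))
  }
  seed27 <- substr(seq, 2, 7)
  seed28 <- substr(seq, 2, 8)
  m6 <- revcomp(chartr("U", "T", seed27))
  m7m8 <- revcomp(chartr("U", "T", seed28))
  c(
    "6mer" = m6,
    "7mer-A1" = paste0(m6, "A"),
    "7mer-m8" = m7m8,
    "8mer" = paste0(m7m8, "A")
  )[SITE_TYPES]
}

# All (possibly overlapping) exact occurrences of `pattern` in `subject`;
# returns 1-based start positions. fixed = TRUE: N in the UTR matches nothing.
match_starts <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject), fixed = TRUE)
  Biostrings::start(m)
}

#' Find canonical seed-binding sites of miRNAs in 3'UTRs
#'
#' Scans every supplied UTR for every supplied miRNA. Where several site
#' types share the same 6mer seed-match core, only the most specific type is
#' reported (8mer > 7mer-m8 > 7mer-A1 > 6mer), so one binding event yields
#' one row.
#'
#' @param utrs tibble of UTR records (see [read_utr()]): `utr_id`, `gene_id`,
#'   `sequence`.
#' @param mirnas tibble of mature miRNAs (see [read_mirna()]): `mirna_id`,
#'   `sequence`.
#' @return a tibble with columns `mirna_id`, `utr_id`, `gene_id`, `start`,
#'   `end` (1-based, inclusive), `site_type`, `site_seq`, sorted by UTR and
#'   start.
#' @export
find_seed_sites <- function(utrs, mirnas) {
  stopifnot_cols(utrs, c("utr_id", "sequence"), "utrs")
  stopifnot_cols(mirnas, c("mirna_id", "sequence"), "mirnas")
  if (!"gene_id" %in% names(utrs)) utrs$gene_id <- utrs$utr_id
  grid <- tidyr::expand_grid(u = seq_len(nrow(utrs)), m = seq_len(nrow(mirnas)))
  res <- pmap(grid, function(u, m) {
    find_seed_sites_one(
      utrs$sequence[u], utrs$utr_id[u], utrs$gene_id[u],
      mirnas$sequence[m], mirnas$mirna_id[m]
    )
  })
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(
      mirna_id = character(), utr_id = character(), gene_id = character(),
      start = integer(), end = integer(), site_type = character(),
      site_seq = character()
    ))
  }
  arrange(out, .data$utr_id, .data$mirna_id, .data$start, .data$end)
}

find_seed_sites_one <- function(utr_seq, utr_id, gene_id, mirna_seq, mirna_id) {
  utr_seq <- normalize_dna(utr_seq)
  pats <- seed_patterns(mirna_seq)
  # offset of the 6mer core within each pattern (the m8 base precedes it)
  core_offset <- c("6mer" = 0L, "7mer-A1" = 0L, "7mer-m8" = 1L, "8mer" = 1L)
  hits <- imap(pats, function(pat, type) {
    starts <- match_starts(pat, utr_seq)
    if (!length(starts)) return(NULL)
    tibble(
      site_type = type,
      start = starts,
      end = starts + nchar(pat) - 1L,
      core_start = starts + core_offset[[type]]
    )
  })
  hits <- bind_rows(hits)
  if (!nrow(hits)) return(NULL)
  hits |>
    mutate(priority = SITE_PRIORITY[.data$site_type]) |>
    group_by(.data$core_start) |>
    slice_max(.data$priority, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(
      mirna_id = mirna_id,
      utr_id = utr_id,
      gene_id = gene_id,
      start = .data$start,
      end = .data$end,
      site_type = .data$site_type,
      site_seq = substr(utr_seq, .data$start, .data$end)
    )
}

#' Does a miRNA have a canonical site in any of a gene's UTRs?
#'
#' @param utrs tibble of UTR records (at least one row).
#' @param mirna one-row tibble (or list) with `mirna_id` and `sequence`.
#' @return `TRUE` iff at least one supplied UTR contains at least one
#'   canonical site for the miRNA.
#' @export
has_canonical_site <- function(utrs, mirna) {
  if (!nrow(utrs)) abort("has_canonical_site() requires at least one UTR")
  mirna <- as_tibble(mirna[c("mirna_id", "sequence")])
  nrow(find_seed_sites(utrs, mirna[1, ])) > 0
}

# gene_ids (among those present in utrs) carrying >= 1 canonical site
genes_with_site <- function(utrs, mirna) {
  if (!nrow(utrs)) return(character(0))
  mirna <- as_tibble(mirna[c("mirna_id", "sequence")])
  sites <- find_seed_sites(utrs, mirna[1, ])
  unique(sites$gene_id)
}

iupac_to_regex <- function(motif) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(IUPAC_CODES)
  if (any(bad)) {
    abort(sprintf("illegal IUPAC character(s) in motif '%s'", motif))
  }
  cls <- vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    # an ambiguity code that allows any base also tolerates N in the sequence
    if (ch == "N") bases <- c(bases, "N")
    if (length(bases) == 1) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1))
  paste(cls, collapse = "")
}

# Overlap-aware regex scan; returns 1-based start positions.
regex_starts <- function(regex, subject) {
  m <- gregexpr(paste0("(?=", regex, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Find restriction-enzyme recognition sites in a 3'UTR
#'
#' IUPAC-expanded scan of the sense strand; for non-palindromic motifs the
#' antisense strand is additionally scanned (reported in sense-strand
#' coordinates with `strand = "antisense"`). Overlapping matches are all
#' reported. `N` in a motif matches any base including `N`; `N` in the UTR
#' matches only motif positions that tolerate any base.
#'
#' @param utrs tibble of UTR records.
#' @param catalog enzyme catalog (see [read_enzymes()]).
#' @return a tibble with columns `utr_id`, `enzyme_name`, `start`, `end`
#'   (1-based, inclusive), `strand` (`sense`/`antisense`), `match_seq`.
#' @export
find_restriction_sites <- function(utrs, catalog) {
  stopifnot_cols(utrs, c("utr_id", "sequence"), "utrs")
  catalog <- as_enzyme_catalog(catalog)
  empty <- tibble(
    utr_id = character(), enzyme_name = character(),
    start = integer(), end = integer(), strand = character(),
    match_seq = character()
  )
  if (!nrow(catalog) || !nrow(utrs)) return(empty)
  res <- pmap(
    tidyr::expand_grid(u = seq_len(nrow(utrs)), e = seq_len(nrow(catalog))),
    function(u, e) {
      seq <- normalize_dna(utrs$sequence[u])
      motif <- catalog$recognition_motif[e]
      len <- nchar(motif)
      rc <- revcomp(motif)
      sense <- regex_starts(iupac_to_regex(motif), seq)
      anti <- if (!identical(rc, motif)) regex_starts(iupac_to_regex(rc), seq) else integer(0)
      starts <- c(sense, anti)
      if (!length(starts)) return(NULL)
      tibble(
        utr_id = utrs$utr_id[u],
        enzyme_name = catalog$enzyme_name[e],
        start = starts,
        end = starts + len - 1L,
        strand = c(rep("sense", length(sense)), rep("antisense", length(anti))),
        match_seq = substr(rep(seq, length(starts)), starts, starts + len - 1L)
      )
    }
  )
  out <- bind_rows(res)
  if (!nrow(out)) return(empty)
  arrange(out, .data$utr_id, .data$start, .data$enzyme_name, .data$strand)
}

#' Enzymes with no recognition site in a UTR
#'
#' Useful for choosing cloning enzymes: returns exactly the catalog entries
#' with zero hits (either strand) in the supplied sequence(s).
#'
#' @param utrs tibble of UTR records.
#' @param catalog enzyme catalog.
#' @return character vector of enzyme names, sorted.
#' @export
enzymes_without_cut <- function(utrs, catalog) {
  catalog <- as_enzyme_catalog(catalog)
  hits <- find_restriction_sites(utrs, catalog)
  sort(setdiff(catalog$enzyme_name, unique(hits$enzyme_name)))
}
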