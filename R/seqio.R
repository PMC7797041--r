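#' Read mature miRNA sequences from FASTA
#'
#' Sequences are normalized to uppercase RNA (`T` becomes `U`) and validated
#' against the `{A,C,G,U}` alphabet. The header line (up to the first
#' whitespace) becomes `mirna_id`.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `mirna_id`, `sequence` (5'->3' RNA), in file
#'   order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">miR-34a-5p", "UGGCAGUGUCUUAGCUGGUUGU"), fa)
#' read_mirna(fa)
read_mirna <- function(path) {
  recs <- read_fasta_records(path)
  out <- tibble(
    mirna_id = recs$id,
    sequence = normalize_rna(recs$sequence)
  )
  short <- nchar(out$sequence) < 8
  if (any(short)) {
    abort(sprintf(
      "miRNA record(s) shorter than 8 nt: %s",
      paste(out$mirna_id[short], collapse = ", ")
    ))
  }
  out
}

#' Read 3'UTR sequences from FASTA
#'
#' Sequences are normalized to uppercase sense-strand DNA (`U` becomes `T`);
#' `N` is allowed. Headers of the form `GENE` or `GENE|TRANSCRIPT` populate
#' `gene_id` and the optional `transcript_id`; several UTR records per gene
#' are allowed (the choice of transcript is left to the caller).
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `utr_id`, `gene_id`, `transcript_id`,
#'   `sequence`, in file order.
#' @export
read_utr <- function(path) {
  recs <- read_fasta_records(path)
  parts <- strsplit(recs$id, "|", fixed = TRUE)
  tibble(
    utr_id = recs$id,
    gene_id = map_chr(parts, 1),
    transcript_id = map_chr(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_),
    sequence = normalize_dna(recs$sequence)
  )
}

# Shared FASTA ingestion: a light line scan enforces the error contract
# (malformed header / empty record reported with its line number), then
# Biostrings does the actual parsing.
read_fasta_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(sprintf("malformed FASTA at line %d: expected '>' header", nonblank[1]))
  }
  headers <- nonblank[startsWith(lines[nonblank], ">")]
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (!nzchar(trimws(sub("^>", "", lines[h])))) {
      abort(sprintf("malformed FASTA at line %d: empty header", h))
    }
    upto <- if (i < length(headers)) headers[i + 1] - 1L else length(lines)
    body <- lines[setdiff(intersect(nonblank, seq(h, upto)), h)]
    if (!length(body)) {
      abort(sprintf("malformed FASTA at line %d: record has empty sequence", h))
    }
  }
  set <- Biostrings::readBStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set))
  )
}

#' Write sequences to FASTA
#'
#' @param data a data frame holding identifiers and sequences.
#' @param path output path.
#' @param id_col,seq_col column names for record ids and sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, id_col = "utr_id", seq_col = "sequence") {
  stopifnot_cols(data, c(id_col, seq_col), "FASTA data")
  set <- Biostrings::BStringSet(setNames(data[[seq_col]], data[[id_col]]))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, required, what)
  df
}

#' Read a target-prediction table (TSV)
#'
#' Expects columns `mirna_id`, `gene_id`, `tool_name`, optionally
#' `stringency` (one of low/medium/high/default; missing values default to
#' "default") and `score`. Unknown columns are preserved. Duplicate
#' `(mirna_id, gene_id, tool_name, stringency)` rows are an error.
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble, one row per prediction.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_checked(path, c("mirna_id", "gene_id", "tool_name"), "prediction table")
  as_prediction_table(df)
}

#' Validate (or coerce) an in-memory prediction table
#'
#' @param df a data frame with at least `mirna_id`, `gene_id`, `tool_name`.
#' @return the validated tibble with a `stringency` column.
#' @export
as_prediction_table <- function(df) {
  stopifnot_cols(df, c("mirna_id", "gene_id", "tool_name"), "prediction table")
  df <- as_tibble(df)
  if (!"stringency" %in% names(df)) df$stringency <- "default"
  df$stringency <- dplyr::coalesce(as.character(df$stringency), "default")
  bad <- !df$stringency %in% c("low", "medium", "high", "default")
  if (any(bad)) {
    abort(sprintf(
      "invalid stringency value(s): %s",
      paste(unique(df$stringency[bad]), collapse = ", ")
    ))
  }
  if (any(!nzchar(df$tool_name) | is.na(df$tool_name))) {
    abort("tool_name must be non-empty")
  }
  dup <- df |>
    count(.data$mirna_id, .data$gene_id, .data$tool_name, .data$stringency) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicate prediction rows for: %s",
      paste(sprintf(
        "(%s, %s, %s, %s)",
        dup$mirna_id, dup$gene_id, dup$tool_name, dup$stringency
      ), collapse = "; ")
    ))
  }
  df
}

#' Read a validated-interaction table (TSV)
#'
#' Expects columns `mirna_id`, `gene_id`, `outcome` (strictly `positive` or
#' `negative`) and optionally `evidence`. Duplicate `(mirna_id, gene_id,
#' outcome)` rows are an error.
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble of validated interactions.
#' @export
read_validated <- function(path) {
  df <- read_tsv_checked(path, c("mirna_id", "gene_id", "outcome"), "validated table")
  as_validated_table(df)
}

#' Validate an in-memory validated-interaction table
#' @param df a data frame with `mirna_id`, `gene_id`, `outcome`.
#' @return the validated tibble.
#' @export
as_validated_table <- function(df) {
  stopifnot_cols(df, c("mirna_id", "gene_id", "outcome"), "validated table")
  df <- as_tibble(df)
  bad <- !df$outcome %in% c("positive", "negative")
  if (any(bad)) {
    abort(sprintf(
      "outcome must be 'positive' or 'negative'; found: %s",
      paste(unique(df$outcome[bad]), collapse = ", ")
    ))
  }
  dup <- df |>
    count(.data$mirna_id, .data$gene_id, .data$outcome) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicate validated rows for: %s",
      paste(sprintf("(%s, %s, %s)", dup$mirna_id, dup$gene_id, dup$outcome),
        collapse = "; "
      )
    ))
  }
  df
}

#' Read a restriction-enzyme catalog (TSV)
#'
#' Expects columns `enzyme_name` and `recognition_motif` (IUPAC DNA, length
#' >= 4). Motif characters outside the IUPAC alphabet are an error.
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble with one row per enzyme.
#' @export
read_enzymes <- function(path) {
  df <- read_tsv_checked(path, c("enzyme_name", "recognition_motif"), "enzyme catalog")
  as_enzyme_catalog(df)
}

#' Validate an in-memory enzyme catalog
#' @param df a data frame with `enzyme_name`, `recognition_motif`.
#' @return the validated tibble.
#' @export
as_enzyme_catalog <- function(df) {
  stopifnot_cols(df, c("enzyme_name", "recognition_motif"), "enzyme catalog")
  df <- as_tibble(df)
  df$recognition_motif <- toupper(df$recognition_motif)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", df$recognition_motif)
  if (any(bad)) {
    abort(sprintf(
      "non-IUPAC motif for enzyme(s): %s",
      paste(df$enzyme_name[bad], collapse = ", ")
    ))
  }
  short <- nchar(df$recognition_motif) < 4
  if (any(short)) {
    abort(sprintf(
      "motif shorter than 4 nt for enzyme(s): %s",
      paste(df$enzyme_name[short], collapse = ", ")
    ))
  }
  if (anyDuplicated(df$enzyme_name)) {
    abort("duplicate enzyme names in catalog")
  }
  df
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT: one set per line with tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' de-duplicated within a set; duplicate set names and lines with fewer than
#' three fields are errors.
#'
#' @param path path to a GMT file.
#' @return a tibble with columns `set_name`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf(
      "GMT parse error at line %d: fewer than 3 tab-separated fields",
      which(nf < 3)[1]
    ))
  }
  out <- tibble(
    set_name = map_chr(fields, 1),
    description = map_chr(fields, 2),
    genes = map(fields, function(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(out$set_name)) {
    abort(sprintf(
      "duplicate gene-set name(s): %s",
      paste(unique(out$set_name[duplicated(out$set_name)]), collapse = ", ")
    ))
  }
  if (any(lengths(out$genes) == 0)) abort("GMT contains an empty gene set")
  out
}

#' Write a gene-set collection to GMT
#' @param collection a tibble as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot_cols(collection, c("set_name", "description", "genes"), "gene-set collection")
  lines <- pmap(collection[c("set_name", "description", "genes")], function(set_name, description, genes) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read replicate-level luciferase well measurements (TSV)
#'
#' Expects columns `plate_id`, `well_id`, `design`, `construct_label`,
#' `gene_id`, `firefly`, `renilla`. `design` must be one of the four
#' transfection arms: `empty_mir+empty_utr`, `empty_mir+utr`,
#' `mir+empty_utr`, `mir+utr`.
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble of well measurements.
#' @export
read_wells <- function(path) {
  df <- read_tsv_checked(
    path,
    c("plate_id", "well_id", "design", "construct_label", "gene_id", "firefly", "renilla"),
    "well table"
  )
  arms <- c("empty_mir+empty_utr", "empty_mir+utr", "mir+empty_utr", "mir+utr")
  bad <- !df$design %in% arms
  if (any(bad)) {
    abort(sprintf(
      "unknown design value(s): %s (expected %s)",
      paste(unique(df$design[bad]), collapse = ", "),
      paste(arms, collapse = ", ")
    ))
  }
  if (any(df$renilla <= 0)) abort("renilla readings must be > 0")
  if (any(df$firefly < 0)) abort("firefly readings must be >= 0")
  df
}

#' Read pre-normalized replicate RLU values (TSV)
#'
#' Expects columns `construct_label`, `gene_id`, `replicate`, `rlu` where
#' `rlu` is the normalized relative luciferase activity (1.0 = no effect).
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble of replicate RLUs.
#' @export
read_rlu <- function(path) {
  df <- read_tsv_checked(
    path, c("construct_label", "gene_id", "replicate", "rlu"),
    "RLU table"
  )
  if (any(df$rlu < 0)) abort("rlu values must be >= 0")
  df
}
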