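#' Consensus filter over target predictions
#'
#' Collapses a prediction table to one row per (miRNA, gene) pair and keeps
#' pairs predicted by at least `min_tools` distinct tools. Several
#' stringency tiers of the same tool count once.
#'
#' @param predictions prediction tibble (see [read_predictions()]).
#' @param min_tools minimum number of distinct predicting tools (the
#'   screens bundled here used 4).
#' @return a tibble with `mirna_id`, `gene_id`, `tool_count` and a
#'   list-column `tools`, sorted by decreasing `tool_count`.
#' @export
consensus_filter <- function(predictions, min_tools = 4) {
  if (min_tools < 1) abort("min_tools must be >= 1")
  predictions <- as_prediction_table(predictions)
  if (!nrow(predictions)) abort("empty prediction table")
  predictions |>
    distinct(.data$mirna_id, .data$gene_id, .data$tool_name) |>
    summarise(
      tool_count = dplyr::n(),
      tools = list(sort(.data$tool_name)),
      .by = c("mirna_id", "gene_id")
    ) |>
    filter(.data$tool_count >= min_tools) |>
    arrange(desc(.data$tool_count), .data$mirna_id, .data$gene_id)
}

#' Drop pairs already validated elsewhere
#'
#' Removes rows whose (miRNA, gene) pair appears with outcome `positive` in
#' the validated-interaction table; negative interactions are kept (a prior
#' negative does not pre-empt re-testing).
#'
#' @param rows consensus rows (any tibble with `mirna_id`, `gene_id`).
#' @param validated validated-interaction tibble (see [read_validated()]).
#' @return `rows` without the previously validated pairs.
#' @export
exclude_known <- function(rows, validated) {
  stopifnot_cols(rows, c("mirna_id", "gene_id"), "rows")
  if (is.null(validated) || !nrow(validated)) return(rows)
  validated <- as_validated_table(validated)
  pos <- filter(validated, .data$outcome == "positive")
  anti_join(rows, pos, by = c("mirna_id", "gene_id"))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected when drawing `n = |query|` genes from the background of
#' size `N`: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where `K`
#' is the set size within the background and `k` the observed overlap.
#' P-values are adjusted across all tested sets (Benjamini-Hochberg by
#' default).
#'
#' @param query character vector of gene ids (must be a subset of
#'   `background`).
#' @param collection gene-set tibble from [read_gmt()].
#' @param background character vector of gene ids defining the universe.
#' @param method multiple-testing adjustment passed to [stats::p.adjust()].
#' @return a tibble with `set_name`, `N`, `K`, `n`, `k`, `p_value`,
#'   `q_value`, sorted by `q_value` then `p_value`.
#' @export
ora <- function(query, collection, background, method = "BH") {
  background <- unique(background)
  query <- unique(query)
  if (!length(background)) abort("empty background")
  if (length(setdiff(query, background))) {
    abort("query must be a subset of the background")
  }
  stopifnot_cols(collection, c("set_name", "genes"), "collection")
  N <- length(background)
  n <- length(query)
  res <- collection |>
    mutate(
      members = map(.data$genes, intersect, background),
      K = lengths(.data$members),
      k = map_int(.data$members, function(m) length(intersect(m, query))),
      N = N,
      n = n,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE)
    ) |>
    select("set_name", "N", "K", "n", "k", "p_value")
  res$q_value <- p.adjust(res$p_value, method = method)
  arrange(res, .data$q_value, .data$p_value, .data$set_name)
}

#' Select candidates by membership in enriched categories
#'
#' Keeps rows whose gene belongs to at least one significantly enriched
#' gene set (`q <= q_max`) whose name matches one of the supplied patterns
#' (case-insensitive substring, e.g. `"TNF"` or `"Parkinson"`). The union
#' over matching categories is taken and genes are kept once.
#'
#' @param rows consensus rows (tibble with `mirna_id`, `gene_id`).
#' @param enrichment result of [ora()] computed on `collection`.
#' @param collection the gene-set tibble used for `enrichment`.
#' @param patterns character vector of name substrings (or exact set names).
#' @param q_max significance threshold on the adjusted p-value.
#' @return the selected subset of `rows`.
#' @export
select_by_categories <- function(rows, enrichment, collection, patterns,
                                 q_max = 0.05) {
  stopifnot_cols(rows, "gene_id", "rows")
  stopifnot_cols(enrichment, c("set_name", "q_value"), "enrichment")
  stopifnot_cols(collection, c("set_name", "genes"), "collection")
  matches <- map(tolower(patterns), function(p) {
    collection$set_name[grepl(p, tolower(collection$set_name), fixed = TRUE)]
  })
  matched_sets <- unique(unlist(matches))
  if (!length(matched_sets)) {
    warn(sprintf(
      "no gene-set name matches pattern(s): %s; selection is empty",
      paste(patterns, collapse = ", ")
    ))
    return(rows[0, , drop = FALSE])
  }
  signif_sets <- enrichment$set_name[enrichment$q_value <= q_max]
  keep_sets <- intersect(matched_sets, signif_sets)
  members <- unique(unlist(collection$genes[collection$set_name %in% keep_sets]))
  filter(rows, .data$gene_id %in% members)
}

#' Run the three computational candidate filters plus the site check
#'
#' Applies, in order: (1) consensus filtering (`min_tools` distinct
#' predictors), (2) over-representation analysis and selection of genes in
#' enriched categories matching `patterns`, (3) exclusion of pairs already
#' validated elsewhere, (4) requirement of at least one canonical seed site
#' in a supplied UTR. Per-stage pair counts are recorded for audit.
#'
#' @param predictions prediction tibble.
#' @param validated validated-interaction tibble (may be empty).
#' @param utrs UTR tibble (see [read_utr()]); genes without any UTR record
#'   fail the site check.
#' @param mirnas miRNA tibble; the site check is per (miRNA, gene) pair.
#' @param collection gene-set tibble.
#' @param background background gene universe for the ORA; defaults to all
#'   genes in the prediction table.
#' @param min_tools,patterns,q_max filter parameters (see
#'   [consensus_filter()], [select_by_categories()]).
#' @return a `candidate_screen` object; `tidy()` returns the candidate
#'   table, `glance()` the per-stage counts.
#' @export
candidate_pipeline <- function(predictions, validated, utrs, mirnas,
                               collection, background = NULL,
                               min_tools = 4, patterns, q_max = 0.05) {
  predictions <- as_prediction_table(predictions)
  if (is.null(background)) background <- unique(predictions$gene_id)
  counts <- c(input_pairs = nrow(distinct(predictions, .data$mirna_id, .data$gene_id)))

  if (!nrow(predictions)) {
    cand <- tibble(
      mirna_id = character(), gene_id = character(),
      tool_count = integer(), tools = list()
    )
    counts <- c(counts,
      after_consensus = 0L, after_enrichment = 0L,
      after_exclusion = 0L, after_site_check = 0L
    )
    return(new_candidate_screen(cand, counts, ora_table = NULL))
  }

  rows <- consensus_filter(predictions, min_tools)
  counts <- c(counts, after_consensus = nrow(rows))

  enr <- ora(intersect(unique(rows$gene_id), background), collection, background)
  rows <- select_by_categories(rows, enr, collection, patterns, q_max)
  counts <- c(counts, after_enrichment = nrow(rows))

  rows <- exclude_known(rows, validated)
  counts <- c(counts, after_exclusion = nrow(rows))

  stopifnot_cols(mirnas, c("mirna_id", "sequence"), "mirnas")
  keep <- map_lgl(seq_len(nrow(rows)), function(i) {
    mi <- mirnas[mirnas$mirna_id == rows$mirna_id[i], ]
    if (!nrow(mi)) return(FALSE)
    g_utrs <- utrs[utrs$gene_id == rows$gene_id[i], ]
    if (!nrow(g_utrs)) return(FALSE)
    has_canonical_site(g_utrs, mi[1, ])
  })
  rows <- rows[keep, , drop = FALSE]
  counts <- c(counts, after_site_check = nrow(rows))

  new_candidate_screen(rows, counts, enr)
}

new_candidate_screen <- function(candidates, counts, ora_table) {
  structure(
    list(candidates = candidates, stage_counts = counts, ora = ora_table),
    class = "candidate_screen"
  )
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat("Candidate screen\n")
  cat("  stage counts:\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("    %-16s %d\n", nm, x$stage_counts[[nm]]))
  }
  cat(sprintf("  final candidates: %d\n", nrow(x$candidates)))
  invisible(x)
}

#' @rdname candidate_pipeline
#' @param x a `candidate_screen` object.
#' @param ... unused.
#' @export
tidy.candidate_screen <- function(x, ...) {
  as_tibble(x$candidates)
}

#' @rdname candidate_pipeline
#' @export
glance.candidate_screen <- function(x, ...) {
  as_tibble(as.list(x$stage_counts))
}
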