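# Shared in-code fixtures.

SITE_TYPES_TEST <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

mir34a <- function() {
  tibble::tibble(mirna_id = "miR-34a-5p", sequence = "UGGCAGUGUCUUAGCUGGUUGU")
}

utr_tbl <- function(seq, id = "u1", gene = sub("\\|.*", "", id)) {
  tibble::tibble(utr_id = id, gene_id = gene, sequence = seq)
}

enzyme_tbl <- function() {
  tibble::tibble(
    enzyme_name = c("SpeI", "SacI", "BsaI", "HindIII"),
    recognition_motif = c("ACTAGT", "GAGCTC", "GGTCTC", "AAGCTT")
  )
}

# A 980-nt UTR with miR-34a 8mer sites at fixed positions (1-based starts),
# mirroring a two-segment reporter design.
fixture_980_utr <- function(starts = c(101L, 701L), seed = 42) {
  withr::with_seed(seed, {
    bg <- random_dna_str(980)
    mir <- mir34a()
    # scrub accidental sites so only the planted ones remain
    repeat {
      hits <- mirscreen::find_seed_sites(utr_tbl(bg), mir)
      if (!nrow(hits)) break
      for (i in seq_len(nrow(hits))) {
        substr(bg, hits$start[i], hits$end[i]) <-
          random_dna_str(hits$end[i] - hits$start[i] + 1L)
      }
    }
    for (s in starts) substr(bg, s, s + 7L) <- "CACTGCCA"
    bg
  })
}

# Composed screen fixture where every stage's effect is known by
# construction: 100 genes predicted for one miRNA; 50 of them by >= 4
# tools, among those the 10 planted in an enriched category; 2 of the 10
# pre-validated; 1 of the remaining 8 without a canonical site -> 7 final
# candidates.
build_pipeline_fixture <- function() {
  mir <- mir34a()
  genes <- sprintf("G%d", 1:100)
  strong <- genes[1:50] # predicted by 4 tools
  weak <- genes[51:100] # predicted by 1 tool
  preds <- dplyr::bind_rows(
    tidyr::expand_grid(gene_id = strong, tool_name = c("t1", "t2", "t3", "t4")),
    tibble::tibble(gene_id = weak, tool_name = "t1")
  ) |>
    dplyr::mutate(mirna_id = mir$mirna_id, stringency = "default")
  planted <- genes[1:10]
  coll <- mirscreen::sim_gene_sets(
    genes,
    n_sets = 15, set_size = 15,
    enriched_set_genes = planted,
    enriched_set_name = "TNF signaling pathway",
    seed = 77
  )
  validated <- tibble::tibble(
    mirna_id = mir$mirna_id, gene_id = c("G1", "G2"), outcome = "positive"
  )
  # UTRs only for the planted genes: all but G10 carry one 8mer
  spec <- tibble::tibble(
    gene_id = sprintf("G%d", 1:9), mirna_id = mir$mirna_id,
    site_type = "8mer", count = 1L
  )
  sim <- mirscreen::sim_utrs(10, mir, spec, length_mean = 400, seed = 78)
  list(
    mir = mir, preds = preds, coll = coll, validated = validated,
    utrs = sim$utrs, genes = genes
  )
}

# Construct-level results table with a prescribed validation pattern:
# p-values and means are set directly so counts are exact by construction.
fixture_results <- function(n_validated, n_not) {
  n_total <- n_validated + n_not
  strong <- seq_len(n_total) <= n_validated
  mean_rlu <- ifelse(
    strong,
    seq(0.40, 0.70, length.out = n_total),
    seq(0.75, 1.10, length.out = n_total)
  )
  p.value <- ifelse(
    strong,
    seq(1e-5, 0.004, length.out = n_total),
    seq(0.06, 0.9, length.out = n_total)
  )
  tibble::tibble(
    construct_label = sprintf("C%d_1", seq_len(n_total)),
    gene_id = sprintf("C%d", seq_len(n_total)),
    n = 8L,
    mean_rlu = mean_rlu,
    statistic = ifelse(strong, -8, -0.5),
    df = 7,
    p.value = p.value
  )
}
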