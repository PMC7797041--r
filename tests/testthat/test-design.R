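test_that("split_utr places boundaries per the exhaustive-search oracle", {
  mir <- mir34a()
  seq <- fixture_980_utr(starts = c(101L, 701L))
  utr <- utr_tbl(seq, id = "CLOCK", gene = "CLOCK")
  sites <- find_seed_sites(utr, mir)
  expect_equal(sites$start, c(101L, 701L)) # planted sites recovered

  params <- design_params(target_chunk_len = 490, min_flank = 10)
  inserts <- split_utr(utr, sites, params)
  expect_equal(nrow(inserts), 2)
  expect_equal(inserts$label, c("CLOCK_1", "CLOCK_2"))

  # oracle: admissible cuts lie in [118, 690]; nearest to 490 is 490
  b <- oracle_best_boundary(980L, sites, 10L, 490L)
  expect_equal(b, 490L)
  expect_equal(inserts$end[1], b)
  expect_equal(inserts$start[2], b + 1L)

  # each segment holds exactly one site, re-based to the insert
  expect_equal(sapply(inserts$sites, nrow), c(1L, 1L))
  expect_equal(inserts$sites[[1]]$start, 101L)
  expect_equal(inserts$sites[[2]]$start, 701L - 490L)
})

test_that("short UTRs stay a single segment and dense sites are infeasible", {
  utr <- utr_tbl(strrep("ACGT", 75), id = "g", gene = "g") # 300 nt
  ins <- split_utr(utr, NULL, design_params(target_chunk_len = 490))
  expect_equal(nrow(ins), 1)
  expect_equal(ins$sequence, utr$sequence)
  expect_equal(ins$label, "g_1")

  # sites covering the whole partition-point neighbourhood block the design
  utr2 <- utr_tbl(strrep("A", 980), id = "g2", gene = "g2")
  dense <- tibble::tibble(
    mirna_id = "m", site_type = "8mer",
    start = seq(1L, 971L, by = 9L), end = pmin(seq(1L, 971L, by = 9L) + 7L, 980L)
  )
  expect_error(
    split_utr(utr2, dense, design_params(target_chunk_len = 490, min_flank = 10)),
    "no admissible boundary"
  )
})

test_that("segment tiling and site conservation hold on random designs", {
  mirs <- sim_mirnas(2, seed = 21)
  withr::with_seed(22, {
    for (i in 1:25) {
      n_sites <- sample(0:3, 1)
      spec <- if (n_sites > 0) {
        tibble::tibble(
          gene_id = "G1",
          mirna_id = sample(mirs$mirna_id, n_sites, replace = TRUE),
          site_type = sample(c("8mer", "7mer-m8", "7mer-A1", "6mer"), n_sites, replace = TRUE),
          count = 1L
        )
      } else {
        NULL
      }
      sim <- sim_utrs(
        1, mirs, spec,
        length_mean = sample(500:1400, 1), seed = 1000 + i
      )
      utr <- sim$utrs[1, ]
      sites <- find_seed_sites(utr, mirs)
      inserts <- split_utr(utr, sites, design_params(target_chunk_len = 490))

      # tiling reconstructs the UTR exactly
      expect_equal(paste(inserts$sequence, collapse = ""), utr$sequence)
      expect_equal(inserts$start[1], 1L)
      expect_equal(inserts$end[nrow(inserts)], nchar(utr$sequence))
      if (nrow(inserts) > 1) {
        expect_equal(inserts$start[-1], inserts$end[-nrow(inserts)] + 1L)
      }
      expect_true(all(inserts$length <= 1500))
      expect_equal(inserts$segment_index, seq_len(nrow(inserts)))

      # site multiset is conserved after re-basing
      rebased <- dplyr::bind_rows(lapply(seq_len(nrow(inserts)), function(j) {
        s <- inserts$sites[[j]]
        if (!nrow(s)) return(NULL)
        s$abs_start <- s$start + inserts$start[j] - 1L
        s
      }))
      abs_starts <- if (is.null(rebased) || !nrow(rebased)) integer(0) else rebased$abs_start
      expect_equal(sort(abs_starts), sort(sites$start))
    }
  })
})

test_that("validate_insert reports enzyme hits, crowded sites and length", {
  params <- design_params(cloning_enzymes = c("SpeI", "SacI"))
  cat <- enzyme_tbl()
  ins <- tibble::tibble(
    label = "g_1", gene_id = "g", utr_id = "g", segment_index = 1L,
    start = 1L, end = 20L, length = 20L,
    sequence = "GGACTAGTGGGGGGGGGGGG",
    sites = list(tibble::tibble(
      mirna_id = "m", start = 3L, end = 10L, site_type = "8mer"
    ))
  )
  v <- validate_insert(ins, params, cat)
  expect_setequal(unique(v$violation), c("cloning_enzyme_hit", "site_near_end"))

  clean <- tibble::tibble(
    label = "g_1", gene_id = "g", utr_id = "g", segment_index = 1L,
    start = 1L, end = 40L, length = 40L,
    sequence = strrep("AC", 20),
    sites = list(tibble::tibble(
      mirna_id = "m", start = 15L, end = 22L, site_type = "8mer"
    ))
  )
  expect_equal(nrow(validate_insert(clean, params, cat)), 0)

  long <- clean
  long$length <- 1600L
  long$sequence <- strrep("AC", 800)
  v <- validate_insert(long, design_params(max_insert_len = 1500))
  expect_equal(v$violation, "length_exceeded")

  expect_error(
    validate_insert(clean, design_params(cloning_enzymes = "NoSuchEnzyme"), cat),
    "unknown cloning enzyme"
  )
})

test_that("knockout mutants lose their sites, keep length and are reproducible", {
  mir <- mir34a()
  seq <- fixture_980_utr(starts = c(101L, 701L))
  utr <- utr_tbl(seq, id = "CREB1", gene = "CREB1")
  sites <- find_seed_sites(utr, mir)
  params <- design_params(cloning_enzymes = "SpeI")
  inserts <- split_utr(utr, sites, params)

  mut <- design_knockout(inserts[1, ], mir,
    catalog = enzyme_tbl(),
    params = params, seed = 9
  )
  expect_equal(mut$label, "CREB1_1_mut")
  expect_equal(nchar(mut$sequence), inserts$length[1])
  subs <- mut$substitutions[[1]]
  expect_lte(nrow(subs), 6)
  expect_gt(nrow(subs), 0)
  # every substitution is a transversion at the recorded position
  purine <- c("A", "G")
  for (r in seq_len(nrow(subs))) {
    expect_equal(substr(inserts$sequence[1], subs$pos[r], subs$pos[r]), subs$ref[r])
    expect_equal(substr(mut$sequence, subs$pos[r], subs$pos[r]), subs$alt[r])
    expect_true(xor(subs$ref[r] %in% purine, subs$alt[r] %in% purine))
  }
  # site-finder oracle: nothing canonical remains on the mutated interval
  resid <- find_seed_sites(utr_tbl(mut$sequence, id = "mut"), mir)
  ms <- mut$mutated_sites[[1]]
  if (nrow(resid)) {
    expect_false(any(resid$start <= ms$end[1] & resid$end >= ms$start[1]))
  }
  # no new cloning-enzyme hit
  hits_parent <- find_restriction_sites(
    utr_tbl(inserts$sequence[1], id = "p"), enzyme_tbl()[1, ]
  )
  hits_mut <- find_restriction_sites(
    utr_tbl(mut$sequence, id = "m"), enzyme_tbl()[1, ]
  )
  expect_lte(nrow(hits_mut), nrow(hits_parent))

  # determinism and identity for the empty subset
  mut2 <- design_knockout(inserts[1, ], mir,
    catalog = enzyme_tbl(),
    params = params, seed = 9
  )
  expect_equal(mut$sequence, mut2$sequence)
  ident <- design_knockout(inserts[1, ], mir,
    site_subset = integer(0),
    catalog = enzyme_tbl(), params = params, seed = 9
  )
  expect_equal(ident$sequence, inserts$sequence[1])
  expect_equal(nrow(ident$substitutions[[1]]), 0)
})

test_that("increasing min_flank never makes an infeasible design feasible", {
  utr <- utr_tbl(strrep("A", 600), id = "g", gene = "g")
  sites <- tibble::tibble(
    mirna_id = "m", site_type = "8mer",
    start = seq(250L, 350L, by = 10L), end = seq(257L, 357L, by = 10L)
  )
  feasible_at <- function(flank) {
    !inherits(try(
      split_utr(utr, sites, design_params(target_chunk_len = 300, min_flank = flank)),
      silent = TRUE
    ), "try-error")
  }
  feas <- vapply(c(0L, 5L, 10L, 30L, 60L, 120L), feasible_at, logical(1))
  # once infeasible, larger flanks stay infeasible
  expect_true(all(diff(as.integer(feas)) <= 0))
})

test_that("design_report orders, labels and round-trips the design", {
  mir <- mir34a()
  seq <- fixture_980_utr()
  utr <- utr_tbl(seq, id = "CLOCK", gene = "CLOCK")
  inserts <- split_utr(utr, find_seed_sites(utr, mir), design_params())
  single <- split_utr(
    utr_tbl(strrep("ACGT", 50), id = "ONE", gene = "ONE"), NULL, design_params()
  )
  all_ins <- dplyr::bind_rows(inserts, single)
  mut <- design_knockout(inserts[1, ], mir, seed = 3)

  prefix <- file.path(withr::local_tempdir(), "design")
  annot <- design_report(all_ins, mut, path_prefix = prefix)
  expect_true(file.exists(paste0(prefix, ".fasta")))
  expect_true(file.exists(paste0(prefix, ".tsv")))
  expect_equal(annot$label, c("CLOCK_1", "CLOCK_2", "ONE_1", "CLOCK_1_mut"))

  back <- Biostrings::readBStringSet(paste0(prefix, ".fasta"))
  expect_equal(unname(as.character(back)), annot$sequence)
  tsv <- readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE)
  expect_equal(tsv$label, annot$label)

  # empty design gives a header-only report
  empty <- design_report(mirscreen:::empty_inserts())
  expect_equal(nrow(empty), 0)

  expect_error(design_report(dplyr::bind_rows(inserts, inserts)), "duplicate")
})
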