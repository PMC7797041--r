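# Seeded generators for fully synthetic inputs with known ground truth.
# They emulate the shape of a reporter-assay screen (3'UTRs with planted
# seed sites, four-arm luciferase plates, per-tool prediction matrices,
# gene-set collections); they are not models of real UTR composition.

#' Generate random mature miRNA sequences
#'
#' @param n number of miRNAs.
#' @param length sequence length in nt (mature miRNAs are ~22 nt).
#' @param seed integer seed.
#' @return a tibble with `mirna_id`, `sequence` (RNA).
#' @export
sim_mirnas <- function(n, length = 22, seed = 1) {
  stopifnot(length >= 8)
  with_seed(as.integer(seed), {
    tibble(
      mirna_id = sprintf("miR-sim-%d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(RNA_ALPHABET, length, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

random_dna <- function(n, gc_content) {
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs), collapse = "")
}

# Resample any window matching a seed pattern of the given miRNAs until the
# sequence is free of accidental canonical sites.
scrub_accidental_sites <- function(seq, mirnas, gc_content, max_iter = 50) {
  for (i in seq_len(max_iter)) {
    sites <- find_seed_sites(
      tibble(utr_id = "x", gene_id = "x", sequence = seq), mirnas
    )
    if (!nrow(sites)) return(seq)
    for (j in seq_len(nrow(sites))) {
      w <- sites$end[j] - sites$start[j] + 1L
      substr(seq, sites$start[j], sites$end[j]) <- random_dna(w, gc_content)
    }
  }
  abort("could not scrub accidental seed sites from background sequence")
}

#' Generate 3'UTR sequences with planted canonical seed sites
#'
#' Backgrounds are i.i.d. nucleotides at the requested GC content,
#' rejection-sampled so that no accidental canonical site for any supplied
#' miRNA remains; the requested sites are then planted at random
#' non-overlapping positions (with flanks adjusted so a planted site keeps
#' exactly its requested type) and the result re-verified with the site
#' scanner.
#'
#' @param n_genes number of genes (ids `G1`, `G2`, ...), one UTR each.
#' @param mirnas miRNA tibble (`mirna_id`, `sequence`); accidental-site
#'   scrubbing applies to these miRNAs.
#' @param sites_spec tibble with `gene_id`, `mirna_id`, `site_type`,
#'   `count`; `NULL` plants nothing.
#' @param length_mean,length_sd UTR length distribution in nt (study-like
#'   default ~980 nt, the scale at which a UTR splits into two ~490 nt
#'   inserts).
#' @param gc_content background GC fraction.
#' @param end_margin minimum distance between a planted site and a UTR end.
#' @param seed integer seed; same seed and parameters give identical output.
#' @return a list with `utrs` (tibble as from [read_utr()]) and `truth`
#'   (tibble of planted sites: `utr_id`, `gene_id`, `mirna_id`,
#'   `site_type`, `start`, `end`).
#' @export
sim_utrs <- function(n_genes, mirnas, sites_spec = NULL,
                     length_mean = 980, length_sd = 0, gc_content = 0.45,
                     end_margin = 30, seed = 1) {
  stopifnot(n_genes >= 1, length_mean > 0, gc_content > 0, gc_content < 1)
  stopifnot_cols(mirnas, c("mirna_id", "sequence"), "mirnas")
  genes <- sprintf("G%d", seq_len(n_genes))
  if (!is.null(sites_spec)) {
    stopifnot_cols(sites_spec, c("gene_id", "mirna_id", "site_type", "count"), "sites_spec")
    if (length(setdiff(sites_spec$gene_id, genes))) {
      abort("sites_spec refers to unknown gene ids (use G1..Gn)")
    }
    if (length(setdiff(sites_spec$mirna_id, mirnas$mirna_id))) {
      abort("sites_spec refers to unknown miRNA ids")
    }
    if (any(!sites_spec$site_type %in% SITE_TYPES)) abort("unknown site_type in sites_spec")
  }

  with_seed(as.integer(seed), {
    utr_rows <- list()
    truth_rows <- list()
    for (g in genes) {
      L <- max(60L, as.integer(round(rnorm(1, length_mean, length_sd))))
      spec_g <- if (is.null(sites_spec)) NULL else filter(sites_spec, .data$gene_id == g)
      planted <- plant_gene_utr(L, g, mirnas, spec_g, gc_content, end_margin)
      utr_rows <- c(utr_rows, list(tibble(
        utr_id = g, gene_id = g, transcript_id = NA_character_,
        sequence = planted$seq
      )))
      truth_rows <- c(truth_rows, list(planted$truth))
    }
    list(
      utrs = bind_rows(utr_rows),
      truth = bind_rows(truth_rows)
    )
  })
}

plant_gene_utr <- function(L, gene_id, mirnas, spec_g, gc_content, end_margin,
                           max_attempts = 25) {
  wanted <- if (is.null(spec_g) || !nrow(spec_g)) {
    tibble(mirna_id = character(), site_type = character())
  } else {
    spec_g |>
      tidyr::uncount(.data$count) |>
      select("mirna_id", "site_type")
  }
  empty_truth <- tibble(
    utr_id = character(), gene_id = character(), mirna_id = character(),
    site_type = character(), start = integer(), end = integer()
  )
  for (attempt in seq_len(max_attempts)) {
    seq <- scrub_accidental_sites(random_dna(L, gc_content), mirnas, gc_content)
    if (!nrow(wanted)) {
      return(list(seq = seq, truth = empty_truth))
    }
    truth <- plant_sites_once(seq, L, wanted, mirnas, end_margin)
    if (is.null(truth)) next
    # re-verify: the scanner must report exactly the planted sites
    found <- find_seed_sites(
      tibble(utr_id = gene_id, gene_id = gene_id, sequence = truth$seq), mirnas
    )
    expected <- arrange(truth$truth, .data$mirna_id, .data$start)
    got <- arrange(
      select(found, "mirna_id", "site_type", "start", "end"),
      .data$mirna_id, .data$start
    )
    if (identical(
      as.data.frame(select(expected, "mirna_id", "site_type", "start", "end")),
      as.data.frame(got)
    )) {
      truth$truth$utr_id <- gene_id
      truth$truth$gene_id <- gene_id
      return(list(seq = truth$seq, truth = truth$truth))
    }
  }
  abort(sprintf("could not place requested sites in %s without artifacts", gene_id))
}

plant_sites_once <- function(seq, L, wanted, mirnas, end_margin, pad = 15L) {
  occupied <- matrix(numeric(0), ncol = 2)
  truth <- list()
  for (i in seq_len(nrow(wanted))) {
    mi <- mirnas[mirnas$mirna_id == wanted$mirna_id[i], ][1, ]
    pats <- seed_patterns(mi$sequence)
    type <- wanted$site_type[i]
    pat <- pats[[type]]
    w <- nchar(pat)
    lo <- end_margin + 2L
    hi <- L - w - end_margin - 1L
    if (hi < lo) return(NULL)
    placed <- FALSE
    for (try in seq_len(50)) {
      s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      e <- s + w - 1L
      if (nrow(occupied) &&
        any(s <= occupied[, 2] + pad & e >= occupied[, 1] - pad)) {
        next
      }
      substr(seq, s, e) <- pat
      # keep the planted site at exactly its requested type: no accidental
      # A1-adenine downstream, no accidental m8 match upstream
      m8 <- substr(pats[["7mer-m8"]], 1, 1)
      if (type %in% c("6mer", "7mer-m8")) {
        if (substr(seq, e + 1L, e + 1L) == "A") substr(seq, e + 1L, e + 1L) <- "C"
      }
      if (type %in% c("6mer", "7mer-A1")) {
        if (substr(seq, s - 1L, s - 1L) == m8) {
          substr(seq, s - 1L, s - 1L) <- setdiff(c("C", "G", "T", "A"), m8)[1]
        }
      }
      occupied <- rbind(occupied, c(s, e))
      truth <- c(truth, list(tibble(
        utr_id = NA_character_, gene_id = NA_character_,
        mirna_id = mi$mirna_id, site_type = type,
        start = as.integer(s), end = as.integer(e)
      )))
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  list(seq = seq, truth = bind_rows(truth))
}

#' Simulate a four-arm dual-luciferase plate
#'
#' Emits well-level firefly/renilla readings for the four transfection arms
#' of each construct, with a multiplicative miRNA effect planted on the
#' `mir+utr` arm. Useful for exercising [normalize_rlu()] end to end.
#'
#' @param constructs tibble with `construct_label`, `gene_id`, `effect`
#'   (expected RLU of the miR arm; 1 = no effect).
#' @param n_replicates wells per arm (assays here ran 8).
#' @param noise_cv lognormal coefficient of variation of per-well ratios.
#' @param seed integer seed.
#' @return a well-level tibble as accepted by [normalize_rlu()].
#' @export
sim_plate <- function(constructs, n_replicates = 8, noise_cv = 0.05, seed = 1) {
  stopifnot_cols(constructs, c("construct_label", "gene_id", "effect"), "constructs")
  arms <- c("empty_mir+empty_utr", "empty_mir+utr", "mir+empty_utr", "mir+utr")
  with_seed(as.integer(seed), {
    rows <- pmap(constructs, function(construct_label, gene_id, effect, ...) {
      per_arm <- map(arms, function(arm) {
        mult <- if (arm == "mir+utr") effect else 1
        renilla <- exp(rnorm(n_replicates, log(1e5), 0.2))
        ratio <- mult * exp(rnorm(n_replicates, 0, noise_cv))
        tibble(
          plate_id = "P1",
          well_id = sprintf("%s_%s_%d", construct_label, arm, seq_len(n_replicates)),
          design = arm,
          construct_label = construct_label,
          gene_id = gene_id,
          firefly = ratio * renilla,
          renilla = renilla
        )
      })
      bind_rows(per_arm)
    })
    bind_rows(rows)
  })
}

#' Simulate replicate-level RLU values with planted effects
#'
#' True targets draw replicate RLUs from `Normal(effect_mean, effect_sd)`
#' truncated at zero; null constructs from `Normal(1, null_sd)`. The
#' defaults mirror a strong reporter response (mean RLU 0.6 of control,
#' within the 0.33-0.8 range typical of validated targets) with 8
#' replicates.
#'
#' @param n_true,n_null numbers of true-target and null constructs.
#' @param effect_mean,effect_sd RLU distribution of true targets.
#' @param null_sd RLU spread of null constructs (mean 1).
#' @param n_replicates replicates per construct (>= 2).
#' @param seed integer seed.
#' @return a list with `rlu` (tibble `construct_label`, `gene_id`,
#'   `replicate`, `rlu`) and `truth` (tibble `construct_label`, `gene_id`,
#'   `is_target`).
#' @export
sim_rlu <- function(n_true, n_null, effect_mean = 0.6, effect_sd = 0.1,
                    null_sd = 0.1, n_replicates = 8, seed = 1) {
  stopifnot(n_replicates >= 2, effect_sd > 0, null_sd > 0)
  draw_trunc <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(x < 0)) {
      bad <- x < 0
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    x
  }
  with_seed(as.integer(seed), {
    truth <- tibble(
      gene_id = c(sprintf("TG%d", seq_len(n_true)), sprintf("NG%d", seq_len(n_null))),
      is_target = rep(c(TRUE, FALSE), c(n_true, n_null))
    )
    truth$construct_label <- paste0(truth$gene_id, "_1")
    rlu <- pmap(truth, function(gene_id, is_target, construct_label) {
      vals <- if (is_target) {
        draw_trunc(n_replicates, effect_mean, effect_sd)
      } else {
        draw_trunc(n_replicates, 1, null_sd)
      }
      tibble(
        construct_label = construct_label,
        gene_id = gene_id,
        replicate = seq_len(n_replicates),
        rlu = vals
      )
    })
    list(rlu = bind_rows(rlu), truth = select(truth, "construct_label", "gene_id", "is_target"))
  })
}

#' Simulate a per-tool prediction table from known labels
#'
#' Each tool predicts each true pair with probability equal to its
#' sensitivity, and each false pair with probability `1 - specificity`,
#' independently across pairs and tools.
#'
#' @param truth tibble with `mirna_id`, `gene_id`, `is_target`.
#' @param tools_spec tibble with `tool_name`, `sensitivity`, `specificity`
#'   and optionally `stringency`.
#' @param seed integer seed.
#' @return a prediction tibble as accepted by [as_prediction_table()].
#' @export
sim_predictions <- function(truth, tools_spec, seed = 1) {
  stopifnot_cols(truth, c("mirna_id", "gene_id", "is_target"), "truth")
  stopifnot_cols(tools_spec, c("tool_name", "sensitivity", "specificity"), "tools_spec")
  if (any(tools_spec$sensitivity < 0 | tools_spec$sensitivity > 1 |
    tools_spec$specificity < 0 | tools_spec$specificity > 1)) {
    abort("sensitivity and specificity must lie in [0, 1]")
  }
  if (!"stringency" %in% names(tools_spec)) tools_spec$stringency <- "default"
  with_seed(as.integer(seed), {
    rows <- pmap(tools_spec, function(tool_name, sensitivity, specificity, stringency, ...) {
      p_hit <- ifelse(truth$is_target, sensitivity, 1 - specificity)
      hit <- runif(nrow(truth)) < p_hit
      if (!any(hit)) return(NULL)
      tibble(
        mirna_id = truth$mirna_id[hit],
        gene_id = truth$gene_id[hit],
        tool_name = tool_name,
        stringency = stringency
      )
    })
    out <- bind_rows(rows)
    if (!nrow(out)) {
      out <- tibble(
        mirna_id = character(), gene_id = character(),
        tool_name = character(), stringency = character()
      )
    }
    out
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' @param genes universe of gene ids.
#' @param n_sets number of random sets.
#' @param set_size members per random set.
#' @param enriched_set_genes genes forming the planted set (`NULL` for no
#'   planted set).
#' @param enriched_set_name name of the planted set.
#' @param seed integer seed.
#' @return a gene-set tibble as from [read_gmt()].
#' @export
sim_gene_sets <- function(genes, n_sets = 20, set_size = 15,
                          enriched_set_genes = NULL,
                          enriched_set_name = "TNF signaling pathway",
                          seed = 1) {
  stopifnot(set_size <= length(genes))
  with_seed(as.integer(seed), {
    out <- tibble(
      set_name = sprintf("RANDOM_SET_%02d", seq_len(n_sets)),
      description = "random set",
      genes = map(seq_len(n_sets), function(i) sample(genes, set_size))
    )
    if (!is.null(enriched_set_genes)) {
      out <- bind_rows(
        tibble(
          set_name = enriched_set_name,
          description = "planted enriched set",
          genes = list(unique(enriched_set_genes))
        ),
        out
      )
    }
    out
  })
}
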