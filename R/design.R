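#' Reporter-insert design parameters
#'
#' @param target_chunk_len desired insert length in nt; long UTRs are split
#'   into `round(length / target_chunk_len)` segments. The bundled screens
#'   used ~490 nt and ~690 nt inserts.
#' @param max_insert_len hard upper limit on insert length in nt (synthesis /
#'   cloning limit, default 1500).
#' @param min_flank minimum distance (nt) between a segment boundary and any
#'   binding site, so no site is clipped or crowded by a cut (default 10).
#' @param cloning_enzymes names of restriction enzymes whose motifs must not
#'   occur in a valid insert.
#' @return a `design_params` list.
#' @export
design_params <- function(target_chunk_len = 490,
                          max_insert_len = 1500,
                          min_flank = 10,
                          cloning_enzymes = character()) {
  if (target_chunk_len <= 0 || target_chunk_len > max_insert_len) {
    abort("need 0 < target_chunk_len <= max_insert_len")
  }
  if (min_flank < 0) abort("min_flank must be >= 0")
  structure(
    list(
      target_chunk_len = as.integer(target_chunk_len),
      max_insert_len = as.integer(max_insert_len),
      min_flank = as.integer(min_flank),
      cloning_enzymes = as.character(cloning_enzymes)
    ),
    class = "design_params"
  )
}

empty_inserts <- function() {
  tibble(
    label = character(), gene_id = character(), utr_id = character(),
    segment_index = integer(), start = integer(), end = integer(),
    length = integer(), sequence = character(), sites = list()
  )
}

#' Split a 3'UTR into reporter-insert segments
#'
#' Segments tile the UTR without gaps or overlaps. The number of segments is
#' `max(1, round(length / target_chunk_len))`; each internal boundary is
#' placed in a site-free window (at least `min_flank` nt from every binding
#' site) as close as possible to the equal-partition point, so every site
#' falls wholly inside exactly one segment. Segments are numbered
#' consecutively from the 5' end and labelled `<gene>_<index>`.
#'
#' @param utr one-row tibble with `utr_id`, `gene_id`, `sequence`.
#' @param sites binding sites on this UTR (tibble with `start`, `end`,
#'   `site_type`, `mirna_id`; 1-based inclusive), e.g. from
#'   [find_seed_sites()].
#' @param params a [design_params()] object.
#' @return a tibble of inserts: `label`, `gene_id`, `utr_id`,
#'   `segment_index`, `start`, `end`, `length`, `sequence` and a list-column
#'   `sites` with coordinates re-based to the insert.
#' @export
split_utr <- function(utr, sites = NULL, params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  utr <- as_tibble(utr)
  stopifnot_cols(utr, c("utr_id", "gene_id", "sequence"), "utr")
  if (nrow(utr) != 1) abort("split_utr() designs one UTR at a time")
  seq <- normalize_dna(utr$sequence)
  len <- nchar(seq)
  if (is.null(sites)) {
    sites <- tibble(
      mirna_id = character(), start = integer(), end = integer(),
      site_type = character()
    )
  }
  sites <- as_tibble(sites)
  if (nrow(sites)) {
    stopifnot_cols(sites, c("start", "end"), "sites")
    if (any(sites$start < 1 | sites$end > len | sites$start > sites$end)) {
      abort("sites must lie within the UTR")
    }
    sites <- arrange(sites, .data$start)
  }

  n_chunks <- max(1L, as.integer(floor(len / params$target_chunk_len + 0.5)))
  if (len / n_chunks > params$max_insert_len) {
    n_chunks <- as.integer(ceiling(len / params$max_insert_len))
  }

  bounds <- integer(0) # cut after these positions
  prev <- 0L
  if (n_chunks > 1) {
    for (i in seq_len(n_chunks - 1L)) {
      ideal <- as.integer(floor(i * len / n_chunks + 0.5))
      cand <- seq.int(prev + 1L, len - 1L)
      ok <- rep(TRUE, length(cand))
      if (nrow(sites)) {
        for (j in seq_len(nrow(sites))) {
          s <- sites$start[j]
          e <- sites$end[j]
          ok <- ok & (cand <= s - params$min_flank - 1L | cand >= e + params$min_flank)
        }
      }
      ok <- ok & !(cand %in% bounds)
      if (!any(ok)) {
        abort(sprintf(
          "no admissible boundary window near position %d of %s (sites too dense)",
          ideal, utr$utr_id
        ))
      }
      cand <- cand[ok]
      p <- cand[order(abs(cand - ideal), cand)][1]
      bounds <- c(bounds, p)
      prev <- p
    }
  }

  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, len)
  if (any(ends - starts + 1L > params$max_insert_len)) {
    abort(sprintf(
      "%s cannot be split into segments of at most %d nt with the given sites",
      utr$utr_id, params$max_insert_len
    ))
  }

  inserts <- tibble(
    label = sprintf("%s_%d", utr$gene_id, seq_len(n_chunks)),
    gene_id = utr$gene_id,
    utr_id = utr$utr_id,
    segment_index = seq_len(n_chunks),
    start = starts,
    end = ends,
    length = ends - starts + 1L,
    sequence = substr(rep(seq, n_chunks), starts, ends)
  )
  inserts$sites <- map2(starts, ends, function(s, e) {
    if (!nrow(sites)) return(sites)
    inside <- sites$start >= s & sites$end <= e
    sub <- sites[inside, , drop = FALSE]
    sub$start <- sub$start - s + 1L
    sub$end <- sub$end - s + 1L
    sub
  })
  n_placed <- sum(map_int(inserts$sites, nrow))
  if (n_placed != nrow(sites)) {
    abort("internal error: a binding site was split across segment boundaries")
  }
  inserts
}

#' Check inserts for synthesis readiness
#'
#' Reports cloning-enzyme hits, binding sites closer than `min_flank` to an
#' insert end, and length violations. An empty result means the insert is
#' ready to be synthesized.
#'
#' @param inserts insert tibble from [split_utr()] (or a mutant from
#'   [design_knockout()]).
#' @param params a [design_params()] object.
#' @param catalog enzyme catalog covering all `cloning_enzymes`.
#' @return a tibble of violations: `label`, `violation`, `detail`.
#' @export
validate_insert <- function(inserts, params = design_params(), catalog = NULL) {
  stopifnot(inherits(params, "design_params"))
  out <- list()
  if (length(params$cloning_enzymes)) {
    if (is.null(catalog)) abort("a catalog is required to check cloning enzymes")
    catalog <- as_enzyme_catalog(catalog)
    unknown <- setdiff(params$cloning_enzymes, catalog$enzyme_name)
    if (length(unknown)) {
      abort(sprintf("unknown cloning enzyme(s): %s", paste(unknown, collapse = ", ")))
    }
    cat_sub <- catalog[catalog$enzyme_name %in% params$cloning_enzymes, ]
    hits <- find_restriction_sites(
      tibble(utr_id = inserts$label, sequence = inserts$sequence), cat_sub
    )
    if (nrow(hits)) {
      out <- c(out, list(tibble(
        label = hits$utr_id,
        violation = "cloning_enzyme_hit",
        detail = sprintf("%s at %d-%d (%s)", hits$enzyme_name, hits$start, hits$end, hits$strand)
      )))
    }
  }
  for (i in seq_len(nrow(inserts))) {
    st <- inserts$sites[[i]]
    if (!is.null(st) && nrow(st)) {
      near <- st$start - 1L < params$min_flank |
        inserts$length[i] - st$end < params$min_flank
      if (any(near)) {
        out <- c(out, list(tibble(
          label = inserts$label[i],
          violation = "site_near_end",
          detail = sprintf(
            "site at %d-%d is < %d nt from an insert end",
            st$start[near], st$end[near], params$min_flank
          )
        )))
      }
    }
    if (inserts$length[i] > params$max_insert_len) {
      out <- c(out, list(tibble(
        label = inserts$label[i],
        violation = "length_exceeded",
        detail = sprintf("%d nt > limit %d nt", inserts$length[i], params$max_insert_len)
      )))
    }
  }
  if (!length(out)) {
    return(tibble(label = character(), violation = character(), detail = character()))
  }
  bind_rows(out)
}

#' Design a binding-site knockout mutant of an insert
#'
#' Within each selected site, the six bases pairing miRNA positions 2-7 (the
#' seed-match core) are replaced by transversions, chosen by a deterministic
#' seeded search, such that no canonical site type for the miRNA remains
#' overlapping the original site interval and no new cloning-enzyme motif is
#' introduced. Unselected sites are untouched; the mutant has the same
#' length as its parent.
#'
#' @param insert one-row insert tibble from [split_utr()].
#' @param mirna one-row tibble (or list) with `mirna_id` and `sequence`.
#' @param site_subset row indices into `insert$sites[[1]]` to knock out;
#'   `NULL` selects every site of that miRNA.
#' @param catalog enzyme catalog (required if `params$cloning_enzymes` is
#'   non-empty).
#' @param params a [design_params()] object.
#' @param seed integer seed making the substitution search reproducible.
#' @param max_tries search budget before giving up.
#' @return a one-row tibble: `label` (`<parent>_mut`), `parent_label`,
#'   `sequence`, list-columns `substitutions` (`pos`, `ref`, `alt`) and
#'   `mutated_sites`.
#' @export
design_knockout <- function(insert, mirna, site_subset = NULL,
                            catalog = NULL, params = design_params(),
                            seed = 1L, max_tries = 200L) {
  stopifnot(nrow(insert) == 1)
  mirna <- as_tibble(mirna[c("mirna_id", "sequence")])[1, ]
  sites <- insert$sites[[1]]
  if (is.null(sites)) sites <- tibble()
  if (is.null(site_subset)) {
    site_subset <- which(sites$mirna_id == mirna$mirna_id)
  }
  if (length(site_subset) && (!nrow(sites) || any(site_subset < 1 | site_subset > nrow(sites)))) {
    abort("site_subset must index rows of the insert's contained sites")
  }
  mutant_row <- function(seq, subs, msites) {
    tibble(
      label = paste0(insert$label, "_mut"),
      parent_label = insert$label,
      gene_id = insert$gene_id,
      sequence = seq,
      substitutions = list(subs),
      mutated_sites = list(msites)
    )
  }
  no_subs <- tibble(pos = integer(), ref = character(), alt = character())
  if (!length(site_subset)) {
    return(mutant_row(insert$sequence, no_subs, sites[0, , drop = FALSE]))
  }

  sel <- sites[site_subset, , drop = FALSE]
  core_shift <- ifelse(sel$site_type %in% c("7mer-m8", "8mer"), 1L, 0L)
  core_pos <- unique(unlist(map2(
    sel$start + core_shift, sel$start + core_shift + 5L, seq.int
  )))
  core_pos <- sort(core_pos)
  parent_seq <- insert$sequence
  parent_chars <- strsplit(parent_seq, "", fixed = TRUE)[[1]]
  transversions <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  if (any(!parent_chars[core_pos] %in% names(transversions))) {
    abort("cannot mutate ambiguous bases (N) in a seed-match core")
  }

  cloning_cat <- NULL
  parent_hits <- NULL
  if (length(params$cloning_enzymes)) {
    if (is.null(catalog)) abort("a catalog is required to check cloning enzymes")
    catalog <- as_enzyme_catalog(catalog)
    cloning_cat <- catalog[catalog$enzyme_name %in% params$cloning_enzymes, ]
    parent_hits <- find_restriction_sites(
      tibble(utr_id = "x", sequence = parent_seq), cloning_cat
    )
  }

  with_seed(as.integer(seed), {
    for (try in seq_len(max_tries)) {
      chars <- parent_chars
      for (p in core_pos) {
        opts <- transversions[[parent_chars[p]]]
        chars[p] <- sample(opts, 1)
      }
      mut_seq <- paste(chars, collapse = "")
      resid <- find_seed_sites(
        tibble(utr_id = "x", gene_id = "x", sequence = mut_seq), mirna
      )
      overlaps <- FALSE
      if (nrow(resid)) {
        for (j in seq_len(nrow(sel))) {
          overlaps <- overlaps ||
            any(resid$start <= sel$end[j] & resid$end >= sel$start[j])
        }
      }
      if (overlaps) next
      if (!is.null(cloning_cat) && nrow(cloning_cat)) {
        mut_hits <- find_restriction_sites(
          tibble(utr_id = "x", sequence = mut_seq), cloning_cat
        )
        new_hit <- nrow(anti_join(
          mut_hits, parent_hits,
          by = c("enzyme_name", "start", "end", "strand")
        )) > 0
        if (new_hit) next
      }
      changed <- which(chars != parent_chars)
      subs <- tibble(pos = changed, ref = parent_chars[changed], alt = chars[changed])
      return(mutant_row(mut_seq, subs, sel))
    }
    abort(sprintf(
      "no admissible knockout substitution found for %s within %d tries",
      insert$label, max_tries
    ))
  })
}

#' Report designed inserts (FASTA + annotation TSV)
#'
#' Writes the synthesis-ready sequences as FASTA and a companion annotation
#' table as TSV, ordered by gene then segment index (mutants follow their
#' parents). Coordinates in the report are 1-based inclusive on the source
#' UTR.
#'
#' @param inserts insert tibble from [split_utr()] (possibly several genes,
#'   row-bound).
#' @param mutants optional mutant tibble from [design_knockout()].
#' @param path_prefix if non-`NULL`, files `<prefix>.fasta` and
#'   `<prefix>.tsv` are written.
#' @param params a [design_params()] object.
#' @param catalog optional enzyme catalog for validation status.
#' @return the annotation tibble, invisibly if files were written.
#' @export
design_report <- function(inserts, mutants = NULL, path_prefix = NULL,
                          params = design_params(), catalog = NULL) {
  inserts <- arrange(inserts, .data$gene_id, .data$segment_index)
  annot <- inserts |>
    mutate(
      n_sites = map_int(.data$sites, nrow),
      site_list = map_chr(.data$sites, function(s) {
        if (!nrow(s)) return("")
        paste(sprintf("%d-%d:%s", s$start, s$end, s$site_type), collapse = ",")
      }),
      is_mutant = FALSE,
      n_substitutions = 0L
    ) |>
    select(
      "label", "gene_id", "utr_id", "segment_index", "start", "end",
      "length", "n_sites", "site_list", "is_mutant", "n_substitutions",
      "sequence"
    )
  viol <- validate_insert(inserts, params, catalog)
  annot$status <- ifelse(
    annot$label %in% viol$label,
    map_chr(annot$label, function(l) {
      paste(unique(viol$violation[viol$label == l]), collapse = ";")
    }),
    "ok"
  )
  if (!is.null(mutants) && nrow(mutants)) {
    mut_annot <- mutants |>
      mutate(
        utr_id = NA_character_,
        segment_index = NA_integer_,
        start = NA_integer_, end = NA_integer_,
        length = nchar(.data$sequence),
        n_sites = map_int(.data$mutated_sites, nrow),
        site_list = map_chr(.data$mutated_sites, function(s) {
          if (!nrow(s)) return("")
          paste(sprintf("%d-%d:%s", s$start, s$end, s$site_type), collapse = ",")
        }),
        is_mutant = TRUE,
        n_substitutions = map_int(.data$substitutions, nrow),
        status = "ok"
      ) |>
      select(all_of(names(annot)))
    annot <- bind_rows(annot, mut_annot)
  }
  if (anyDuplicated(annot$label)) {
    abort(sprintf(
      "duplicate insert label(s): %s",
      paste(unique(annot$label[duplicated(annot$label)]), collapse = ", ")
    ))
  }
  if (!is.null(path_prefix)) {
    write_fasta(annot, paste0(path_prefix, ".fasta"), id_col = "label")
    readr::write_tsv(select(annot, -"sequence"), paste0(path_prefix, ".tsv"))
    return(invisible(annot))
  }
  annot
}
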