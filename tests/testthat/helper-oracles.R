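# Independent oracles: deliberately naive implementations that share no code
# with the package internals.

# Reverse complement via Biostrings (the package uses its own character map).
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Seed-match strings for the four canonical types, built from first
# principles: complement the seed, reverse it, append the A1 adenine.
oracle_patterns <- function(mirna_rna) {
  dna <- chartr("U", "T", toupper(mirna_rna))
  p6 <- oracle_revcomp(substr(dna, 2, 7))
  p7m8 <- oracle_revcomp(substr(dna, 2, 8))
  list(
    "6mer" = p6,
    "7mer-A1" = paste0(p6, "A"),
    "7mer-m8" = p7m8,
    "8mer" = paste0(p7m8, "A")
  )
}

# All-window scan for every site type with most-specific-per-core dedup,
# written as plain loops over substrings.
oracle_seed_scan <- function(utr_seq, mirna_rna) {
  utr_seq <- toupper(utr_seq)
  pats <- oracle_patterns(mirna_rna)
  core_off <- c("6mer" = 0L, "7mer-A1" = 0L, "7mer-m8" = 1L, "8mer" = 1L)
  prio <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
  L <- nchar(utr_seq)
  rows <- list()
  for (type in names(pats)) {
    p <- pats[[type]]
    w <- nchar(p)
    if (L < w) next
    for (s in seq_len(L - w + 1L)) {
      if (substr(utr_seq, s, s + w - 1L) == p) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_type = type, start = s, end = s + w - 1L,
          core = s + core_off[[type]], prio = prio[[type]]
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      site_type = character(), start = integer(), end = integer()
    ))
  }
  df <- do.call(rbind, rows)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$core), function(idx) {
    idx[which.max(df$prio[idx])]
  }))
  df <- df[sort(keep), c("site_type", "start", "end")]
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  df
}

# IUPAC window scan via Biostrings fuzzy matching (sense strand only).
oracle_iupac_starts <- function(motif, subject) {
  hits <- Biostrings::matchPattern(
    motif, Biostrings::DNAString(subject),
    fixed = FALSE
  )
  Biostrings::start(hits)
}

# Upper-tail hypergeometric probability from binomial coefficients.
oracle_hyper_upper <- function(N, K, n, k) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  js <- seq.int(k, jmax)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up written out directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Closed-form one-sample two-tailed t-test.
oracle_ttest <- function(x, mu) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}

# Brute-force association rules: enumerate every subset of the item universe
# as an antecedent and compute support/confidence by direct counting.
oracle_rules <- function(txns, min_support, min_confidence, consequent) {
  outcome_items <- c("validated", "not_validated")
  items <- sort(setdiff(unique(unlist(txns)), outcome_items))
  n <- length(txns)
  supp <- function(set) {
    sum(vapply(txns, function(t) all(set %in% t), logical(1))) / n
  }
  rows <- list()
  if (length(items)) {
    for (k in seq_along(items)) {
      combos <- utils::combn(items, k, simplify = FALSE)
      for (a in combos) {
        s_joint <- supp(c(a, consequent))
        if (s_joint < min_support) next
        conf <- s_joint / supp(a)
        if (conf < min_confidence) next
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent_str = paste(a, collapse = ","),
          support = s_joint, confidence = conf
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      antecedent_str = character(), support = numeric(), confidence = numeric()
    ))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$confidence, -df$support, df$antecedent_str), ]
  rownames(df) <- NULL
  df
}

# Exhaustive admissible-boundary search for a two-segment split.
oracle_best_boundary <- function(len, sites, min_flank, ideal) {
  cand <- seq_len(len - 1L)
  ok <- rep(TRUE, length(cand))
  if (nrow(sites)) {
    for (j in seq_len(nrow(sites))) {
      ok <- ok & (cand <= sites$start[j] - min_flank - 1L |
        cand >= sites$end[j] + min_flank)
    }
  }
  cand <- cand[ok]
  if (!length(cand)) return(NA_integer_)
  cand[order(abs(cand - ideal), cand)][1]
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
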