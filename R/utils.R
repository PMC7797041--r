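# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
RNA_ALPHABET <- c("A", "C", "G", "U")

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Normalize a nucleotide string to DNA (sense strand, uppercase, U -> T)
#'
#' @param x character vector of sequences.
#' @param allow_n allow ambiguous N (TRUE for 3'UTRs).
#' @return normalized character vector over \{A,C,G,T\} (plus N if allowed).
#' @keywords internal
normalize_dna <- function(x, allow_n = TRUE) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", allowed), x)
  if (any(bad)) {
    abort(sprintf(
      "invalid DNA character(s) in sequence(s): %s",
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  x
}

#' Normalize a nucleotide string to RNA (uppercase, T -> U)
#' @keywords internal
normalize_rna <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf(
      "invalid RNA character(s) in sequence(s): %s",
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  x
}

# Reverse complement of a plain DNA/IUPAC string (vectorized).
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- IUPAC_COMPLEMENT[chars]
    if (anyNA(comp)) abort(sprintf("cannot complement sequence '%s'", s))
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round half away from zero (base round() is banker's).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Percentage to one decimal, half away from zero: 0.598315 -> 59.8.
as_percent <- function(p, digits = 1) round_half_up(100 * p, digits)

# All randomness in the package flows through seeds passed explicitly;
# withr::with_seed keeps the caller's RNG state untouched.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Stable key for a (miRNA, gene) pair.
pair_key <- function(mirna_id, gene_id) paste(mirna_id, gene_id, sep = "\r")

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
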