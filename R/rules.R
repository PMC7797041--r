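OUTCOME_ITEMS <- c("validated", "not_validated")

#' Build transactions linking tool predictions to validation outcome
#'
#' One transaction per experimentally tested (miRNA, gene) pair: its items
#' are the tools predicting the pair (stringency tiers of a tool collapse
#' to one item) plus exactly one outcome item, `validated` for a positive
#' assay outcome and `not_validated` for a negative one. Setting
#' `invert_outcome = TRUE` negates the outcome vector, which is useful to
#' check that non-validated targets are not predicted systematically.
#'
#' @param predictions prediction tibble.
#' @param validated validated-interaction tibble; its pairs define the
#'   universe.
#' @param invert_outcome swap the outcome items.
#' @return a tibble with `mirna_id`, `gene_id`, `outcome` and a list-column
#'   `items`.
#' @export
build_transactions <- function(predictions, validated, invert_outcome = FALSE) {
  predictions <- as_prediction_table(predictions)
  validated <- as_validated_table(validated)
  if (!nrow(validated)) abort("empty transaction universe")
  tools_by_pair <- predictions |>
    distinct(.data$mirna_id, .data$gene_id, .data$tool_name) |>
    summarise(tools = list(sort(.data$tool_name)), .by = c("mirna_id", "gene_id"))
  out <- validated |>
    distinct(.data$mirna_id, .data$gene_id, .data$outcome) |>
    left_join(tools_by_pair, by = c("mirna_id", "gene_id")) |>
    mutate(
      tools = map(.data$tools, function(t) if (is.null(t)) character(0) else t),
      outcome_item = ifelse(
        xor(.data$outcome == "positive", invert_outcome),
        "validated", "not_validated"
      ),
      items = map2(.data$tools, .data$outcome_item, function(t, o) c(t, o))
    ) |>
    select("mirna_id", "gene_id", "outcome", "items")
  out
}

itemset_support <- function(txns, itemset) {
  mean(map_lgl(txns, function(t) all(itemset %in% t)))
}

#' Mine association rules toward a validation outcome
#'
#' Level-wise (apriori) search for rules `antecedent -> consequent` where
#' the antecedent is a non-empty set of tools and the consequent is one
#' outcome item. Rule support is the joint frequency of antecedent and
#' consequent; confidence is the conditional frequency of the consequent
#' given the antecedent. Candidate antecedents are pruned by support
#' anti-monotonicity before counting.
#'
#' @param transactions tibble from [build_transactions()] (or a bare list
#'   of character item vectors).
#' @param min_support minimum rule support (screens here used 0.25).
#' @param min_confidence minimum confidence (screens here used 0.8).
#' @param consequent outcome item, `"validated"` or `"not_validated"`.
#' @return a tibble with list-column `antecedent`, plus `antecedent_str`,
#'   `consequent`, `n_items`, `support`, `confidence`, sorted by confidence
#'   then support (both decreasing), then antecedent.
#' @export
apriori_rules <- function(transactions, min_support = 0.25,
                          min_confidence = 0.8, consequent = "validated") {
  if (!(min_support > 0 && min_support <= 1)) abort("need 0 < min_support <= 1")
  if (!(min_confidence > 0 && min_confidence <= 1)) abort("need 0 < min_confidence <= 1")
  if (!consequent %in% OUTCOME_ITEMS) {
    abort(sprintf(
      "consequent must be one of: %s", paste(OUTCOME_ITEMS, collapse = ", ")
    ))
  }
  txns <- if (is.data.frame(transactions)) transactions$items else transactions
  txns <- map(txns, as.character)
  if (!length(txns)) abort("no transactions")

  items <- sort(setdiff(unique(unlist(txns)), OUTCOME_ITEMS))
  empty <- tibble(
    antecedent = list(), antecedent_str = character(),
    consequent = character(), n_items = integer(),
    support = double(), confidence = double()
  )
  if (!length(items)) return(empty)

  set_key <- function(s) paste(s, collapse = "\r")
  # frequency of antecedent jointly with the consequent (the rule support);
  # anti-monotone in the antecedent, so it drives the level-wise pruning
  joint_supp <- function(s) itemset_support(txns, c(s, consequent))

  frequent <- list() # per level: list of antecedent character vectors
  level1 <- keep(map(items, identity), function(s) joint_supp(s) >= min_support)
  frequent[[1]] <- level1
  k <- 1L
  while (length(frequent[[k]]) > 1) {
    prev <- frequent[[k]]
    prev_keys <- vapply(prev, set_key, character(1))
    cand <- list()
    seen <- character(0)
    for (i in seq_along(prev)) {
      for (j in seq_along(prev)) {
        if (i == j) next
        u <- sort(union(prev[[i]], prev[[j]]))
        if (length(u) != k + 1L) next
        key <- set_key(u)
        if (key %in% seen) next
        seen <- c(seen, key)
        # apriori pruning: every k-subset must itself be frequent
        subs_ok <- all(vapply(seq_along(u), function(d) {
          set_key(u[-d]) %in% prev_keys
        }, logical(1)))
        if (subs_ok) cand <- c(cand, list(u))
      }
    }
    nxt <- keep(cand, function(s) joint_supp(s) >= min_support)
    if (!length(nxt)) break
    k <- k + 1L
    frequent[[k]] <- nxt
  }

  antecedents <- unlist(frequent, recursive = FALSE)
  if (is.null(antecedents) || !length(antecedents)) return(empty)
  rows <- map(antecedents, function(a) {
    supp_joint <- joint_supp(a)
    supp_a <- itemset_support(txns, a)
    tibble(
      antecedent = list(a),
      antecedent_str = paste(a, collapse = ","),
      consequent = consequent,
      n_items = length(a),
      support = supp_joint,
      confidence = supp_joint / supp_a
    )
  })
  bind_rows(rows) |>
    filter(.data$confidence >= min_confidence) |>
    arrange(desc(.data$confidence), desc(.data$support), .data$antecedent_str)
}
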