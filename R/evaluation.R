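#' Confusion counts on the tested universe
#'
#' The evaluation universe is strictly the experimentally tested pairs
#' (positives plus negatives); predicted pairs outside it are ignored.
#'
#' @param predicted tibble of predicted pairs (`mirna_id`, `gene_id`).
#' @param positives,negatives tibbles of tested pairs with positive /
#'   negative outcome (disjoint).
#' @return a one-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, positives, negatives) {
  key <- function(df) {
    stopifnot_cols(df, c("mirna_id", "gene_id"), "pair table")
    unique(pair_key(df$mirna_id, df$gene_id))
  }
  pos <- key(positives)
  neg <- key(negatives)
  if (length(intersect(pos, neg))) {
    abort("positive and negative sets overlap")
  }
  pred <- key(predicted)
  tibble(
    TP = length(intersect(pred, pos)),
    TN = length(setdiff(neg, pred)),
    FP = length(intersect(pred, neg)),
    FN = length(setdiff(pos, pred))
  )
}

#' Classifier metrics from confusion counts
#'
#' Computes sensitivity (= recall), specificity, balanced accuracy
#' (their mean), precision and F1. Ratios with a zero denominator are
#' returned as `NA` and named in `undefined` rather than silently zeroed.
#' `*_pct` columns give percentages rounded half away from zero to one
#' decimal.
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @return a one-row tibble of counts, proportions, percentages and the
#'   `undefined` flag field.
#' @export
#' @examples
#' confusion_metrics(124, 32, 32, 54)$balanced_accuracy_pct # 59.8
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(TP, TP + FN)
  spec <- ratio(TN, TN + FP)
  prec <- ratio(TP, TP + FP)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  undef <- c(
    if (TP + FN == 0) "sensitivity",
    if (TN + FP == 0) "specificity",
    if (TP + FP == 0) "precision",
    if (is.na(f1)) "f1"
  )
  tibble(
    TP = TP, TN = TN, FP = FP, FN = FN,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = ba,
    precision = prec,
    recall = sens,
    f1 = f1,
    sensitivity_pct = as_percent(sens),
    specificity_pct = as_percent(spec),
    balanced_accuracy_pct = as_percent(ba),
    undefined = paste(undef, collapse = ",")
  )
}

#' Benchmark prediction tools against validated interactions
#'
#' Each (tool, stringency) tier is scored as a separate predictor on the
#' universe of tested pairs. A tool with zero predictions on the universe
#' gets an all-negative confusion row and is flagged.
#'
#' @param predictions prediction tibble (see [read_predictions()]).
#' @param validated validated-interaction tibble with both outcomes.
#' @return a tibble with one metrics row per (tool, stringency), ordered by
#'   decreasing balanced accuracy, ties by tool name.
#' @export
benchmark_tools <- function(predictions, validated) {
  predictions <- as_prediction_table(predictions)
  validated <- as_validated_table(validated)
  positives <- filter(validated, .data$outcome == "positive")
  negatives <- filter(validated, .data$outcome == "negative")
  if (!nrow(positives) || !nrow(negatives)) {
    abort("validated table must contain both positive and negative outcomes")
  }
  tiers <- distinct(predictions, .data$tool_name, .data$stringency)
  rows <- pmap(tiers, function(tool_name, stringency) {
    pred <- filter(
      predictions,
      .data$tool_name == .env$tool_name, .data$stringency == .env$stringency
    )
    cc <- confusion_counts(pred, positives, negatives)
    m <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
    m$tool_name <- tool_name
    m$stringency <- stringency
    m$no_predictions_on_universe <- cc$TP + cc$FP == 0
    m
  })
  bind_rows(rows) |>
    relocate("tool_name", "stringency") |>
    arrange(desc(.data$balanced_accuracy), .data$tool_name, .data$stringency)
}
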