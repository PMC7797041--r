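#' Normalize raw luciferase readings to replicate RLUs
#'
#' Per well the transfection-corrected ratio `r = firefly / renilla` is
#' taken; per construct, each miR-arm replicate is then scaled by the mean
#' ratio of that construct's empty-miR arm:
#' `RLU_i = r(mir+utr)_i / mean(r(empty_mir+utr))`. An RLU of 1.0 is the
#' reference level (no miRNA effect).
#'
#' @param wells well-level tibble (see [read_wells()]).
#' @return a tibble with `construct_label`, `gene_id`, `replicate`, `rlu`.
#' @export
normalize_rlu <- function(wells) {
  stopifnot_cols(
    wells, c("design", "construct_label", "gene_id", "firefly", "renilla"),
    "wells"
  )
  if (any(wells$renilla <= 0)) abort("renilla readings must be > 0")
  wells <- mutate(wells, ratio = .data$firefly / .data$renilla)
  per_construct <- wells |>
    filter(.data$design %in% c("mir+utr", "empty_mir+utr")) |>
    tidyr::nest(.by = c("construct_label", "gene_id"))
  out <- pmap(per_construct, function(construct_label, gene_id, data) {
    trt <- data$ratio[data$design == "mir+utr"]
    ctl <- data$ratio[data$design == "empty_mir+utr"]
    if (!length(trt) || !length(ctl)) {
      abort(sprintf(
        "construct %s is missing the %s arm",
        construct_label,
        if (!length(trt)) "mir+utr" else "empty_mir+utr"
      ))
    }
    tibble(
      construct_label = construct_label,
      gene_id = gene_id,
      replicate = seq_along(trt),
      rlu = trt / mean(ctl)
    )
  })
  bind_rows(out)
}

#' One-sample two-tailed t-test
#'
#' Tests whether the mean of `values` differs from `mu`:
#' `t = (mean - mu) / (sd / sqrt(n))` on `n - 1` degrees of freedom.
#'
#' @param values numeric replicate values (n >= 2, non-zero spread).
#' @param mu null-hypothesis mean (1.0 for RLUs: no miRNA effect).
#' @return a one-row tibble: `estimate` (sample mean), `statistic`, `df`,
#'   `p.value`.
#' @export
one_sample_ttest <- function(values, mu = 1) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("need at least 2 replicates for a t-test")
  if (sd(values) == 0) {
    abort("degenerate sample: replicate values have zero variance")
  }
  fit <- t.test(values, mu = mu, alternative = "two.sided")
  tibble(
    estimate = unname(fit$estimate),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p.value = fit$p.value
  )
}

#' Test every construct against the no-effect reference level
#'
#' @param rlu replicate-level RLU tibble (`construct_label`, `gene_id`,
#'   `rlu`), e.g. from [normalize_rlu()].
#' @param mu reference level (default 1.0).
#' @return a tibble with one row per construct: `construct_label`,
#'   `gene_id`, `n`, `mean_rlu`, `statistic`, `df`, `p.value`.
#' @export
test_constructs <- function(rlu, mu = 1) {
  stopifnot_cols(rlu, c("construct_label", "gene_id", "rlu"), "rlu")
  if (!nrow(rlu)) abort("empty RLU table")
  rlu |>
    tidyr::nest(.by = c("construct_label", "gene_id")) |>
    mutate(
      n = map_int(.data$data, nrow),
      fit = map(.data$data, function(d) one_sample_ttest(d$rlu, mu))
    ) |>
    tidyr::unnest("fit") |>
    rename(mean_rlu = "estimate") |>
    select("construct_label", "gene_id", "n", "mean_rlu", "statistic", "df", "p.value")
}

#' Validation cut-off presets
#'
#' * `standard`: significant two-tailed reduction, `p < 0.05` with mean RLU
#'   below the reference level.
#' * `stringent`: `p < 0.005` and mean RLU below 80% of the reference.
#' * `custom`: user-supplied `p_max` / `rlu_max`.
#'
#' @param name preset name.
#' @param p_max,rlu_max cut-offs for a custom preset.
#' @param require_downshift only count reductions (mean RLU < 1) as
#'   validated.
#' @return a `validation_preset` list.
#' @export
validation_preset <- function(name = c("standard", "stringent", "custom"),
                              p_max = NULL, rlu_max = NULL,
                              require_downshift = TRUE) {
  name <- match.arg(name)
  if (name == "standard") {
    p_max <- 0.05
    rlu_max <- 1.0
  } else if (name == "stringent") {
    p_max <- 0.005
    rlu_max <- 0.8
  } else if (is.null(p_max) || is.null(rlu_max)) {
    abort("a custom preset needs p_max and rlu_max")
  }
  if (p_max <= 0 || p_max > 1 || rlu_max <= 0 || rlu_max > 1) {
    abort("need 0 < p_max <= 1 and 0 < rlu_max <= 1")
  }
  structure(
    list(
      name = name, p_max = p_max, rlu_max = rlu_max,
      require_downshift = isTRUE(require_downshift)
    ),
    class = "validation_preset"
  )
}

#' Classify constructs as validated under a preset
#'
#' A construct is validated when `p < p_max`, `mean_rlu < rlu_max` and (if
#' the preset requires a downshift) `mean_rlu < 1`.
#'
#' @param results construct-level tibble from [test_constructs()].
#' @param preset a [validation_preset()] (or preset name).
#' @return logical vector, one flag per row of `results`.
#' @export
classify_construct <- function(results, preset = validation_preset("standard")) {
  if (is.character(preset)) preset <- validation_preset(preset)
  stopifnot_cols(results, c("mean_rlu", "p.value"), "results")
  ok <- results$p.value < preset$p_max & results$mean_rlu < preset$rlu_max
  if (preset$require_downshift) ok <- ok & results$mean_rlu < 1
  ok
}

#' Aggregate construct results to the gene level
#'
#' A gene counts as validated when at least one of its tested 3'UTR
#' segments is validated under the preset.
#'
#' @param results construct-level tibble from [test_constructs()].
#' @param preset a [validation_preset()].
#' @return a tibble with `gene_id`, `n_segments`, `n_validated`,
#'   `validated`.
#' @export
aggregate_genes <- function(results, preset = validation_preset("standard")) {
  if (!nrow(results)) abort("empty results")
  results |>
    mutate(v = classify_construct(results, preset)) |>
    summarise(
      n_segments = dplyr::n(),
      n_validated = sum(.data$v),
      validated = any(.data$v),
      .by = "gene_id"
    )
}

#' Validation rate at construct or gene level
#'
#' @param results construct-level tibble from [test_constructs()].
#' @param preset a [validation_preset()].
#' @param level `"construct"` (fraction of tested segments validated) or
#'   `"gene"` (fraction of genes with >= 1 validated segment).
#' @return a fraction in `[0, 1]`.
#' @export
validation_rate <- function(results, preset = validation_preset("standard"),
                            level = c("construct", "gene")) {
  level <- match.arg(level)
  if (!nrow(results)) abort("empty results")
  if (level == "construct") {
    mean(classify_construct(results, preset))
  } else {
    mean(aggregate_genes(results, preset)$validated)
  }
}

#' Validation rates over a grid of cut-offs
#'
#' Enumerates p-value and mean-RLU thresholds and computes the validation
#' rate for every combination; the rate is non-increasing as either cut-off
#' tightens.
#'
#' @param results construct-level tibble from [test_constructs()].
#' @param p_grid,rlu_grid numeric vectors of thresholds.
#' @param level `"construct"` or `"gene"`.
#' @return a tibble with `p_max`, `rlu_max`, `rate`.
#' @export
cutoff_grid <- function(results, p_grid = c(0.05, 0.01, 0.005, 0.001),
                        rlu_grid = c(1.0, 0.9, 0.8, 0.7),
                        level = c("construct", "gene")) {
  level <- match.arg(level)
  if (!length(p_grid) || !length(rlu_grid)) abort("empty threshold grid")
  tidyr::expand_grid(p_max = p_grid, rlu_max = rlu_grid) |>
    mutate(rate = map2_dbl(.data$p_max, .data$rlu_max, function(p, r) {
      validation_rate(
        results,
        validation_preset("custom", p_max = p, rlu_max = r),
        level = level
      )
    }))
}

#' Test for a systematic 3'UTR length bias
#'
#' For paired assays of the same gene with a long and a short insert,
#' computes the per-gene ratio `long / short` of mean RLUs and applies a
#' one-sample two-sided t-test against mu = 1. A zero-variance ratio vector
#' (all ratios identical) carries no evidence of bias and is reported as
#' such instead of a t statistic.
#'
#' @param long,short paired numeric vectors of mean RLUs (same genes, same
#'   order; `short` values must be positive).
#' @return a `length_bias` object with `ratios`, `statistic`, `df`,
#'   `p.value` and a `note`; `tidy()`/`glance()` methods are provided.
#' @export
length_bias_test <- function(long, short) {
  if (length(long) != length(short)) abort("long and short must be paired")
  if (length(long) < 2) abort("need at least 2 pairs")
  if (any(short <= 0)) abort("short-assay RLUs must be > 0")
  ratios <- long / short
  if (sd(ratios) == 0) {
    warn("all length ratios identical: no detectable bias")
    out <- list(
      ratios = ratios, statistic = NA_real_, df = length(ratios) - 1L,
      p.value = NA_real_, note = "no detectable bias"
    )
  } else {
    fit <- one_sample_ttest(ratios, mu = 1)
    out <- list(
      ratios = ratios, statistic = fit$statistic, df = fit$df,
      p.value = fit$p.value, note = NA_character_
    )
  }
  structure(out, class = "length_bias")
}

#' @export
print.length_bias <- function(x, ...) {
  cat("3'UTR length-bias test (one-sample t on long/short ratios, mu = 1)\n")
  if (!is.na(x$note)) {
    cat(" ", x$note, "\n")
  } else {
    cat(sprintf(
      "  n = %d, t = %.4f, df = %d, p = %.4g\n",
      length(x$ratios), x$statistic, x$df, x$p.value
    ))
  }
  invisible(x)
}

#' @rdname length_bias_test
#' @param x a `length_bias` object.
#' @param ... unused.
#' @export
tidy.length_bias <- function(x, ...) {
  tibble(pair = seq_along(x$ratios), ratio = x$ratios)
}

#' @rdname length_bias_test
#' @export
glance.length_bias <- function(x, ...) {
  tibble(
    n = length(x$ratios),
    mean_ratio = mean(x$ratios),
    statistic = x$statistic,
    df = x$df,
    p.value = x$p.value,
    note = x$note
  )
}
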