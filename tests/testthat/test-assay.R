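make_wells <- function(trt_ratio, ctl_ratio = 1, n = 4, renilla = 1e5) {
  arms <- tibble::tibble(
    design = rep(c("mir+utr", "empty_mir+utr"), each = n),
    ratio = rep(c(trt_ratio, ctl_ratio), each = n)
  )
  tibble::tibble(
    plate_id = "P1",
    well_id = sprintf("w%d", seq_len(nrow(arms))),
    design = arms$design,
    construct_label = "c1",
    gene_id = "g1",
    firefly = arms$ratio * renilla,
    renilla = renilla
  )
}

test_that("normalize_rlu is a ratio of ratios anchored at 1", {
  # identical arms -> all RLUs exactly 1
  out <- normalize_rlu(make_wells(1, 1))
  expect_equal(out$rlu, rep(1, 4))

  # halved miR-arm ratios -> RLUs 0.5
  out <- normalize_rlu(make_wells(0.5, 1))
  expect_equal(out$rlu, rep(0.5, 4))

  # scaling every reading of the plate by a common factor changes nothing
  wells <- make_wells(0.7, 1)
  scaled <- dplyr::mutate(wells, firefly = firefly * 3.7, renilla = renilla * 3.7)
  expect_equal(normalize_rlu(scaled)$rlu, normalize_rlu(wells)$rlu)

  # missing control arm is an error
  expect_error(
    normalize_rlu(dplyr::filter(wells, design == "mir+utr")),
    "empty_mir\\+utr"
  )
})

test_that("a simulated plate recovers the planted effect", {
  wells <- sim_plate(
    tibble::tibble(construct_label = "TCRA_1", gene_id = "TCRA", effect = 0.547),
    n_replicates = 8, noise_cv = 0.04, seed = 12
  )
  rlu <- normalize_rlu(wells)
  expect_equal(nrow(rlu), 8)
  expect_equal(mean(rlu$rlu), 0.547, tolerance = 0.05)
})

test_that("one_sample_ttest matches the closed form", {
  # df = 2 has the closed-form CDF 0.5 * (1 + t / sqrt(t^2 + 2))
  fit <- one_sample_ttest(c(0.5, 0.6, 0.7), mu = 1)
  expect_equal(fit$statistic, -6.9282, tolerance = 1e-4)
  expect_equal(fit$df, 2)
  t <- fit$statistic
  p_closed <- 2 * 0.5 * (1 + t / sqrt(t^2 + 2))
  expect_equal(fit$p.value, p_closed, tolerance = 1e-9)
  expect_equal(fit$p.value, 0.0202, tolerance = 1e-3)

  expect_error(one_sample_ttest(rep(1, 5), 1), "zero variance")
  expect_error(one_sample_ttest(0.4, 1), "at least 2")

  # symmetric sample around mu: t = 0, p = 1
  fit <- one_sample_ttest(c(0.9, 1.1, 1.05, 0.95), mu = 1)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p.value, 1)

  withr::with_seed(51, {
    for (i in 1:50) {
      x <- rnorm(sample(3:20, 1), mean = runif(1, 0.3, 1.5), sd = runif(1, 0.02, 0.3))
      ref <- oracle_ttest(x, 1)
      fit <- one_sample_ttest(x, 1)
      expect_equal(fit$statistic, ref$t, tolerance = 1e-9)
      expect_equal(fit$p.value, ref$p, tolerance = 1e-9)
    }
  })
})

test_that("presets classify constructs with the downshift requirement", {
  res <- tibble::tibble(
    construct_label = c("a", "b", "c"), gene_id = c("a", "b", "c"),
    n = 8, mean_rlu = c(0.6, 0.85, 1.2), statistic = 0, df = 7,
    p.value = c(0.001, 0.001, 0.001)
  )
  expect_equal(classify_construct(res, validation_preset("standard")), c(TRUE, TRUE, FALSE))
  expect_equal(classify_construct(res, validation_preset("stringent")), c(TRUE, FALSE, FALSE))
  # boundary: p and RLU cut-offs are strict
  res2 <- dplyr::mutate(res, p.value = 0.05, mean_rlu = 0.5)
  expect_equal(classify_construct(res2, "standard"), c(FALSE, FALSE, FALSE))
})

test_that("gene-level aggregation validates a gene from any one segment", {
  res <- tibble::tibble(
    construct_label = c("g1_1", "g1_2", "g2_1", "g3_1"),
    gene_id = c("g1", "g1", "g2", "g3"),
    n = 8,
    mean_rlu = c(0.5, 1.0, 1.0, 0.6),
    statistic = 0, df = 7,
    p.value = c(0.001, 0.9, 0.9, 0.002)
  )
  agg <- aggregate_genes(res, validation_preset("standard"))
  expect_equal(agg$validated[match(c("g1", "g2", "g3"), agg$gene_id)], c(TRUE, FALSE, TRUE))
  # single-segment gene equals its segment flag
  expect_equal(
    agg$validated[agg$gene_id == "g3"],
    classify_construct(res[4, ], "standard")
  )
  expect_equal(validation_rate(res, level = "construct"), 0.5)
  expect_equal(validation_rate(res, level = "gene"), 2 / 3)
})

test_that("validation_rate reproduces a 12-of-30 screen", {
  res <- fixture_results(n_validated = 12, n_not = 18)
  expect_equal(validation_rate(res, validation_preset("standard")), 0.40)
  expect_equal(validation_rate(fixture_results(0, 10)), 0)
})

test_that("cutoff_grid is consistent and monotone in stringency", {
  res <- fixture_results(n_validated = 14, n_not = 16)
  g <- cutoff_grid(res, p_grid = 0.05, rlu_grid = 1.0)
  expect_equal(g$rate, validation_rate(res, validation_preset("standard")))

  grid <- cutoff_grid(
    res,
    p_grid = c(0.05, 0.01, 0.005, 0.001),
    rlu_grid = c(1.0, 0.9, 0.8, 0.7, 0.45)
  )
  # tightening either axis can only lower the rate
  for (p in unique(grid$p_max)) {
    rates <- grid$rate[grid$p_max == p][order(-grid$rlu_max[grid$p_max == p])]
    expect_true(all(diff(rates) <= 0))
  }
  for (r in unique(grid$rlu_max)) {
    rates <- grid$rate[grid$rlu_max == r][order(-grid$p_max[grid$rlu_max == r])]
    expect_true(all(diff(rates) <= 0))
  }
  expect_lte(
    grid$rate[grid$p_max == 0.005 & grid$rlu_max == 0.8],
    grid$rate[grid$p_max == 0.05 & grid$rlu_max == 1.0]
  )
  expect_s3_class(plot_cutoff_grid(grid), "ggplot")
})

test_that("every stringent-validated construct is standard-validated", {
  for (seed in 1:5) {
    sim <- sim_rlu(30, 30, effect_mean = 0.75, effect_sd = 0.15, seed = seed)
    res <- test_constructs(sim$rlu)
    stringent <- classify_construct(res, validation_preset("stringent"))
    standard <- classify_construct(res, validation_preset("standard"))
    expect_true(all(!stringent | standard))
  }
})

test_that("length_bias_test handles bias, symmetry and degeneracy", {
  # symmetric ratios: t = 0, p = 1
  lb <- length_bias_test(c(0.9, 1.1, 1.0, 1.0), c(1, 1, 1, 1))
  expect_equal(lb$statistic, 0)
  expect_equal(lb$p.value, 1)
  expect_s3_class(glance(lb), "tbl_df")
  expect_equal(nrow(tidy(lb)), 4)
  expect_s3_class(autoplot(lb), "ggplot")

  # all pairs equal -> zero-variance ratios surface as "no detectable bias"
  expect_warning(
    lb0 <- length_bias_test(c(1, 1, 1), c(1, 1, 1)),
    "no detectable bias"
  )
  expect_equal(lb0$note, "no detectable bias")
  expect_true(is.na(lb0$p.value))

  expect_error(length_bias_test(c(1, 1), c(0, 1)), "> 0")

  # with no planted length effect the p-value is approximately uniform
  withr::with_seed(61, {
    ps <- replicate(200, {
      long <- rnorm(10, 1, 0.1)
      short <- rnorm(10, 1, 0.1)
      length_bias_test(long, short)$p.value
    })
    expect_gt(mean(ps < 0.5), 0.35)
    expect_lt(mean(ps < 0.05), 0.15)
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
  })
})
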