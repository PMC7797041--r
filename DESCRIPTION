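Package: mirscreen
Title: Design and Evaluation of High-Throughput miRNA Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for high-throughput validation of microRNA targets with
    dual-luciferase reporter assays. Detects canonical seed-binding sites
    (6mer, 7mer-A1, 7mer-m8, 8mer) and restriction-enzyme motifs in 3'UTRs,
    designs synthesis-ready reporter inserts including segment splitting and
    binding-site knockout mutants, filters candidate targets by consensus
    prediction, hypergeometric over-representation and pathway membership,
    evaluates replicate-level luciferase results with one-sample t-tests and
    configurable validation cut-offs, benchmarks target predictors against
    validated positive/negative sets (balanced accuracy and related measures),
    and mines association rules linking tool combinations to validation
    outcome. Includes seeded generators for fully synthetic inputs with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
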