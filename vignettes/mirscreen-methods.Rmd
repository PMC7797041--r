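---
title: "Methods: models, parameters and design choices in mirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mirscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

`mirscreen` implements the computational workflow around high-throughput
dual-luciferase validation of miRNA targets: finding seed-binding sites,
designing reporter inserts, filtering candidate targets, scoring assay
results and benchmarking prediction tools. This vignette explains the
underlying models, the tunable parameters and the choices made where the
design was genuinely open.

## Canonical seed sites

A mature miRNA pairs with its target predominantly through the seed,
nucleotides 2–7 (optionally extended to 8) counted from the miRNA 5′
end. On the target strand (written 5′→3′ as DNA) the four canonical site
types are:

* **6mer** — reverse complement of miRNA positions 2–7;
* **7mer-m8** — reverse complement of positions 2–8;
* **7mer-A1** — the 6mer followed by an adenine opposite miRNA position 1
  (the A1 adenine is a property of the target, not a pairing);
* **8mer** — the 7mer-m8 followed by that adenine.

`seed_patterns()` derives these match strings; `find_seed_sites()` scans
UTRs for all four. Because the 8mer contains both 7mers and the 6mer, a
single binding event would otherwise be reported up to four times: the
scanner therefore groups matches that share the same 6mer core and keeps
only the most specific type (8mer > 7mer-m8 > 7mer-A1 > 6mer). This makes
"number of sites" mean "number of binding events", which is what insert
design and mutant verification need.

Two asymmetric conventions are deliberate: `N` in a UTR never satisfies a
seed pattern (a fabricated site is worse than a missed one when the site
list drives mutagenesis), while `N` in a restriction-enzyme motif matches
any base including `N` (that is what the IUPAC code means in an enzyme
catalog). Non-canonical sites — offset 6mers, bulged or 3′-supplementary
pairing — are out of scope; only exact canonical matches are reported.

Coordinates are 1-based and inclusive everywhere, the convention of the
R/Bioconductor ecosystem this package lives in; the same coordinates
appear in reports, so no conversion layer exists.

## Reporter-insert design

Synthesis and cloning impose a practical insert-length ceiling (default
`max_insert_len = 1500` nt), and screens work best with inserts of
roughly uniform size (`target_chunk_len`, default 490 nt — with a ~690 nt
alternative typical for a second screen). `split_utr()` chooses

```
n_chunks = max(1, round(length / target_chunk_len))
```

(half-up rounding, so the rule is deterministic where `round()`'s
banker's rounding would be ambiguous) and places each internal boundary
as close as possible to the equal-partition point, restricted to
positions at least `min_flank` nt (default 10) away from every binding
site. Segments therefore tile the UTR exactly — concatenating them in
segment order reproduces the input — and every site falls wholly inside
one segment, at least `min_flank` from the cut. If sites crowd every
admissible window, the design fails loudly rather than clipping a site.
Segment labels are `<gene>_<index>`, numbered from the 5′ end.

Knockout mutants (`design_knockout()`) replace the six bases pairing
miRNA positions 2–7 within each selected site by transversions, chosen by
a seeded search that accepts the first proposal satisfying three
conditions: no canonical site for the miRNA remains overlapping the
original site interval, no cloning-enzyme motif is created that the
parent lacked, and at most six substitutions per site are used.
Transversions are preferred because they break Watson–Crick pairing
maximally; the seeded search makes designs reproducible and lets the
site scanner itself verify the result. Inserts are emitted as bare
sequences; cloning adapters vary by vector and vendor and are left to
the caller.

## Candidate selection

The screen narrows a deliberately sensitive starting set in a fixed
order, with a per-stage audit count:

1. **Consensus** (`consensus_filter()`): keep (miRNA, gene) pairs
   predicted by at least `min_tools` distinct tools (default 4 — the
   regime where most single-tool noise is already gone). Stringency
   tiers of one tool count once.
2. **Enrichment** (`ora()` + `select_by_categories()`): an upper-tail
   hypergeometric test per gene set,
   `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, Benjamini–Hochberg
   adjusted; genes are kept if they belong to at least one enriched set
   (`q <= 0.05` by default) whose name matches a user pattern
   (case-insensitive substring — categories are usually picked by topic,
   e.g. "TNF" or "Parkinson"). The background defaults to all genes in
   the prediction table, the universe the predictions were actually
   drawn from; it is configurable because enrichment is sensitive to
   this choice.
3. **Exclusion** (`exclude_known()`): drop pairs already validated
   positive elsewhere; negative prior results do not block re-testing.
4. **Site check** (`has_canonical_site()`): require at least one
   canonical site in at least one supplied UTR of the gene. Genes with
   several annotated UTRs are accepted as multiple records; the package
   does not choose a transcript.

The stage order mirrors how such screens are run: cheap set operations
first, the sequence scan last on the smallest set.

## Assay statistics

Each well yields a transfection-corrected ratio `r = firefly/renilla`;
each miR-arm replicate is then normalized by the mean ratio of the
construct's empty-miR arm, so RLU 1.0 means "no miRNA effect". This
ratio-of-ratios is the standard dual-luciferase convention; the
replicate-level mean-of-ratios (rather than ratio-of-means) is used
because it keeps per-replicate variability visible to the t-test.
Per-plate scale factors cancel exactly; positional effects are not
modelled (plate layouts randomize control positions instead).

Constructs are tested with a two-tailed one-sample t-test against µ = 1
(`one_sample_ttest()`, n − 1 degrees of freedom; zero-variance replicate
sets raise an explicit error rather than returning p = 0). Validation is
a separate, directional decision (`classify_construct()`):

* **standard** — p < 0.05 and mean RLU < 1 (a significant *reduction*);
* **stringent** — p < 0.005 and mean RLU < 0.8.

Both cut-offs are strict inequalities. The second preset is named
"stringent" here; in informal usage the same pair of thresholds is
sometimes called permissive when the emphasis is on how robust a
validation rate remains under it. `cutoff_grid()` enumerates arbitrary
threshold grids; the rate is monotone non-increasing as either cut-off
tightens, and every stringent-validated construct is standard-validated.
Gene-level aggregation uses the any-segment rule: a gene validates when
at least one of its tested 3′UTR segments does — the natural reading
when segments isolate individual binding sites.

The length-bias test (`length_bias_test()`) takes paired long/short mean
RLUs per gene, forms ratios and t-tests them against µ = 1. If all
ratios are identical the t statistic is undefined; since identical
ratios carry no evidence of a length effect, the result is reported as
"no detectable bias" with `NA` statistics instead of an error.

## Benchmarking and rule mining

Tools are evaluated strictly on the tested universe — the union of
assay-positive and assay-negative pairs — never against the whole
transcriptome, so `TP + FN` and `TN + FP` always equal the class sizes.
From the confusion counts, sensitivity, specificity, balanced accuracy
(their mean, robust to the heavy class imbalance of validated sets),
precision, recall and F1 are derived; ratios with zero denominators are
returned as `NA` and flagged, not silently zeroed. Percentages are
rounded half away from zero to one decimal. Each stringency tier of a
tool is benchmarked as its own predictor.

`build_transactions()` turns the same data into one transaction per
tested pair — the predicting tools plus exactly one outcome item — and
`apriori_rules()` mines rules `tool set → outcome` by level-wise
frequent-itemset search. Rule support (the joint frequency of antecedent
and consequent) is anti-monotone in the antecedent, which drives
candidate pruning; defaults are support ≥ 0.25 and confidence ≥ 0.8.
Antecedents may have any cardinality, and only outcome items are allowed
as consequents: tool→tool rules are uninformative for ranking
predictors. Inverting the outcome vector checks that *non*-validated
targets are not predicted systematically by any tool subset.

## Synthetic data: what it emulates, and what it does not

The generators produce every input format with known ground truth:

* `sim_utrs()` — i.i.d. backgrounds at configurable GC content
  (default 0.45, a typical 3′UTR value), default length 980 nt (the
  scale at which a UTR splits into two ~490-nt inserts),
  rejection-sampled so no accidental canonical site for the miRNAs under
  test survives, then planted with the requested sites (flanking bases
  adjusted so a planted site keeps exactly its requested type) and
  re-verified with the scanner itself.
* `sim_plate()` / `sim_rlu()` — lognormal well noise, and replicate RLUs
  from truncated-at-zero normals: true targets
  `Normal(effect_mean = 0.6, effect_sd = 0.1)` — the centre of the
  0.33–0.8 range typical of validated reporter responses — and nulls
  `Normal(1, 0.1)`, with 8 replicates as in automated 96-well screens.
* `sim_predictions()` — each tool fires on true pairs with probability
  equal to its sensitivity and on false pairs with `1 − specificity`,
  independently.
* `sim_gene_sets()` — random sets plus one planted enriched set.

These fixtures are deliberately simple: real 3′UTRs have positional and
compositional structure, real assay noise has outliers and plate
effects, and real prediction tools are correlated with each other (they
share features and training data). Passing tests on these fixtures
therefore demonstrate the correctness of the computations, not the field
performance of any threshold; in particular the parameter-recovery rates
measured on the synthetic screen (≥ 99% of planted targets at ≤ 5%
false positives under the standard preset) describe the fixture's
signal-to-noise, not an expected laboratory validation rate.

All generators are deterministic given `(parameters, seed)`; every
random draw in the package flows through an explicit seed argument.

## Problem sizes and numerical notes

The test suite runs the site scanner against a naive all-window oracle
on 500 random (miRNA, UTR) pairs, checks designer invariants on 200
random design problems, compares the t-test to a closed-form reference
at 1e-9 on 1000 random samples, enumerates the hypergeometric tail
exhaustively for all backgrounds up to N = 25, and compares the rule
miner to brute-force antecedent enumeration up to 12 items and 64
transactions. The acceptance script uses a 200-construct screen and a
100-gene candidate fixture. These sizes exercise every code path while
keeping the whole suite fast enough to run routinely.

Ties in boundary placement (two admissible cuts equally near the ideal
point) resolve to the 5′-most cut; rule ordering is confidence, then
support, then the lexicographic antecedent string; benchmark ordering is
balanced accuracy descending with ties broken by tool name — all so that
repeated runs are byte-identical.

## Known limitations

* Only exact canonical seed matches are detected; thermodynamics,
  conservation and non-canonical pairing are out of scope.
* Gene identifiers are opaque strings; no symbol/accession mapping is
  attempted, so inputs must agree on an identifier system.
* The assay model has no plate/position random effects and no outlier
  handling; replicate RLUs enter the t-test as given.
* The ORA treats gene sets as flat lists (no ontology-graph
  propagation).
* `consensus_filter()` weighs all tools equally; correlated tools are
  counted as independent votes, which the rule-mining module partially
  diagnoses but does not correct.
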