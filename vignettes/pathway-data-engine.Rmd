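---
title: "An on-demand data engine for pathway-level exploration of two-group expression studies"
author: "pathwaylens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An on-demand data engine for pathway-level exploration of two-group expression studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaylens)
```

## The problem

Epidemiological gene-expression studies — for instance blood transcriptomes
from healthy women stratified by plasma ratios of essential fatty acids —
are routinely revisited with new questions, and the people revisiting them
are rarely the people who can re-run an analysis pipeline by hand. A
pathway-exploration application answers this by keeping the data and the
statistics on a server and letting a browser ask small questions: *what is
the fold change of these genes? which are significant? what does this KEGG
pathway look like with the statistics painted on?*

`pathwaylens` is the server side of that design: a KGML parser, an
on-demand two-group differential-expression engine, an expression-to-color
overlay builder, a caching client for KEGG-style REST resources, and a thin
HTTP transport. Everything the browser would consume is a JSON document;
nothing in the package renders pixels.

## The statistical model

The dataset is a genes × samples matrix of log2-scale intensities with a
two-level group factor; one level is designated the *reference* explicitly
(never alphabetically — the sign of every fold change depends on it). The
model is deliberately the plain one an epidemiologist reads in a methods
section:

* **Fold change** is the difference of group means on the log2 scale,
  `mean(case) − mean(reference)`. Zero is the neutral point, which is what
  makes the diverging color map meaningful. Input data are assumed already
  log2-transformed and normalized; a convenience flag reports linear ratios
  `2^fc` for display. Per-sample fold changes (each sample minus the
  reference-group mean) feed the bar-chart view of a single gene.
* **Testing** is a two-sided two-sample t-test per gene, Welch by default.
  The unequal-variance form with Welch–Satterthwaite degrees of freedom is
  the safer default for group comparisons of expression intensities, where
  variance heterogeneity between groups is common; the pooled-variance
  Student's form is available via `var_equal = TRUE` for fidelity with
  older analyses.
* **Multiplicity** is handled with the Benjamini–Hochberg step-up
  adjustment. The q-values are always computed over the full gene universe
  of the dataset and then subset to whatever a query asks for. Adjusting
  within a query would make a gene's q-value depend on which other genes
  happened to be on screen, which is statistically indefensible for a
  query-driven service.

Degenerate inputs follow documented conventions rather than producing NaN,
because the service must emit valid JSON numbers: both groups constant with
equal means gives `t = 0, p = 1`; both constant with different means gives
`p = 0` with infinite signed `t`. Genes absent from the dataset are data
(`null` in responses), not errors — a pathway's gene set routinely exceeds
what is on the array.

## Parsing KGML into a graph

A KGML document describes one KEGG pathway as `entry` elements with pixel
graphics plus `relation` and `reaction` elements. Several choices here were
genuinely open and are the package's own:

* Entries may carry several KEGG identifiers in one space-separated `name`
  attribute; all are kept in `kegg_ids`. The display label is the first
  comma-separated alias of the graphics name, matching how KEGG renders its
  own maps.
* Graphics `x`/`y` are node centers in the background image's pixel space,
  origin top-left, y downward, stored with no rescaling or flip — overlays
  must align with the KEGG-drawn image. Missing `width`/`height` default to
  the 46×17 box KEGG draws.
* `group` entries stay as nodes carrying `member_ids`; members remain
  independent nodes. Flattening would lose information the client may want.
* A reaction with several substrates and products expands to the cross
  product of substrate→product edges (subtype = reaction type), keeping the
  edge model uniform rather than inventing hyperedges.
* Unknown entry types map to `other` instead of erroring — KGML dialects
  drift across KEGG releases — and relations pointing at entries that do
  not exist in the document are dropped with a warning rather than
  poisoning the graph.

The exported view document (a `nodes`/`edges` JSON structure for
Cytoscape-style viewers) is lossless for everything above:
`parse → export → re-import` reproduces ids, labels, types, coordinates,
KEGG ids, group members and the edge list exactly, and the test suite
asserts this over generated fixtures spanning all entry kinds.

## The overlay

Fill color is a linear interpolation in RGB along a diverging
blue–white–red scale: `#0571B0` at −limit, white at 0, `#CA0020` at
+limit, clamping beyond. The anchors are a colorblind-safer diverging pair,
and the default `limit = 2` log2 units (four-fold change) covers the
effect-size range typical of microarray group comparisons; both are
parameters. Genes without statistics, and non-gene nodes, are neutral gray
(`#BEBEBE`).

Significance is a frame color for genes with `q ≤ α`, default `α = 0.05`,
with the boundary counted as significant — the inclusive reading of
"significant at the 5% level". When one node represents several genes
(a common KGML situation), the node takes the gene with the smallest
q-value, ties broken by lexicographically smallest gene id: the
representative is the signal a researcher would want to notice, and the
tie-break keeps the choice deterministic.

## The service and the cache

`handle_request()` is the pure routing core — path in, status plus JSON
out — and `serve()` wraps it in a minimal blocking HTTP/1.1 loop over a
base R server socket, one request per connection. The endpoints mirror the
library exactly: `/genes`, `/fc/{genes}`, `/pvalues/{genes}`,
`/exprs/{genes}` (gene lists are `+`-separated, KEGG-REST style; commas are
rejected with a hint) and `/pathway/{id}` (graph document merged with the
overlay). The default port is 8888. All endpoints are read-only and
idempotent, so repeated identical requests return identical bodies for a
fixed dataset; dataset-wide statistics are computed once at application
construction.

Remote KEGG resources flow through a client whose byte source is an
injected function, so offline deployments and tests run entirely on
fixtures and the REST base URL is configuration, not logic. Every fetched
payload is stored verbatim on disk under a key that percent-encodes the
resource path (injective and filesystem-safe), and entries never expire:
KEGG pathway payloads change rarely, and pinning favors reproducibility.
A failed fetch stores nothing, and an explicit `purge_cache()` is the only
invalidation.

## The synthetic-data generator

The generator stands in for the cohort data a deployment would hold, which
cannot be shipped. It emulates a two-group log2-intensity study: per-gene
baselines from Normal(7, 2) — a rough log2-microarray intensity range —
within-group Gaussian noise with standard deviation σ, and a planted shift
of δ log2 units added to the case group of a chosen subset of genes. The
defaults (1000 genes, 10 samples per group, 50 differentially expressed
genes, δ = 2, σ = 1) are the study conditions used throughout the
validation suite. Every simulation can be written to disk with a JSON truth
manifest recording the planted genes and all parameters, and the matching
KGML fixture generator can draw its gene identifiers from the simulated
gene universe so that pathway and dataset join.

What the generator does **not** emulate: probe-level effects, batch
structure, missingness, inter-gene correlation, or heavy-tailed noise.
Passing tests therefore demonstrate correctness of the computations and
calibration under independent Gaussian noise — not robustness to the
artifacts of any particular array platform.

## Validation choices and problem sizes

The package's guarantees are checked as properties, at sizes chosen to
keep Monte-Carlo error small relative to the margins being asserted:

* BH agreement with an independently coded step-up rule on 1000 random
  p-vectors (lengths 1–200), to 10⁻¹²; Welch t/p against the closed-form
  formula on 500 random group pairs, to 10⁻¹⁰ relative error.
* Realized false-discovery proportion at `q ≤ 0.05` averaged over 100
  replicate studies at the default conditions, required to stay within
  twice its Monte-Carlo standard error of the nominal 0.05; power at δ = 2
  must exceed power at δ = 0.5 (monotonicity in effect size).
* Global-null calibration over 200 replicates (any-discovery rate within
  binomial error of 0.05) plus a Kolmogorov–Smirnov uniformity check of
  raw p-values at the 1% level on a 1000-gene null study.
* Structural guarantees (round-trip, API-library equivalence, the
  fetch-at-most-once cache contract, and the equality of served
  significance frames with an independent recount of significant pathway
  genes) are exact counts, not tolerances.

`scripts/acceptance.R` recomputes all of these from scratch under a single
`--seed` and writes the measured values as JSON.

## Known limitations

Two groups only — no paired designs, covariates, or more than two levels;
no normalization or batch correction (inputs are taken as analysis-ready
log2 intensities); no moderated (empirical-Bayes) variance estimates, so
very small groups rely on the raw per-gene t-test; the HTTP loop is
single-threaded and unauthenticated, intended to sit behind whatever
process supervision and transport security a deployment already has; and
KGML writing is limited to the synthetic fixture generator — the package
consumes KEGG's documents, it does not re-serialize arbitrary graphs back
to KGML.
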