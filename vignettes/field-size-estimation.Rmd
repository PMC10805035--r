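---
title: "Estimating the size of research fields from unique author counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the size of research fields from unique author counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcensus)
library(dplyr)
```

## The measurement

A scientific field is made of people, not papers. `fieldcensus` estimates
the size of a field — the human workforce attached to a research topic —
by counting the **distinct author names** appearing on the field's
publications in each calendar year. Counting authors rather than papers
controls for differences in laboratory productivity: a field of 100 labs
publishing one paper each is larger than one lab publishing 100 papers,
and only an author census can tell them apart.

The pipeline is:

1. a field is denoted by a search query (tokens joined with `+`, e.g.
   `Penicillium+marneffei`) matched by the bibliographic backend against
   titles, abstracts and keywords;
2. the matching records are parsed from either of the two standard PubMed
   exchange formats (MEDLINE tagged text via `read_medline()`, or
   `PubmedArticleSet` XML via `read_pubmed_xml()`);
3. an **eligibility filter** (`eligible_records()`) keeps only records
   with a publication date and authors with a recorded first *and* last
   name — abbreviated `AU`-only authors carry no usable first name and
   are excluded;
4. `census()` reports, per calendar year, the number of papers and the
   cardinality of the set of normalised (first, last) name keys.

### Name keys and their known biases

`name_key()` normalises deterministically: Unicode canonical composition,
trimming, internal-whitespace collapse, case folding. Nothing fuzzier is
attempted, by design:

* two researchers printing the same name **merge** (homonyms);
* one researcher printing name variants ("Smith, John" vs "Smith, J")
  **splits**.

Both biases are inherent to name-based counting; the package measures and
reports them (the synthetic generator reproduces the homonym mechanism
exactly) rather than attempting probabilistic disambiguation, which would
trade a transparent bias for an opaque one. Accents are preserved
(`é` ≠ `e`) because stripping them would merge distinct names; case is
folded because letter case varies by cataloguing practice, not by person.
Whether upstream catalogues fold case themselves is unknowable from the
data, so folding is the conservative choice and is documented here.

Uniqueness is scoped **per calendar year**: the same person active in ten
years contributes one count to each of the ten years. A cumulative
variant (`census(cumulative = TRUE)`) is available but is not the
default, since per-year counts are what growth models and funding
comparisons need. Years with no records are gaps and are never
interpolated.

## Growth models

`fit_linear()` and `fit_exponential()` fit the two standard growth laws
by ordinary least squares:

* linear: `count ~ year`, slope in authors/year;
* exponential: `log(count) ~ year`; the natural log is used, and the
  reported `annual_growth_rate = exp(slope) - 1` makes the choice of base
  irrelevant to users.

Counts of zero or below are outside the log's domain and are **dropped**,
not offset-shifted — an arbitrary `+1` moves small-field fits materially,
and a dropped-point count is recorded instead. Each fit reports slope,
intercept (on the raw year scale; the computation centres years
internally for numerical stability), adjusted R², residual standard error
sigma, and the F statistic on (1, n − 2) degrees of freedom, satisfying
the usual identities `adj R² = 1 − (1 − R²)(n − 1)/(n − 2)` and
`F = R²/(1 − R²) · (n − 2)`; these identities are asserted exactly in the
test suite against a normal-equations oracle.

`compare_growth()` fits both models on the same positive-count year set
(so the adjusted R² values are comparable) and prefers the larger
adjusted R², breaking ties within 1e-9 toward the simpler linear model.
When both adjusted R² fall below 0.5 the comparison is annotated as
poorly fit — rise-then-fall fields (a pattern real fields such as
declining viral systems exhibit) are not described by either monotone
model, and the note says so instead of silently picking a winner.

On the packaged reference series (`fungal_field_data()`, six fungal
genera over 1985–2022) the exponential model outperforms the linear one
for every genus, consistent with near-universal exponential growth of
biomedical fields; the acceptance script recomputes these fits at run
time.

## Funding, inflation and burden

Funding series are nominal dollars per field-year. `adjust_funding()`
deflates with an annual-average all-urban-consumers CPI table supplied by
the user (`cpi_table()`); the base year defaults to the table's latest
year, so that year's adjusted and nominal amounts coincide. Because
published tables often print both nominal and adjusted amounts,
`derive_deflator()` recovers the implied year deflator from any such
pair; within a year this ratio is field-independent, a property the test
suite verifies on the packaged table to 1e-5 relative (observed agreement
is ~5e-9, i.e. printed-precision limited). The CPI itself is deliberately
an input rather than a bundled dataset — CPI vintages differ and the
right vintage belongs to the analysis, not the package.

`funding_per_author()` divides funding by the unique-author count on the
year intersection of the two series (zero-author years are skipped with a
warning). `correlate()` reports Pearson and Spearman coefficients
(average ranks on ties) on complete pairs and flags zero-variance inputs
as degenerate instead of returning `NaN`. `burden_vs_size()` inner-joins
a disease case-burden table with a census table on case-folded labels for
one year; Spearman is the headline statistic because case burdens span
orders of magnitude and only the ranking is comparable across diseases.

`merge_series(mode = "pooled")` supports combined regressions over a
category of fields (e.g. a WHO priority tier) by **stacking** the
(year, count) points of the member fields. Summing counts across fields
was rejected: authors publishing in two member fields would be counted
twice, so the pooled regression is fit to the stacked point cloud
instead.

## The synthetic corpus generator

`simulate_corpus()` exists so every stage can be validated against known
ground truth without any network access. It models:

* an active-author population following `growth_linear()` or
  `growth_exponential()`;
* yearly author turnover (default 0.3: 30% of each year's authors are
  new to the field, a figure in the range one expects from trainee
  throughput in a biomedical subfield);
* per-author productivity of `1 + Poisson(mean − 1)` paper-appearances a
  year (default mean 1.5; the floor of 1 makes every active author
  observable, so ground truth is exact rather than probabilistic);
* bylines of 1–8 authors (default mean ≈ 3.9, typical of experimental
  biomedicine), assembled by randomly partitioning the multiset of
  author-appearances;
* homonym collisions: with probability `name_collision_rate` (default
  0.02) a newly minted author reuses an existing name key. Collisions are
  modelled at name-mint time rather than by editing strings, so the
  name-to-author multiplicity map is exact and the census undercount is
  measurable, not estimated.

Names are assembled combinatorially from syllable fragments; they are
synthetic and denote no real person. Generation is deterministic given
(spec, seed), and `emit_medline()` serialises the corpus to MEDLINE text
so the parser and filter are exercised end to end; the round trip is
byte-lossless including diacritics.

What the generator does **not** emulate: multi-field authorship, citation
structure, secular drift in byline length, indexing-coverage growth, and
name-variant splitting (initials-only records). Passing recovery tests
therefore show the machinery is correct, not that real-world census
counts are unbiased — the homonym/variant biases discussed above still
apply to real data.

### Problem sizes and tolerances

The validation suite uses corpora of 5–30 years with initial populations
of 3–50 authors (up to roughly 10,000 records at the largest growth
rate), 50 randomised corpora for the census-versus-oracle identity, and
growth-rate recovery at rates 0.03, 0.08 and 0.15 over 30 years, where
the fitted log-linear slope recovers the generating rate to within 0.02
(observed errors are below 0.001; the 0.02 bound allows for the sampling
noise floor at small populations). Numerical comparisons against the
normal-equations oracle use a 1e-9 relative tolerance; rank statistics
are compared exactly against a pairwise-counting oracle.

## Design choices that were genuinely open

* **Date parsing.** Publication dates in the wild include ranges and
  seasons ("1998 Dec-1999 Jan", "2000 Spring"). The first 4-digit token
  is taken as the year — deterministic, and resolving ranges to their
  leading year matches common bibliometric practice.
* **Duplicate identifiers** within one input collapse to the first
  occurrence (exports repeat records across pages); the collapse count is
  reported.
* **Eligibility of `AU`-only authors.** Abbreviated entries lack a
  recorded first name; treating them as ineligible mirrors the filter's
  requirement of a full first and last name rather than inventing an
  expansion.
* **Retrieval contract.** Retrieval is a pluggable function; the package
  ships the file-based implementation (`file_fetcher()`), which keeps
  analyses reproducible against a fixed snapshot. A live E-utilities
  client can satisfy the same contract, but results then depend on the
  database snapshot, so snapshotting to files first is the recommended
  workflow. Year restriction is applied post hoc from parsed dates, not
  delegated to backend date fielding.
* **Query sensitivity is measured, not fixed.** `compare_queries()`
  reports identifier overlap (Jaccard) between the record sets two
  phrasings return; no synonym expansion or spelling correction is
  attempted, because phrasing sensitivity is itself a finding users need
  to see.

## Limitations

Name-based counting gives an upper-ceiling estimate of a field's
workforce: occasional authors, collaborators and service authorship all
add names, homonyms subtract distinct people and name variants add
phantom ones. Coverage of the underlying database grows over time, which
inflates late-series counts independently of field growth. None of these
is corrected; all are reported where measurable.

## A worked example

```{r example, eval = FALSE}
spec <- corpus_spec(1991:2020, growth_exponential(rate = 0.08, initial = 50))
sim <- simulate_corpus(spec, seed = 7)

corpus <- tempfile(fileext = ".nbib")
emit_medline(sim$records, corpus)

records <- read_medline(corpus) |> eligible_records()
size <- census(records, label = "simulated field")
fit <- compare_growth(size)
glance(fit)
autoplot(fit, size)
```
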