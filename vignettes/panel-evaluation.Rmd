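---
title: "Evaluating CPGx panels: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating CPGx panels: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgxeval)
```

## The problem and the model

Targeted-variant pharmacogenomic assays only see the variants on their
menu. Star alleles are haplotypes defined by sets of core variants; when
none of an allele's defining variants is targeted, the assay cannot
distinguish that allele from the reference and reports `*1` by default.
For a patient carrying an untargeted no-function allele this produces a
false-normal phenotype call. `cpgxeval` measures that risk at the
population level through two statistics:

* **Coverage percentage** — the targeted share of a gene's known-variant
  universe, `100 |T ∩ V| / |V|`. It says how much of the catalogue an
  assay looks at, not how much clinically relevant mass it captures.
* **Detection rate** — among individuals whose genotype-predicted
  phenotype is an *altered metabolizer* (a phenotype that, per the CPIC
  guideline for the gene, requires a therapy modification), the
  percentage whose diplotype is *detectable*, i.e. whose **both** alleles
  have all their defining variants targeted. One-sided coverage does not
  count: an assay that can call `*2` but not `*3` does not detect a
  `*2/*3` carrier.

The two disagree by design: a low-coverage assay targeting the few
high-frequency alleles can reach a high detection rate, because rare
variants carry little diplotype mass.

### Phenotype translation

Two rule kinds reproduce the CPIC-derived altered criteria
(`cpic_altered_rules()`):

* **Activity-score genes** (CYP2C9, CYP2D6). Each allele contributes
  `activity_value × copy_number`; the diplotype score is the sum. The
  normal window is a closed interval and altered status is *strict*
  exceedance — CYP2C9 altered below 2, CYP2D6 altered below 1.25 or above
  2.25, so scores exactly at a bound are never altered ("less than" /
  "greater than" taken literally). Copy-number alleles are parsed from
  the `xN` name suffix (N capped at 4, warning above 2).
* **Categorical genes** (CYP2B6, CYP2C19, CYP3A5). The diplotype is
  translated through the unordered pair of allele function classes via a
  lookup (`default_translation()`), with diplotype-specific override rows
  taking precedence; the altered rule is label membership. "Likely
  intermediate" and "likely poor" are distinct vocabulary entries, both
  altered for CYP2C19 — they are not collapsed into their unqualified
  labels. CYP3A5 uses expresser terminology: any functional allele makes
  an expresser (extensive or intermediate), and those — not the poor
  metabolizer — are the altered states, because expressers need
  tacrolimus dose increases.

Both paths coexist: a call carries a score whenever both alleles have
activity values and a label whenever a translation exists. For
activity-score genes the score is authoritative for classification;
labels are reporting-only. Alleles with `unknown` function are excluded
from classification with a warning (and thus from both the altered set
and the detectable mass); a flag reinterprets them as normal function
instead. Every diplotype is otherwise classified — there is no silent
third state.

## File formats and missing data

Readers and writers cover four dialects: gene-model TSV (with a
known-variant companion file), PharmGKB-layout frequency TSV (identifier
column plus one column per population), panel JSON, and rule JSON. Two
conventions matter:

* **Missing is never zero.** A blank frequency cell is missing data; a
  population whose column is entirely blank is flagged missing, excluded
  from every average, and reported `NA`. A compatibility flag renders
  missing populations as annotated zeros in the prevalence chart only.
* **Frequency sums.** Per population, haplotype frequencies may sum to
  less than 1 (curated tables omit rare alleles); sums above `1 + 1e-6`
  are rejected. The residual is *not* reassigned to `*1` — there is no
  principled reason to assume undocumented mass is reference — but
  `renormalize = TRUE` rescales before Hardy–Weinberg expansion, which
  otherwise requires sums within `1e-6` of 1.

Diplotype identifiers are canonicalized (lexicographically sorted pair,
`"*1/*2"`), so allele order never matters in lookups or files. Variant
identifiers are opaque strings compared exactly after trimming; no
rsID-to-coordinate resolution is attempted, because panel and allele
definitions both come from curated lists.

## The synthetic-data generator

Real inputs for this kind of study are archived snapshots of curated
databases. The generator (`sim_config()`, `simulate_gene_model()`,
`simulate_population_frequencies()`, `simulate_panels()`) emulates their
statistical shape so the whole pipeline is testable offline:

* a dominant reference allele — per population, the `*1` frequency is a
  Beta draw with mean `reference_mass` (default 0.6, pseudo-count 30),
  and the remaining mass is split over non-reference alleles by a
  symmetric Dirichlet with the configured `concentration` (default 1,
  giving strong population differentiation; the infinite-concentration
  limit collapses all populations onto one profile);
* nine populations by default, labelled with the PharmGKB
  biogeographical group abbreviations (AAAC, Amer, CSA, EA, Eur, Lat,
  NE, Oc, SSA);
* allele function classes drawn from a configurable mix (default 25%
  normal / 35% decreased / 30% no / 10% increased), activity values
  implied by class (1, 0.5 or 0.25, 0; increased-function alleles are
  realized as `x2` duplications), one to three defining variants per
  allele, and extra known variants so panels can sit below 100% coverage;
* panels hitting requested coverage targets to one variant's granularity,
  chosen uniformly without replacement.

Determinism is a contract: one seed in the config, threaded through
`withr::with_seed` with fixed per-stage offsets (model +0, frequencies
+1, panels +2), makes models, tables, panels and written bundles
byte-identical across runs. What the generator does **not** emulate:
linkage between variants, genotyping error, sampling noise of finite
cohorts, or the actual frequency values of any real gene — so passing
tests demonstrate the correctness of the arithmetic and the
classification logic on realistic *shapes*, not agreement with any
particular population's true frequencies.

## Verification strategy

The load-bearing check is an independent oracle:
`brute_force_detection()` enumerates every diplotype explicitly,
classifies, filters and sums with no code shared with the pipeline
(its own score arithmetic, lookup walk, rule application and
subset test), and refuses models above eight alleles. The test suite
asserts pipeline/oracle agreement within 1e-9 on every result field over
200 seeded random configurations, exact recovery of detection rates from
panels constructed to cover alleles carrying known shares of altered
mass, and monotonicity: growing a panel one variant at a time never
decreases coverage, never flips a diplotype from detectable to
undetectable, and never lowers a detection rate. Recommended-allele tiers
are evaluated as ordinary panels — same code path, property-tested by
aliasing a tier and an identically-targeted assay.

## Numerical and reporting choices

* Undefined cells (zero altered frequency) carry a status, not a NaN;
  they are excluded from averages rather than imputed to 0 or 100. The
  per-gene average denominator is the set of defined cells — whether to
  include tests with some undefined cells is genuinely open, and
  exclusion is this package's documented choice.
* Averages across tests are unweighted arithmetic means; written tables
  round percentages to one decimal (R's round-half-even), frequencies to
  six decimals, and round-trip losslessly at that precision.
* Heatmaps anchor the diverging blue–red scale at 0–100 rather than the
  data range, so panels are comparable across genes; `NA` cells are grey
  with an explicit label. The view layer only reformats matrix cells —
  it never recomputes.
* Detectability requires **all** of an allele's defining variants to be
  targeted (core-allele semantics); `match = "any"` is available for
  sensitivity analysis. Because the reference allele is detectable by
  definition, detection rates are flattered exactly where default-`*1`
  calling masks false negatives — the `default_call_frac` column
  surfaces how much of each detected mass relies on that default.
* Ranking "best tests" rounds to reporting precision first and breaks
  ties lexicographically, reporting the tie.

## Problem sizes

The shipped property suites use models of 2–6 alleles (the oracle's
exhaustive enumeration stays trivial there), up to nine populations, and
up to five panels per configuration; the analysis workflow simulates five
genes of 3–7 alleles. These sizes exercise every code path, including
degenerate ones (single-allele tables, zero altered mass, missing
populations), while keeping the whole suite's runtime in minutes.

## Limitations

Classification fidelity is bounded by the rule and translation inputs:
the shipped ruleset encodes the altered criteria for five CYP genes only,
and the default function-pair translation is a generic CPIC-style
mapping, not a per-gene curated table (overrides exist for that purpose).
Hardy–Weinberg expansion ignores inbreeding and population structure
below the group level. Coverage percentages depend entirely on the
supplied known-variant universe; two sources listing different universes
give different coverage for the same assay. And detection rate measures
genotype-level callability, not analytical accuracy — a targeted variant
is assumed to be called correctly.
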