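# cpgxeval

Combinatorial pharmacogenomic (CPGx) assays genotype a fixed menu of
targeted variants across several pharmacogenes at once, and report any
allele whose variants they do not target as the reference `*1` by default.
How much of a population's clinically relevant variation such a test
actually sees therefore depends on which star-allele defining variants it
targets — and star-allele frequencies differ sharply between
biogeographical groups. `cpgxeval` quantifies this for cytochrome P450
genes: it translates diplotypes to genotype-predicted phenotypes,
classifies *altered metabolizers* (phenotypes that would trigger a CPIC
guideline change of drug or dose), and computes per-test, per-gene,
per-population **coverage percentages** and **detection rates**. It is
aimed at pharmacogenomics implementers comparing assay menus, and at
anyone auditing recommended-allele sets (e.g. AMP tier recommendations)
against population diversity.

## The statistics

For a gene with known-variant universe *V* (the variants listed in a
PharmGKB-style frequency table) and a test targeting the subset *T*:

```
coverage % = 100 * |T ∩ V| / |V|
```

A diplotype *a/b* is **detectable** when the test can call both alleles:
every defining core variant of *a* and of *b* is targeted (the reference
allele, with no defining variants, is always callable by default). With
*A* the set of diplotypes classified altered and *f_p* the diplotype
frequencies in population *p*:

```
population altered frequency  = Σ_{d ∈ A} f_p(d)
detectable altered frequency  = Σ_{d ∈ A, d detectable} f_p(d)
detection rate % = 100 * detectable altered / population altered
```

The rate is undefined (reported `NA`, excluded from averages) when the
population altered frequency is zero. Altered status comes from per-gene
rules: categorical phenotype sets (CYP2B6, CYP2C19, CYP3A5) or strict
activity-score windows (CYP2C9 altered below 2; CYP2D6 altered outside
the closed window [1.25, 2.25]), shipped as
`cpic_altered_rules()`. Diplotype frequencies can be given directly or
expanded from haplotype frequencies under Hardy–Weinberg equilibrium
(`hwe_expand()`).

## Worked example

A three-allele gene: `*1` (activity 1, frequency 0.5), `*2` and `*3`
(activity 0, frequencies 0.3 and 0.2), altered = activity score below 2,
and a test targeting only `*2`'s defining variant:

```r
library(cpgxeval)
model <- gene_model("TOYCYP", tibble::tibble(
  allele = c("*1", "*2", "*3"),
  defining_variants = c("", "rs000002", "rs000003"),
  activity_value = c(1, 0, 0)))
haps <- freq_table("TOYCYP", tibble::tibble(
  identifier = c("*1", "*2", "*3"), POP1 = c(0.5, 0.3, 0.2)))
rules <- phenotype_ruleset(TOYCYP = rule_activity_interval(2))
panel <- test_panel("toy_star2_only", list(TOYCYP = "rs000002"))
evaluate_panels(list(panel), list(TOYCYP = model), list(TOYCYP = haps), rules)
#>   test           gene  population status coverage_pct population_altered_freq
#>   toy_star2_only TOYCYP POP1      ok               50                    0.75
#>   detectable_altered_freq detection_rate_pct default_call_frac
#>                      0.39                 52             0.769
```

Reading the row: under HWE every diplotype except `*1/*1` scores below 2,
so 75% of the population are altered metabolizers; of that mass only
`*1/*2` (0.30) and `*2/*2` (0.09) have both alleles callable, so the test
detects 0.39/0.75 = **52%** of altered metabolizers while targeting 50%
of known variants. The `default_call_frac` column flags how much of the
detected mass leaned on the default-`*1` call. The same cell is confirmed
by an independent brute-force enumerator, `brute_force_detection()`.

## Analysis workflow

The `analysis/` scripts run a complete synthetic study (no downloads):

```sh
Rscript analysis/01_simulate_inputs.R     # 5 genes, 9 populations, 16 panels
Rscript analysis/02_altered_prevalence.R  # prevalence table + bar chart
Rscript analysis/03_detection_rates.R     # detection matrix + summaries
Rscript analysis/04_heatmaps.R            # per-gene heatmaps with coverage bars
```

Outputs land under `results/`. The schemas accept curated PharmGKB-style
tables and GTR-derived panel lists verbatim, so the same workflow runs on
real inputs; `run_pipeline()` does all steps from file paths in one call.

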