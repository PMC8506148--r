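# Shared in-code fixtures: the three-allele worked example and small builders.

toy_model <- function() {
  gene_model("TOYCYP", tibble::tibble(
    allele = c("*1", "*2", "*3"),
    defining_variants = c("", "rs000002", "rs000003"),
    activity_value = c(1, 0, 0),
    function_class = c("normal", "no", "no")
  ))
}

toy_haps <- function(pop = "POP1") {
  df <- tibble::tibble(identifier = c("*1", "*2", "*3"))
  df[[pop]] <- c(0.5, 0.3, 0.2)
  freq_table("TOYCYP", df, level = "haplotype")
}

toy_rules <- function() {
  phenotype_ruleset(TOYCYP = rule_activity_interval(2))
}

toy_panel_star2 <- function() {
  test_panel("toy_star2_only", list(TOYCYP = "rs000002"))
}

# CYP-like categorical fixture: CYP2C19-flavoured allele set.
c19_model <- function() {
  gene_model("CYP2C19", tibble::tibble(
    allele = c("*1", "*2", "*17"),
    defining_variants = c("", "rs4244285", "rs12248560"),
    activity_value = c(NA, NA, NA),
    function_class = c("normal", "no", "increased")
  ))
}

# CYP3A5 expresser fixture: *1 functional, *3 non-functional.
c3a5_model <- function() {
  gene_model("CYP3A5", tibble::tibble(
    allele = c("*1", "*3"),
    defining_variants = c("", "rs776746"),
    activity_value = c(NA, NA),
    function_class = c("normal", "no")
  ))
}

# Random evaluation case under a fixed seed: simulated model, frequencies,
# panels, and a score rule whose normal point is the reference homozygote.
random_case <- function(seed, max_alleles = 6, max_pops = 9, n_panels = 3) {
  withr::with_seed(seed * 1000L, {
    cfg <- sim_config(
      seed = seed,
      n_alleles = sample(2:max_alleles, 1),
      n_populations = sample(1:max_pops, 1),
      reference_mass = runif(1, 0.3, 0.9),
      concentration = runif(1, 0.5, 3),
      copy_number_prob = runif(1, 0, 0.3)
    )
    targets <- sort(runif(n_panels, 0, 100))
  })
  model <- simulate_gene_model(cfg)
  haps <- simulate_population_frequencies(model, cfg)
  panels <- simulate_panels(model, targets, cfg)
  names(panels) <- vapply(panels, function(p) p$test_name, character(1))
  panels <- panels[!duplicated(names(panels))]
  rules <- phenotype_ruleset(stats::setNames(
    list(rule_activity_interval(2)), model$gene))
  list(config = cfg, model = model, haps = haps, panels = panels,
       rules = rules)
}

expect_result_rows_equal <- function(actual, expected, tol = 1e-9) {
  for (col in c("coverage_pct", "population_altered_freq",
                "detectable_altered_freq", "detection_rate_pct")) {
    a <- actual[[col]]; e <- expected[[col]]
    expect_equal(is.na(a), is.na(e), info = col)
    if (!is.na(a)) expect_equal(a, e, tolerance = tol, info = col)
  }
  expect_identical(actual$status, expected$status)
}
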