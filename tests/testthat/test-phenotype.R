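test_that("activity scores sum allele activity times copy number, symmetric", {
  c9 <- gene_model("CYP2C9", tibble::tibble(
    allele = c("*1", "*3"), defining_variants = c("", "rs1057910"),
    activity_value = c(1, 0)))
  expect_equal(diplotype_activity_score("*1/*3", c9), 1)
  expect_equal(diplotype_activity_score("*3/*1", c9), 1)
  expect_equal(diplotype_activity_score("*1/*1", c9), 2)

  d6 <- gene_model("CYP2D6", tibble::tibble(
    allele = c("*1", "*1x2", "*4"),
    defining_variants = c("", "", "rs3892097"),
    activity_value = c(1, 1, 0)))
  expect_equal(diplotype_activity_score("*1x2/*4", d6), 2)
  expect_equal(diplotype_activity_score("*4/*1x2", d6), 2)

  expect_error(
    diplotype_activity_score("*1/*2", gene_model("G", tibble::tibble(
      allele = c("*1", "*2"), defining_variants = c("", "rsA"),
      activity_value = c(1, NA), function_class = c("normal", "no")))),
    class = "cpgx_unscorable")
})

test_that("diplotypes translate to phenotype labels through the lookup", {
  lk <- default_translation()
  call <- assign_phenotype("*1/*17", c19_model(), lk)
  expect_equal(call$phenotype_label, "rapid")
  expect_equal(assign_phenotype("*17/*17", c19_model(), lk)$phenotype_label,
               "ultrarapid")
  expect_equal(assign_phenotype("*1/*2", c19_model(), lk)$phenotype_label,
               "intermediate")

  expect_equal(assign_phenotype("*3/*3", c3a5_model(), lk)$phenotype_label,
               "poor")
  expect_equal(assign_phenotype("*1/*1", c3a5_model(), lk)$phenotype_label,
               "extensive")
  expect_equal(assign_phenotype("*1/*3", c3a5_model(), lk)$phenotype_label,
               "intermediate")

  # diplotype-specific overrides beat the function-pair rows
  lk_ov <- translation_lookup(
    lk$pairs,
    tibble::tibble(gene = "CYP2C19", diplotype = "*1/*17", label = "normal"))
  expect_equal(assign_phenotype("*17/*1", c19_model(), lk_ov)$phenotype_label,
               "normal")

  # unknown-function pair with no lookup entry and no score: untranslatable
  mu <- gene_model("G", tibble::tibble(
    allele = c("*1", "*9"), defining_variants = c("", "rsU"),
    function_class = c("normal", "unknown")))
  expect_error(assign_phenotype("*1/*9", mu, lk),
               class = "cpgx_untranslatable")
})

test_that("interval rules are strictly exceeded at both bounds", {
  rules <- cpic_altered_rules()
  score_call <- function(s) list(diplotype = "x", activity_score = s,
                                 phenotype_label = NA_character_)
  # CYP2D6 normal window is the closed [1.25, 2.25]
  expect_true(classify_altered(score_call(1.0), rules, "CYP2D6"))
  expect_false(classify_altered(score_call(1.25), rules, "CYP2D6"))
  expect_false(classify_altered(score_call(2.0), rules, "CYP2D6"))
  expect_false(classify_altered(score_call(2.25), rules, "CYP2D6"))
  expect_true(classify_altered(score_call(2.5), rules, "CYP2D6"))
  # CYP2C9: altered strictly below 2
  expect_false(classify_altered(score_call(2.0), rules, "CYP2C9"))
  expect_true(classify_altered(score_call(1.0), rules, "CYP2C9"))

  label_call <- function(l) list(diplotype = "x", activity_score = NA_real_,
                                 phenotype_label = l)
  expect_true(classify_altered(label_call("intermediate"), rules, "CYP2B6"))
  expect_false(classify_altered(label_call("normal"), rules, "CYP2B6"))
  expect_true(classify_altered(label_call("likely poor"), rules, "CYP2C19"))

  # rule/call mismatches are named errors
  expect_error(classify_altered(label_call("poor"), rules, "CYP2C9"),
               class = "cpgx_rule_mismatch")
  expect_error(classify_altered(score_call(1), rules, "CYP2B6"),
               class = "cpgx_rule_mismatch")
  expect_error(classify_altered(score_call(1), rules, "CYP9Z9"),
               class = "cpgx_missing_rule")
})

test_that("altered diplotype set matches exhaustive enumeration on the toy model", {
  dips <- hwe_expand(toy_haps())
  alt <- altered_diplotype_set(dips, toy_model(), toy_rules())
  expect_setequal(alt, c("*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3"))

  # nothing altered when every diplotype sits exactly on the normal point
  mn <- gene_model("G", tibble::tibble(
    allele = c("*1", "*2"), defining_variants = c("", "rsA"),
    activity_value = c(1, 1)))
  tn <- freq_table("G", tibble::tibble(identifier = c("*1", "*2"),
                                       P1 = c(0.5, 0.5)))
  rn <- phenotype_ruleset(G = rule_activity_interval(2, 2))
  expect_length(altered_diplotype_set(hwe_expand(tn), mn, rn), 0)

  # CYP3A5 expressers: every *1-carrying diplotype is altered
  t35 <- freq_table("CYP3A5", tibble::tibble(
    identifier = c("*1", "*3"), P1 = c(0.3, 0.7)))
  alt35 <- altered_diplotype_set(hwe_expand(t35), c3a5_model(),
                                 cpic_altered_rules(), default_translation())
  expect_setequal(alt35, c("*1/*1", "*1/*3"))
})

test_that("classification is exhaustive and unknown-function alleles are excluded with warning", {
  mu <- gene_model("G", tibble::tibble(
    allele = c("*1", "*2", "*9"),
    defining_variants = c("", "rsA", "rsU"),
    activity_value = c(1, 0, NA),
    function_class = c("normal", "no", "unknown")))
  tu <- freq_table("G", tibble::tibble(
    identifier = c("*1", "*2", "*9"), P1 = c(0.8, 0.1, 0.1)))
  dips <- hwe_expand(tu)
  expect_warning(
    alt <- altered_diplotype_set(dips, mu, phenotype_ruleset(
      G = rule_activity_interval(2))),
    "unknown function")
  # every diplotype is either classified or explicitly excluded
  excluded <- grep("\\*9", dips$data$identifier, value = TRUE)
  expect_setequal(c(alt, setdiff(dips$data$identifier, alt)),
                  dips$data$identifier)
  expect_length(intersect(alt, excluded), 0)
  expect_setequal(alt, c("*1/*2", "*2/*2"))

  # treating unknown as normal reinstates those diplotypes
  mu2 <- mu
  alt2 <- suppressWarnings(altered_diplotype_set(
    dips, mu2, phenotype_ruleset(G = rule_activity_interval(2)),
    lookup = default_translation(), unknown_function = "normal"))
  expect_true("*2/*9" %in% alt2)
})

test_that("classification is symmetric and monotone under rule widening", {
  for (s in 1:10) {
    case <- random_case(s, max_alleles = 5, max_pops = 2, n_panels = 1)
    dips <- hwe_expand(case$haps)
    # symmetry: swapping allele order never changes the call
    for (id in dips$data$identifier) {
      parts <- diplotype_alleles(id)
      expect_equal(diplotype_activity_score(paste(parts[1], parts[2], sep = "/"),
                                            case$model),
                   diplotype_activity_score(paste(parts[2], parts[1], sep = "/"),
                                            case$model))
    }
    # narrowing the normal interval never shrinks the altered set
    g <- case$model$gene
    wide <- phenotype_ruleset(stats::setNames(
      list(rule_activity_interval(1.5, 2.5)), g))
    narrow <- phenotype_ruleset(stats::setNames(
      list(rule_activity_interval(1.9, 2.1)), g))
    a_wide <- altered_diplotype_set(dips, case$model, wide)
    a_narrow <- altered_diplotype_set(dips, case$model, narrow)
    expect_true(all(a_wide %in% a_narrow))
  }
  # enlarging categorical altered sets never shrinks the set either
  t35 <- freq_table("CYP3A5", tibble::tibble(
    identifier = c("*1", "*3"), P1 = c(0.3, 0.7)))
  small <- phenotype_ruleset(CYP3A5 = rule_categorical("extensive"))
  big <- phenotype_ruleset(CYP3A5 = rule_categorical(
    c("extensive", "intermediate")))
  a_small <- altered_diplotype_set(hwe_expand(t35), c3a5_model(), small,
                                   default_translation())
  a_big <- altered_diplotype_set(hwe_expand(t35), c3a5_model(), big,
                                 default_translation())
  expect_true(all(a_small %in% a_big))
})
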