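test_that("HWE expansion reproduces hand-computed diplotype frequencies", {
  dips <- hwe_expand(toy_haps())
  f <- stats::setNames(dips$data$POP1, dips$data$identifier)
  expect_equal(f[["*1/*1"]], 0.25)
  expect_equal(f[["*1/*2"]], 0.30)
  expect_equal(f[["*1/*3"]], 0.20)
  expect_equal(f[["*2/*2"]], 0.09)
  expect_equal(f[["*2/*3"]], 0.12)
  expect_equal(f[["*3/*3"]], 0.04)
  expect_equal(sum(f), 1, tolerance = 1e-9)

  # degenerate single allele
  one <- freq_table("G", tibble::tibble(identifier = "*1", P1 = 1))
  d1 <- hwe_expand(one)
  expect_equal(d1$data$identifier, "*1/*1")
  expect_equal(d1$data$P1, 1)

  # output mass is conserved for any valid input (binomial identity)
  for (s in 1:10) {
    case <- random_case(s, max_alleles = 6, max_pops = 3, n_panels = 1)
    d <- hwe_expand(case$haps)
    for (p in d$populations) expect_equal(sum(d$data[[p]]), 1, tolerance = 1e-9)
  }

  # off-unit sums error unless renormalization is requested
  off <- freq_table("G", tibble::tibble(
    identifier = c("*1", "*2"), P1 = c(0.5, 0.3)))
  expect_error(hwe_expand(off), class = "cpgx_validation_error")
  d_rn <- hwe_expand(off, renormalize = TRUE)
  expect_equal(sum(d_rn$data$P1), 1, tolerance = 1e-9)

  # missing populations stay missing, never silently zero
  part <- freq_table("G", tibble::tibble(
    identifier = c("*1", "*2"), P1 = c(0.6, 0.4), P2 = c(NA_real_, NA_real_)))
  expect_equal(missing_populations(hwe_expand(part)), "P2")
})

test_that("coverage percentage is the targeted share of known variants", {
  # 14 of 61 known variants, the CYP2C9-scale case
  known <- sprintf("rs%03d", 1:61)
  m61 <- gene_model("CYP2C9", tibble::tibble(
    allele = c("*1", "*2"), defining_variants = c("", "rs001"),
    activity_value = c(1, 0)), known_variants = known)
  expect_length(m61$known_variants, 61L)
  p14 <- test_panel("p14", list(CYP2C9 = known[1:14]))
  expect_equal(coverage_percentage(p14, "CYP2C9", m61), 100 * 14 / 61)
  expect_equal(round(coverage_percentage(p14, "CYP2C9", m61), 2), 22.95)

  full <- test_panel("full", list(CYP2C9 = known))
  expect_equal(coverage_percentage(full, "CYP2C9", m61), 100)
  none <- test_panel("none", list(CYP2C9 = "rs_not_known"))
  expect_equal(coverage_percentage(none, "CYP2C9", m61), 0)
})

test_that("detectability needs both alleles' defining variants targeted", {
  m <- toy_model()
  p2 <- toy_panel_star2()
  expect_true(is_detectable("*1/*2", p2, m))   # *1 by default, *2 targeted
  expect_false(is_detectable("*1/*3", p2, m))  # *3 untargeted
  expect_false(is_detectable("*2/*3", p2, m))  # one-sided coverage insufficient
  expect_true(is_detectable("*1/*1", p2, m))

  # all-variants semantics vs relaxed any-variant mode
  m2 <- gene_model("G", tibble::tibble(
    allele = c("*1", "*2"), defining_variants = c("", "rsA;rsB"),
    activity_value = c(1, 0)))
  p_half <- test_panel("half", list(G = "rsA"))
  expect_false(is_detectable("*1/*2", p_half, m2))
  expect_true(is_detectable("*1/*2", p_half, m2, match = "any"))

  expect_error(is_detectable("*1/*9", p2, m), class = "cpgx_unknown_allele")
})

test_that("population altered frequency and detection rate match the worked example", {
  dips <- hwe_expand(toy_haps())
  alt <- altered_diplotype_set(dips, toy_model(), toy_rules())
  expect_equal(population_altered_frequency(dips, alt, "POP1"), 0.75)
  expect_equal(population_altered_frequency(dips, character(), "POP1"), 0)
  expect_equal(population_altered_frequency(dips, dips$data$identifier, "POP1"),
               1, tolerance = 1e-9)

  expect_equal(detection_rate(dips, alt, toy_panel_star2(), toy_model(), "POP1"),
               52.0)
  full <- test_panel("full", list(TOYCYP = c("rs000002", "rs000003")))
  expect_equal(detection_rate(dips, alt, full, toy_model(), "POP1"), 100)
  none <- test_panel("none", list(TOYCYP = "rs_extra"))
  expect_equal(detection_rate(dips, alt, none, toy_model(), "POP1"), 0)

  # zero altered mass: undefined, not zero
  zero <- hwe_expand(freq_table("TOYCYP", tibble::tibble(
    identifier = c("*1", "*2", "*3"), P1 = c(1, 0, 0))))
  expect_true(is.na(detection_rate(zero, alt, full, toy_model(), "P1")))
})

test_that("evaluate_panels crosses tests, genes, populations and marks non-cells", {
  m <- toy_model()
  h2 <- freq_table("TOYCYP", tibble::tibble(
    identifier = c("*1", "*2", "*3"),
    POPA = c(0.5, 0.3, 0.2), POPB = c(0.8, 0.1, 0.1),
    POPC = rep(NA_real_, 3)))
  other <- gene_model("OTHER", tibble::tibble(
    allele = c("*1", "*2"), defining_variants = c("", "rsO"),
    activity_value = c(1, 0)))
  ho <- freq_table("OTHER", tibble::tibble(
    identifier = c("*1", "*2"), POPA = c(0.9, 0.1), POPB = c(0.7, 0.3),
    POPC = rep(NA_real_, 2)))
  rules <- phenotype_ruleset(TOYCYP = rule_activity_interval(2),
                             OTHER = rule_activity_interval(2))
  both <- test_panel("both", list(TOYCYP = "rs000002", OTHER = "rsO"))
  toy_only <- test_panel("toy_only", list(TOYCYP = "rs000002"))
  mx <- evaluate_panels(list(both, toy_only),
                        list(TOYCYP = m, OTHER = other),
                        list(TOYCYP = h2, OTHER = ho), rules)
  expect_equal(nrow(mx), 2L * 2L * 3L)
  na_rows <- mx[mx$test == "toy_only" & mx$gene == "OTHER", ]
  expect_true(all(na_rows$status == "not_applicable"))
  expect_true(all(is.na(na_rows$detection_rate_pct)))
  miss <- mx[mx$population == "POPC" & mx$status != "not_applicable", ]
  expect_true(all(miss$status == "missing_population"))
  ok <- mx[mx$test == "both" & mx$gene == "TOYCYP" & mx$population == "POPA", ]
  expect_equal(ok$detection_rate_pct, 52.0)
  # invariant: detectable <= population altered, rates within [0, 100]
  okr <- mx[mx$status == "ok", ]
  expect_true(all(okr$detectable_altered_freq <=
                    okr$population_altered_freq + 1e-12))
  expect_true(all(okr$detection_rate_pct >= 0 & okr$detection_rate_pct <= 100))
})

test_that("tier allele sets run through the identical panel code path", {
  # an AMP-style tier expressed as a panel equals the same targets as a test
  m <- toy_model()
  tier1 <- test_panel("AMP_Tier1", list(TOYCYP = "rs000002"))
  assay <- test_panel("assayX", list(TOYCYP = "rs000002"))
  mx <- evaluate_panels(list(tier1, assay), list(TOYCYP = m),
                        list(TOYCYP = toy_haps()), toy_rules())
  t1 <- mx[mx$test == "AMP_Tier1", ]
  ax <- mx[mx$test == "assayX", ]
  expect_equal(t1$detection_rate_pct, ax$detection_rate_pct)
  expect_equal(t1$coverage_pct, ax$coverage_pct)
})

test_that("summaries exclude undefined cells and report ranges", {
  mx <- tibble::tibble(
    test = c("a", "b", "c"), gene = "G", population = "P",
    status = c("ok", "ok", "undefined"),
    coverage_pct = c(10, 20, 30),
    population_altered_freq = c(0.5, 0.5, 0),
    detectable_altered_freq = c(0.2, 0.3, 0),
    detection_rate_pct = c(40, 60, NA),
    default_call_frac = NA_real_)
  class(mx) <- c("detection_matrix", class(mx))
  s <- summarize_detection(mx, by = c("gene", "population"))
  expect_equal(s$mean_detection_rate, 50)
  expect_equal(s$min_detection_rate, 40)
  expect_equal(s$max_detection_rate, 60)
  expect_equal(s$n_defined, 2L)
  expect_equal(s$n_undefined, 1L)

  # all-100 group: mean 100, range 100-100
  mx2 <- dplyr::mutate(mx, detection_rate_pct = c(100, 100, NA))
  s2 <- summarize_detection(mx2, by = "gene")
  expect_equal(s2$mean_detection_rate, 100)
  expect_equal(s2$min_detection_rate, 100)
  expect_equal(s2$max_detection_rate, 100)

  # singleton mean is the identity
  s3 <- summarize_detection(mx[1, ], by = "test")
  expect_equal(s3$mean_detection_rate, 40)

  # all-undefined group: NA mean with counts, not an error
  s4 <- summarize_detection(mx[3, ], by = "test")
  expect_true(is.na(s4$mean_detection_rate))
  expect_equal(s4$n_undefined, 1L)
})

test_that("ranking breaks ties lexicographically and reports them", {
  mx <- tibble::tibble(
    test = c("zeta", "alpha", "mid"), gene = "G", population = "P",
    status = "ok", coverage_pct = 50,
    population_altered_freq = 0.5, detectable_altered_freq = 0.25,
    detection_rate_pct = c(80, 80, 40), default_call_frac = NA_real_)
  class(mx) <- c("detection_matrix", class(mx))
  r <- top_tests(mx)
  expect_equal(r$best_test, "alpha")
  expect_equal(r$tied, "alpha;zeta")
})

test_that("growing a panel never decreases coverage or detection rate", {
  for (s in 1:12) {
    case <- random_case(s, max_alleles = 6, max_pops = 3, n_panels = 1)
    model <- case$model
    dips <- hwe_expand(case$haps)
    alt <- altered_diplotype_set(dips, model, case$rules)
    known <- model$known_variants
    order_v <- withr::with_seed(s, sample(known))
    prev_cov <- -1
    prev_rate <- stats::setNames(rep(-1, length(dips$populations)),
                                 dips$populations)
    prev_det <- stats::setNames(rep(FALSE, 0), character())
    for (k in seq_along(order_v)) {
      pan <- test_panel("grow", stats::setNames(list(order_v[1:k]), model$gene))
      cov <- coverage_percentage(pan, model$gene, model)
      expect_gte(cov, prev_cov)
      prev_cov <- cov
      det_now <- vapply(dips$data$identifier, is_detectable, logical(1),
                        panel = pan, model = model)
      # detectability never flips true -> false as the panel grows
      if (length(prev_det)) expect_true(all(det_now[names(prev_det)] >= prev_det))
      prev_det <- det_now
      for (pop in dips$populations) {
        r <- detection_rate(dips, alt, pan, model, pop)
        if (!is.na(r)) {
          expect_true(r >= -1e-9 && r <= 100 + 1e-9)
          expect_gte(r, prev_rate[[pop]] - 1e-9)
          prev_rate[[pop]] <- r
        }
      }
    }
  }
})
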