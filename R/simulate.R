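#' Simulation configuration
#'
#' Parameters of the synthetic-data generator, which emulates the
#' statistical shape of curated pharmacogene inputs: a dominant reference
#' allele, skewed and population-differentiated non-reference frequencies,
#' allele function annotations including copy-number alleles, and a
#' known-variant universe larger than any panel targets.
#'
#' Defaults mirror the study conditions the package models: nine
#' biogeographical populations, a reference-allele mass of 0.6 (altered
#' prevalences in real CYP tables span roughly 10-90%, which this
#' reproduces across rule choices), and a unit Dirichlet concentration
#' giving strong between-population differentiation.
#'
#' @param seed Integer seed; identical seed and config give identical
#'   outputs. Component stages use fixed offsets of the seed (model `+0`,
#'   frequencies `+1`, panels `+2`) so each is independently reproducible.
#' @param n_alleles Total allele count including the reference (>= 2).
#' @param n_populations Number of populations (labels follow the nine
#'   PharmGKB biogeographical groups, recycled with suffixes beyond nine).
#' @param reference_mass Expected reference-allele frequency, in (0, 1).
#' @param concentration Symmetric Dirichlet concentration for non-reference
#'   frequencies; larger values pull populations toward a shared profile.
#' @param function_mix Named probabilities over function classes
#'   `normal`, `decreased`, `no`, `increased` for non-reference alleles.
#' @param variants_per_allele Length-2 integer range of defining variants
#'   per non-reference allele.
#' @param copy_number_prob Probability a non-reference allele is emitted as
#'   a copy-number (`x2`) duplication.
#' @param n_extra_variants Known variants beyond those defining alleles
#'   (so simulated panels can have coverage below 100% without missing
#'   allele-defining variants).
#' @param gene Gene symbol for the simulated model.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_alleles = 6L, n_populations = 9L,
                       reference_mass = 0.6, concentration = 1,
                       function_mix = c(normal = 0.25, decreased = 0.35,
                                        no = 0.3, increased = 0.1),
                       variants_per_allele = c(1L, 3L),
                       copy_number_prob = 0.1,
                       n_extra_variants = 3L,
                       gene = "CYPSIM1") {
  seed <- as.integer(seed)
  n_alleles <- as.integer(n_alleles)
  n_populations <- as.integer(n_populations)
  if (n_alleles < 2L) cpgx_abort("n_alleles must be >= 2", "cpgx_config_error")
  if (n_populations < 1L) cpgx_abort("n_populations must be >= 1", "cpgx_config_error")
  if (!(reference_mass > 0 && reference_mass < 1)) {
    cpgx_abort("reference_mass must be in (0, 1)", "cpgx_config_error")
  }
  if (concentration <= 0) cpgx_abort("concentration must be positive", "cpgx_config_error")
  fm_names <- c("normal", "decreased", "no", "increased")
  if (!all(names(function_mix) %in% fm_names) || any(function_mix < 0) ||
      sum(function_mix) <= 0) {
    cpgx_abort("function_mix must be non-negative weights over normal/decreased/no/increased",
               "cpgx_config_error")
  }
  function_mix <- function_mix / sum(function_mix)
  variants_per_allele <- as.integer(variants_per_allele)
  if (length(variants_per_allele) != 2L || variants_per_allele[1] < 1L ||
      variants_per_allele[1] > variants_per_allele[2]) {
    cpgx_abort("variants_per_allele must be an increasing range of positive integers",
               "cpgx_config_error")
  }
  if (copy_number_prob < 0 || copy_number_prob > 1) {
    cpgx_abort("copy_number_prob must be in [0, 1]", "cpgx_config_error")
  }
  structure(list(
    seed = seed, n_alleles = n_alleles, n_populations = n_populations,
    reference_mass = reference_mass, concentration = concentration,
    function_mix = function_mix, variants_per_allele = variants_per_allele,
    copy_number_prob = copy_number_prob,
    n_extra_variants = as.integer(n_extra_variants), gene = gene
  ), class = "sim_config")
}

sim_population_labels <- function(n) {
  base <- PGKB_POPULATIONS
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- paste0("Pop", seq_len(n - length(base)))
  c(base, extra)
}

#' Simulate a star-allele gene model
#'
#' Builds a reference allele `*1` (empty defining set, normal function,
#' activity 1) plus `n_alleles - 1` non-reference alleles. Each draws a
#' function class from `function_mix`, with activity values fixed by class
#' (normal 1, decreased 0.5 or 0.25, no 0, increased 1 on a duplicated
#' allele), between one and `variants_per_allele[2]` distinct defining
#' variants, and possibly an `x2` copy-number suffix. The known-variant
#' universe is the union of defining variants plus `n_extra_variants`
#' undefined extras.
#'
#' @param config A [sim_config()].
#' @return A [gene_model()], identical across runs for a fixed config.
#' @export
simulate_gene_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_non_ref <- config$n_alleles - 1L
    classes <- sample(names(config$function_mix), n_non_ref, replace = TRUE,
                      prob = config$function_mix)
    activity <- vapply(classes, function(cl) switch(
      cl,
      normal = 1, decreased = sample(c(0.5, 0.25), 1), no = 0, increased = 1
    ), numeric(1))
    cn <- 1L + stats::rbinom(n_non_ref, 1L,
                             ifelse(classes == "increased", 1,
                                    config$copy_number_prob))
    nv <- sample(seq(config$variants_per_allele[1],
                     config$variants_per_allele[2]),
                 n_non_ref, replace = TRUE)
    rs_pool <- sprintf("rs%06d", sample.int(999999L, sum(nv) + config$n_extra_variants))
    offsets <- cumsum(c(0L, nv))
    defs <- lapply(seq_len(n_non_ref), function(k) {
      rs_pool[(offsets[k] + 1L):offsets[k + 1L]]
    })
    allele_names <- paste0("*", seq_len(n_non_ref) + 1L,
                           ifelse(cn > 1L, paste0("x", cn), ""))
    alleles <- tibble::tibble(
      allele = c("*1", allele_names),
      defining_variants = c(list(character()), defs),
      activity_value = c(1, unname(activity)),
      function_class = c("normal", classes),
      copy_number = c(1L, cn)
    )
    known <- rs_pool  # defining variants plus the extras
    gene_model(config$gene, alleles, known_variants = known)
  })
}

#' Simulate per-population star-allele frequencies
#'
#' Per population, the reference-allele frequency is drawn from a Beta
#' distribution with mean `reference_mass` (moderate jitter), and the
#' remaining mass is split over non-reference alleles by a symmetric
#' Dirichlet draw with the configured concentration — large concentrations
#' make populations converge to a shared profile, small ones differentiate
#' them. Frequencies sum to exactly 1 per population.
#'
#' @param model A [gene_model()], typically from [simulate_gene_model()].
#' @param config A [sim_config()].
#' @return A haplotype-level [freq_table()].
#' @export
simulate_population_frequencies <- function(model, config) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    alleles <- model$alleles$allele
    ref <- reference_alleles(model)
    if (!length(ref)) cpgx_abort("model has no reference allele", "cpgx_config_error")
    non_ref <- setdiff(alleles, ref[1])
    pops <- sim_population_labels(config$n_populations)
    out <- tibble::tibble(identifier = c(ref[1], non_ref))
    kappa <- 30  # Beta pseudo-count controlling reference-mass jitter
    for (pop in pops) {
      p_ref <- stats::rbeta(1, config$reference_mass * kappa,
                            (1 - config$reference_mass) * kappa)
      w <- stats::rgamma(length(non_ref), shape = config$concentration, rate = 1)
      p_non <- (1 - p_ref) * w / sum(w)
      out[[pop]] <- c(p_ref, p_non)
    }
    freq_table(model$gene, out, level = "haplotype")
  })
}

#' Simulate panels with controlled coverage
#'
#' For each coverage target, picks `round(target / 100 * K)` of the model's
#' `K` known variants uniformly without replacement; realized coverage is
#' within one variant's granularity (`100 / K` percentage points) of the
#' target. A 0% target yields a panel targeting one non-allele-defining
#' extra variant (panels must be non-empty), so its intersection with any
#' allele's defining set is empty.
#'
#' @param model A [gene_model()].
#' @param coverage_targets Numeric vector of target percentages in
#'   `[0, 100]`.
#' @param config A [sim_config()].
#' @return List of [test_panel()] objects named `simpanel_<target>`.
#' @export
simulate_panels <- function(model, coverage_targets, config) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  known <- model$known_variants
  K <- length(known)
  defined <- unique(unlist(model$alleles$defining_variants))
  extras <- setdiff(known, defined)
  withr::with_seed(config$seed + 2L, {
    lapply(coverage_targets, function(t) {
      if (t < 0 || t > 100) {
        cpgx_abort(sprintf("coverage target %g%% outside [0, 100]", t),
                   "cpgx_config_error")
      }
      k <- round(t / 100 * K)
      if (k == 0L) {
        if (!length(extras)) {
          cpgx_abort(sprintf(
            "0%% target unachievable: no non-defining variants (granularity %.2f%%)",
            100 / K), "cpgx_config_error")
        }
        tv <- sample(extras, 1L)
      } else {
        tv <- sample(known, k)
      }
      test_panel(sprintf("simpanel_%03d", round(t)),
                 targets = stats::setNames(list(tv), model$gene),
                 lab = "simulated")
    })
  })
}

#' Write a simulated input bundle to disk
#'
#' Emits the simulated gene model, haplotype frequency table, panels and
#' ruleset in the exact file dialects the readers consume, so a simulated
#' bundle is indistinguishable from a curated one.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param coverage_targets Coverage targets for [simulate_panels()].
#' @param rules A [phenotype_ruleset()] to ship with the bundle; defaults
#'   to a score-below-2 rule on the simulated gene (reference homozygote
#'   scores exactly 2).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_simulated_bundle <- function(config, dir,
                                   coverage_targets = c(25, 50, 75, 100),
                                   rules = NULL) {
  model <- simulate_gene_model(config)
  haps <- simulate_population_frequencies(model, config)
  panels <- simulate_panels(model, coverage_targets, config)
  if (is.null(rules)) {
    rules <- phenotype_ruleset(stats::setNames(
      list(rule_activity_interval(2)), model$gene))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gene_model = file.path(dir, "gene_model.tsv"),
    known_variants = file.path(dir, "known_variants.tsv"),
    frequencies = file.path(dir, "frequencies.tsv"),
    panels = file.path(dir, "panels.json"),
    rules = file.path(dir, "rules.json")
  )
  write_gene_model(model, paths$gene_model, paths$known_variants)
  write_frequency_table(haps, paths$frequencies)
  write_panels(panels, paths$panels)
  write_rules(rules, paths$rules)
  invisible(paths)
}
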