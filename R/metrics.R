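#' Variant coverage percentage of a panel for one gene
#'
#' The number of known variants the assay targets, as a percentage of all
#' known variants for the gene:
#' `100 * |targets intersect known_variants| / |known_variants|`.
#' Targeted identifiers outside the known-variant universe do not count.
#'
#' @param panel A [test_panel()].
#' @param gene Gene symbol; must be listed in the panel's targets.
#' @param model The gene's [gene_model()].
#' @return Percentage in `[0, 100]`.
#' @export
coverage_percentage <- function(panel, gene, model) {
  stopifnot(inherits(panel, "test_panel"), inherits(model, "gene_model"))
  if (!gene %in% names(panel$targets)) {
    cpgx_abort(sprintf("panel %s does not list gene %s", panel$test_name, gene),
               "cpgx_validation_error")
  }
  known <- model$known_variants
  if (!length(known)) {
    cpgx_abort(sprintf("gene %s has no known variants; coverage undefined", gene),
               "cpgx_undefined")
  }
  100 * length(intersect(panel$targets[[gene]], known)) / length(known)
}

allele_detectable <- function(defining, targets, match) {
  if (!length(defining)) return(TRUE)  # reference allele: default call
  if (match == "all") all(defining %in% targets) else any(defining %in% targets)
}

#' Is a diplotype detectable by a panel?
#'
#' A diplotype is detectable when the assay can call both of its alleles: an
#' allele is detectable when the panel targets its defining core variants
#' (all of them by default; `match = "any"` relaxes this for sensitivity
#' analysis), and the reference allele — empty defining set — is always
#' detectable because untargeted assays report `*1` by default. One-sided
#' coverage is insufficient: both alleles must be callable.
#'
#' @param dip Diplotype identifier.
#' @param panel A [test_panel()].
#' @param model A [gene_model()]; the gene must be in the panel's targets.
#' @param match `"all"` (default) or `"any"`: how many of an allele's
#'   defining variants the panel must target.
#' @return Logical scalar.
#' @export
is_detectable <- function(dip, panel, model, match = c("all", "any")) {
  match <- match.arg(match)
  targets <- panel$targets[[model$gene]]
  if (is.null(targets)) {
    cpgx_abort(sprintf("panel %s does not list gene %s",
                       panel$test_name, model$gene), "cpgx_validation_error")
  }
  parts <- diplotype_alleles(dip)
  all(vapply(parts, function(a) {
    allele_detectable(model_allele(model, a)$defining_variants[[1]],
                      targets, match)
  }, logical(1)))
}

#' Population altered-metabolizer frequency
#'
#' The sum of the frequencies of all altered-metabolizer diplotypes in one
#' population — the denominator of the detection rate.
#'
#' @param dips A diplotype-level [freq_table()].
#' @param altered Character vector of altered diplotype identifiers
#'   (canonical), e.g. from [altered_diplotype_set()].
#' @param population Population label; raising a missing-data error (never
#'   silently 0) when the population has no frequency data.
#' @return Frequency in `[0, 1]`.
#' @export
population_altered_frequency <- function(dips, altered, population) {
  stopifnot(inherits(dips, "freq_table"))
  if (dips$level != "diplotype") {
    cpgx_abort("needs a diplotype-level table", "cpgx_validation_error")
  }
  f <- population_frequencies(dips, population)
  sum(f[names(f) %in% altered], na.rm = TRUE)
}

#' Detection rate of a panel in one population
#'
#' The detectable altered-metabolizer frequency (altered diplotypes whose
#' both alleles the panel can call) divided by the population
#' altered-metabolizer frequency, times 100. Undefined (returned as `NA`)
#' when the population altered frequency is zero.
#'
#' @inheritParams population_altered_frequency
#' @inheritParams is_detectable
#' @return Percentage in `[0, 100]`, or `NA` when undefined.
#' @export
detection_rate <- function(dips, altered, panel, model, population,
                           match = c("all", "any")) {
  match <- match.arg(match)
  f <- population_frequencies(dips, population)
  alt <- f[names(f) %in% altered]
  pop_alt <- sum(alt, na.rm = TRUE)
  if (pop_alt == 0) return(NA_real_)
  det <- vapply(names(alt), is_detectable, logical(1),
                panel = panel, model = model, match = match)
  100 * sum(alt[det], na.rm = TRUE) / pop_alt
}

#' Evaluate test panels across genes and populations
#'
#' The full evaluation: for every (test, gene, population) triple, the
#' coverage percentage, population altered-metabolizer frequency,
#' detectable altered frequency, detection rate, and a default-call
#' diagnostic — the share of the detectable altered mass carried by
#' diplotypes with at least one reference allele, whose call relies on the
#' default-`*1` convention and can therefore mask false negatives.
#'
#' AMP tier allele sets are evaluated by expressing them as panels and
#' passing them here alongside the assays; there is no separate code path.
#'
#' @param panels List of [test_panel()] objects (validated against
#'   `models`).
#' @param models Named list of [gene_model()] objects.
#' @param tables Named list of [freq_table()] objects, one per gene;
#'   haplotype-level tables are expanded under Hardy-Weinberg equilibrium.
#' @param rules A [phenotype_ruleset()].
#' @param lookup A [translation_lookup()] (needed for categorical genes).
#' @param match Allele detectability mode, see [is_detectable()].
#' @param renormalize Passed to [hwe_expand()] for haplotype-level tables.
#' @param unknown_function Passed to [altered_diplotype_set()].
#' @return A tibble of class `detection_matrix`: one row per (test, gene,
#'   population) with `status` `"ok"`, `"undefined"` (zero altered
#'   frequency), `"not_applicable"` (the test does not cover the gene) or
#'   `"missing_population"` (no frequency data). Rates are `NA` outside
#'   `"ok"`.
#' @export
evaluate_panels <- function(panels, models, tables, rules, lookup = NULL,
                            match = c("all", "any"), renormalize = FALSE,
                            unknown_function = "exclude") {
  match <- match.arg(match)
  if (inherits(panels, "test_panel")) panels <- list(panels)
  validate_panels(panels, models)
  genes <- names(models)
  missing_tables <- setdiff(genes, names(tables))
  if (length(missing_tables)) {
    cpgx_abort(sprintf("no frequency table for gene(s): %s",
                       paste(missing_tables, collapse = ", ")),
               "cpgx_validation_error")
  }
  per_gene <- lapply(genes, function(g) {
    tab <- tables[[g]]
    if (tab$level == "haplotype") tab <- hwe_expand(tab, renormalize = renormalize)
    list(dips = tab,
         altered = altered_diplotype_set(tab, models[[g]], rules, lookup,
                                         unknown_function = unknown_function),
         missing = missing_populations(tab))
  })
  names(per_gene) <- genes

  rows <- list()
  for (p in panels) {
    for (g in genes) {
      pg <- per_gene[[g]]
      pops <- pg$dips$populations
      if (!g %in% names(p$targets)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          test = p$test_name, gene = g, population = pops,
          status = "not_applicable", coverage_pct = NA_real_,
          population_altered_freq = NA_real_,
          detectable_altered_freq = NA_real_,
          detection_rate_pct = NA_real_, default_call_frac = NA_real_)
        next
      }
      cov <- coverage_percentage(p, g, models[[g]])
      ref <- reference_alleles(models[[g]])
      for (pop in pops) {
        if (pop %in% pg$missing) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            test = p$test_name, gene = g, population = pop,
            status = "missing_population", coverage_pct = cov,
            population_altered_freq = NA_real_,
            detectable_altered_freq = NA_real_,
            detection_rate_pct = NA_real_, default_call_frac = NA_real_)
          next
        }
        f <- population_frequencies(pg$dips, pop)
        alt <- f[names(f) %in% pg$altered]
        alt[is.na(alt)] <- 0
        pop_alt <- sum(alt)
        det <- vapply(names(alt), is_detectable, logical(1),
                      panel = p, model = models[[g]], match = match)
        det_alt <- sum(alt[det])
        via_default <- vapply(names(alt), function(d) {
          any(diplotype_alleles(d) %in% ref)
        }, logical(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          test = p$test_name, gene = g, population = pop,
          status = if (pop_alt == 0) "undefined" else "ok",
          coverage_pct = cov,
          population_altered_freq = pop_alt,
          detectable_altered_freq = det_alt,
          detection_rate_pct = if (pop_alt == 0) NA_real_
                               else 100 * det_alt / pop_alt,
          default_call_frac = if (det_alt == 0) NA_real_
                              else sum(alt[det & via_default]) / det_alt)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("detection_matrix", class(out))
  out
}

#' Summarize a detection matrix
#'
#' Unweighted mean, minimum and maximum of the detection rate over the
#' defined (`status == "ok"`) cells in each group; undefined, missing and
#' not-applicable cells are excluded from the averages and counted instead
#' of being imputed.
#'
#' @param matrix A `detection_matrix` from [evaluate_panels()].
#' @param by Character vector of grouping axes among `"test"`, `"gene"`,
#'   `"population"`.
#' @return A tibble with `mean_detection_rate`, `min_detection_rate`,
#'   `max_detection_rate`, `mean_coverage_pct`, `n_defined`, `n_undefined`,
#'   `n_missing`. Groups whose cells are all undefined get `NA` means.
#' @export
summarize_detection <- function(matrix, by = c("gene", "population")) {
  stopifnot(all(by %in% c("test", "gene", "population")))
  if (!nrow(matrix)) cpgx_abort("empty detection matrix", "cpgx_validation_error")
  matrix |>
    dplyr::filter(.data$status != "not_applicable") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_detection_rate = mean_or_na(.data$detection_rate_pct[.data$status == "ok"]),
      min_detection_rate = min_or_na(.data$detection_rate_pct[.data$status == "ok"]),
      max_detection_rate = max_or_na(.data$detection_rate_pct[.data$status == "ok"]),
      mean_coverage_pct = mean_or_na(.data$coverage_pct[.data$status %in% c("ok", "undefined")]),
      n_defined = sum(.data$status == "ok"),
      n_undefined = sum(.data$status == "undefined"),
      n_missing = sum(.data$status == "missing_population"),
      .groups = "drop"
    )
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
min_or_na <- function(x) if (length(x)) min(x) else NA_real_
max_or_na <- function(x) if (length(x)) max(x) else NA_real_

#' Rank tests by detection rate within a group
#'
#' Identifies the highest-performing tests per gene and population; ties on
#' the rounded rate are broken by test name (lexicographic) and reported
#' together.
#'
#' @param matrix A `detection_matrix`.
#' @param digits Rounding applied before ranking (ties at reported
#'   precision).
#' @return Tibble with one row per (gene, population): `best_test`
#'   (lexicographically first among the tied best), `best_rate`, `tied`
#'   (semicolon-joined tied test names).
#' @export
top_tests <- function(matrix, digits = 1) {
  matrix |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::mutate(rate_r = round(.data$detection_rate_pct, digits)) |>
    dplyr::group_by(.data$gene, .data$population) |>
    dplyr::filter(.data$rate_r == max(.data$rate_r)) |>
    dplyr::arrange(.data$test, .by_group = TRUE) |>
    dplyr::summarise(
      best_test = dplyr::first(.data$test),
      best_rate = dplyr::first(.data$rate_r),
      tied = paste(.data$test, collapse = ";"),
      .groups = "drop"
    )
}
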