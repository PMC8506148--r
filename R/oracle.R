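#' Brute-force detection-rate oracle
#'
#' An independent verification path for the evaluation pipeline: it
#' enumerates every diplotype of the gene explicitly from the haplotype
#' frequencies, scores and labels each with its own arithmetic, applies the
#' altered rule and the both-alleles detectability requirement with its own
#' logic, and sums — sharing no code with [evaluate_panels()] or the
#' phenotype/metric functions. Intended for property tests and small
#' fixtures; refuses models above eight alleles.
#'
#' @param model A [gene_model()] with at most 8 alleles.
#' @param haps A haplotype-level [freq_table()] over the model's alleles.
#' @param panel A [test_panel()] listing the gene.
#' @param rules A [phenotype_ruleset()].
#' @param population Population label.
#' @param lookup A [translation_lookup()] for categorical genes.
#' @param match `"all"` or `"any"` defining-variant matching.
#' @return A one-row tibble with `test`, `gene`, `population`,
#'   `coverage_pct`, `population_altered_freq`, `detectable_altered_freq`,
#'   `detection_rate_pct` (NA when the altered frequency is zero) and
#'   `status`.
#' @export
brute_force_detection <- function(model, haps, panel, rules, population,
                                  lookup = NULL, match = "all") {
  if (nrow(model$alleles) > 8L) {
    cpgx_abort("brute-force oracle refuses models with more than 8 alleles",
               "cpgx_config_error")
  }
  if (haps$level != "haplotype") {
    cpgx_abort("oracle needs a haplotype-level table", "cpgx_validation_error")
  }
  gene <- model$gene
  al <- model$alleles
  p <- haps$data[[population]]
  if (is.null(p) || all(is.na(p))) {
    cpgx_abort(sprintf("population %s missing", population),
               "cpgx_missing_population")
  }
  names(p) <- haps$data$identifier
  p <- unname(p[al$allele])

  rule <- rules[[gene]]
  if (is.null(rule)) cpgx_abort(sprintf("no rule for %s", gene), "cpgx_missing_rule")
  targets <- panel$targets[[gene]]
  if (is.null(targets)) {
    cpgx_abort(sprintf("panel %s omits %s", panel$test_name, gene),
               "cpgx_validation_error")
  }

  # per-allele facts, computed directly from the allele table
  act <- al$activity_value * al$copy_number
  fn <- al$function_class
  unknown_fn <- fn %in% "unknown"
  callable <- vapply(al$defining_variants, function(dv) {
    if (length(dv) == 0L) TRUE
    else if (match == "all") length(setdiff(dv, targets)) == 0L
    else length(intersect(dv, targets)) > 0L
  }, logical(1))

  n <- nrow(al)
  pop_alt <- 0
  det_alt <- 0
  for (i in seq_len(n)) {
    for (j in i:n) {
      freq <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      if (is.na(freq)) next
      if (unknown_fn[i] || unknown_fn[j]) next  # unknown function: excluded
      if (rule$rule_kind == "activity_interval") {
        score <- act[i] + act[j]
        if (is.na(score)) {
          cpgx_abort(sprintf("allele without activity value in %s/%s",
                             al$allele[i], al$allele[j]), "cpgx_unscorable")
        }
        altered <- score < rule$normal_interval[["lo"]] ||
          score > rule$normal_interval[["hi"]]
      } else {
        # unordered function pair, diplotype override first
        dip_id <- paste(sort(c(al$allele[i], al$allele[j])), collapse = "/")
        lab <- NA_character_
        if (!is.null(lookup)) {
          ov <- lookup$overrides
          k <- which(ov$gene == gene & ov$diplotype == dip_id)
          if (length(k)) {
            lab <- ov$label[k[1]]
          } else {
            flo <- min(fn[i], fn[j]); fhi <- max(fn[i], fn[j])
            for (g in c(gene, "*")) {
              k <- which(lookup$pairs$gene == g &
                           lookup$pairs$function_a == flo &
                           lookup$pairs$function_b == fhi)
              if (length(k)) { lab <- lookup$pairs$label[k[1]]; break }
            }
          }
        }
        if (is.na(lab)) {
          cpgx_abort(sprintf("no translation for %s/%s",
                             al$allele[i], al$allele[j]), "cpgx_untranslatable")
        }
        altered <- lab %in% rule$altered_categories
      }
      if (altered) {
        pop_alt <- pop_alt + freq
        if (callable[i] && callable[j]) det_alt <- det_alt + freq
      }
    }
  }
  cov <- 100 * sum(targets %in% model$known_variants) /
    length(model$known_variants)
  tibble::tibble(
    test = panel$test_name, gene = gene, population = population,
    status = if (pop_alt == 0) "undefined" else "ok",
    coverage_pct = cov,
    population_altered_freq = pop_alt,
    detectable_altered_freq = det_alt,
    detection_rate_pct = if (pop_alt == 0) NA_real_ else 100 * det_alt / pop_alt
  )
}
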