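#' Diplotype-to-phenotype translation lookup
#'
#' For genes whose phenotype is categorical (CYP2B6, CYP2C19, CYP3A5) the
#' diplotype is translated through its pair of allele function classes,
#' with optional diplotype-specific overrides taking precedence. The pair
#' table is keyed by gene (the wildcard gene `"*"` supplies generic
#' fallbacks) and by the unordered function-class pair.
#'
#' @param pairs Data frame with columns `gene`, `function_a`, `function_b`,
#'   `label`.
#' @param overrides Optional data frame with columns `gene`, `diplotype`,
#'   `label` for diplotype-specific assignments.
#' @return An object of class `translation_lookup`.
#' @export
translation_lookup <- function(pairs, overrides = NULL) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("gene", "function_a", "function_b", "label")
  if (!all(need %in% names(pairs))) {
    cpgx_abort(sprintf("pair table needs columns %s",
                       paste(need, collapse = ", ")), "cpgx_format_error")
  }
  bad <- setdiff(unique(pairs$label), PHENOTYPE_VOCAB)
  if (length(bad)) {
    cpgx_abort(sprintf("translation label(s) outside controlled vocabulary: %s",
                       paste(bad, collapse = ", ")), "cpgx_validation_error")
  }
  # store the function pair unordered
  lo <- pmin(pairs$function_a, pairs$function_b)
  hi <- pmax(pairs$function_a, pairs$function_b)
  pairs$function_a <- lo
  pairs$function_b <- hi
  pairs <- pairs[, c("gene", "function_a", "function_b", "label")]
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    if (!all(c("gene", "diplotype", "label") %in% names(overrides))) {
      cpgx_abort("override table needs columns gene, diplotype, label",
                 "cpgx_format_error")
    }
    overrides$diplotype <- canonical_diplotype(overrides$diplotype)
  } else {
    overrides <- tibble::tibble(gene = character(), diplotype = character(),
                                label = character())
  }
  structure(list(pairs = pairs, overrides = overrides),
            class = "translation_lookup")
}

#' Default function-class pair translation
#'
#' Generic CPIC-style mapping of unordered allele function pairs to
#' metabolizer phenotypes (two no-function alleles are a poor metabolizer,
#' a normal plus an increased-function allele is rapid, and so on), with a
#' CYP3A5-specific block using expresser terminology: any functional CYP3A5
#' allele makes an expresser, labelled extensive (two) or intermediate
#' (one).
#'
#' @return A [translation_lookup()].
#' @export
default_translation <- function() {
  generic <- tibble::tribble(
    ~function_a, ~function_b, ~label,
    "normal",    "normal",    "normal",
    "normal",    "decreased", "intermediate",
    "normal",    "no",        "intermediate",
    "decreased", "decreased", "poor",
    "decreased", "no",        "poor",
    "no",        "no",        "poor",
    "normal",    "increased", "rapid",
    "increased", "increased", "ultrarapid",
    "increased", "no",        "intermediate",
    "increased", "decreased", "likely intermediate"
  )
  generic$gene <- "*"
  cyp3a5 <- tibble::tribble(
    ~function_a, ~function_b, ~label,
    "normal",    "normal",    "extensive",
    "normal",    "decreased", "intermediate",
    "normal",    "no",        "intermediate",
    "decreased", "decreased", "poor",
    "decreased", "no",        "poor",
    "no",        "no",        "poor"
  )
  cyp3a5$gene <- "CYP3A5"
  translation_lookup(rbind(cyp3a5, generic))
}

lookup_label <- function(lookup, gene, dip_id, fn_a, fn_b) {
  ov <- lookup$overrides
  hit <- which(ov$gene == gene & ov$diplotype == dip_id)
  if (length(hit)) return(ov$label[hit[1]])
  if (is.na(fn_a) || is.na(fn_b)) return(NA_character_)
  lo <- min(fn_a, fn_b); hi <- max(fn_a, fn_b)
  for (g in c(gene, "*")) {
    p <- lookup$pairs
    hit <- which(p$gene == g & p$function_a == lo & p$function_b == hi)
    if (length(hit)) return(p$label[hit[1]])
  }
  NA_character_
}

#' Activity score of a diplotype
#'
#' The CPIC convention: each allele contributes its activity value times its
#' copy number, and the diplotype score is the sum over the two alleles. The
#' score is symmetric in allele order.
#'
#' @param dip Diplotype identifier (e.g. `"*1/*3"`).
#' @param model A [gene_model()]; both alleles must carry an
#'   `activity_value`.
#' @return Non-negative numeric score.
#' @export
diplotype_activity_score <- function(dip, model) {
  parts <- diplotype_alleles(dip)
  vals <- vapply(parts, function(a) {
    row <- model_allele(model, a)
    if (is.na(row$activity_value)) {
      cpgx_abort(sprintf("allele %s of %s has no activity value; cannot score",
                         a, model$gene), "cpgx_unscorable")
    }
    row$activity_value * row$copy_number
  }, numeric(1))
  sum(vals)
}

#' Translate a diplotype to a genotype-predicted phenotype
#'
#' Attaches an activity score whenever both alleles carry activity values,
#' and a phenotype label whenever a translation path exists (a
#' diplotype-specific override, or the unordered function-class pair in the
#' lookup). A diplotype with neither path is untranslatable. Alleles with
#' `"unknown"` function class and no activity value have no defined
#' phenotype; by default they raise the untranslatable condition (callers
#' may choose to drop or reinterpret them).
#'
#' @param dip Diplotype identifier.
#' @param model A [gene_model()].
#' @param lookup A [translation_lookup()], or `NULL` when only the score
#'   path is wanted.
#' @return A list with elements `diplotype` (canonical id), `gene`,
#'   `activity_score` (numeric or `NA`), `phenotype_label` (character or
#'   `NA`).
#' @export
assign_phenotype <- function(dip, model, lookup = NULL) {
  parts <- diplotype_alleles(dip)
  id <- diplotype(parts[1], parts[2])
  rows <- lapply(parts, model_allele, model = model)
  score <- NA_real_
  if (!anyNA(vapply(rows, function(r) r$activity_value, numeric(1)))) {
    score <- sum(vapply(rows, function(r) r$activity_value * r$copy_number,
                        numeric(1)))
  }
  label <- NA_character_
  if (!is.null(lookup)) {
    fns <- vapply(rows, function(r) r$function_class, character(1))
    fns[fns %in% "unknown"] <- NA_character_
    label <- lookup_label(lookup, model$gene, id, fns[1], fns[2])
  }
  if (is.na(score) && is.na(label)) {
    cpgx_abort(sprintf(
      "diplotype %s of %s is untranslatable: no activity values and no lookup entry",
      id, model$gene), "cpgx_untranslatable")
  }
  list(diplotype = id, gene = model$gene,
       activity_score = score, phenotype_label = label)
}

#' Classify a phenotype call as altered or not
#'
#' Activity-interval rules compare the score against the closed normal
#' window with strict exceedance ("less than" / "greater than"): a score
#' exactly at either bound is not altered. Categorical rules test label
#' membership in the altered set.
#'
#' @param call A phenotype call as returned by [assign_phenotype()], or any
#'   list with `activity_score` / `phenotype_label`.
#' @param rules A [phenotype_ruleset()].
#' @param gene Gene symbol selecting the rule.
#' @return Logical scalar.
#' @export
classify_altered <- function(call, rules, gene) {
  r <- ruleset_rule(rules, gene)
  if (r$rule_kind == "activity_interval") {
    s <- call$activity_score
    if (is.null(s) || is.na(s)) {
      cpgx_abort(sprintf(
        "%s uses an activity-score rule but the call for %s carries no score",
        gene, call$diplotype %||% "<diplotype>"), "cpgx_rule_mismatch")
    }
    return(s < r$normal_interval[["lo"]] || s > r$normal_interval[["hi"]])
  }
  lab <- call$phenotype_label
  if (is.null(lab) || is.na(lab)) {
    cpgx_abort(sprintf(
      "%s uses a categorical rule but the call for %s carries no label",
      gene, call$diplotype %||% "<diplotype>"), "cpgx_rule_mismatch")
  }
  lab %in% r$altered_categories
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Altered-metabolizer diplotypes of a frequency table
#'
#' Classifies every diplotype in a diplotype-level table and returns those
#' predicting an altered-metabolizer phenotype. Diplotypes involving an
#' allele of unknown function (and with no scorable path or override) are
#' excluded with a warning by default — they contribute to neither the
#' altered set nor downstream frequency sums — or treated as carrying
#' normal function when `unknown_function = "normal"`.
#'
#' @param table A diplotype-level [freq_table()], e.g. from [hwe_expand()].
#' @param model A [gene_model()].
#' @param rules A [phenotype_ruleset()].
#' @param lookup A [translation_lookup()] for categorical genes.
#' @param unknown_function `"exclude"` (default) or `"normal"`.
#' @return Character vector of canonical diplotype identifiers (sorted).
#' @export
altered_diplotype_set <- function(table, model, rules, lookup = NULL,
                                  unknown_function = c("exclude", "normal")) {
  unknown_function <- match.arg(unknown_function)
  stopifnot(inherits(table, "freq_table"))
  if (table$level != "diplotype") {
    cpgx_abort("altered_diplotype_set() needs a diplotype-level table; expand first",
               "cpgx_validation_error")
  }
  model_use <- model
  if (unknown_function == "normal") {
    fc <- model_use$alleles$function_class
    unk <- fc %in% "unknown"
    model_use$alleles$function_class[unk] <- "normal"
    # normal function implies unit activity when none is annotated
    fix_act <- unk & is.na(model_use$alleles$activity_value)
    model_use$alleles$activity_value[fix_act] <- 1
  }
  unknown_alleles <- model_use$alleles$allele[
    model_use$alleles$function_class %in% "unknown"]
  skipped <- character()
  altered <- character()
  for (id in table$data$identifier) {
    if (any(diplotype_alleles(id) %in% unknown_alleles)) {
      skipped <- c(skipped, id)
      next
    }
    call <- tryCatch(
      assign_phenotype(id, model_use, lookup),
      cpgx_untranslatable = function(e) e
    )
    if (inherits(call, "condition")) {
      skipped <- c(skipped, id)
      next
    }
    is_alt <- tryCatch(
      classify_altered(call, rules, model$gene),
      cpgx_rule_mismatch = function(e) {
        cpgx_abort(sprintf("diplotype %s: %s", id, conditionMessage(e)),
                   "cpgx_rule_mismatch")
      }
    )
    if (is_alt) altered <- c(altered, id)
  }
  if (length(skipped)) {
    rlang::warn(sprintf(
      "%s: %d diplotype(s) excluded from classification (unknown function): %s",
      model$gene, length(skipped), paste(utils::head(skipped, 5), collapse = ", ")))
  }
  sort(altered)
}
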