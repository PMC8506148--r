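#' Read and write star-allele gene models
#'
#' The gene-model TSV has columns `gene`, `allele`,
#' `defining_variants` (semicolon-separated, empty for the reference
#' allele), and optionally `activity_value`, `function_class`,
#' `copy_number`. The known-variant universe comes from a companion
#' single-column TSV (column `variant`) or a JSON array; when absent it
#' defaults to the union of defining variants.
#'
#' @param path Gene-model TSV path.
#' @param known_variants_path Optional companion TSV or JSON path.
#' @return `read_gene_model()`: a [gene_model()] (or a named list of them
#'   when the file holds several genes).
#' @export
read_gene_model <- function(path, known_variants_path = NULL) {
  if (!file.exists(path)) {
    cpgx_abort(sprintf("gene model file not found: %s", path), "cpgx_io_error")
  }
  df <- read_tsv_strict(path, c("gene", "allele", "defining_variants"))
  known <- NULL
  if (!is.null(known_variants_path)) {
    known <- read_known_variants(known_variants_path)
  }
  genes <- unique(df$gene)
  models <- lapply(genes, function(g) {
    sub <- df[df$gene == g, setdiff(names(df), "gene")]
    kv <- if (is.data.frame(known)) known$variant[known$gene == g]
          else known
    gene_model(g, sub, known_variants = kv)
  })
  names(models) <- genes
  if (length(models) == 1L) models[[1]] else models
}

read_known_variants <- function(path) {
  if (!file.exists(path)) {
    cpgx_abort(sprintf("known-variants file not found: %s", path),
               "cpgx_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.list(v) && !is.null(names(v))) {
      return(tibble::tibble(gene = rep(names(v), lengths(v)),
                            variant = unlist(v, use.names = FALSE)))
    }
    return(as.character(v))
  }
  df <- read_tsv_strict(path, "variant")
  if ("gene" %in% names(df)) df[, c("gene", "variant")] else df$variant
}

#' @rdname read_gene_model
#' @param model A [gene_model()] (or named list of them).
#' @param known_variants_path Where to write the companion known-variant
#'   TSV; omitted if `NULL`.
#' @export
write_gene_model <- function(model, path, known_variants_path = NULL) {
  models <- if (inherits(model, "gene_model")) list(model) else model
  rows <- lapply(models, function(m) {
    tibble::tibble(
      gene = m$gene,
      allele = m$alleles$allele,
      defining_variants = vapply(m$alleles$defining_variants,
                                 paste, character(1), collapse = ";"),
      activity_value = m$alleles$activity_value,
      function_class = m$alleles$function_class,
      copy_number = m$alleles$copy_number
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, na = "")
  if (!is.null(known_variants_path)) {
    kv <- dplyr::bind_rows(lapply(models, function(m) {
      tibble::tibble(gene = m$gene, variant = m$known_variants)
    }))
    readr::write_tsv(kv, known_variants_path, na = "")
  }
  invisible(path)
}

#' Read and write PharmGKB-style frequency tables
#'
#' Layout: `gene`, `identifier` (star allele, or `"A/B"` diplotype), then
#' one numeric column per population. Blank cells are missing data, not
#' zeros; a fully blank population column is flagged missing.
#'
#' @param path TSV path.
#' @param level `"haplotype"` or `"diplotype"`.
#' @return A [freq_table()] (or a named list by gene).
#' @export
read_frequency_table <- function(path, level = c("haplotype", "diplotype")) {
  level <- match.arg(level)
  if (!file.exists(path)) {
    cpgx_abort(sprintf("frequency file not found: %s", path), "cpgx_io_error")
  }
  df <- read_tsv_strict(path, c("gene", "identifier"))
  genes <- unique(df$gene)
  tabs <- lapply(genes, function(g) {
    freq_table(g, df[df$gene == g, setdiff(names(df), "gene")], level = level)
  })
  names(tabs) <- genes
  if (length(tabs) == 1L) tabs[[1]] else tabs
}

#' @rdname read_frequency_table
#' @param table A [freq_table()] (or list of them).
#' @export
write_frequency_table <- function(table, path) {
  tabs <- if (inherits(table, "freq_table")) list(table) else table
  rows <- lapply(tabs, function(t) {
    dplyr::bind_cols(tibble::tibble(gene = t$gene), t$data)
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, na = "")
  invisible(path)
}

#' Read and write test-panel definitions
#'
#' JSON layout:
#' `{"tests": [{"name": "...", "lab": "...", "targets": {"CYP2C9": ["rs..."]}}]}`.
#' When gene models are supplied, panels are validated against them
#' (unresolvable genes error; targeted variants outside the known universe
#' warn).
#'
#' @param path Panel JSON path.
#' @param models Optional named list of [gene_model()]s for validation.
#' @return List of [test_panel()] objects.
#' @export
read_panels <- function(path, models = NULL) {
  if (!file.exists(path)) {
    cpgx_abort(sprintf("panel file not found: %s", path), "cpgx_io_error")
  }
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$tests)) {
    cpgx_abort(sprintf("%s: expected a top-level \"tests\" array", path),
               "cpgx_format_error")
  }
  panels <- lapply(js$tests, function(t) {
    if (is.null(t$name)) {
      cpgx_abort(sprintf("%s: test entry missing \"name\"", path),
                 "cpgx_format_error")
    }
    targets <- lapply(t$targets, function(v) unlist(v, use.names = FALSE))
    test_panel(t$name, targets, lab = t$lab %||% NA_character_)
  })
  nm <- vapply(panels, function(p) p$test_name, character(1))
  if (anyDuplicated(nm)) {
    cpgx_abort(sprintf("duplicate test name(s) in %s: %s", path,
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")),
               "cpgx_validation_error")
  }
  if (!is.null(models)) validate_panels(panels, models)
  panels
}

#' @rdname read_panels
#' @param panels List of [test_panel()] objects.
#' @export
write_panels <- function(panels, path) {
  if (inherits(panels, "test_panel")) panels <- list(panels)
  body <- list(tests = lapply(panels, function(p) {
    out <- list(name = p$test_name, targets = p$targets)
    if (!is.na(p$lab)) out$lab <- p$lab
    out
  }))
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write altered-metabolizer rule sets
#'
#' JSON mirror of the ruleset: per gene either
#' `{"rule_kind": "categorical", "altered_categories": [...]}` or
#' `{"rule_kind": "activity_interval", "normal_interval": [lo, hi]}`
#' (`hi` may be `null` for an unbounded upper end). The shipped default
#' `inst/extdata/cpic_altered_rules.json` encodes [cpic_altered_rules()].
#'
#' @param path Rule JSON path.
#' @return A [phenotype_ruleset()].
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) {
    cpgx_abort(sprintf("rules file not found: %s", path), "cpgx_io_error")
  }
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(js, function(r) {
    kind <- r$rule_kind %||% cpgx_abort("rule entry missing rule_kind",
                                        "cpgx_format_error")
    if (kind == "categorical") {
      rule_categorical(unlist(r$altered_categories))
    } else if (kind == "activity_interval") {
      iv <- r$normal_interval
      lo <- iv[[1]]
      hi <- if (length(iv) < 2L || is.null(iv[[2]])) Inf else iv[[2]]
      rule_activity_interval(lo, hi)
    } else {
      cpgx_abort(sprintf("unknown rule_kind: %s", kind), "cpgx_format_error")
    }
  })
  phenotype_ruleset(rules)
}

#' @rdname read_rules
#' @param rules A [phenotype_ruleset()].
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "phenotype_ruleset"))
  body <- lapply(unclass(rules), function(r) {
    if (r$rule_kind == "categorical") {
      list(rule_kind = "categorical",
           altered_categories = as.list(r$altered_categories))
    } else {
      hi <- r$normal_interval[["hi"]]
      list(rule_kind = "activity_interval",
           normal_interval = list(r$normal_interval[["lo"]],
                                  if (is.finite(hi)) hi else NULL))
    }
  })
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read and write phenotype translation lookups
#'
#' One TSV with columns `gene`, `function_a`, `function_b`, `diplotype`,
#' `label`: function-pair rows leave `diplotype` blank, diplotype-specific
#' override rows leave the function columns blank.
#'
#' @param path Translation TSV path.
#' @return A [translation_lookup()].
#' @export
read_translation <- function(path) {
  if (!file.exists(path)) {
    cpgx_abort(sprintf("translation file not found: %s", path), "cpgx_io_error")
  }
  df <- read_tsv_strict(path, c("gene", "label"))
  if (!"diplotype" %in% names(df)) df$diplotype <- NA_character_
  is_override <- !is.na(df$diplotype) & nzchar(df$diplotype)
  pairs <- df[!is_override, c("gene", "function_a", "function_b", "label")]
  overrides <- df[is_override, c("gene", "diplotype", "label")]
  translation_lookup(pairs, if (nrow(overrides)) overrides else NULL)
}

#' @rdname read_translation
#' @param lookup A [translation_lookup()].
#' @export
write_translation <- function(lookup, path) {
  stopifnot(inherits(lookup, "translation_lookup"))
  pairs <- lookup$pairs
  pairs$diplotype <- NA_character_
  ov <- lookup$overrides
  if (nrow(ov)) {
    ov$function_a <- NA_character_
    ov$function_b <- NA_character_
  }
  out <- dplyr::bind_rows(pairs, ov)[, c("gene", "function_a", "function_b",
                                         "diplotype", "label")]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Write and re-read detection results
#'
#' Long-format TSV with fixed column order (`test`, `gene`, `population`,
#' `status`, `coverage_pct`, `population_altered_freq`,
#' `detectable_altered_freq`, `detection_rate_pct`, `default_call_frac`).
#' Percentages are written at `digits` decimal places (half-even rounding),
#' frequencies at `digits + 5`; undefined cells are the literal `NA`. The
#' file round-trips losslessly at that precision.
#'
#' @param results A `detection_matrix` (or any data frame with those
#'   columns).
#' @param path Output TSV path.
#' @param digits Decimal places for percentage columns.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = 1) {
  if (!nrow(results)) {
    cpgx_abort("refusing to write an empty results table", "cpgx_validation_error")
  }
  cols <- c("test", "gene", "population", "status", "coverage_pct",
            "population_altered_freq", "detectable_altered_freq",
            "detection_rate_pct", "default_call_frac")
  missing <- setdiff(cols, names(results))
  if (length(missing)) {
    cpgx_abort(sprintf("results lack column(s): %s",
                       paste(missing, collapse = ", ")), "cpgx_format_error")
  }
  out <- results[, cols]
  for (cc in c("coverage_pct", "detection_rate_pct")) {
    out[[cc]] <- round(out[[cc]], digits)
  }
  for (cc in c("population_altered_freq", "detectable_altered_freq",
               "default_call_frac")) {
    out[[cc]] <- round(out[[cc]], digits + 5L)
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    cpgx_abort(sprintf("results file not found: %s", path), "cpgx_io_error")
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                         col_types = readr::cols(
                           test = "c", gene = "c", population = "c",
                           status = "c", .default = "d"))
  class(out) <- c("detection_matrix", class(out))
  out
}

read_tsv_strict <- function(path, required) {
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                    progress = FALSE),
    error = function(e) {
      cpgx_abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                 "cpgx_format_error")
    })
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    cpgx_abort(sprintf("%s: missing required column(s) %s", path,
                       paste(missing, collapse = ", ")), "cpgx_format_error")
  }
  df
}
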