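#' Construct a test-panel definition
#'
#' A combinatorial pharmacogenomic (CPGx) assay is described by the variant
#' identifiers it targets in each gene. Variant identifiers are free-form
#' strings (rsIDs or core-variant labels) compared by exact match after
#' whitespace trimming; no coordinate resolution is attempted, since panel
#' definitions and allele definitions come from curated lists.
#'
#' @param test_name Assay name (unique within a panel collection).
#' @param targets Named list: gene symbol to character vector of targeted
#'   variant identifiers. Every listed gene must target at least one variant.
#' @param lab Optional provenance string (laboratory).
#' @return An object of class `test_panel`.
#' @export
test_panel <- function(test_name, targets, lab = NA_character_) {
  stopifnot(is.character(test_name), length(test_name) == 1L, nzchar(test_name))
  if (!is.list(targets) || is.null(names(targets)) || !all(nzchar(names(targets)))) {
    cpgx_abort("`targets` must be a named list of variant vectors",
               "cpgx_format_error")
  }
  targets <- lapply(targets, function(v) {
    v <- unique(trimws(as.character(v)))
    v[nzchar(v)]
  })
  empty <- names(targets)[lengths(targets) == 0L]
  if (length(empty)) {
    cpgx_abort(sprintf("panel %s: empty target set for gene(s) %s",
                       test_name, paste(empty, collapse = ", ")),
               "cpgx_validation_error")
  }
  structure(list(test_name = test_name, lab = lab, targets = targets),
            class = "test_panel")
}

#' @export
print.test_panel <- function(x, ...) {
  cat(sprintf("<test_panel> %s: %s\n", x$test_name,
              paste(sprintf("%s (%d)", names(x$targets), lengths(x$targets)),
                    collapse = ", ")))
  invisible(x)
}

#' Validate panels against gene models
#'
#' Checks that every gene a panel lists has a gene model, and warns about
#' targeted variants absent from the model's known-variant universe (they
#' are retained but cannot contribute to coverage or detectability, since
#' both are computed by intersection with known variants).
#'
#' @param panels List of [test_panel()] objects.
#' @param models Named list of [gene_model()] objects (names = gene symbols).
#' @return `panels`, invisibly, after validation.
#' @export
validate_panels <- function(panels, models) {
  nm <- vapply(panels, function(p) p$test_name, character(1))
  if (anyDuplicated(nm)) {
    cpgx_abort(sprintf("duplicate test name(s): %s",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")),
               "cpgx_validation_error")
  }
  for (p in panels) {
    unknown_genes <- setdiff(names(p$targets), names(models))
    if (length(unknown_genes)) {
      cpgx_abort(sprintf("panel %s targets gene(s) with no gene model: %s",
                         p$test_name, paste(unknown_genes, collapse = ", ")),
                 "cpgx_validation_error")
    }
    for (g in names(p$targets)) {
      stray <- setdiff(p$targets[[g]], models[[g]]$known_variants)
      if (length(stray)) {
        rlang::warn(sprintf(
          "panel %s, gene %s: %d targeted variant(s) not among known variants (%s)",
          p$test_name, g, length(stray),
          paste(utils::head(stray, 5), collapse = ", ")))
      }
    }
  }
  invisible(panels)
}
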