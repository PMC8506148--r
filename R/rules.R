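#' Altered-metabolizer classification rules
#'
#' An altered metabolizer is a genotype-predicted phenotype that, per the
#' CPIC guideline for the gene, would require a change of drug or dose. Two
#' rule kinds cover the CYPs: categorical rules name the altered phenotype
#' labels outright, and activity-interval rules declare a closed normal
#' interval `[lo, hi]` of the diplotype activity score whose strict
#' complement (score < lo or score > hi) is altered.
#'
#' `rule_categorical()` and `rule_activity_interval()` build single-gene
#' rules; `phenotype_ruleset()` bundles one rule per gene.
#'
#' @param altered_categories Phenotype labels classified as altered; must be
#'   drawn from the controlled vocabulary (`"ultrarapid"`, `"rapid"`,
#'   `"normal"`, `"likely intermediate"`, `"intermediate"`, `"likely poor"`,
#'   `"poor"`, `"extensive"`).
#' @param lo,hi Closed bounds of the normal activity-score interval;
#'   `hi = Inf` means only the lower bound is active.
#' @param ... Named single-gene rules, e.g.
#'   `phenotype_ruleset(CYP2C9 = rule_activity_interval(2))`.
#' @return A `phenotype_rule` or `phenotype_ruleset` object.
#' @export
rule_categorical <- function(altered_categories) {
  altered_categories <- unique(as.character(altered_categories))
  bad <- setdiff(altered_categories, PHENOTYPE_VOCAB)
  if (length(bad)) {
    cpgx_abort(sprintf("phenotype label(s) outside controlled vocabulary: %s",
                       paste(bad, collapse = ", ")), "cpgx_validation_error")
  }
  structure(list(rule_kind = "categorical",
                 altered_categories = altered_categories),
            class = "phenotype_rule")
}

#' @rdname rule_categorical
#' @export
rule_activity_interval <- function(lo, hi = Inf) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (lo > hi) {
    cpgx_abort("normal interval needs lo <= hi", "cpgx_validation_error")
  }
  structure(list(rule_kind = "activity_interval",
                 normal_interval = c(lo = lo, hi = hi)),
            class = "phenotype_rule")
}

#' @rdname rule_categorical
#' @export
phenotype_ruleset <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1]]) &&
      !inherits(rules[[1]], "phenotype_rule")) {
    rules <- rules[[1]]
  }
  if (is.null(names(rules)) || !all(nzchar(names(rules)))) {
    cpgx_abort("every rule must be named by its gene", "cpgx_format_error")
  }
  if (anyDuplicated(names(rules))) {
    cpgx_abort("exactly one rule per gene", "cpgx_validation_error")
  }
  ok <- vapply(rules, inherits, logical(1), what = "phenotype_rule")
  if (!all(ok)) {
    cpgx_abort("all entries must be phenotype_rule objects", "cpgx_format_error")
  }
  structure(rules, class = "phenotype_ruleset")
}

#' @export
print.phenotype_ruleset <- function(x, ...) {
  for (g in names(x)) {
    r <- x[[g]]
    if (r$rule_kind == "categorical") {
      cat(sprintf("%s: altered if phenotype in {%s}\n", g,
                  paste(r$altered_categories, collapse = ", ")))
    } else {
      cat(sprintf("%s: altered if activity score < %g or > %g\n", g,
                  r$normal_interval[["lo"]], r$normal_interval[["hi"]]))
    }
  }
  invisible(x)
}

ruleset_rule <- function(rules, gene) {
  if (!inherits(rules, "phenotype_ruleset")) {
    cpgx_abort("`rules` must be a phenotype_ruleset", "cpgx_format_error")
  }
  r <- rules[[gene]]
  if (is.null(r)) {
    cpgx_abort(sprintf("no altered-metabolizer rule for gene %s", gene),
               "cpgx_missing_rule")
  }
  r
}

#' CPIC-derived altered-metabolizer rules for five CYP genes
#'
#' The shipped default ruleset. Altered status per gene:
#' \describe{
#'   \item{CYP2B6}{intermediate and poor metabolizers (efavirenz guideline).}
#'   \item{CYP2C19}{ultrarapid, rapid, likely intermediate, intermediate,
#'     likely poor and poor metabolizers (PPI/SSRI/TCA/clopidogrel
#'     guidelines).}
#'   \item{CYP2C9}{activity score strictly below 2 (phenytoin/NSAID
#'     guidelines).}
#'   \item{CYP2D6}{activity score strictly below 1.25 or strictly above
#'     2.25, i.e. outside the closed normal window [1.25, 2.25].}
#'   \item{CYP3A5}{intermediate and extensive metabolizers — CYP3A5
#'     expressers need higher tacrolimus doses, so the non-expresser
#'     poor metabolizer is the "normal" here.}
#' }
#'
#' @return A [phenotype_ruleset()].
#' @export
cpic_altered_rules <- function() {
  phenotype_ruleset(
    CYP2B6  = rule_categorical(c("intermediate", "poor")),
    CYP2C19 = rule_categorical(c("ultrarapid", "rapid", "likely intermediate",
                                 "intermediate", "likely poor", "poor")),
    CYP2C9  = rule_activity_interval(2),
    CYP2D6  = rule_activity_interval(1.25, 2.25),
    CYP3A5  = rule_categorical(c("intermediate", "extensive"))
  )
}
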