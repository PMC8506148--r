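#' Construct a star-allele gene model
#'
#' A gene model bundles the star alleles of one pharmacogene — each with its
#' defining core variants, activity value and/or function class, and copy
#' number — together with the universe of known variants for the gene (the
#' denominator of the coverage percentage). The reference allele is any
#' allele with an empty defining-variant set (conventionally `*1`): targeted
#' genotyping assays report it by default when no targeted variant is found.
#'
#' @param gene Gene symbol, e.g. `"CYP2C9"`.
#' @param alleles A data frame with columns `allele` (character),
#'   `defining_variants` (list of character vectors, or a
#'   semicolon-separated character column), and optionally `activity_value`
#'   (non-negative numeric), `function_class` (one of `"normal"`,
#'   `"decreased"`, `"no"`, `"increased"`, `"unknown"`) and `copy_number`
#'   (positive integer). When `copy_number` is absent it is parsed from an
#'   `xN` suffix on the allele name (`"*1x2"` has copy number 2).
#' @param known_variants Character vector of all known variant identifiers
#'   for the gene. Defaults to the union of the alleles' defining variants;
#'   it may be a superset (PharmGKB frequency tables list variants beyond
#'   those defining common star alleles) but never a subset.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, alleles, known_variants = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  alleles <- tibble::as_tibble(alleles)
  if (!all(c("allele", "defining_variants") %in% names(alleles))) {
    cpgx_abort("`alleles` needs columns `allele` and `defining_variants`",
               "cpgx_format_error")
  }
  if (anyDuplicated(alleles$allele)) {
    dup <- unique(alleles$allele[duplicated(alleles$allele)])
    cpgx_abort(sprintf("duplicate allele name(s) for %s: %s",
                       gene, paste(dup, collapse = ", ")),
               "cpgx_validation_error")
  }
  if (is.character(alleles$defining_variants)) {
    alleles$defining_variants <- split_variants(alleles$defining_variants)
  }
  alleles$defining_variants <- lapply(alleles$defining_variants, function(v) {
    v <- trimws(as.character(v))
    unique(v[nzchar(v)])
  })
  if (!"activity_value" %in% names(alleles)) alleles$activity_value <- NA_real_
  alleles$activity_value <- as.numeric(alleles$activity_value)
  if (any(alleles$activity_value < 0, na.rm = TRUE)) {
    cpgx_abort("activity values must be non-negative", "cpgx_validation_error")
  }
  if (!"function_class" %in% names(alleles)) alleles$function_class <- NA_character_
  bad_fn <- setdiff(stats::na.omit(unique(alleles$function_class)), FUNCTION_CLASSES)
  if (length(bad_fn)) {
    cpgx_abort(sprintf("unknown function class(es): %s (allowed: %s)",
                       paste(bad_fn, collapse = ", "),
                       paste(FUNCTION_CLASSES, collapse = ", ")),
               "cpgx_validation_error")
  }
  if (!"copy_number" %in% names(alleles) || all(is.na(alleles$copy_number))) {
    alleles$copy_number <- parse_copy_number(alleles$allele)
  } else {
    miss <- is.na(alleles$copy_number)
    alleles$copy_number[miss] <- parse_copy_number(alleles$allele[miss])
  }
  alleles$copy_number <- as.integer(alleles$copy_number)
  if (any(alleles$copy_number < 1L)) {
    cpgx_abort("copy_number must be >= 1", "cpgx_validation_error")
  }
  if (any(alleles$copy_number > 2L)) {
    rlang::warn(sprintf("%s: copy number above 2 for allele(s) %s", gene,
                        paste(alleles$allele[alleles$copy_number > 2L],
                              collapse = ", ")))
  }
  defined <- unique(unlist(alleles$defining_variants))
  if (is.null(known_variants)) {
    known_variants <- defined
  } else {
    known_variants <- unique(trimws(as.character(known_variants)))
    known_variants <- known_variants[nzchar(known_variants)]
    orphan <- setdiff(defined, known_variants)
    if (length(orphan)) {
      cpgx_abort(sprintf(
        "%s: defining variant(s) absent from known_variants: %s",
        gene, paste(orphan, collapse = ", ")), "cpgx_validation_error")
    }
  }
  structure(
    list(gene = gene, alleles = alleles, known_variants = known_variants),
    class = "gene_model"
  )
}

split_variants <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), trimws)
}

# "xN" suffix convention for structural duplications; N capped at 4.
parse_copy_number <- function(allele) {
  m <- regmatches(allele, regexpr("x([0-9]+)$", allele))
  cn <- rep(1L, length(allele))
  has <- lengths(regmatches(allele, gregexpr("x[0-9]+$", allele))) > 0
  cn[has] <- as.integer(sub("^x", "", m))
  if (any(cn > 4L)) {
    cpgx_abort("copy number above 4 is not supported", "cpgx_validation_error")
  }
  cn
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d alleles, %d known variants\n",
              x$gene, nrow(x$alleles), length(x$known_variants)))
  invisible(x)
}

#' @export
format.gene_model <- function(x, ...) {
  sprintf("<gene_model %s>", x$gene)
}

model_allele <- function(model, name) {
  i <- match(name, model$alleles$allele)
  if (is.na(i)) {
    cpgx_abort(sprintf("allele %s not in %s model", name, model$gene),
               "cpgx_unknown_allele")
  }
  model$alleles[i, ]
}

#' Reference alleles of a gene model
#'
#' Alleles with an empty defining-variant set; a targeted assay calls these
#' by default when none of its targeted variants is observed.
#'
#' @param model A [gene_model()].
#' @return Character vector of allele names.
#' @export
reference_alleles <- function(model) {
  model$alleles$allele[lengths(model$alleles$defining_variants) == 0L]
}

#' Canonical diplotype identifier
#'
#' Diplotypes are unordered pairs of star alleles; the canonical form sorts
#' the two allele names lexicographically and joins them with `/`, so
#' `diplotype("*2", "*1")` and `diplotype("*1", "*2")` are the same string
#' and hash, look up, and serialize identically.
#'
#' @param a1,a2 Star-allele names.
#' @return Canonical `"A/B"` identifier (vectorized).
#' @export
diplotype <- function(a1, a2) {
  swap <- a2 < a1
  lo <- ifelse(swap, a2, a1)
  hi <- ifelse(swap, a1, a2)
  paste(lo, hi, sep = "/")
}

#' @rdname diplotype
#' @param id A diplotype identifier such as `"*1/*2"` (canonical or not).
#' @return `diplotype_alleles()`: length-2 character vector of allele names.
#' @export
diplotype_alleles <- function(id) {
  parts <- strsplit(id, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    cpgx_abort(sprintf("malformed diplotype identifier: %s", id),
               "cpgx_format_error")
  }
  trimws(parts)
}

#' @rdname diplotype
#' @export
canonical_diplotype <- function(id) {
  vapply(id, function(d) {
    p <- diplotype_alleles(d)
    diplotype(p[1], p[2])
  }, character(1), USE.NAMES = FALSE)
}

#' All diplotypes of a gene model
#'
#' @param model A [gene_model()].
#' @return Character vector of canonical diplotype identifiers, all unordered
#'   pairs (with replacement) of the model's alleles.
#' @export
all_diplotypes <- function(model) {
  a <- sort(model$alleles$allele)
  n <- length(a)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  diplotype(a[idx[, 1]], a[idx[, 2]])
}
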