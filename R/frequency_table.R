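#' Construct a population frequency table
#'
#' Holds star-allele (haplotype) or diplotype frequencies for one gene across
#' populations, in the PharmGKB layout: one row per allele or diplotype, one
#' column per population. Blank cells are missing data, never zero — PharmGKB
#' omits frequencies it has no evidence for, and a population with no entries
#' at all is flagged missing rather than silently contributing zeros.
#'
#' @param gene Gene symbol.
#' @param data Data frame with an `identifier` column (allele name, or
#'   `"A/B"` diplotype) followed by one numeric column per population;
#'   `NA` marks a missing frequency.
#' @param level `"haplotype"` or `"diplotype"`.
#' @param sum_tolerance Per-population frequency sums may exceed 1 by at most
#'   this amount; sums below 1 are accepted (rare alleles are often omitted).
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(gene, data, level = c("haplotype", "diplotype"),
                       sum_tolerance = 1e-6) {
  level <- match.arg(level)
  data <- tibble::as_tibble(data)
  if (!"identifier" %in% names(data)) {
    cpgx_abort("frequency data needs an `identifier` column",
               "cpgx_format_error")
  }
  pops <- setdiff(names(data), "identifier")
  if (!length(pops)) {
    cpgx_abort("frequency data needs at least one population column",
               "cpgx_format_error")
  }
  data$identifier <- trimws(as.character(data$identifier))
  if (level == "diplotype") {
    data$identifier <- canonical_diplotype(data$identifier)
  }
  if (anyDuplicated(data$identifier)) {
    dup <- unique(data$identifier[duplicated(data$identifier)])
    cpgx_abort(sprintf("duplicate identifier(s): %s",
                       paste(dup, collapse = ", ")), "cpgx_validation_error")
  }
  for (p in pops) {
    v <- as.numeric(data[[p]])
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      bad <- data$identifier[which(v < 0 | v > 1)[1]]
      cpgx_abort(sprintf("frequency outside [0,1] in population %s (%s)",
                         p, bad), "cpgx_validation_error")
    }
    s <- sum(v, na.rm = TRUE)
    if (s > 1 + sum_tolerance) {
      cpgx_abort(sprintf("population %s frequencies sum to %.6f > 1", p, s),
                 "cpgx_validation_error")
    }
    data[[p]] <- v
  }
  structure(
    list(gene = gene, level = level, data = data, populations = pops),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  miss <- missing_populations(x)
  cat(sprintf("<freq_table> %s (%s level): %d identifiers x %d populations%s\n",
              x$gene, x$level, nrow(x$data), length(x$populations),
              if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", "))
              else ""))
  invisible(x)
}

#' Populations with no frequency data
#'
#' @param table A [freq_table()].
#' @return Character vector of population labels whose column is entirely
#'   missing. Such populations are reported as `NA` downstream and excluded
#'   from averages (never imputed to zero).
#' @export
missing_populations <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  table$populations[vapply(table$populations,
                           function(p) all(is.na(table$data[[p]])),
                           logical(1))]
}

population_frequencies <- function(table, population) {
  if (!population %in% table$populations) {
    cpgx_abort(sprintf("population %s not in table for %s",
                       population, table$gene), "cpgx_missing_population")
  }
  if (population %in% missing_populations(table)) {
    cpgx_abort(sprintf("population %s has no frequency data for %s",
                       population, table$gene), "cpgx_missing_population")
  }
  stats::setNames(table$data[[population]], table$data$identifier)
}

#' Expand haplotype frequencies to diplotype frequencies under HWE
#'
#' Under Hardy-Weinberg equilibrium a diplotype's frequency is `p^2` for a
#' homozygote and `2 p q` for a heterozygote. PharmGKB publishes precomputed
#' diplotype tables for the CYPs; this expansion serves haplotype-only and
#' simulated inputs, producing a diplotype-level table whose per-population
#' totals equal (the square of) the input totals.
#'
#' @param haps A haplotype-level [freq_table()].
#' @param renormalize If `TRUE`, per-population haplotype frequencies are
#'   rescaled to sum to 1 before expansion. If `FALSE` (default), sums must
#'   already be within `tol` of 1.
#' @param tol Tolerance on the per-population haplotype sum.
#' @return A diplotype-level [freq_table()]. Missing populations stay
#'   missing.
#' @export
hwe_expand <- function(haps, renormalize = FALSE, tol = 1e-6) {
  stopifnot(inherits(haps, "freq_table"))
  if (haps$level != "haplotype") {
    cpgx_abort("hwe_expand() needs a haplotype-level table",
               "cpgx_validation_error")
  }
  alleles <- haps$data$identifier
  n <- length(alleles)
  ord <- order(alleles)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ord[idx[, 1]]; j <- ord[idx[, 2]]
  out <- tibble::tibble(identifier = diplotype(alleles[i], alleles[j]))
  miss <- missing_populations(haps)
  for (pop in haps$populations) {
    if (pop %in% miss) {
      out[[pop]] <- NA_real_
      next
    }
    p <- haps$data[[pop]]
    if (anyNA(p)) {
      cpgx_abort(sprintf(
        "population %s has partially missing haplotype frequencies; cannot expand",
        pop), "cpgx_validation_error")
    }
    s <- sum(p)
    if (abs(s - 1) > tol) {
      if (!renormalize) {
        cpgx_abort(sprintf(
          "population %s haplotype frequencies sum to %.6f, not 1; set renormalize = TRUE",
          pop, s), "cpgx_validation_error")
      }
      p <- p / s
    }
    out[[pop]] <- ifelse(i == j, p[i]^2, 2 * p[i] * p[j])
  }
  freq_table(haps$gene, out, level = "diplotype")
}
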