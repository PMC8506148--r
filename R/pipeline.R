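#' Run the full panel-evaluation pipeline from files
#'
#' Reads a gene-model TSV, frequency TSV, panel JSON and rule JSON, runs
#' [evaluate_panels()], and writes the results table, per-(gene,
#' population) and per-test summaries, one detection-rate heatmap per gene
#' and an altered-prevalence chart into `out_dir`. Any stage failure raises
#' a stage-named condition and removes files written in this run.
#'
#' @param genes Path to the gene-model TSV.
#' @param freq Path to the frequency TSV.
#' @param panels Path to the panel JSON.
#' @param rules Path to the rule JSON (defaults to the shipped
#'   CPIC-derived Table of altered phenotypes, [cpic_altered_rules()]).
#' @param out_dir Output directory (created if needed).
#' @param known_variants Optional companion known-variant file.
#' @param translation Optional translation TSV; defaults to
#'   [default_translation()].
#' @param level Level of the frequency table (`"haplotype"` tables are
#'   expanded under HWE).
#' @param renormalize Rescale haplotype frequencies to sum to 1 before
#'   expansion.
#' @param missing_as_zero Render missing populations as zero in the
#'   prevalence chart (compatibility mode); they stay excluded from all
#'   averages.
#' @param match Allele detectability mode, see [is_detectable()].
#' @param digits Decimal places for percentages in written tables.
#' @param plots Also render heatmaps and the prevalence chart.
#' @return The `detection_matrix`, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(genes, freq, panels, rules = NULL, out_dir,
                         known_variants = NULL, translation = NULL,
                         level = c("haplotype", "diplotype"),
                         renormalize = FALSE, missing_as_zero = FALSE,
                         match = "all", digits = 1, plots = TRUE) {
  level <- match.arg(level)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cpgx_abort(sprintf("[%s] %s", name, conditionMessage(e)),
                 "cpgx_stage_error")
    })
  }
  models <- stage("read_gene_model", {
    m <- read_gene_model(genes, known_variants_path = known_variants)
    if (inherits(m, "gene_model")) stats::setNames(list(m), m$gene) else m
  })
  tables <- stage("read_frequency_table", {
    t <- read_frequency_table(freq, level = level)
    if (inherits(t, "freq_table")) stats::setNames(list(t), t$gene) else t
  })
  panel_list <- stage("read_panels", read_panels(panels, models = models))
  ruleset <- stage("read_rules", {
    if (is.null(rules)) cpic_altered_rules() else read_rules(rules)
  })
  lookup <- stage("read_translation", {
    if (is.null(translation)) default_translation() else read_translation(translation)
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    matrix <- stage("evaluate_panels",
                    evaluate_panels(panel_list, models, tables, ruleset,
                                    lookup = lookup, match = match,
                                    renormalize = renormalize))
    f_results <- file.path(out_dir, "detection_results.tsv")
    write_results(matrix, f_results, digits = digits)
    written <- c(written, f_results)

    sum_gp <- summarize_detection(matrix, by = c("gene", "population"))
    f_gp <- file.path(out_dir, "summary_gene_population.tsv")
    readr::write_tsv(round_numeric(sum_gp, digits), f_gp, na = "NA")
    written <- c(written, f_gp)

    sum_test <- summarize_detection(matrix, by = c("test", "gene"))
    f_t <- file.path(out_dir, "summary_test_gene.tsv")
    readr::write_tsv(round_numeric(sum_test, digits), f_t, na = "NA")
    written <- c(written, f_t)

    n_missing <- sum(matrix$status == "missing_population")
    n_undef <- sum(matrix$status == "undefined")
    message(sprintf(
      "evaluated %d tests x %d genes x %d populations: %d rows (%d undefined, %d missing-population)",
      length(panel_list), length(models),
      length(unique(matrix$population)), nrow(matrix), n_undef, n_missing))

    if (plots) {
      for (g in names(models)) {
        if (!any(matrix$gene == g & matrix$status == "ok")) next
        base <- file.path(out_dir, sprintf("heatmap_%s", g))
        render_heatmap(matrix, g, paste0(base, ".png"))
        render_heatmap(matrix, g, paste0(base, ".svg"))
        written <- c(written, paste0(base, c(".png", ".svg")))
      }
      f_prev <- file.path(out_dir, "altered_prevalence.png")
      render_prevalence_chart(tables, models, ruleset, f_prev,
                              lookup = lookup, renormalize = renormalize,
                              missing_as_zero = missing_as_zero)
      written <- c(written, f_prev)
    }
    invisible(matrix)
  }, error = on_fail_cleanup)
}

round_numeric <- function(df, digits) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}
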