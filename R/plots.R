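#' Detection-rate heatmap with coverage bars
#'
#' One gene's detection matrix as a tests-by-populations heatmap on a
#' diverging blue-to-red scale anchored at 0-100 (bright red = high
#' detection rate, dark blue = low; the anchoring is fixed, not
#' data-scaled, so panels are comparable across genes), with an adjacent
#' horizontal bar panel giving each test's coverage percentage. Cells with
#' no defined rate (undefined, missing population, not applicable) are
#' drawn grey and labelled `NA`. Tier allele sets evaluated as panels
#' appear as ordinary rows.
#'
#' @param matrix A `detection_matrix` from [evaluate_panels()].
#' @param gene Gene symbol to plot.
#' @param path Output path; the device is chosen from the extension
#'   (`.png` or `.svg`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(matrix, gene, path, width = 9, height = 5) {
  sub <- matrix[matrix$gene == gene & matrix$status != "not_applicable", ]
  if (!nrow(sub) || !any(sub$status == "ok")) {
    cpgx_abort(sprintf("no defined detection-rate cells for %s", gene),
               "cpgx_validation_error")
  }
  sub$test <- factor(sub$test, levels = rev(sort(unique(sub$test))))
  sub$label <- ifelse(is.na(sub$detection_rate_pct), "NA",
                      sprintf("%.0f", sub$detection_rate_pct))
  hm <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$population, y = .data$test,
                                          fill = .data$detection_rate_pct)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", midpoint = 50,
                                  limits = c(0, 100), na.value = "grey80",
                                  name = "Detection\nrate (%)") +
    ggplot2::labs(title = sprintf("%s detection rate", gene),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
  cov <- unique(sub[sub$status != "missing_population" | !is.na(sub$coverage_pct),
                    c("test", "coverage_pct")])
  cov <- cov[!is.na(cov$coverage_pct), ]
  cov <- cov[!duplicated(cov$test), ]
  bars <- ggplot2::ggplot(cov, ggplot2::aes(x = .data$coverage_pct, y = .data$test)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Coverage (%)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  p <- patchwork::wrap_plots(hm, bars, widths = c(4, 1))
  save_figure(p, path, width, height)
}

#' Altered-metabolizer prevalence chart
#'
#' Grouped bars of the population altered-metabolizer frequency per gene
#' and population, the prevalence view of the pipeline's denominator.
#' Missing populations are annotated with `*` at zero height when
#' `missing_as_zero = TRUE` (compatibility rendering), or omitted from the
#' chart otherwise.
#'
#' @param tables Named list of [freq_table()]s (haplotype tables are
#'   expanded under HWE).
#' @param models Named list of [gene_model()]s.
#' @param rules A [phenotype_ruleset()].
#' @param path Output path (`.png` or `.svg`).
#' @param lookup Optional [translation_lookup()].
#' @param renormalize Passed to [hwe_expand()].
#' @param missing_as_zero Draw missing populations as annotated zeros.
#' @param width,height Device size in inches.
#' @return Invisibly, the plotted data (gene, population,
#'   altered_frequency, missing flag).
#' @export
render_prevalence_chart <- function(tables, models, rules, path, lookup = NULL,
                                    renormalize = FALSE,
                                    missing_as_zero = FALSE,
                                    width = 8, height = 4.5) {
  prev <- altered_prevalence(tables, models, rules, lookup = lookup,
                             renormalize = renormalize)
  dat <- prev
  if (!missing_as_zero) {
    dat <- dat[!dat$missing, ]
  } else {
    dat$altered_frequency[dat$missing] <- 0
  }
  if (!nrow(dat)) {
    cpgx_abort("no classifiable populations to plot", "cpgx_validation_error")
  }
  dat$pct <- 100 * dat$altered_frequency
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$population, y = .data$pct,
                                         fill = .data$population)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(
      data = dat[dat$missing, ],
      ggplot2::aes(label = "*"), y = 1, size = 5, na.rm = TRUE) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = NULL, y = "Altered metabolizers (%)") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  save_figure(p, path, width, height)
  invisible(prev)
}

#' Altered-metabolizer prevalence table
#'
#' @inheritParams render_prevalence_chart
#' @return Tibble with `gene`, `population`, `altered_frequency` (`NA` for
#'   missing populations) and `missing`.
#' @export
altered_prevalence <- function(tables, models, rules, lookup = NULL,
                               renormalize = FALSE) {
  rows <- list()
  for (g in names(tables)) {
    tab <- tables[[g]]
    if (tab$level == "haplotype") tab <- hwe_expand(tab, renormalize = renormalize)
    altered <- altered_diplotype_set(tab, models[[g]], rules, lookup)
    miss <- missing_populations(tab)
    for (pop in tab$populations) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, population = pop,
        altered_frequency = if (pop %in% miss) NA_real_
                            else population_altered_frequency(tab, altered, pop),
        missing = pop %in% miss)
    }
  }
  dplyr::bind_rows(rows)
}

save_figure <- function(p, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg")) {
    cpgx_abort(sprintf("unsupported figure format: .%s (use .png or .svg)", ext),
               "cpgx_io_error")
  }
  if (ext == "svg" && !capabilities("cairo")) {
    # svglite is not a dependency; cairo-less builds fall back to png
    path <- sub("\\.svg$", ".png", path, ignore.case = TRUE)
    ext <- "png"
  }
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
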