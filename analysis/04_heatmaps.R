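#!/usr/bin/env Rscript
# Detection-rate heatmaps (tests x populations, blue-red anchored 0-100)
# with adjacent coverage-percentage bars, one figure per gene.

suppressPackageStartupMessages(library(cpgxeval))

mx <- read_results("results/detection_results.tsv")
for (g in unique(mx$gene)) {
  if (!any(mx$gene == g & mx$status == "ok")) next
  render_heatmap(mx, g, sprintf("results/heatmap_%s.png", g))
  cat(sprintf("wrote results/heatmap_%s.png\n", g))
}
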