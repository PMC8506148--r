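#!/usr/bin/env Rscript
# Build a synthetic five-gene, nine-population study bundle: gene models,
# haplotype frequency tables, fourteen multi-gene assay panels spanning low
# to high coverage, and two recommended-allele "tier" panels. All files go
# to results/inputs/ in the exact dialects the package readers consume.

suppressPackageStartupMessages(library(cpgxeval))

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20210928L %% 10000L  # fixed study seed

genes <- paste0("CYPSIM", 1:5)
cfgs <- list(
  sim_config(seed + 1L, n_alleles = 5, reference_mass = 0.45, gene = genes[1]),
  sim_config(seed + 2L, n_alleles = 6, reference_mass = 0.50, gene = genes[2]),
  sim_config(seed + 3L, n_alleles = 4, reference_mass = 0.70, gene = genes[3]),
  sim_config(seed + 4L, n_alleles = 7, reference_mass = 0.60, gene = genes[4]),
  sim_config(seed + 5L, n_alleles = 3, reference_mass = 0.55, gene = genes[5])
)
models <- lapply(cfgs, simulate_gene_model)
names(models) <- genes
tables <- Map(simulate_population_frequencies, models, cfgs)
names(tables) <- genes

# 14 assays: per gene, a sweep of coverage targets; some assays omit the
# small genes, as real CPGx menus do.
n_tests <- 14L
targets <- withr::with_seed(seed, {
  lapply(genes, function(g) round(runif(n_tests, 5, 75)))
})
names(targets) <- genes
omit <- withr::with_seed(seed + 10L, {
  lapply(genes, function(g) sample(c(rep(FALSE, 10), rep(TRUE, 4))))
})
names(omit) <- genes

panels <- lapply(seq_len(n_tests), function(j) {
  tg <- list()
  for (g in genes) {
    if (omit[[g]][j]) next
    p <- simulate_panels(models[[g]], targets[[g]][j], cfgs[[match(g, genes)]])
    tg[[g]] <- p[[1]]$targets[[g]]
  }
  test_panel(sprintf("assay_%02d", j), tg, lab = "simulated")
})

# Tier panels: defining variants of the most frequent non-reference alleles
# (top 2 = tier 1, top 4 = tier 2), averaged across populations.
tier_panel <- function(name, top_n) {
  tg <- lapply(genes, function(g) {
    t <- tables[[g]]
    mean_f <- rowMeans(as.matrix(t$data[t$data$identifier != "*1",
                                        t$populations]))
    top <- t$data$identifier[t$data$identifier != "*1"][
      order(mean_f, decreasing = TRUE)][seq_len(min(top_n, length(mean_f)))]
    unique(unlist(lapply(top, function(a) {
      models[[g]]$alleles$defining_variants[[
        match(a, models[[g]]$alleles$allele)]]
    })))
  })
  names(tg) <- genes
  test_panel(name, tg[lengths(tg) > 0], lab = "recommendation")
}
panels <- c(panels, list(tier_panel("Tier1", 2L), tier_panel("Tier2", 4L)))

rules <- phenotype_ruleset(stats::setNames(
  replicate(5, rule_activity_interval(2), simplify = FALSE), genes))

write_gene_model(models, file.path(out_dir, "gene_models.tsv"),
                 file.path(out_dir, "known_variants.tsv"))
write_frequency_table(tables, file.path(out_dir, "frequencies.tsv"))
write_panels(panels, file.path(out_dir, "panels.json"))
write_rules(rules, file.path(out_dir, "rules.json"))

cat(sprintf("simulated %d genes (%s alleles), %d panels, 9 populations -> %s\n",
            length(genes),
            paste(vapply(models, function(m) nrow(m$alleles), integer(1)),
                  collapse = "/"),
            length(panels), out_dir))
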