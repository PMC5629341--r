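#!/usr/bin/env Rscript
# Chromosomal landscape of the novel calls: densities per Mbp, genic
# category table, euchromatin (Fisher) and genic (hypergeometric)
# enrichment, and the matched-random-locus permutation test of
# window-count variance. The toy genome is two 250-kb chromosomes, so
# windows are scaled to 50 kb span / 5 kb step (the same 10:1 ratio the
# megabase-scale analysis uses).

suppressMessages(library(onsenscan))
dir.create("results", showWarnings = FALSE)
set.seed(43)
st <- readRDS("scratch/sim/state.rds")
part <- readRDS("scratch/sim/partition.rds")
calls <- read_calls("results/calls.tsv")
novel <- calls[calls$status == "novel", ]

dens <- insertion_density(novel, chrom_lengths(st$gen$genome))
utils::write.table(dens, "results/landscape_density.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("densities (insertions/Mbp):\n")
print(dens[, c("chrom", "count", "density_1dp")])

cats <- classify_insertions(novel, st$gen$annot)
tab <- category_table(cats)
utils::write.table(
  data.frame(category = names(tab$counts), count = as.integer(tab$counts),
             percent = as.numeric(tab$percent)),
  "results/landscape_categories.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("category counts:\n"); print(tab$counts)
cat("cumulative genic %:", tab$cumulative_genic, "\n")

## enrichment of insertions in euchromatin (counts vs Mbp per class)
eu_n <- sum(GenomicRanges::countOverlaps(
  GenomicRanges::GRanges(novel$chrom,
                         IRanges::IRanges(novel$start, novel$start)),
  part$eu) > 0)
sizes <- class_sizes(part)
fis <- fisher_exact_2x2(matrix(c(eu_n, nrow(novel) - eu_n,
                                 round(sizes["eu"]) + 1,
                                 round(sizes["het"]) + 1), 2))
cat("euchromatin enrichment: ", eu_n, "of", nrow(novel),
    "in euchromatin; Fisher p =", signif(fis$p, 3), "\n")

## genic enrichment against the annotated gene space
genic_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(
  st$gen$annot$genes, ignore.strand = TRUE)))
genic_cats <- c("utr5", "exon", "intron", "utr3")
n_genic <- sum(as.character(cats) %in% genic_cats)
hyp <- genic_enrichment_hypergeom(n_genic, nrow(novel), genic_bp,
                                  sum(chrom_lengths(st$gen$genome)))
cat("genic enrichment:", n_genic, "of", nrow(novel),
    "in transcribed space (", round(genic_bp / 1e3), "kb );",
    "hypergeometric p =", signif(hyp$p, 3), "\n")

## permutation test of window-count variance (scaled windows)
pt <- permutation_variance_test(novel, part$eu, n_perm = 1000,
                                window = 5e4, step = 5e3)
cat("window-count variance:", round(pt$observed, 3),
    "; gamma(shape =", round(pt$shape, 2), ", scale =",
    round(pt$scale, 3), "); p =", signif(pt$p, 3),
    "(empirical", signif(pt$p_empirical, 3), ")\n")
stats_tab <- data.frame(
  test = c("fisher_euchromatin", "hypergeom_genic", "permutation_variance"),
  statistic = c(fis$odds_ratio, NA, pt$observed),
  p = c(fis$p, hyp$p, pt$p))
utils::write.table(stats_tab, "results/landscape_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
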