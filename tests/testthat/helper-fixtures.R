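# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# One full detection replicate at benchmark scale (30 planted insertions,
# 30x, 5-bp TSD), with all intermediate objects kept.
det_fixture <- function() {
  memo("det", function() {
    bm <- detection_benchmark(seeds = 101L, keep_last = TRUE)
    bm$last$summary <- bm$per_seed
    bm$last
  })
}

# A small euchromatin partition used by permutation-test checks:
# three 4-Mb chromosomes, central 0.6-Mb heterochromatin gap.
toy_euchromatin <- function() {
  eu <- GenomicRanges::GRanges(
    rep(paste0("chr", 1:3), 2),
    IRanges::IRanges(rep(c(1L, 2300001L), each = 3),
                     rep(c(1700000L, 4000000L), each = 3)))
  GenomicRanges::sort(eu)
}

# A hand-sized annotation: two genes on chr1 and one TE feature.
#   GENE_A: + strand 1001..2900 (utr5 1001-1200, exons 1201-1600/1751-2150/
#           2301-2700 with introns between, utr3 2701-2900)
#   GENE_B: - strand 8001..9900, mirrored layout
#   TE_1:   12001..13000
toy_annotation <- function() {
  g <- function(chrom, s, e, strand, id) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                 strand = strand)
    S4Vectors::mcols(gr)$gene_id <- id
    gr
  }
  genes <- c(g("chr1", 1001, 2900, "+", "GENE_A"),
             g("chr1", 8001, 9900, "-", "GENE_B"))
  exons <- c(g("chr1", 1201, 1600, "+", "GENE_A"),
             g("chr1", 1751, 2150, "+", "GENE_A"),
             g("chr1", 2301, 2700, "+", "GENE_A"),
             g("chr1", 8201, 8600, "-", "GENE_B"),
             g("chr1", 8751, 9150, "-", "GENE_B"),
             g("chr1", 9301, 9700, "-", "GENE_B"))
  utr5 <- c(g("chr1", 1001, 1200, "+", "GENE_A"),
            g("chr1", 9701, 9900, "-", "GENE_B"))
  utr3 <- c(g("chr1", 2701, 2900, "+", "GENE_A"),
            g("chr1", 8001, 8200, "-", "GENE_B"))
  te <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12001, 13000))
  S4Vectors::mcols(te)$te_id <- "TE_1"
  S4Vectors::mcols(te)$family <- "SYN"
  annotation_model(genes, exons, utr5 = utr5, utr3 = utr3, te = te)
}

# Brute-force two-sided Fisher p by hypergeometric enumeration:
# sum of P(tables with the observed margins) over tables no more
# probable than the observed one.
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
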