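test_that("LTR identity holds for every generated consensus", {
  for (seed in 1:10) {
    set.seed(seed)
    te <- build_te_consensus(element_len = 5000, ltr_len = 400)
    expect_identical(substr(te$seq, 1, 400), substr(te$seq, 4601, 5000))
    expect_identical(te$ltr_seq, substr(te$seq, 1, 400))
  }
  set.seed(1)
  tiny <- build_te_consensus(element_len = 5, ltr_len = 1)
  expect_identical(substr(tiny$seq, 1, 1), substr(tiny$seq, 5, 5))
  set.seed(1); a <- build_te_consensus(1000, 100)
  set.seed(2); b <- build_te_consensus(1000, 100)
  expect_false(identical(a$seq, b$seq))
  expect_error(build_te_consensus(100, 50))
})

test_that("toy genomes respect the heterochromatin fraction and are reproducible", {
  cfg <- sim_config(n_chrom = 5, chrom_len = 400e3, het_fraction = 0.15,
                    n_te_copies = 0)
  set.seed(5)
  g1 <- build_toy_genome(cfg)
  expect_equal(sum(GenomicRanges::width(g1$het)), 5 * 60e3, tolerance = 1e-4)
  set.seed(5)
  g2 <- build_toy_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  cfg0 <- sim_config(n_chrom = 2, chrom_len = 100e3, het_fraction = 0,
                     n_te_copies = 0)
  set.seed(5)
  g0 <- build_toy_genome(cfg0)
  expect_equal(length(g0$het), 0L)

  expect_error(build_toy_genome(sim_config(gene_density = 1/1000,
                                           n_te_copies = 0)),
               "density incompatible")
})

test_that("planting adds element + TSD to the chromosome length and biases into genes", {
  cfg <- sim_config(n_chrom = 2, chrom_len = 120e3, n_te_copies = 0,
                    n_insertions = 4, element_len = 1000, ltr_len = 100,
                    min_spacing = 3000)
  set.seed(9)
  te <- build_te_consensus(1000, 100)
  gen <- build_toy_genome(cfg, te)

  cfg0 <- cfg; cfg0$tsd_len <- 0L
  set.seed(10)
  p0 <- plant_insertions(gen$genome, gen$annot, te, cfg0)
  expect_equal(sum(chrom_lengths(p0$genome)) - sum(chrom_lengths(gen$genome)),
               4 * 1000)
  set.seed(10)
  p5 <- plant_insertions(gen$genome, gen$annot, te, cfg)
  expect_equal(sum(chrom_lengths(p5$genome)) - sum(chrom_lengths(gen$genome)),
               4 * (1000 + 5))

  ## the TSD is duplicated around the element
  tr <- p5$truth[1, ]
  ref <- as.character(gen$genome[[tr$chrom]])
  mutseq <- as.character(p5$genome[[tr$chrom]])
  off <- sum(p5$truth$point < tr$point & p5$truth$chrom == tr$chrom) * 1005
  tsd <- substr(ref, tr$point + 1, tr$point + 5)
  expect_identical(substr(mutseq, tr$point + off + 1, tr$point + off + 5), tsd)
  expect_identical(substr(mutseq, tr$point + off + 1006, tr$point + off + 1010),
                   tsd)

  ## genic bias: 100 insertions at bias 0.9 land in genes ~90% of the time
  cfgb <- sim_config(n_chrom = 2, chrom_len = 400e3, n_te_copies = 0,
                     n_insertions = 100, element_len = 1000, ltr_len = 100,
                     genic_bias = 0.9, min_spacing = 1500)
  set.seed(11)
  genb <- build_toy_genome(cfgb, te)
  pb <- plant_insertions(genb$genome, genb$annot, te, cfgb)
  expect_gt(mean(pb$truth$genic), 0.80)
  expect_lt(mean(pb$truth$genic), 0.98)
})

test_that("alignment simulation yields no unmapped reads for a TE-free genome", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 50e3, n_te_copies = 0,
                    n_insertions = 0, error_rate = 0, coverage = 10)
  set.seed(21)
  te <- build_te_consensus(1000, 100)
  gen <- build_toy_genome(cfg, te)
  pl <- plant_insertions(gen$genome, gen$annot, te, cfg)
  aln <- simulate_alignments(pl$genome, gen$genome, te, cfg, pl$truth,
                             gen$te_copies)
  expect_gt(nrow(aln), 0)
  expect_true(all(aln$mapped))
  ## coverage 0 gives empty output, not an error
  cfg0 <- cfg; cfg0$coverage <- 0
  aln0 <- simulate_alignments(pl$genome, gen$genome, te, cfg0, pl$truth,
                              gen$te_copies)
  expect_equal(nrow(aln0), 0L)
})

test_that("a planted insertion produces both discordant and junction evidence", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 60e3, n_te_copies = 0,
                    n_insertions = 1, coverage = 30, error_rate = 0)
  set.seed(22)
  te <- build_te_consensus(cfg$element_len, cfg$ltr_len)
  gen <- build_toy_genome(cfg, te)
  pl <- plant_insertions(gen$genome, gen$annot, te, cfg)
  aln <- simulate_alignments(pl$genome, gen$genome, te, cfg, pl$truth,
                             gen$te_copies)
  disc <- find_discordant_candidates(aln, te)
  frag <- find_junction_fragments(aln[!aln$mapped, c("qname", "seq")], te)
  junc <- remap_fragments(frag, gen$genome)
  p <- pl$truth$point[1]
  expect_gte(sum(abs((disc$start + disc$end) / 2 - p) < 1000), 2)
  expect_gte(sum(abs(junc$junction - p) <= 10), 1)

  set.seed(22)
  te2 <- build_te_consensus(cfg$element_len, cfg$ltr_len)
  gen2 <- build_toy_genome(cfg, te2)
  pl2 <- plant_insertions(gen2$genome, gen2$annot, te2, cfg)
  aln2 <- simulate_alignments(pl2$genome, gen2$genome, te2, cfg, pl2$truth,
                              gen2$te_copies)
  expect_identical(aln, aln2)   # fixed seed, identical alignments
})

test_that("the simulator's mapping rule equals exact unique search on the masked reference", {
  ## independent oracle: a mate is mapped iff its error-free sequence has a
  ## unique full-length exact match in the masked reference
  cfg <- sim_config(n_chrom = 1, chrom_len = 40e3, n_te_copies = 1,
                    n_insertions = 2, coverage = 4, error_rate = 0,
                    element_len = 1000, ltr_len = 100, min_spacing = 3000)
  set.seed(23)
  te <- build_te_consensus(1000, 100)
  gen <- build_toy_genome(cfg, te)
  pl <- plant_insertions(gen$genome, gen$annot, te, cfg)
  masked <- mask_te_copies(gen$genome, gen$te_copies)
  aln <- simulate_alignments(pl$genome, masked, te, cfg, pl$truth,
                             gen$te_copies)
  idx <- sample(nrow(aln), 300)
  for (i in idx) {
    s <- Biostrings::DNAString(aln$seq[i])
    hits <- Biostrings::countPattern(s, masked[[1]]) +
      Biostrings::countPattern(Biostrings::reverseComplement(s), masked[[1]])
    expect_equal(aln$mapped[i], hits == 1L,
                 info = paste("read", aln$qname[i], aln$mate[i]))
  }
})

test_that("every planted insertion carries the guaranteed evidence classes across seeds", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 60e3, n_te_copies = 0,
                    n_insertions = 2, coverage = 20, error_rate = 0.005,
                    min_spacing = 8000)
  for (seed in 1:20) {
    set.seed(seed)
    te <- build_te_consensus(cfg$element_len, cfg$ltr_len)
    gen <- build_toy_genome(cfg, te)
    pl <- plant_insertions(gen$genome, gen$annot, te, cfg)
    aln <- simulate_alignments(pl$genome, gen$genome, te, cfg, pl$truth,
                               gen$te_copies)
    disc <- find_discordant_candidates(aln, te)
    junc <- remap_fragments(
      find_junction_fragments(aln[!aln$mapped, c("qname", "seq")], te),
      gen$genome)
    for (p in pl$truth$point) {
      expect_gte(sum(abs((disc$start + disc$end) / 2 - p) < 1000), 2)
      expect_gte(sum(abs(junc$junction - p) <= 10), 1)
    }
  }
})

test_that("simulated chromatin tracks are two-level step functions at zero noise", {
  cfg <- sim_config(n_chrom = 2, chrom_len = 60e3, n_te_copies = 0)
  set.seed(31)
  gen <- build_toy_genome(cfg)
  tr <- simulate_h3k9me2_track(gen$het, gen$genome, 60, signal_high = 3,
                               signal_low = 0.5, noise_sd = 0)
  expect_setequal(unique(unlist(tr$values)), c(3, 0.5))
  ## equal levels leave nothing above any threshold beyond the level
  tr2 <- simulate_h3k9me2_track(gen$het, gen$genome, 60, signal_high = 1,
                                signal_low = 1, noise_sd = 0)
  part <- chromatin_partition(tr2, window_tiles = 100, threshold = 1.5)
  expect_equal(length(part$het), 0L)
})

test_that("count simulation is deterministic and null fold changes stay null", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 100e3, n_te_copies = 0,
                    n_insertions = 0)
  set.seed(41)
  gen <- build_toy_genome(cfg)
  truth <- data.frame(gene_id = character(0), genic = logical(0))
  set.seed(42)
  ct1 <- simulate_count_table(gen$annot, truth, fold_change = 1)
  set.seed(42)
  ct2 <- simulate_count_table(gen$annot, truth, fold_change = 1)
  expect_identical(ct1$counts, ct2$counts)

  de <- classify_de(naive_de(ct1$counts, ct1$samples))
  expect_lt(mean(de$status != "unchanged"), 0.1)
})
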