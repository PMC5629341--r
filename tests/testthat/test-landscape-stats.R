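test_that("per-chromosome insertion densities reproduce printed-table arithmetic", {
  lens <- tair10_chrom_lengths()
  calls <- data.frame(chrom = rep(names(lens), c(88, 58, 63, 59, 70)))
  d <- insertion_density(calls, lens)
  expect_equal(d$density_1dp[1:5], c(2.9, 2.9, 2.7, 3.2, 2.6))
  expect_equal(d$density_1dp[d$chrom == "total"], 2.8)
  expect_equal(d$count[d$chrom == "total"], 338L)

  d0 <- insertion_density(calls[0, , drop = FALSE], lens)
  expect_true(all(d0$density == 0))
  expect_error(insertion_density(calls, c(lens, Chr6 = 0L)), "zero-length")
})

test_that("insertion points classify by feature precedence and promoter distance", {
  ann <- toy_annotation()
  cl <- function(pos) as.character(classify_insertions(
    data.frame(chrom = "chr1", start = pos), ann))
  expect_equal(cl(1400), "exon")              # inside exon 1201-1600
  expect_equal(cl(1100), "utr5")
  expect_equal(cl(2800), "utr3")
  expect_equal(cl(1700), "intron")            # between exons 1 and 2
  expect_equal(cl(701), "promoter_lt500")     # 300 bp upstream of + TSS 1001
  expect_equal(cl(301), "promoter_500_1000")  # 700 bp upstream
  expect_equal(cl(5000), "intergenic_gt1000")
  expect_equal(cl(12500), "te")
  ## on the - strand gene the TSS is the right end (9900)
  expect_equal(cl(10200), "promoter_lt500")
  ## every call gets exactly one category (row-sum property)
  pts <- data.frame(chrom = "chr1", start = seq(101, 14000, by = 37))
  cats <- classify_insertions(pts, ann)
  expect_false(anyNA(cats))
  expect_equal(sum(table(cats)), nrow(pts))
})

test_that("synthetic truth classifies into the planted genic breakdown", {
  fx <- det_fixture()
  truth <- fx$plant$truth
  cats <- classify_insertions(
    data.frame(chrom = truth$chrom, start = truth$point + 1L),
    fx$gen$annot)
  genic_cats <- c("utr5", "exon", "intron", "utr3")
  expect_equal(as.character(cats) %in% genic_cats, truth$genic)
})

test_that("category tables report percentages and cumulative genic roll-ups", {
  counts <- c(promoter_500_1000 = 9, promoter_lt500 = 17, utr5 = 11,
              exon = 211, intron = 42, utr3 = 12, intergenic_gt1000 = 19,
              te = 17)
  tab <- category_table(counts)
  expect_equal(unname(tab$percent["exon"]), 62.4)
  expect_equal(unname(tab$percent["intron"]), 12.4)
  expect_equal(unname(tab$percent), c(2.7, 5.0, 3.3, 62.4, 12.4, 3.6, 5.6, 5.0))
  expect_equal(unname(tab$cumulative_genic), c(81.7, 86.7, 89.3))

  one <- factor(rep("exon", 12), levels = insertion_categories())
  t1 <- category_table(one)
  expect_equal(unname(t1$percent["exon"]), 100)
  expect_equal(sum(t1$percent), 100)
})

test_that("Fisher exact p-values equal full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 1, 1, 2), 2))$p,
               fisher_enum_p(matrix(c(2, 1, 1, 2), 2)))
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2))$p, 1)

  ## oracle sweep over random tables with N <= 40
  set.seed(71)
  for (i in 1:300) {
    n <- sample(40, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tab <- matrix(c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2],
                    n - cuts[3]), 2)
    expect_equal(fisher_exact_2x2(tab)$p, fisher_enum_p(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
})

test_that("hypergeometric genic enrichment matches a brute-force tail sum", {
  expect_equal(genic_enrichment_hypergeom(6, 6, 1000, 1000)$p, 1)
  ## 5 of 6 draws from a half-genic population
  p <- genic_enrichment_hypergeom(5, 6, 50, 100)$p
  brute <- sum(vapply(5:6, function(k)
    stats::dhyper(k, 50, 50, 6), 0))
  expect_equal(p, brute, tolerance = 1e-12)
  expect_lt(genic_enrichment_hypergeom(302, 338, 59.6e6, 119.15e6)$p, 1e-15)
})

test_that("matched locus sampling preserves counts and is uniform within euchromatin", {
  eu <- toy_euchromatin()
  expect_equal(nrow(sample_matched_loci(
    data.frame(chrom = character(0), start = integer(0), end = integer(0)),
    eu)), 0L)

  set.seed(72)
  calls <- data.frame(chrom = sample(paste0("chr", 1:3), 60, TRUE),
                      start = 5L, end = 9L)
  loci <- sample_matched_loci(calls, eu)
  expect_equal(table(loci$chrom), table(calls$chrom))
  expect_true(all(loci$end - loci$start == 4L))

  ## uniformity: 1e4 draws on one chromosome, chi-square over 20 bins
  one <- data.frame(chrom = rep("chr1", 1e4), start = 1L, end = 1L)
  s <- sample_matched_loci(one, eu)
  eu1 <- eu[as.character(GenomicRanges::seqnames(eu)) == "chr1"]
  offs <- rep(NA_real_, nrow(s))
  cum <- c(0, cumsum(GenomicRanges::width(eu1)))
  for (i in seq_along(eu1)) {
    in_i <- s$start >= GenomicRanges::start(eu1)[i] &
      s$start <= GenomicRanges::end(eu1)[i]
    offs[in_i] <- cum[i] + s$start[in_i] - GenomicRanges::start(eu1)[i]
  }
  expect_false(anyNA(offs))
  ct <- table(cut(offs, breaks = seq(0, cum[length(cum)], length.out = 21)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.001)
})

test_that("window-count variance equals direct computation and ignores order", {
  eu <- toy_euchromatin()
  w <- make_windows(eu, 1e6, 1e5)
  set.seed(73)
  loci <- data.frame(chrom = sample(paste0("chr", 1:3), 50, TRUE),
                     start = 1L, end = 1L)
  loci <- sample_matched_loci(loci, eu)
  v <- window_count_variance(loci, w)
  mid <- floor((loci$start + loci$end) / 2)
  counts <- vapply(seq_along(w), function(i) {
    ch <- as.character(GenomicRanges::seqnames(w))[i]
    sum(loci$chrom == ch & mid >= GenomicRanges::start(w)[i] &
          mid <= GenomicRanges::end(w)[i])
  }, 0L)
  expect_equal(v, mean((counts - mean(counts))^2))
  expect_equal(window_count_variance(loci[sample(nrow(loci)), ], w), v)
  ## one locus centered in each window of a disjoint tiling: variance 0
  ww <- make_windows(eu, 1e6, 1e6)
  eq <- data.frame(chrom = as.character(GenomicRanges::seqnames(ww)),
                   start = GenomicRanges::start(ww) + 5e5)
  eq$end <- eq$start
  expect_equal(window_count_variance(eq, ww), 0)
})

test_that("the binned permutation engine agrees with the generic counter", {
  eu <- toy_euchromatin()
  set.seed(74)
  calls <- sample_matched_loci(
    data.frame(chrom = sample(paste0("chr", 1:3), 40, TRUE),
               start = 1L, end = 1L), eu)
  w <- make_windows(eu, 1e6, 1e5)
  lay <- onsenscan:::binned_layout(eu, 1e6, 1e5)
  expect_false(is.null(lay))
  expect_equal(length(lay$win_first), length(w))
  ## binned counts of the observed calls equal countOverlaps counts
  mid <- calls$start
  iv_of_chr <- split(seq_along(lay$chr), lay$chr)
  bins <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    j <- iv_of_chr[[calls$chrom[i]]]
    k <- j[mid[i] >= lay$s[j] & mid[i] < lay$s[j] + lay$w[j]]
    bins[i] <- lay$off[k] + (mid[i] - lay$s[k]) %/% 1e5 + 1L
  }
  B <- tabulate(bins, lay$nbins)
  cs <- cumsum(c(0L, B))
  wc <- cs[lay$win_first + lay$K] - cs[lay$win_first]
  expect_equal(wc, unname(GenomicRanges::countOverlaps(
    w, GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(mid, mid)))))
})

test_that("the gamma tail fit is sane at the boundaries and under known gammas", {
  eu <- toy_euchromatin()
  set.seed(75)
  calls <- sample_matched_loci(
    data.frame(chrom = sample(paste0("chr", 1:3), 50, TRUE),
               start = 1L, end = 1L), eu)
  r <- permutation_variance_test(calls, eu, n_perm = 300)
  expect_true(r$p >= 0 && r$p <= 1)
  expect_gt(r$shape, 0)
  expect_gt(r$scale, 0)
  ## observed variance 0 sits at the lower support bound: upper tail 1
  expect_equal(stats::pgamma(0, r$shape, scale = r$scale,
                             lower.tail = FALSE), 1)
  ## gamma p and empirical tail agree when p is moderate
  if (r$p > 0.01)
    expect_lt(abs(r$p - r$p_empirical), 0.02 + 1e-9)

  ## moment matching recovers known gamma parameters within 10% at 1e5
  set.seed(76)
  x <- stats::rgamma(1e5, shape = 3.2, scale = 0.7)
  fit <- gamma_moment_fit(x)
  expect_lt(abs(fit["shape"] - 3.2) / 3.2, 0.10)
  expect_lt(abs(fit["scale"] - 0.7) / 0.7, 0.10)
})

test_that("KS distance matches an ECDF supremum oracle", {
  same <- c(1, 2, 3, 4.5, 7)
  r0 <- ks_distance_test(same, same)
  expect_equal(r0$D, 0)
  expect_equal(r0$p, 1)

  r1 <- ks_distance_test(1:30, 31:60)
  expect_equal(r1$D, 1)

  set.seed(77)
  x <- stats::rnorm(12); y <- stats::rnorm(15, 0.5)
  r <- ks_distance_test(x, y)
  grid <- sort(c(x, y))
  Fx <- vapply(grid, function(g) mean(x <= g), 0)
  Fy <- vapply(grid, function(g) mean(y <= g), 0)
  expect_equal(r$D, max(abs(Fx - Fy)), tolerance = 1e-12)
})

test_that("length-corrected chi-squared matches hand computation", {
  ## observation equals expectation exactly
  r0 <- length_corrected_chisq(rep(c("a", "b"), c(5, 5)),
                               all_gene_lengths = c(100, 100),
                               all_flags = c("a", "b"))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p, 1)
  ## toy: observed (8,2), expected (5,5): 1.8 + 1.8 = 3.6
  r <- length_corrected_chisq(rep(c("a", "b"), c(8, 2)),
                              all_gene_lengths = c(100, 100),
                              all_flags = c("a", "b"))
  expect_equal(unname(r$statistic), 3.6)
  ## invariant to class order
  r2 <- length_corrected_chisq(rep(c("b", "a"), c(2, 8)),
                               all_gene_lengths = c(50, 50),
                               all_flags = c("b", "a"))
  expect_equal(unname(r2$statistic), 3.6)
})
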