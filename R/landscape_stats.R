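## Statistical characterization of insertion positions: densities,
## euchromatin and genic enrichment, the eight-way genic category table,
## and the matched-random-locus permutation test of window-count variance
## with a gamma tail fit.

#' Canonical insertion category levels
#' @export
insertion_categories <- function() {
  c("promoter_500_1000", "promoter_lt500", "utr5", "exon", "intron",
    "utr3", "intergenic_gt1000", "te")
}

#' Insertions per Mbp, per chromosome and total
#'
#' @param calls Insertion-call data.frame (at least `chrom`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return A data.frame with one row per chromosome plus a `total` row:
#'   count, length_mbp, density (insertions/Mbp) and density_1dp as
#'   printed in summary tables.
#' @export
insertion_density <- function(calls, chrom_lengths) {
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  cnt <- table(factor(calls$chrom, levels = names(chrom_lengths)))
  df <- data.frame(chrom = names(chrom_lengths),
                   count = as.integer(cnt),
                   length_mbp = as.numeric(chrom_lengths) / 1e6)
  df <- rbind(df, data.frame(chrom = "total", count = nrow(calls),
                             length_mbp = sum(chrom_lengths) / 1e6))
  df$density <- df$count / df$length_mbp
  df$density_1dp <- round(df$density, 1)
  df
}

#' Classify an insertion point against the annotation
#'
#' Precedence: TE feature, then the most specific containing gene feature
#' (exon > 5'UTR > 3'UTR > intron), then promoter distance measured
#' upstream from the nearest gene's TSS on that gene's strand (< 500 bp,
#' then 500-1000 bp), else intergenic.
#'
#' @param calls Calls data.frame (`chrom`, `start` used as the insertion
#'   point).
#' @param annot `AnnotationModel`.
#' @param promoter_near,promoter_far Promoter distance cutoffs (bp).
#' @return Factor of categories (levels [insertion_categories()]), one per
#'   call.
#' @export
classify_insertions <- function(calls, annot, promoter_near = 500,
                                promoter_far = 1000) {
  pts <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$start))
  inside <- function(gr) GenomicRanges::countOverlaps(
    pts, gr, ignore.strand = TRUE) > 0
  cat <- rep(NA_character_, nrow(calls))
  hit_te <- inside(annot$te)
  hit <- list(exon = inside(annot$exons), utr5 = inside(annot$utr5),
              utr3 = inside(annot$utr3), intron = inside(annot$introns))
  ## promoter distance to the nearest TSS upstream region
  g <- annot$genes
  tss <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
                GenomicRanges::start(g), GenomicRanges::end(g))
  gchr <- as.character(GenomicRanges::seqnames(g))
  for (i in seq_len(nrow(calls))) {
    if (hit_te[i]) { cat[i] <- "te"; next }
    if (hit$exon[i]) { cat[i] <- "exon"; next }
    if (hit$utr5[i]) { cat[i] <- "utr5"; next }
    if (hit$utr3[i]) { cat[i] <- "utr3"; next }
    if (hit$intron[i]) { cat[i] <- "intron"; next }
    p <- calls$start[i]
    same <- gchr == calls$chrom[i]
    d <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
                tss - p, p - tss)
    d <- d[same]
    d <- d[d > 0]
    dmin <- if (length(d)) min(d) else Inf
    cat[i] <- if (dmin < promoter_near) "promoter_lt500"
      else if (dmin < promoter_far) "promoter_500_1000"
      else "intergenic_gt1000"
  }
  factor(cat, levels = insertion_categories())
}

#' Category counts, percentages and cumulative genic roll-ups
#'
#' Percentages are reported at one decimal. The roll-ups accumulate the
#' transcribed classes (5'UTR + exon + intron + 3'UTR), then add the
#' proximal promoter (< 500 bp), then the distal promoter (500-1000 bp).
#'
#' @param categories Factor from [classify_insertions()] (or counts named
#'   by category).
#' @return A list: `counts`, `percent` (1 decimal), `cumulative_genic`
#'   (3 percentages), `n`.
#' @export
category_table <- function(categories) {
  lv <- insertion_categories()
  counts <- if (is.factor(categories)) {
    stats::setNames(as.integer(table(categories)), lv)
  } else {
    stopifnot(all(lv %in% names(categories)))
    categories[lv]
  }
  n <- sum(counts)
  pct <- round(100 * counts / n, 1)
  transcribed <- sum(counts[c("utr5", "exon", "intron", "utr3")])
  cum <- cumsum(c(transcribed, counts["promoter_lt500"],
                  counts["promoter_500_1000"]))
  list(counts = counts, percent = pct,
       cumulative_genic = round(100 * cum / n, 1), n = n)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by summation of hypergeometric outcomes no more probable
#' than the observed one; sample odds ratio alongside the conditional MLE.
#' A zero margin yields p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A list of class `EnrichmentResult`: `table`, `odds_ratio`
#'   (sample), `odds_ratio_cmle`, `p`, `test`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
    or_cmle <- NA_real_
  } else {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value
    or_cmle <- unname(ft$estimate)
  }
  res <- list(table = tab,
              odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
              odds_ratio_cmle = or_cmle, p = p,
              test = "Fisher's exact test for count data")
  class(res) <- "EnrichmentResult"
  res
}

#' Upper-tail hypergeometric enrichment of genic insertions
#'
#' Probability of observing at least `n_genic` genic insertions when
#' `n_total` sites are drawn uniformly from a base-pair population with
#' `genic_bp` genic positions out of `total_bp`.
#'
#' @param n_genic,n_total Genic and total insertion counts.
#' @param genic_bp,total_bp Genic and total genome sizes (bp).
#' @param resolution Population scaling in bp per unit (default 1).
#' @return An `EnrichmentResult` with the upper-tail p.
#' @export
genic_enrichment_hypergeom <- function(n_genic, n_total, genic_bp, total_bp,
                                       resolution = 1) {
  stopifnot(n_genic <= n_total, genic_bp <= total_bp)
  K <- round(genic_bp / resolution)
  N <- round(total_bp / resolution)
  p <- stats::phyper(n_genic - 1, K, N - K, n_total, lower.tail = FALSE)
  res <- list(table = matrix(c(n_genic, n_total - n_genic, K, N - K), 2,
                             dimnames = list(c("genic", "other"),
                                             c("insertions", "population"))),
              odds_ratio = NA_real_, odds_ratio_cmle = NA_real_, p = p,
              test = "hypergeometric upper tail")
  class(res) <- "EnrichmentResult"
  res
}

#' Sample random loci matched to observed calls
#'
#' One random locus per call, uniform over the euchromatin of the same
#' chromosome, with the same interval length, never crossing a class
#' boundary.
#'
#' @param calls Calls data.frame (`chrom`, `start`, `end`).
#' @param euchromatin `GRanges` of euchromatin intervals.
#' @return Data.frame (chrom, start, end) of sampled loci.
#' @export
sample_matched_loci <- function(calls, euchromatin) {
  if (!nrow(calls))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  echr <- as.character(GenomicRanges::seqnames(euchromatin))
  es <- GenomicRanges::start(euchromatin)
  ew <- GenomicRanges::width(euchromatin)
  out_s <- integer(nrow(calls))
  len <- pmax(1L, calls$end - calls$start + 1L)
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    j <- which(echr == ch)
    if (!length(j)) stop("no euchromatin on ", ch)
    for (k in i) {
      room <- ew[j] - len[k] + 1L
      ok <- room > 0
      if (!any(ok)) stop("no euchromatin interval can host a ", len[k],
                         "-bp locus on ", ch)
      pick <- j[ok][sample.int(sum(ok), 1L, prob = room[ok])]
      out_s[k] <- es[pick] + sample.int(ew[pick] - len[k] + 1L, 1L) - 1L
    }
  }
  data.frame(chrom = calls$chrom, start = out_s, end = out_s + len - 1L)
}

#' Sliding windows over euchromatin
#'
#' @param euchromatin `GRanges`.
#' @param window Window span (bp, default 1 Mb).
#' @param step Step between window starts (bp, default 100 kb).
#' @return `GRanges` of windows, each fully inside one euchromatin
#'   interval.
#' @export
make_windows <- function(euchromatin, window = 1e6, step = 1e5) {
  rows <- lapply(seq_along(euchromatin), function(i) {
    s <- GenomicRanges::start(euchromatin)[i]
    e <- GenomicRanges::end(euchromatin)[i]
    if (e - s + 1 < window) return(NULL)
    st <- seq(s, e - window + 1, by = step)
    GenomicRanges::GRanges(GenomicRanges::seqnames(euchromatin)[i],
                           IRanges::IRanges(st, st + window - 1))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no window fits inside the euchromatin intervals")
  suppressWarnings(do.call(c, rows))
}

#' Population variance of per-window locus counts
#'
#' Loci are counted into windows by their midpoints; the population
#' variance (denominator n) of the count vector is returned, the same
#' estimator used for observed and permuted samples.
#'
#' @param loci Data.frame (`chrom`, `start`, `end`).
#' @param windows `GRanges` from [make_windows()].
#' @return The variance (scalar).
#' @export
window_count_variance <- function(loci, windows) {
  if (!length(windows)) stop("no windows")
  mid <- floor((loci$start + loci$end) / 2)
  pts <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(mid, mid))
  x <- GenomicRanges::countOverlaps(windows, pts)
  mean((x - mean(x))^2)
}

## Fast permutation engine: loci midpoints are binned at `step`
## resolution inside each euchromatin interval; a window's count is the
## sum of window/step consecutive bins. Exact when window is a multiple
## of step and every euchromatin interval is aligned to the step grid.
binned_layout <- function(euchromatin, window, step) {
  K <- window / step
  if (K != round(K)) return(NULL)
  s <- GenomicRanges::start(euchromatin)
  e <- GenomicRanges::end(euchromatin)
  if (any((s - 1) %% step != 0) || any(e %% step != 0)) return(NULL)
  nb <- (e - s + 1) %/% step
  off <- cumsum(c(0, nb[-length(nb)]))
  win_first <- unlist(lapply(seq_along(nb), function(i)
    if (nb[i] >= K) off[i] + seq_len(nb[i] - K + 1) else integer(0)))
  if (!length(win_first)) return(NULL)
  list(K = as.integer(K), nb = nb, off = off, nbins = sum(nb),
       win_first = win_first,
       chr = as.character(GenomicRanges::seqnames(euchromatin)),
       s = s, w = e - s + 1)
}

#' Permutation test of window-count variance with gamma tail fit
#'
#' Compares the observed variance of per-window insertion counts against
#' `n_perm` variances of matched random loci (same chromosome, same
#' length, uniform within euchromatin). A gamma distribution is fitted to
#' the permuted variances by moment matching (shape = mean^2/var,
#' scale = var/mean) and the reported p-value is its upper tail at the
#' observed variance; the empirical tail proportion is reported
#' alongside.
#'
#' @param calls Calls data.frame.
#' @param euchromatin `GRanges` of euchromatin.
#' @param n_perm Number of permutations (default 1000).
#' @param window,step Window span and step (bp).
#' @return A list of class `PermutationTestResult`: `observed`,
#'   `permuted`, `shape`, `scale`, `p`, `p_empirical`, `n_windows`.
#' @export
permutation_variance_test <- function(calls, euchromatin, n_perm = 1000,
                                      window = 1e6, step = 1e5) {
  stopifnot(n_perm >= 2)
  windows <- make_windows(euchromatin, window, step)
  obs <- window_count_variance(calls, windows)
  lay <- binned_layout(euchromatin, window, step)
  n <- nrow(calls)
  if (!is.null(lay)) {
    ## draw all permutations at once; bin, moving-sum, variance
    iv_of_chr <- split(seq_along(lay$chr), lay$chr)
    bin_idx <- matrix(0L, n, n_perm)
    for (ch in unique(calls$chrom)) {
      rows <- which(calls$chrom == ch)
      j <- iv_of_chr[[ch]]
      if (is.null(j)) stop("no euchromatin on ", ch)
      nd <- length(rows) * n_perm
      pick <- j[sample.int(length(j), nd, replace = TRUE,
                           prob = lay$w[j])]
      pos_in_iv <- floor(stats::runif(nd) * lay$w[pick])   # 0-based offset
      bin_idx[rows, ] <- lay$off[pick] + pos_in_iv %/% step + 1L
    }
    B <- matrix(0L, lay$nbins, n_perm)
    for (p in seq_len(n_perm))
      B[, p] <- tabulate(bin_idx[, p], lay$nbins)
    CS <- apply(rbind(0L, B), 2, cumsum)
    wc <- CS[lay$win_first + lay$K, , drop = FALSE] -
      CS[lay$win_first, , drop = FALSE]
    mu <- colMeans(wc)
    perm <- colMeans(wc^2) - mu^2
  } else {
    perm <- vapply(seq_len(n_perm), function(p) {
      window_count_variance(sample_matched_loci(calls, euchromatin),
                            windows)
    }, 0)
  }
  m <- mean(perm)
  v <- mean((perm - m)^2)
  p_emp <- mean(perm >= obs)
  if (v <= 0 || m <= 0) {
    warning("degenerate permuted variances; reporting the empirical tail")
    shape <- scale <- NA_real_
    p <- p_emp
  } else {
    shape <- m^2 / v
    scale <- v / m
    p <- stats::pgamma(obs, shape = shape, scale = scale,
                       lower.tail = FALSE)
  }
  res <- list(observed = obs, permuted = perm, shape = shape, scale = scale,
              p = p, p_empirical = p_emp, n_windows = length(windows))
  class(res) <- "PermutationTestResult"
  res
}

#' Gamma moment-matching estimators
#'
#' @param x Positive sample.
#' @return c(shape, scale) with shape = mean^2/var, scale = var/mean
#'   (population variance).
#' @export
gamma_moment_fit <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  c(shape = m^2 / v, scale = v / m)
}

#' Two-sample Kolmogorov-Smirnov distance test
#'
#' @param x,y Non-empty numeric samples (e.g. distances of affected vs
#'   unaffected adjacent genes).
#' @return A list with `D` and asymptotic `p`.
#' @export
ks_distance_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Gene-length-corrected chi-squared test of class membership
#'
#' Compares the observed class counts among targeted genes with the
#' expectation proportional to the summed gene length per class over the
#' gene universe, so that long genes (which collect more insertions by
#' chance) do not masquerade as enriched classes.
#'
#' @param target_flags Class labels of the targeted genes.
#' @param all_gene_lengths,all_flags Lengths and class labels of the gene
#'   universe.
#' @return A list with `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
length_corrected_chisq <- function(target_flags, all_gene_lengths,
                                   all_flags) {
  lev <- sort(unique(c(as.character(target_flags),
                       as.character(all_flags))))
  obs <- table(factor(target_flags, levels = lev))
  lensum <- tapply(all_gene_lengths, factor(all_flags, levels = lev), sum,
                   default = 0)
  props <- lensum / sum(lensum)
  keep <- props > 0
  ct <- suppressWarnings(stats::chisq.test(as.integer(obs[keep]),
                                           p = props[keep]))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, observed = obs[keep],
       expected = sum(obs) * props[keep])
}
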