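test_that("masking replaces interval bases with N and leaves nothing findable", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTAC"))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 4))
  expect_equal(as.character(mask_te_copies(g, iv)[[1]]), "ACNNAC")
  expect_equal(as.character(mask_te_copies(g, GenomicRanges::GRanges())[[1]]),
               "ACGTAC")
  expect_error(mask_te_copies(g, GenomicRanges::GRanges("chr1",
               IRanges::IRanges(4, 9))), "out of chromosome bounds")

  ## masking the TE copies makes the element unfindable in the reference
  fx <- det_fixture()
  masked <- mask_te_copies(fx$gen$genome, fx$gen$te_copies)
  hits <- sum(vapply(seq_along(masked), function(i)
    Biostrings::countPattern(Biostrings::DNAString(fx$te$seq), masked[[i]]),
    0L))
  expect_equal(hits, 0L)
})

test_that("LTR matching finds exact prefixes on both strands and rejects random reads", {
  set.seed(51)
  te <- build_te_consensus(5000, 400)
  params <- detection_params()

  m <- match_to_ltr(substr(te$ltr_seq, 1, 30), te, params)
  expect_equal(m$ltr_lo, 1L)
  expect_equal(m$mlen, 30L)
  expect_equal(m$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(te$ltr_seq, 100, 129))))
  m2 <- match_to_ltr(rc, te, params)
  expect_equal(m2$strand, "-")
  expect_equal(m2$ltr_lo, 100L)

  ## empirical false-positive rate on random 75-mers
  rnd <- vapply(seq_len(10000), function(i)
    paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = ""), "")
  hits <- onsenscan:::ltr_match_many(rnd, te, params)
  n_hit <- if (is.null(hits)) 0L else length(unique(hits$read))
  expect_lt(n_hit / 10000, 1e-3)
})

test_that("discordant mining keeps only LTR-supported one-mapped pairs", {
  set.seed(52)
  te <- build_te_consensus(2000, 200)
  mk <- function(qname, mate, mapped, pos, strand, seq, mate_mapped) {
    data.frame(qname = qname, mate = mate, mapped = mapped,
               chrom = ifelse(mapped, "chr1", NA), pos = ifelse(mapped, pos, NA),
               strand = ifelse(mapped, strand, NA),
               cigar = ifelse(mapped, "75M", NA),
               mapq = ifelse(mapped, 42L, 0L), mate_mapped = mate_mapped,
               mate_chrom = NA, mate_pos = NA, seq = seq, unique = mapped)
  }
  rand75 <- paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = "")
  proper <- rbind(mk("p", 1, TRUE, 100, "+", rand75, TRUE),
                  mk("p", 2, TRUE, 300, "-", rand75, TRUE))
  expect_equal(nrow(find_discordant_candidates(proper, te)), 0L)

  ltr_read <- substr(te$ltr_seq, 1, 75)
  disc <- rbind(mk("d", 1, TRUE, 100, "+", rand75, FALSE),
                mk("d", 2, FALSE, NA, NA, ltr_read, TRUE))
  ev <- find_discordant_candidates(disc, te)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "discordant")
  expect_equal(ev$start, 100L)
  expect_equal(ev$end, 174L)
  expect_equal(ev$anchor_strand, "+")

  ## both mates unmapped: skipped (junction path handles them)
  both <- rbind(mk("b", 1, FALSE, NA, NA, ltr_read, FALSE),
                mk("b", 2, FALSE, NA, NA, ltr_read, FALSE))
  expect_equal(nrow(find_discordant_candidates(both, te)), 0L)
})

test_that("junction trimming keeps the genomic fragment and respects thresholds", {
  set.seed(53)
  te <- build_te_consensus(2000, 200)
  genome40 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  read5 <- paste0(genome40, substr(te$ltr_seq, 1, 35))
  fr <- find_junction_fragments(data.frame(qname = "j5", seq = read5), te)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$side, "junction5")
  expect_equal(fr$fragment, genome40)

  Lltr <- nchar(te$ltr_seq)
  read3 <- paste0(substr(te$ltr_seq, Lltr - 34, Lltr), genome40)
  fr3 <- find_junction_fragments(data.frame(qname = "j3", seq = read3), te)
  expect_equal(fr3$side, "junction3")
  expect_equal(fr3$fragment, genome40)

  all_te <- find_junction_fragments(
    data.frame(qname = "t", seq = substr(te$ltr_seq, 10, 80)), te)
  expect_equal(nrow(all_te), 0L)
  expect_equal(attr(all_te, "n_all_te"), 1L)

  short <- paste0(substr(genome40, 1, 19), substr(te$ltr_seq, 1, 45))
  fr_short <- find_junction_fragments(data.frame(qname = "s", seq = short), te)
  expect_equal(nrow(fr_short), 0L)
})

test_that("fragment remapping places unique hits and drops ambiguous ones", {
  set.seed(54)
  uniqseq <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  dup <- substr(uniqseq, 101, 160)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(uniqseq, dup)))   # 60-mer duplicated at two loci
  frag_uniq <- data.frame(qname = "a", side = "junction5",
                          fragment = substr(uniqseq, 501, 525))
  ev <- remap_fragments(frag_uniq, genome)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 501L)
  expect_equal(ev$junction, 525L)   # element faces right on a + hit

  frag_dup <- data.frame(qname = "b", side = "junction5",
                         fragment = substr(dup, 1, 30))
  ev2 <- remap_fragments(frag_dup, genome)
  expect_equal(nrow(ev2), 0L)
  expect_equal(attr(ev2, "n_ambiguous"), 1L)

  ## a junction3 fragment's point is the base before its leftmost hit
  frag3 <- data.frame(qname = "c", side = "junction3",
                      fragment = substr(uniqseq, 1001, 1030))
  ev3 <- remap_fragments(frag3, genome)
  expect_equal(ev3$junction, 1000L)
})

test_that("evidence clustering is windowed and order-invariant", {
  ev <- data.frame(kind = "discordant", qname = paste0("r", 1:4),
                   chrom = c("chr1", "chr1", "chr1", "chr2"),
                   start = c(1000L, 1010L, 11000L, 1000L),
                   end = c(1075L, 1085L, 11075L, 1075L),
                   anchor_strand = "+", te_strand = "-",
                   junction = NA_integer_)
  cl <- cluster_evidence(ev, detection_params(cluster_window = 500))
  expect_equal(length(unique(cl$cluster)), 3L)
  expect_equal(length(unique(cl$cluster[cl$chrom == "chr1"])), 2L)

  for (perm in list(c(2, 4, 1, 3), c(4, 3, 2, 1))) {
    cl2 <- cluster_evidence(ev[perm, ], detection_params(cluster_window = 500))
    expect_equal(cl2[order(cl2$qname), c("qname", "cluster")],
                 cl[order(cl$qname), c("qname", "cluster")],
                 ignore_attr = TRUE)
  }
})

test_that("calls recover planted insertions with exact TSDs and label backgrounds", {
  fx <- det_fixture()
  novel <- fx$calls[fx$calls$status == "novel", ]
  truth <- fx$plant$truth
  expect_equal(nrow(novel), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- which(novel$chrom == truth$chrom[i] &
                   abs(novel$start - (truth$point[i] + 1L)) <= 20)
    expect_length(hit, 1L)
    expect_equal(novel$tsd_len[hit], truth$tsd_len[i])
    expect_equal(novel$orientation[hit], truth$orientation[i])
    ## called TSD sequence equals the duplicated target site
    ref <- as.character(fx$gen$genome[[truth$chrom[i]]])
    expect_equal(novel$tsd_seq[hit],
                 substr(ref, truth$point[i] + 1, truth$point[i] + 5))
  }
  ## clusters at pre-existing copies are labeled, not called novel
  pre <- fx$calls[fx$calls$status == "preexisting", ]
  expect_gt(nrow(pre), 0)
  te_chr <- as.character(GenomicRanges::seqnames(fx$gen$te_copies))
  for (i in seq_len(nrow(pre))) {
    d <- abs(c(GenomicRanges::start(fx$gen$te_copies),
               GenomicRanges::end(fx$gen$te_copies)) - pre$start[i])
    same <- rep(te_chr, 2) == pre$chrom[i]
    expect_lte(min(d[same]), 500)
  }
})

test_that("calls shared with a control genotype are subtracted", {
  fx <- det_fixture()
  again <- detect_insertions(fx$aln, fx$gen$genome, fx$te,
                             fx$gen$te_copies, control_calls = fx$calls)
  expect_equal(sum(again$status == "novel"), 0L)
  expect_equal(sum(again$status == "control_shared"),
               sum(fx$calls$status == "novel"))
})

test_that("novel calls are confirmed by in-silico PCR across the insertion", {
  fx <- det_fixture()
  novel <- fx$calls[fx$calls$status == "novel", ]
  pick <- novel[seq_len(min(21L, nrow(novel))), ]
  conf <- vapply(seq_len(nrow(pick)), function(i)
    isTRUE(insilico_pcr_confirm(pick[i, ], fx$gen$genome, fx$plant$genome,
                                fx$te)), NA)
  expect_equal(sum(conf), nrow(pick))
})
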