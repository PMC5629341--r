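## Synthetic data with the statistical structure the pipeline assumes:
## toy genomes with pericentromeric heterochromatin and gene-tiled
## euchromatin, an LTR element consensus, planted insertions with canonical
## target-site duplications, paired-end alignments carrying discordant and
## junction evidence, H3K9me2-like tile tracks, and NB count tables.
##
## All randomness uses R's global RNG; callers fix it with set.seed() (the
## orchestrating drivers and the acceptance script do). Functions never
## reseed internally.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulation configuration
#'
#' Defaults mirror the sequencing design the pipeline targets: 75-bp
#' paired-end reads, ~300-bp inserts, 30x coverage, a 5-bp target-site
#' duplication (canonical for Ty1/copia elements), ~90% genic targeting,
#' and chromosomes with one central heterochromatin block.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param gene_density Genes per bp of euchromatin (default 1/4000, about
#'   the Arabidopsis gene spacing).
#' @param het_fraction Fraction of each chromosome occupied by the central
#'   heterochromatin block.
#' @param n_te_copies Pre-existing element copies placed in the genome
#'   (majority inside heterochromatin).
#' @param n_insertions New insertions to plant.
#' @param genic_bias Probability that a planted site falls inside a gene.
#' @param coverage Mean sequencing depth (x).
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment (insert) size distribution (bp).
#' @param error_rate Per-base substitution sequencing error rate.
#' @param tsd_len Target-site duplication length (bp).
#' @param element_len,ltr_len Element and LTR lengths (bp); Onsen-like
#'   defaults.
#' @param min_spacing Minimum distance between planted sites (bp).
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(n_chrom = 5, chrom_len = 400e3, gene_density = 1/4000,
                       het_fraction = 0.15, n_te_copies = 5,
                       n_insertions = 30, genic_bias = 0.9, coverage = 30,
                       read_len = 75, insert_mean = 300, insert_sd = 30,
                       error_rate = 0.005, tsd_len = 5,
                       element_len = 4900, ltr_len = 400,
                       min_spacing = 5000) {
  cfg <- as.list(environment())
  stopifnot(n_chrom >= 1, chrom_len > 0, gene_density >= 0,
            het_fraction >= 0, het_fraction < 1,
            n_te_copies >= 0, n_insertions >= 0,
            genic_bias >= 0, genic_bias <= 1, coverage >= 0,
            read_len > 0, insert_mean >= 2 * read_len, error_rate >= 0,
            error_rate <= 1, tsd_len >= 0, 2 * ltr_len < element_len)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Build a synthetic LTR element consensus
#'
#' The 5' and 3' long terminal repeats are byte-identical copies at the
#' element extremities, the defining property of an LTR retrotransposon;
#' the internal region is random.
#'
#' @param element_len,ltr_len Lengths in bp; requires `2*ltr_len <
#'   element_len`.
#' @param id Element identifier.
#' @return A list of class `TEConsensus` with `seq`, `ltr5`, `ltr3`
#'   (1-based closed intervals within the element) and `ltr_seq`.
#' @export
build_te_consensus <- function(element_len = 4900, ltr_len = 400,
                               id = "ONSEN_SYN") {
  stopifnot(2 * ltr_len < element_len)
  ltr <- random_dna(ltr_len)
  internal <- random_dna(element_len - 2 * ltr_len)
  te <- list(id = id,
             seq = paste0(ltr, internal, ltr),
             ltr5 = c(1L, as.integer(ltr_len)),
             ltr3 = c(as.integer(element_len - ltr_len + 1L),
                      as.integer(element_len)),
             ltr_seq = ltr,
             element_len = as.integer(element_len),
             ltr_len = as.integer(ltr_len))
  class(te) <- "TEConsensus"
  te
}

#' Build a toy genome with heterochromatin, genes and pre-existing TE copies
#'
#' Each chromosome carries one central heterochromatin block covering
#' `het_fraction` of its length; genes (5'UTR, three exons, two introns,
#' 3'UTR; random strand) tile the euchromatic arms at `gene_density`;
#' `n_te_copies` element copies overwrite the sequence, ~80% of them inside
#' heterochromatin.
#'
#' @param config A [sim_config()].
#' @param te A [build_te_consensus()] element (required when
#'   `n_te_copies > 0`).
#' @return A list with `genome` (DNAStringSet), `annot`
#'   (`AnnotationModel`, TE copies included), `het` (GRanges truth
#'   heterochromatin blocks) and `te_copies` (GRanges).
#' @export
build_toy_genome <- function(config, te = NULL) {
  gene_len <- 1900L          # 200 utr5 + 3x400 exons + 2x150 introns + 200 utr3
  if (config$gene_density > 1 / (gene_len + 200))
    stop("gene density incompatible with gene length: at most one gene per ",
         gene_len + 200, " bp")
  if (config$n_te_copies > 0 && is.null(te))
    stop("a TE consensus is required to place pre-existing copies")
  chroms <- paste0("chr", seq_len(config$n_chrom))
  L <- config$chrom_len
  seqs <- vapply(chroms, function(ch) random_dna(L), "")
  ## central heterochromatin block
  het <- GenomicRanges::GRanges()
  if (config$het_fraction > 0) {
    w <- round(config$het_fraction * L)
    s <- round((L - w) / 2) + 1L
    het <- GenomicRanges::GRanges(chroms, IRanges::IRanges(s, s + w - 1L))
  }
  ## genes tile the euchromatic arms
  gene_rows <- list(); exon_rows <- list(); u5_rows <- list(); u3_rows <- list()
  gi <- 0L
  for (ch in chroms) {
    segs <- if (config$het_fraction > 0) {
      hs <- GenomicRanges::start(het[GenomicRanges::seqnames(het) == ch])
      he <- GenomicRanges::end(het[GenomicRanges::seqnames(het) == ch])
      list(c(1L, hs - 1L), c(he + 1L, L))
    } else list(c(1L, L))
    for (sg in segs) {
      seg_w <- sg[2] - sg[1] + 1L
      ng <- floor(seg_w * config$gene_density)
      if (ng < 1) next
      pitch <- seg_w / ng
      for (k in seq_len(ng)) {
        margin <- pitch - gene_len - 100
        g0 <- sg[1] + round((k - 1) * pitch) + 50L +
          if (margin > 0) sample.int(floor(margin), 1L) else 0L
        if (g0 + gene_len - 1L > sg[2]) next
        gi <- gi + 1L
        id <- sprintf("GENE%04d", gi)
        strand <- sample(c("+", "-"), 1L)
        ## piece layout left to right; roles mirrored on '-' strand
        b <- g0 + cumsum(c(0L, 200L, 400L, 150L, 400L, 150L, 400L)) # bounds
        piece <- cbind(b[1:7], c(b[2:7] - 1L, g0 + gene_len - 1L))
        roles <- c("u5", "exon", "intron", "exon", "intron", "exon", "u3")
        if (strand == "-") roles <- rev(roles)
        gene_rows[[gi]] <- data.frame(chrom = ch, start = g0,
                                      end = g0 + gene_len - 1L,
                                      strand = strand, gene_id = id)
        for (j in which(roles == "exon"))
          exon_rows[[length(exon_rows) + 1L]] <-
            data.frame(chrom = ch, start = piece[j, 1], end = piece[j, 2],
                       strand = strand, gene_id = id)
        j5 <- which(roles == "u5"); j3 <- which(roles == "u3")
        u5_rows[[length(u5_rows) + 1L]] <-
          data.frame(chrom = ch, start = piece[j5, 1], end = piece[j5, 2],
                     strand = strand, gene_id = id)
        u3_rows[[length(u3_rows) + 1L]] <-
          data.frame(chrom = ch, start = piece[j3, 1], end = piece[j3, 2],
                     strand = strand, gene_id = id)
      }
    }
  }
  df2gr <- function(rows) {
    if (!length(rows)) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$gene_id <- character(0)
      return(gr)
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    gr
  }
  genes <- df2gr(gene_rows)
  ## pre-existing TE copies overwrite the sequence (~80% heterochromatic)
  te_gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(te_gr)$te_id <- character(0)
  S4Vectors::mcols(te_gr)$family <- character(0)
  if (config$n_te_copies > 0) {
    E <- te$element_len
    n_het <- if (config$het_fraction > 0)
      round(0.8 * config$n_te_copies) else 0L
    placed <- list()
    occupied <- genes
    place_one <- function(ch, lo, hi) {
      for (try in 1:200) {
        s <- sample(seq.int(lo, hi - E + 1L), 1L)
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + E - 1L))
        hits <- GenomicRanges::countOverlaps(cand, occupied,
                                             ignore.strand = TRUE)
        if (hits == 0) return(cand)
      }
      stop("could not place a pre-existing TE copy")
    }
    for (i in seq_len(config$n_te_copies)) {
      in_het <- i <= n_het
      ch <- sample(chroms, 1L)
      if (in_het) {
        blk <- het[as.character(GenomicRanges::seqnames(het)) == ch]
        cand <- place_one(ch, GenomicRanges::start(blk),
                          GenomicRanges::end(blk))
      } else {
        cand <- place_one(ch, 2000L, L - 2000L)
      }
      occupied <- suppressWarnings(c(occupied, GenomicRanges::GRanges(
        GenomicRanges::seqnames(cand),
        IRanges::IRanges(GenomicRanges::start(cand),
                         GenomicRanges::end(cand)), strand = "*")))
      placed[[i]] <- cand
    }
    te_gr <- suppressWarnings(do.call(c, placed))
    S4Vectors::mcols(te_gr)$te_id <- sprintf("%s_copy%02d", te$id,
                                             seq_along(te_gr))
    S4Vectors::mcols(te_gr)$family <- te$id
    for (i in seq_along(te_gr)) {
      ch <- as.character(GenomicRanges::seqnames(te_gr)[i])
      s <- GenomicRanges::start(te_gr)[i]
      substr(seqs[[ch]], s, s + te$element_len - 1L) <- te$seq
    }
  }
  annot <- annotation_model(genes, df2gr(exon_rows), utr5 = df2gr(u5_rows),
                            utr3 = df2gr(u3_rows), te = te_gr)
  list(genome = Biostrings::DNAStringSet(seqs), annot = annot, het = het,
       te_copies = te_gr)
}

#' Plant new element insertions with target-site duplications
#'
#' At each site the `tsd_len` bases immediately 3' of the insertion point
#' are duplicated flanking the inserted element (canonical TSD mechanism):
#' with point p and TSD t, the mutated chromosome is
#' `ref[1..p+t] + element + ref[p+1..L]`. Orientation is Bernoulli(0.5);
#' a site falls inside an annotated gene with probability `genic_bias`.
#'
#' @param genome Reference `DNAStringSet` (TE copies present, unmasked).
#' @param annot `AnnotationModel` of the genome.
#' @param te `TEConsensus` to insert.
#' @param config A [sim_config()]; uses `n_insertions`, `genic_bias`,
#'   `tsd_len`, `min_spacing`.
#' @return A list with `genome` (mutated `DNAStringSet`) and `truth`
#'   (data.frame: chrom, point (1-based base preceding the target site),
#'   tsd_len, orientation, genic, gene_id).
#' @export
plant_insertions <- function(genome, annot, te, config) {
  n <- config$n_insertions
  t <- config$tsd_len
  chroms <- names(genome)
  lens <- chrom_lengths(genome)
  margin <- max(2L * config$insert_mean, 2000L)
  genes <- annot$genes
  te_iv <- annot$te
  truth <- data.frame(chrom = character(0), point = integer(0),
                      tsd_len = integer(0), orientation = character(0),
                      genic = logical(0), gene_id = character(0))
  if (n == 0) return(list(genome = genome, truth = truth))
  pts_by_chr <- lapply(stats::setNames(nm = chroms), function(x) integer(0))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      genic <- stats::runif(1) < config$genic_bias
      if (genic && length(genes)) {
        g <- sample(length(genes), 1L)
        ch <- as.character(GenomicRanges::seqnames(genes)[g])
        lo <- GenomicRanges::start(genes)[g]
        hi <- GenomicRanges::end(genes)[g] - t - 1L
        if (hi <= lo) next
        p <- sample(seq.int(lo, hi), 1L)
        gid <- genes$gene_id[g]
      } else {
        ch <- sample(chroms, 1L)
        p <- sample(seq.int(margin, lens[[ch]] - margin), 1L)
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(p, p + t + 1L))
        if (length(genes) &&
            suppressWarnings(GenomicRanges::countOverlaps(
              cand, genes, ignore.strand = TRUE)) > 0) next
        genic <- FALSE
        gid <- NA_character_
      }
      if (p < margin || p > lens[[ch]] - margin) next
      ## keep clear of pre-existing copies: a site within the spacing
      ## distance of a masked copy is indistinguishable from background
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(
        max(1L, p - config$min_spacing), p + t + 1L + config$min_spacing))
      if (length(te_iv) &&
          suppressWarnings(GenomicRanges::countOverlaps(
            cand, te_iv, ignore.strand = TRUE)) > 0) next
      if (length(pts_by_chr[[ch]]) &&
          min(abs(pts_by_chr[[ch]] - p)) < config$min_spacing) next
      ok <- TRUE
      break
    }
    if (!ok) stop("cannot place ", n, " insertions under the ",
                  config$min_spacing, "-bp spacing constraint")
    pts_by_chr[[ch]] <- c(pts_by_chr[[ch]], p)
    rows[[i]] <- data.frame(chrom = ch, point = p, tsd_len = t,
                            orientation = sample(c("+", "-"), 1L),
                            genic = genic, gene_id = gid)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$point), , drop = FALSE]
  rownames(truth) <- NULL
  ## mutate sequences (descending so earlier coordinates stay valid)
  seqs <- as.character(genome)
  elem_fwd <- te$seq
  elem_rev <- revcomp_chr(te$seq)
  for (ch in chroms) {
    tt <- truth[truth$chrom == ch, , drop = FALSE]
    if (!nrow(tt)) next
    tt <- tt[order(-tt$point), , drop = FALSE]
    s <- seqs[[ch]]
    for (r in seq_len(nrow(tt))) {
      p <- tt$point[r]
      elem <- if (tt$orientation[r] == "+") elem_fwd else elem_rev
      s <- paste0(substr(s, 1L, p + t), elem,
                  substr(s, p + 1L, nchar(s)))
    }
    seqs[[ch]] <- s
  }
  list(genome = Biostrings::DNAStringSet(seqs), truth = truth)
}

## Segment map of a mutated chromosome: which mutated intervals are
## reference-derived (and mapped where), masked (pre-existing TE copies,
## N in the masked reference) or inserted element. A read maps uniquely to
## the masked reference iff it lies entirely inside one "ok" segment.
mutated_segments <- function(ref_len, masked_iv, truth_chr, element_len) {
  brk <- function(kind, mut_s, mut_e, off)
    data.frame(kind = kind, mut_s = mut_s, mut_e = mut_e, off = off)
  cut_ref <- function(ref_s, ref_e, mut_at) {
    ## split a reference chunk by masked intervals; mut_at = mutated coord
    ## of ref_s
    out <- list()
    pos <- ref_s
    if (nrow(masked_iv)) {
      mi <- masked_iv[masked_iv$e >= ref_s & masked_iv$s <= ref_e, ,
                      drop = FALSE]
      mi <- mi[order(mi$s), , drop = FALSE]
      for (r in seq_len(nrow(mi))) {
        ms <- max(mi$s[r], ref_s); me <- min(mi$e[r], ref_e)
        if (pos < ms)
          out[[length(out) + 1L]] <- c(0L, pos, ms - 1L)   # ok
        out[[length(out) + 1L]] <- c(1L, ms, me)           # masked
        pos <- me + 1L
      }
    }
    if (pos <= ref_e) out[[length(out) + 1L]] <- c(0L, pos, ref_e)
    do.call(rbind, lapply(out, function(x) {
      mut_s <- mut_at + (x[2] - ref_s)
      brk(if (x[1] == 0) "ok" else "masked", mut_s, mut_s + (x[3] - x[2]),
          mut_s - x[2])
    }))
  }
  segs <- list()
  cur_ref <- 1L
  cur_mut <- 1L
  if (nrow(truth_chr)) {
    truth_chr <- truth_chr[order(truth_chr$point), , drop = FALSE]
    for (r in seq_len(nrow(truth_chr))) {
      p <- truth_chr$point[r]; t <- truth_chr$tsd_len[r]
      segs[[length(segs) + 1L]] <- cut_ref(cur_ref, p + t, cur_mut)
      cur_mut <- cur_mut + (p + t - cur_ref + 1L)
      segs[[length(segs) + 1L]] <- brk("element", cur_mut,
                                       cur_mut + element_len - 1L, NA)
      cur_mut <- cur_mut + element_len
      cur_ref <- p + 1L
    }
  }
  segs[[length(segs) + 1L]] <- cut_ref(cur_ref, ref_len, cur_mut)
  do.call(rbind, segs)
}

#' Simulate paired-end alignments against the TE-masked reference
#'
#' Fragments are drawn along the mutated genome at the configured coverage.
#' A mate is reported mapped iff its full length lies in reference-derived
#' sequence that is not masked (so its error-free positions match the
#' masked reference uniquely); reads spanning an insertion junction, inside
#' the inserted element, or inside a pre-existing (masked) copy are
#' reported unmapped with their sequence, which is what the detector
#' consumes. Substitution errors are applied after the mapping decision,
#' i.e. mapping reflects the error-free read placement.
#'
#' @param mutated `DNAStringSet`, the genome carrying the insertions.
#' @param reference_masked `DNAStringSet`, the TE-masked reference (used
#'   for the header dictionary and coordinate frame).
#' @param te `TEConsensus` that was inserted.
#' @param config A [sim_config()].
#' @param truth Truth table from [plant_insertions()].
#' @param te_copies `GRanges` of pre-existing (masked) element copies.
#' @return Alignment record data.frame (see [read_sam()]) with attribute
#'   `seqlengths` of the reference.
#' @export
simulate_alignments <- function(mutated, reference_masked, te, config,
                                truth, te_copies) {
  rl <- config$read_len
  ref_lens <- chrom_lengths(reference_masked)
  out <- vector("list", length(mutated))
  for (ci in seq_along(mutated)) {
    ch <- names(mutated)[ci]
    mseq <- as.character(mutated[[ci]])
    Lm <- nchar(mseq)
    nfrag <- round(config$coverage * Lm / (2 * rl))
    if (nfrag == 0) { out[[ci]] <- empty_alignments(); next }
    isz <- pmax(2L * rl + 10L,
                round(stats::rnorm(nfrag, config$insert_mean,
                                   config$insert_sd)))
    fs <- floor(stats::runif(nfrag, 1, Lm - isz + 1))
    s1 <- fs; e1 <- fs + rl - 1L
    s2 <- fs + isz - rl; e2 <- fs + isz - 1L
    ## segment map: ok / masked / element
    mi_gr <- te_copies[as.character(GenomicRanges::seqnames(te_copies)) == ch]
    masked_iv <- data.frame(s = GenomicRanges::start(mi_gr),
                            e = GenomicRanges::end(mi_gr))
    segs <- mutated_segments(ref_lens[[ch]], masked_iv,
                             truth[truth$chrom == ch, , drop = FALSE],
                             te$element_len)
    seg_of <- function(pos) findInterval(pos, segs$mut_s)
    mapped_in <- function(s, e) {
      i <- seg_of(s)
      ok <- i >= 1 & i == seg_of(e) & segs$kind[i] == "ok"
      list(ok = ok, pos = ifelse(ok, s - segs$off[i], NA_integer_))
    }
    m1 <- mapped_in(s1, e1)
    m2 <- mapped_in(s2, e2)
    sq1 <- substring(mseq, s1, e1)
    sq2_fwd <- substring(mseq, s2, e2)
    ## apply substitution errors (post mapping decision)
    err <- function(sq) {
      ne <- stats::rbinom(length(sq), rl, config$error_rate)
      for (i in which(ne > 0)) {
        pos <- sample.int(rl, ne[i])
        for (p in pos) {
          old <- substr(sq[i], p, p)
          substr(sq[i], p, p) <- sample(setdiff(DNA, old), 1L)
        }
      }
      sq
    }
    sq1 <- err(sq1)
    sq2_fwd <- err(sq2_fwd)
    qn <- sprintf("frag_%s_%07d", ch, seq_len(nfrag))
    ## SAM orientation: mapped records store forward-strand sequence;
    ## unmapped records store the as-sequenced read (R2 is reverse-read).
    seq2 <- ifelse(m2$ok, sq2_fwd, revcomp_chr(sq2_fwd))
    r1 <- data.frame(qname = qn, mate = 1L, mapped = m1$ok,
                     chrom = ifelse(m1$ok, ch, NA_character_),
                     pos = m1$pos,
                     strand = ifelse(m1$ok, "+", NA_character_),
                     cigar = ifelse(m1$ok, paste0(rl, "M"), NA_character_),
                     mapq = ifelse(m1$ok, 42L, 0L),
                     mate_mapped = m2$ok,
                     mate_chrom = ifelse(m2$ok, ch, NA_character_),
                     mate_pos = m2$pos, seq = sq1,
                     unique = m1$ok, stringsAsFactors = FALSE)
    r2 <- data.frame(qname = qn, mate = 2L, mapped = m2$ok,
                     chrom = ifelse(m2$ok, ch, NA_character_),
                     pos = m2$pos,
                     strand = ifelse(m2$ok, "-", NA_character_),
                     cigar = ifelse(m2$ok, paste0(rl, "M"), NA_character_),
                     mapq = ifelse(m2$ok, 42L, 0L),
                     mate_mapped = m1$ok,
                     mate_chrom = ifelse(m1$ok, ch, NA_character_),
                     mate_pos = m1$pos, seq = seq2,
                     unique = m2$ok, stringsAsFactors = FALSE)
    out[[ci]] <- rbind(r1, r2)
  }
  aln <- do.call(rbind, out)
  attr(aln, "seqlengths") <- ref_lens
  aln
}

#' Write reads of an alignment set as FASTQ
#'
#' Emits the as-sequenced reads (mapped reverse-strand records are
#' reverse-complemented back), for users who prefer to run a real aligner.
#'
#' @param aln Alignment records.
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2.
#' @export
write_fastq <- function(aln, path1, path2) {
  emit <- function(df, path) {
    sq <- ifelse(df$mapped & df$strand == "-", revcomp_chr(df$seq), df$seq)
    writeLines(paste0("@", df$qname, "/", df$mate, "\n", sq, "\n+\n",
                      strrep("I", nchar(sq))), path)
  }
  emit(aln[aln$mate == 1L, ], path1)
  emit(aln[aln$mate == 2L, ], path2)
  invisible(c(path1, path2))
}

#' Simulate an H3K9me2-like tile enrichment track
#'
#' Tiles inside the truth heterochromatin blocks get Normal(signal_high,
#' noise_sd) values, tiles outside Normal(signal_low, noise_sd), floored
#' at 0.
#'
#' @param het Truth heterochromatin `GRanges`.
#' @param genome `DNAStringSet` (for chromosome lengths).
#' @param tile_width Tile width in bp.
#' @param signal_high,signal_low,noise_sd Level parameters.
#' @return A `TileTrack`.
#' @export
simulate_h3k9me2_track <- function(het, genome, tile_width = 60,
                                   signal_high = 3.0, signal_low = 0.5,
                                   noise_sd = 0.3) {
  lens <- chrom_lengths(genome)
  values <- lapply(stats::setNames(nm = names(lens)), function(ch) {
    n <- ceiling(lens[[ch]] / tile_width)
    mid <- pmin((seq_len(n) - 0.5) * tile_width, lens[[ch]])
    blk <- het[as.character(GenomicRanges::seqnames(het)) == ch]
    inside <- rep(FALSE, n)
    for (i in seq_along(blk))
      inside <- inside | (mid >= GenomicRanges::start(blk)[i] &
                            mid <= GenomicRanges::end(blk)[i])
    mu <- ifelse(inside, signal_high, signal_low)
    pmax(0, stats::rnorm(n, mu, noise_sd))
  })
  tile_track(values, tile_width, lens)
}

#' Simulate an RNA-seq count table with insertion-linked heat activation
#'
#' Counts are negative binomial (per-gene lognormal baseline means,
#' constant dispersion) over two conditions x two replicates. Genes
#' targeted by a genic planted insertion get their heat-condition mean
#' multiplied by `fold_change`; a `silent_frac` fraction of genes is given
#' a near-zero mean so the presence-call filter has something to drop.
#'
#' @param annot `AnnotationModel` supplying the gene universe.
#' @param truth Truth table from [plant_insertions()] (activated genes =
#'   `gene_id` of genic records).
#' @param baseline_mean Mean of the baseline NB means.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param fold_change Heat activation fold applied to targeted genes
#'   (>= 2 so that log2FC >= 1 is recoverable).
#' @param silent_frac Fraction of non-targeted genes made silent.
#' @return A list: `counts` (genes x 4 integer matrix, columns control_1,
#'   control_2, heat_1, heat_2), `samples` (condition/replicate map), and
#'   `effects` (gene_id, activated, silent).
#' @export
simulate_count_table <- function(annot, truth, baseline_mean = 500,
                                 dispersion = 0.05, fold_change = 8,
                                 silent_frac = 0.1) {
  gids <- annot$genes$gene_id
  ng <- length(gids)
  activated <- gids %in% truth$gene_id[truth$genic]
  silent <- rep(FALSE, ng)
  pool <- which(!activated)
  if (silent_frac > 0 && length(pool))
    silent[sample(pool, round(silent_frac * length(pool)))] <- TRUE
  base_mu <- stats::rlnorm(ng, log(baseline_mean), 0.6)
  base_mu[silent] <- 0.05
  mu <- cbind(control_1 = base_mu, control_2 = base_mu,
              heat_1 = base_mu, heat_2 = base_mu)
  mu[activated, c("heat_1", "heat_2")] <-
    mu[activated, c("heat_1", "heat_2")] * fold_change
  counts <- matrix(stats::rnbinom(ng * 4L, mu = mu, size = 1 / dispersion),
                   nrow = ng, dimnames = list(gids, colnames(mu)))
  samples <- data.frame(sample = colnames(mu),
                        condition = rep(c("control", "heat"), each = 2L),
                        replicate = rep(1:2, 2L))
  list(counts = counts, samples = samples,
       effects = data.frame(gene_id = gids, activated = activated,
                            silent = silent))
}
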