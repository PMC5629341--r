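## Neo-insertion detection: discordant-pair mining against a TE-masked
## reference, LTR junction-read trimming and exact local remapping,
## single-linkage clustering of the evidence, TSD resolution from the
## junction-point offset, and background subtraction against known copies
## and control calls.

#' Detection parameters
#'
#' All thresholds are explicit because the original procedure left the
#' final call to manual assessment; defaults are chosen so that the
#' synthetic recall/precision properties hold and can be tightened or
#' relaxed freely.
#'
#' @param min_ltr_match Minimum ungapped match length to the LTR (bp).
#' @param min_ltr_identity Minimum identity over the matched span.
#' @param min_fragment_len Minimum trimmed genomic fragment length (bp).
#' @param cluster_window Single-linkage clustering window (bp); default
#'   insert mean + 3 sd of the sequencing design.
#' @param min_discordant Minimum discordant pairs for a confident call.
#' @param min_junction Minimum junction reads for a confident call.
#' @param max_tsd Maximum credible target-site duplication (bp); larger
#'   junction-point offsets split the cluster into single-sided
#'   candidates.
#' @param kmer Seed k-mer length for the LTR matcher (internal).
#' @return A list of class `DetectionParams`.
#' @export
detection_params <- function(min_ltr_match = 25, min_ltr_identity = 0.9,
                             min_fragment_len = 20,
                             cluster_window = 300 + 3 * 30,
                             min_discordant = 2, min_junction = 1,
                             max_tsd = 20, kmer = 13) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) > 0), min_ltr_identity <= 1)
  class(p) <- "DetectionParams"
  p
}

#' Hard-mask element copies in a genome
#'
#' Replaces the bases of each interval with N, leaving lengths unchanged.
#' Overlapping intervals are merged silently.
#'
#' @param genome Named `DNAStringSet`.
#' @param intervals `GRanges` of pre-existing element copies.
#' @return Masked `DNAStringSet`.
#' @export
mask_te_copies <- function(genome, intervals) {
  seqs <- as.character(genome)
  if (length(intervals)) {
    iv <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
    ch <- as.character(GenomicRanges::seqnames(iv))
    if (!all(ch %in% names(seqs)))
      stop("mask interval on unknown chromosome")
    s <- GenomicRanges::start(iv); e <- GenomicRanges::end(iv)
    if (any(s < 1) || any(e > chrom_lengths(genome)[ch]))
      stop("mask interval out of chromosome bounds")
    for (i in seq_along(iv))
      substr(seqs[[ch[i]]], s[i], e[i]) <- strrep("N", e[i] - s[i] + 1L)
  }
  Biostrings::DNAStringSet(seqs)
}

## ---- LTR matching ----------------------------------------------------------

## Seed-and-verify ungapped matcher of many reads against the LTR
## consensus. Seeds are exact k-mers; each seed fixes a diagonal, the
## overlap of read and LTR on that diagonal is compared base by base.
## Works in "working orientation": strand "-" means the reverse complement
## of the read was matched, and reported read coordinates refer to that
## reverse-complemented sequence.
ltr_match_many <- function(seqs, te, params) {
  ltr <- te$ltr_seq
  k <- params$kmer
  Lltr <- nchar(ltr)
  ltr_kmers <- substring(ltr, seq_len(Lltr - k + 1L),
                         seq_len(Lltr - k + 1L) + k - 1L)
  ltr_raw <- charToRaw(ltr)
  match_one_strand <- function(ss, strand) {
    n <- length(ss)
    if (!n) return(NULL)
    rl <- nchar(ss)
    res <- vector("list", n)
    ## k-mer seeding, vectorized across reads of equal length
    by_len <- split(seq_len(n), rl)
    cand <- list()
    for (g in by_len) {
      L <- rl[g[1]]
      if (L < k) next
      kpos <- seq(1L, L - k + 1L, by = 2L)
      for (p in kpos) {
        km <- substr(ss[g], p, p + k - 1L)
        hit <- match(km, ltr_kmers)
        got <- !is.na(hit)
        if (any(got))
          cand[[length(cand) + 1L]] <-
            data.frame(read = g[got], d = hit[got] - p)
      }
    }
    if (!length(cand)) return(NULL)
    cand <- unique(do.call(rbind, cand))
    ## evaluate each candidate diagonal over the full clipped overlap
    lo <- pmax(1L, 1L - cand$d)
    hi <- pmin(rl[cand$read], Lltr - cand$d)
    mlen <- hi - lo + 1L
    keep <- mlen >= params$min_ltr_match
    cand <- cand[keep, , drop = FALSE]
    lo <- lo[keep]; hi <- hi[keep]; mlen <- mlen[keep]
    if (!nrow(cand)) return(NULL)
    mm <- integer(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r <- charToRaw(substr(ss[cand$read[i]], lo[i], hi[i]))
      l <- ltr_raw[(lo[i] + cand$d[i]):(hi[i] + cand$d[i])]
      mm[i] <- sum(r != l)
    }
    ident <- 1 - mm / mlen
    keep <- ident >= params$min_ltr_identity
    if (!any(keep)) return(NULL)
    data.frame(read = cand$read[keep], strand = strand,
               read_lo = lo[keep], read_hi = hi[keep],
               ltr_lo = lo[keep] + cand$d[keep],
               ltr_hi = hi[keep] + cand$d[keep],
               mlen = mlen[keep], mismatch = mm[keep],
               identity = ident[keep])
  }
  fwd <- match_one_strand(seqs, "+")
  rev <- match_one_strand(revcomp_chr(seqs), "-")
  res <- rbind(fwd, rev)
  if (is.null(res) || !nrow(res)) return(res)
  ## best candidate per read x strand kept; ties by matched bases
  res$score <- res$mlen - res$mismatch
  res <- res[order(res$read, res$strand, -res$score), , drop = FALSE]
  res[!duplicated(paste(res$read, res$strand)), , drop = FALSE]
}

#' Match a read sequence to the element's LTR
#'
#' Best ungapped local match of the sequence (either strand) to the LTR
#' consensus, requiring `min_ltr_match` length and `min_ltr_identity`
#' identity. Strand "-" means the reverse complement matched; reported
#' read coordinates then refer to the reverse-complemented sequence.
#'
#' @param sequence A single DNA string.
#' @param te `TEConsensus`.
#' @param params [detection_params()].
#' @return A one-row data.frame (strand, read_lo, read_hi, ltr_lo, ltr_hi,
#'   mlen, mismatch, identity) or `NULL` when nothing qualifies.
#' @export
match_to_ltr <- function(sequence, te, params = detection_params()) {
  res <- ltr_match_many(sequence, te, params)
  if (is.null(res) || !nrow(res)) return(NULL)
  res <- res[order(-res$score), , drop = FALSE]
  res[1, setdiff(names(res), c("read", "score")), drop = FALSE]
}

## ---- evidence mining -------------------------------------------------------

#' Find discordant-pair evidence
#'
#' One evidence record per read pair in which exactly one mate is uniquely
#' mapped and the unmapped mate's sequence matches the element's LTR; the
#' anchor is the mapped mate's interval and strand.
#'
#' @param aln Alignment records (see [read_sam()]).
#' @param te `TEConsensus`.
#' @param params [detection_params()].
#' @return Evidence data.frame (kind, qname, chrom, start, end,
#'   anchor_strand, te_strand, junction = NA).
#' @export
find_discordant_candidates <- function(aln, te, params = detection_params()) {
  rl <- nchar(aln$seq)
  key <- paste(aln$qname, aln$mate)
  mate_key <- paste(aln$qname, 3L - aln$mate)
  mate_row <- match(mate_key, key)
  ## anchored mate: uniquely mapped, its mate unmapped
  anc <- which(aln$mapped & aln$unique & !is.na(mate_row) &
                 !aln$mapped[mate_row])
  if (!length(anc)) return(empty_evidence())
  um <- mate_row[anc]
  m <- ltr_match_many(aln$seq[um], te, params)
  if (is.null(m) || !nrow(m)) return(empty_evidence())
  best <- m[order(m$read, -m$score), , drop = FALSE]
  best <- best[!duplicated(best$read), , drop = FALSE]
  i <- anc[best$read]
  data.frame(kind = "discordant", qname = aln$qname[i],
             chrom = aln$chrom[i], start = aln$pos[i],
             end = aln$pos[i] + nchar(aln$seq[i]) - 1L,
             anchor_strand = aln$strand[i], te_strand = best$strand,
             junction = NA_integer_, stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(kind = character(0), qname = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             anchor_strand = character(0), te_strand = character(0),
             junction = integer(0), stringsAsFactors = FALSE)
}

#' Extract junction fragments from unmapped reads
#'
#' A junction read carries host sequence on one side and the element's LTR
#' extremity on the other. Reads whose (working-orientation) suffix
#' matches the LTR start (element 5' outer end) or whose prefix matches
#' the LTR end (element 3' outer end) have the element part trimmed; the
#' remaining genomic fragment is returned when it reaches
#' `min_fragment_len`.
#'
#' @param reads Data.frame with columns `qname` and `seq` (unmapped or
#'   clipped reads).
#' @param te `TEConsensus`.
#' @param params [detection_params()].
#' @return Data.frame (qname, side = junction5/junction3, fragment),
#'   with attribute `n_all_te` counting reads matching the LTR over their
#'   whole length (skipped).
#' @export
find_junction_fragments <- function(reads, te, params = detection_params()) {
  empty <- data.frame(qname = character(0), side = character(0),
                      fragment = character(0), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(structure(empty, n_all_te = 0L))
  m <- ltr_match_many(reads$seq, te, params)
  if (is.null(m) || !nrow(m)) return(structure(empty, n_all_te = 0L))
  Lltr <- nchar(te$ltr_seq)
  rl <- nchar(reads$seq)[m$read]
  work <- function(i) {
    s <- reads$seq[m$read[i]]
    if (m$strand[i] == "-") revcomp_chr(s) else s
  }
  cond5 <- m$ltr_lo == 1L & m$read_hi == rl          # suffix = LTR start
  cond3 <- m$ltr_hi == Lltr & m$read_lo == 1L        # prefix = LTR end
  all_te <- m$read_lo == 1L & m$read_hi == rl
  n_all_te <- length(unique(m$read[all_te]))
  rows <- list()
  for (i in which((cond5 | cond3) & !all_te)) {
    w <- work(i)
    if (cond5[i]) {
      frag <- substr(w, 1L, m$read_lo[i] - 1L)
      side <- "junction5"
    } else {
      frag <- substr(w, m$read_hi[i] + 1L, nchar(w))
      side <- "junction3"
    }
    if (nchar(frag) >= params$min_fragment_len)
      rows[[length(rows) + 1L]] <-
        data.frame(qname = reads$qname[m$read[i]], side = side,
                   fragment = frag, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  ## a read can qualify once per (strand, side); keep unique read/side
  out <- out[!duplicated(paste(out$qname, out$side)), , drop = FALSE]
  structure(out, n_all_te = n_all_te)
}

#' Remap trimmed junction fragments by exact search
#'
#' Each fragment is placed by exact full-length search on both strands of
#' the unmasked reference; only unique hits become junction evidence. The
#' junction point is the reference base abutting the trimmed element
#' sequence: for a fragment whose element side faces right (higher
#' coordinates) the point is the fragment's rightmost base, otherwise the
#' base preceding its leftmost base, so that the two sides of a TSD-t
#' insertion give points p + t and p.
#'
#' @param fragments Output of [find_junction_fragments()].
#' @param genome Unmasked reference `DNAStringSet`.
#' @param params [detection_params()].
#' @return Evidence data.frame; attribute `n_ambiguous` counts fragments
#'   with 0 or >= 2 exact hits.
#' @export
remap_fragments <- function(fragments, genome, params = detection_params()) {
  if (!nrow(fragments))
    return(structure(empty_evidence(), n_ambiguous = 0L))
  seqs <- as.character(genome)
  w <- params$min_fragment_len
  frag <- fragments$fragment
  nfrag <- length(frag)
  hits <- vector("list", nfrag)
  count <- integer(nfrag)
  scan <- function(prefixes, strand) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(prefixes))
    for (ch in names(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[ch]])
      st <- IRanges::start(m)
      for (i in seq_len(nfrag)) {
        ss <- st[[i]]
        if (!length(ss)) next
        fl <- nchar(frag[i])
        full <- if (strand == "+") frag[i] else revcomp_chr(frag[i])
        ok <- ss + fl - 1L <= nchar(seqs[[ch]]) &
          substring(seqs[[ch]], ss, ss + fl - 1L) == full
        ss <- ss[ok]
        if (!length(ss)) next
        count[i] <<- count[i] + length(ss)
        if (count[i] <= 1L && length(ss) == 1L)
          hits[[i]] <<- list(chrom = ch, start = ss, strand = strand)
      }
    }
  }
  scan(substr(frag, 1L, w), "+")
  rc <- revcomp_chr(frag)
  scan(substr(rc, 1L, w), "-")
  uniq <- which(count == 1L)
  n_amb <- nfrag - length(uniq)
  if (!length(uniq))
    return(structure(empty_evidence(), n_ambiguous = n_amb))
  rows <- lapply(uniq, function(i) {
    h <- hits[[i]]
    fl <- nchar(frag[i])
    s <- h$start; e <- h$start + fl - 1L
    side <- fragments$side[i]
    ## element faces right when (5'-junction, + hit) or (3'-junction, - hit)
    right_facing <- (side == "junction5") == (h$strand == "+")
    jp <- if (right_facing) e else s - 1L
    data.frame(kind = side, qname = fragments$qname[i], chrom = h$chrom,
               start = s, end = e, anchor_strand = h$strand,
               te_strand = h$strand, junction = jp,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), n_ambiguous = n_amb)
}

#' Cluster evidence by position
#'
#' Single-linkage clustering of evidence positions (junction point for
#' junction evidence, anchor midpoint for discordant evidence) within
#' `cluster_window` per chromosome. Invariant to input order.
#'
#' @param evidence Evidence data.frame.
#' @param params [detection_params()].
#' @return The evidence with a `cluster` id column, sorted by position.
#' @export
cluster_evidence <- function(evidence, params = detection_params()) {
  if (!nrow(evidence)) {
    evidence$cluster <- integer(0)
    return(evidence)
  }
  pos <- ifelse(is.na(evidence$junction),
                floor((evidence$start + evidence$end) / 2),
                evidence$junction)
  o <- order(evidence$chrom, pos, evidence$kind, evidence$qname)
  evidence <- evidence[o, , drop = FALSE]
  pos <- pos[o]
  newc <- c(TRUE, evidence$chrom[-1] != evidence$chrom[-nrow(evidence)] |
              diff(pos) > params$cluster_window)
  evidence$cluster <- cumsum(newc)
  evidence$pos <- pos
  rownames(evidence) <- NULL
  evidence
}

#' Call insertions from evidence clusters
#'
#' When both junction sides are present the insertion span is
#' `[min(junction points) + 1, max(junction points)]`, whose width is the
#' target-site duplication length; with a single side the call is that
#' point; with discordant evidence only, the midpoint of the anchors.
#' Status assignment: `preexisting` within `cluster_window` of a known
#' element copy, `control_shared` within `cluster_window` of a control
#' call, `low_support` when support is below `min_discordant` /
#' `min_junction`, otherwise `novel`. Clusters whose junction-point spread
#' exceeds `max_tsd` are split into per-side candidates.
#'
#' @param clusters Output of [cluster_evidence()].
#' @param preexisting `GRanges` of known element copies (masked regions).
#' @param control_calls Optional calls data.frame from the control
#'   genotype.
#' @param params [detection_params()].
#' @param genome Optional unmasked reference for extracting `tsd_seq`.
#' @return Insertion-call data.frame (see [read_calls()] for columns).
#' @export
call_insertions <- function(clusters, preexisting,
                            control_calls = NULL,
                            params = detection_params(), genome = NULL) {
  if (!nrow(clusters)) return(empty_calls())
  seqs <- if (!is.null(genome)) as.character(genome) else NULL
  pre_by_chr <- split(data.frame(
    s = GenomicRanges::start(preexisting),
    e = GenomicRanges::end(preexisting)),
    as.character(GenomicRanges::seqnames(preexisting)))
  ctl_by_chr <- if (!is.null(control_calls) && nrow(control_calls))
    split(control_calls, control_calls$chrom) else list()
  one_call <- function(ev) {
    chrom <- ev$chrom[1]
    j5 <- ev$junction[ev$kind == "junction5"]
    j3 <- ev$junction[ev$kind == "junction3"]
    jp <- c(j5, j3)
    has_both <- length(j5) > 0 && length(j3) > 0
    if (has_both) {
      start <- min(jp) + 1L; end <- max(jp)
      tsd_len <- end - start + 1L
    } else if (length(jp)) {
      start <- end <- jp[1]
      tsd_len <- NA_integer_
    } else {
      mid <- round(mean((ev$start + ev$end) / 2))
      start <- end <- as.integer(mid)
      tsd_len <- NA_integer_
    }
    ## orientation votes: junction evidence by hit strand, discordant by
    ## anchor-vs-LTR strand parity
    v <- character(0)
    jev <- ev[ev$kind != "discordant", , drop = FALSE]
    if (nrow(jev)) v <- c(v, jev$te_strand)
    dev <- ev[ev$kind == "discordant", , drop = FALSE]
    if (nrow(dev))
      v <- c(v, ifelse(dev$anchor_strand != dev$te_strand, "+", "-"))
    orientation <- if (sum(v == "+") >= sum(v == "-")) "+" else "-"
    tsd_seq <- NA_character_
    if (has_both && !is.null(seqs) && tsd_len >= 1L)
      tsd_seq <- substr(seqs[[chrom]], start, end)
    if (has_both && tsd_len == 0L) tsd_seq <- ""
    n_disc <- sum(ev$kind == "discordant")
    point <- if (length(jp)) min(jp) else start
    status <- "novel"
    pre <- pre_by_chr[[chrom]]
    if (!is.null(pre) &&
        any(point >= pre$s - params$cluster_window &
              point <= pre$e + params$cluster_window)) {
      status <- "preexisting"
    } else if (!is.null(ctl_by_chr[[chrom]]) &&
               any(abs(ctl_by_chr[[chrom]]$start - start) <=
                     params$cluster_window)) {
      status <- "control_shared"
    } else if (n_disc < params$min_discordant ||
               (length(j5) + length(j3)) < params$min_junction) {
      status <- "low_support"
    }
    data.frame(chrom = chrom, start = start, end = end,
               orientation = orientation, tsd_len = tsd_len,
               tsd_seq = tsd_seq, n_discordant = n_disc,
               n_junction5 = length(j5), n_junction3 = length(j3),
               status = status, stringsAsFactors = FALSE)
  }
  out <- list()
  for (cl in split(clusters, clusters$cluster)) {
    j5 <- cl$junction[cl$kind == "junction5"]
    j3 <- cl$junction[cl$kind == "junction3"]
    if (length(j5) && length(j3) &&
        max(c(j5, j3)) - min(c(j5, j3)) > params$max_tsd) {
      ## implausible TSD: treat the two sides as separate candidates
      out[[length(out) + 1L]] <- one_call(cl[cl$kind != "junction3", ,
                                             drop = FALSE])
      out[[length(out) + 1L]] <- one_call(cl[cl$kind != "junction5", ,
                                             drop = FALSE])
    } else {
      out[[length(out) + 1L]] <- one_call(cl)
    }
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             orientation = character(0), tsd_len = integer(0),
             tsd_seq = character(0), n_discordant = integer(0),
             n_junction5 = integer(0), n_junction3 = integer(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Run the full detection pipeline on an alignment set
#'
#' Discordant-pair mining, junction trimming and remapping, clustering,
#' and calling with background subtraction.
#'
#' @param aln Alignment records (against the TE-masked reference).
#' @param reference Unmasked reference `DNAStringSet`.
#' @param te `TEConsensus`.
#' @param te_intervals `GRanges` of pre-existing element copies.
#' @param control_calls Optional control-genotype calls.
#' @param params [detection_params()].
#' @return Insertion-call data.frame.
#' @export
detect_insertions <- function(aln, reference, te, te_intervals,
                              control_calls = NULL,
                              params = detection_params()) {
  disc <- find_discordant_candidates(aln, te, params)
  unmapped <- aln[!aln$mapped, c("qname", "seq")]
  frags <- find_junction_fragments(unmapped, te, params)
  junc <- remap_fragments(frags, reference, params)
  ev <- rbind(disc, junc)
  cl <- cluster_evidence(ev, params)
  call_insertions(cl, te_intervals, control_calls, params, reference)
}

#' Confirm a call by in-silico PCR
#'
#' Designs flanking primers from the reference around the call and
#' compares product sizes: across a true insertion the mutated-genome
#' product is longer than the reference product by the element length
#' plus the TSD.
#'
#' @param call One row of a calls data.frame.
#' @param reference Reference `DNAStringSet`.
#' @param mutated Mutated genome `DNAStringSet` (same chromosome names).
#' @param te `TEConsensus`.
#' @param primer_len,flank Primer length and distance from the call (bp).
#' @return `TRUE` when the size difference equals element + TSD within
#'   `max_tsd` slack of the unknown duplication, `FALSE` otherwise.
#' @export
insilico_pcr_confirm <- function(call, reference, mutated, te,
                                 primer_len = 20, flank = 150) {
  ref <- as.character(reference[[call$chrom]])
  mut <- as.character(mutated[[call$chrom]])
  fwd_s <- call$start - flank - primer_len
  rev_s <- call$start + flank
  if (fwd_s < 1 || rev_s + primer_len - 1 > nchar(ref)) return(NA)
  fwd <- substr(ref, fwd_s, fwd_s + primer_len - 1L)
  rev_site <- substr(ref, rev_s, rev_s + primer_len - 1L)
  product <- function(template) {
    f <- gregexpr(fwd, template, fixed = TRUE)[[1]]
    r <- gregexpr(rev_site, template, fixed = TRUE)[[1]]
    if (f[1] == -1 || r[1] == -1) return(NA_integer_)
    if (length(f) > 1 || length(r) > 1) return(NA_integer_)
    as.integer(r + primer_len - f)
  }
  p_ref <- product(ref)
  p_mut <- product(mut)
  if (is.na(p_ref) || is.na(p_mut)) return(NA)
  diff <- p_mut - p_ref
  diff >= te$element_len && diff <= te$element_len + 50L
}
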