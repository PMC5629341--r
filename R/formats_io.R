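## Shared I/O and coordinate conventions.
##
## Internal convention: 1-based, closed intervals, as used by
## GenomicRanges/IRanges/Biostrings. Each on-disk format keeps its native
## convention (SAM/GFF3 1-based closed; BED/bedGraph 0-based half-open);
## rtracklayer performs those shifts. Interval length is end - start + 1
## internally and identical to the native length of every format.

#' Read a genome assembly from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]; chromosome lengths are
#'   available via [Biostrings::width()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    stop("FASTA file missing or empty: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  if (any(Biostrings::width(x) == 0L)) stop("empty sequence in ", path)
  names(x) <- nm
  x
}

#' Write a genome assembly to FASTA
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome lengths of an assembly
#'
#' @param genome A named `DNAStringSet`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

## ---- SAM ------------------------------------------------------------------

## Alignment records travel as a data.frame, one row per SAM record:
## qname, mate (1/2), mapped, chrom, pos (1-based leftmost), strand,
## cigar, mapq, unique, mate_mapped, mate_chrom, mate_pos, seq.
## The @SQ dictionary rides along as attr(x, "seqlengths").

#' Read paired-end alignments from a text SAM file
#'
#' Decodes FLAG bits into logical/strand columns so downstream code never
#' touches raw flags. Records are retrievable by read name via the `qname`
#' column. Mapping uniqueness is taken from MAPQ (>= 2, i.e. the aligner
#' reported a single best placement).
#'
#' @param path Path to a SAM file with an @SQ header.
#' @return A data.frame of alignment records with attribute `seqlengths`
#'   (named vector from the header).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  seqlengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seqlengths <- stats::setNames(ln, sn)
  }
  if (!length(body)) {
    out <- empty_alignments()
    attr(out, "seqlengths") <- seqlengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  field <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(field(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  rname <- field(3)
  bad <- mapped & !(rname %in% names(seqlengths))
  if (any(bad))
    stop("SAM record references sequence absent from header: ",
         rname[which(bad)[1]])
  out <- data.frame(
    qname = field(1),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    mapped = mapped,
    chrom = ifelse(mapped, rname, NA_character_),
    pos = ifelse(mapped, as.integer(field(4)), NA_integer_),
    strand = ifelse(!mapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    cigar = ifelse(mapped, field(6), NA_character_),
    mapq = as.integer(field(5)),
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    mate_chrom = field(7),
    mate_pos = as.integer(field(8)),
    seq = field(10),
    stringsAsFactors = FALSE
  )
  out$unique <- out$mapped & out$mapq >= 2L
  attr(out, "seqlengths") <- seqlengths
  out
}

#' Write alignment records to a text SAM file
#'
#' @param aln Alignment record data.frame as produced by [read_sam()] or
#'   [simulate_alignments()].
#' @param path Output path.
#' @param seqlengths Named vector of chromosome lengths for the @SQ header;
#'   defaults to `attr(aln, "seqlengths")`.
#' @export
write_sam <- function(aln, path, seqlengths = attr(aln, "seqlengths")) {
  if (is.null(seqlengths))
    stop("seqlengths required to write the SAM header")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  if (!nrow(aln)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- 1L +                                        # paired
    ifelse(aln$mapped, 0L, 4L) +
    ifelse(aln$mate_mapped, 0L, 8L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  ## mate-strand bit, set from the mate row where available
  key <- paste(aln$qname, 3L - aln$mate)
  self <- paste(aln$qname, aln$mate)
  mstrand <- aln$strand[match(key, self)]
  flag <- flag + ifelse(!is.na(mstrand) & mstrand == "-", 32L, 0L)
  rec <- paste(
    aln$qname, flag,
    ifelse(aln$mapped, aln$chrom, "*"),
    ifelse(aln$mapped, aln$pos, 0L),
    ifelse(aln$mapped, aln$mapq, 0L),
    ifelse(aln$mapped, aln$cigar, "*"),
    ifelse(aln$mate_mapped & !is.na(aln$mate_chrom), aln$mate_chrom, "*"),
    ifelse(aln$mate_mapped & !is.na(aln$mate_pos), aln$mate_pos, 0L),
    0L, aln$seq, "*",
    sep = "\t"
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

empty_alignments <- function() {
  data.frame(qname = character(0), mate = integer(0), mapped = logical(0),
             chrom = character(0), pos = integer(0), strand = character(0),
             cigar = character(0), mapq = integer(0),
             mate_mapped = logical(0), mate_chrom = character(0),
             mate_pos = integer(0), seq = character(0),
             unique = logical(0), stringsAsFactors = FALSE)
}

## ---- GFF3 / annotation model ----------------------------------------------

#' Build an annotation model from feature ranges
#'
#' Introns are derived as the per-gene gaps between consecutive exonic
#' pieces (exons plus UTRs). Used both by [read_gff3()] and by the
#' synthetic-data generator.
#'
#' @param genes,exons,utr5,utr3,te `GRanges` with a `gene_id` (or `te_id`)
#'   metadata column; `genes` must also carry strand.
#' @return An object of class `AnnotationModel`: a list of sorted `GRanges`
#'   (`genes`, `exons`, `utr5`, `utr3`, `introns`, `te`).
#' @export
annotation_model <- function(genes, exons,
                             utr5 = GenomicRanges::GRanges(),
                             utr3 = GenomicRanges::GRanges(),
                             te = GenomicRanges::GRanges()) {
  fix_empty <- function(gr) {
    if (length(gr) == 0 && is.null(S4Vectors::mcols(gr)$gene_id))
      S4Vectors::mcols(gr)$gene_id <- character(0)
    gr
  }
  utr5 <- fix_empty(utr5); utr3 <- fix_empty(utr3)
  gid <- S4Vectors::mcols(exons)$gene_id
  ok <- GenomicRanges::findOverlaps(exons, genes, type = "within")
  hit_ok <- gid == S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(ok)]
  covered <- tabulate(S4Vectors::queryHits(ok)[hit_ok], length(exons)) > 0
  if (!all(covered))
    stop("exon outside its parent gene span: ", paste(gid[!covered],
         collapse = ", "))
  empty_gid <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    gr
  }
  transcribed <- suppressWarnings(c(exons, utr5, utr3))
  introns <- empty_gid()
  if (length(transcribed)) {
    per_gene <- split(transcribed,
                      S4Vectors::mcols(transcribed)$gene_id)
    glist <- lapply(names(per_gene), function(g) {
      gr <- GenomicRanges::reduce(per_gene[[g]], ignore.strand = TRUE)
      if (length(gr) < 2) return(empty_gid())
      gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
      gaps <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr)[-length(gr)],
        IRanges::IRanges(GenomicRanges::end(gr)[-length(gr)] + 1L,
                         GenomicRanges::start(gr)[-1L] - 1L))
      gaps <- gaps[GenomicRanges::width(gaps) > 0]
      S4Vectors::mcols(gaps)$gene_id <- rep(g, length(gaps))
      gaps
    })
    introns <- suppressWarnings(do.call(c, c(glist, list(empty_gid()))))
  }
  m <- list(genes = GenomicRanges::sort(genes, ignore.strand = TRUE),
            exons = GenomicRanges::sort(exons, ignore.strand = TRUE),
            utr5 = GenomicRanges::sort(utr5, ignore.strand = TRUE),
            utr3 = GenomicRanges::sort(utr3, ignore.strand = TRUE),
            introns = GenomicRanges::sort(introns, ignore.strand = TRUE),
            te = GenomicRanges::sort(te, ignore.strand = TRUE))
  class(m) <- "AnnotationModel"
  m
}

#' Read gene and TE annotation from GFF3
#'
#' Parses gene/exon/UTR and transposable-element features, checks that
#' children lie inside their parents, and derives introns.
#'
#' @param path Path to a GFF3 file.
#' @return An `AnnotationModel` (see [annotation_model()]).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gene_id_of <- function(x, raw) {
    id <- raw$ID
    par <- raw$Parent
    if (!is.null(par) && length(par)) {
      p <- vapply(as.list(par), function(v)
        if (length(v)) v[[1]] else NA_character_, "")
      id <- ifelse(is.na(p), as.character(id), p)
    }
    as.character(id)
  }
  genes <- gr[typ == "gene"]
  g <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                              IRanges::IRanges(GenomicRanges::start(genes),
                                               GenomicRanges::end(genes)),
                              strand = GenomicRanges::strand(genes))
  S4Vectors::mcols(g)$gene_id <- as.character(genes$ID)
  grab <- function(t) {
    x <- gr[typ %in% t]
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(x),
                                  IRanges::IRanges(GenomicRanges::start(x),
                                                   GenomicRanges::end(x)),
                                  strand = GenomicRanges::strand(x))
    S4Vectors::mcols(out)$gene_id <- gene_id_of(out, S4Vectors::mcols(x))
    out
  }
  te_raw <- gr[typ %in% c("transposable_element", "transposable_element_gene")]
  te <- GenomicRanges::GRanges(GenomicRanges::seqnames(te_raw),
                               IRanges::IRanges(GenomicRanges::start(te_raw),
                                                GenomicRanges::end(te_raw)))
  if (length(te)) {
    S4Vectors::mcols(te)$te_id <- as.character(te_raw$ID)
    fam <- te_raw$family
    S4Vectors::mcols(te)$family <-
      if (is.null(fam)) NA_character_ else as.character(fam)
  } else {
    S4Vectors::mcols(te)$te_id <- character(0)
    S4Vectors::mcols(te)$family <- character(0)
  }
  annotation_model(g, grab("exon"),
                   utr5 = grab(c("five_prime_UTR", "5UTR")),
                   utr3 = grab(c("three_prime_UTR", "3UTR")),
                   te = te)
}

#' Write an annotation model to GFF3
#'
#' @param annot An `AnnotationModel`.
#' @param path Output path.
#' @export
write_gff3 <- function(annot, path) {
  tag <- function(gr, type, id, parent = NULL) {
    if (!length(gr)) return(NULL)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     src = "onsenscan", type = type,
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     score = ".",
                     strand = as.character(GenomicRanges::strand(gr)),
                     phase = ".")
    df$strand[df$strand == "*"] <- "."
    df$attr <- if (is.null(parent)) paste0("ID=", id)
               else paste0("ID=", id, ";Parent=", parent)
    df
  }
  g <- annot$genes
  n_of <- function(gr) seq_len(length(gr))
  rows <- rbind(
    tag(g, "gene", g$gene_id),
    tag(annot$exons, "exon",
        paste0(annot$exons$gene_id, ".exon", n_of(annot$exons)),
        annot$exons$gene_id),
    tag(annot$utr5, "five_prime_UTR",
        paste0(annot$utr5$gene_id, ".utr5.", n_of(annot$utr5)),
        annot$utr5$gene_id),
    tag(annot$utr3, "three_prime_UTR",
        paste0(annot$utr3$gene_id, ".utr3.", n_of(annot$utr3)),
        annot$utr3$gene_id),
    tag(annot$te, "transposable_element", annot$te$te_id)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(rows))
    writeLines(do.call(paste, c(rows, sep = "\t")), con)
  invisible(path)
}

## ---- bedGraph tile tracks --------------------------------------------------

#' Construct a tile track
#'
#' A tile track holds one enrichment value per fixed-width tile, tiles
#' contiguous from position 1 of each chromosome (the last tile may be
#' truncated at the chromosome end).
#'
#' @param values Named list (by chromosome) of numeric per-tile values.
#' @param tile_width Tile width in bp.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return An object of class `TileTrack`.
#' @export
tile_track <- function(values, tile_width, chrom_lengths) {
  stopifnot(tile_width >= 1, all(names(values) %in% names(chrom_lengths)))
  for (ch in names(values)) {
    ntile <- ceiling(chrom_lengths[[ch]] / tile_width)
    if (length(values[[ch]]) != ntile)
      stop("tile count mismatch on ", ch, ": got ", length(values[[ch]]),
           ", expected ", ntile)
  }
  structure(list(values = values, tile_width = as.integer(tile_width),
                 chrom_lengths = chrom_lengths[names(values)]),
            class = "TileTrack")
}

#' Read a tiled enrichment track from bedGraph
#'
#' Intervals must be aligned to the tile grid (start a multiple of
#' `tile_width`, spanning whole tiles); tiles absent from the file get
#' value 0.
#'
#' @param path Path to a bedGraph file (0-based half-open, as the format
#'   specifies).
#' @param tile_width Tile width in bp (default 60).
#' @param chrom_lengths Named lengths; defaults to the furthest covered
#'   tile per chromosome.
#' @return A `TileTrack`.
#' @export
read_bedgraph_tiles <- function(path, tile_width = 60, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  ch <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L       # back to 0-based
  e0 <- GenomicRanges::end(gr)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(e0, ch), max, 0)
    chrom_lengths <- chrom_lengths[unique(ch)]
  }
  bad <- which(s0 %% tile_width != 0 |
                 (e0 %% tile_width != 0 & e0 != chrom_lengths[ch]))
  if (length(bad))
    stop("bedGraph interval not aligned to the ", tile_width,
         "-bp tile grid at line ", bad[1], ": ", ch[bad[1]], ":",
         s0[bad[1]], "-", e0[bad[1]])
  values <- lapply(stats::setNames(nm = names(chrom_lengths)), function(cc) {
    n <- ceiling(chrom_lengths[[cc]] / tile_width)
    v <- numeric(n)
    i <- which(ch == cc)
    if (length(i)) {
      first <- s0[i] %/% tile_width + 1L
      last <- pmin(n, (e0[i] - 1L) %/% tile_width + 1L)
      for (k in seq_along(i)) v[first[k]:last[k]] <- gr$score[i[k]]
    }
    v
  })
  tile_track(values, tile_width, chrom_lengths)
}

#' Write a tile track to bedGraph
#'
#' Adjacent equal-valued tiles are merged into single intervals.
#'
#' @param track A `TileTrack`.
#' @param path Output path.
#' @export
write_bedgraph_tiles <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    len <- track$chrom_lengths[[ch]]
    r <- rle(v)
    e_tile <- cumsum(r$lengths)
    s_tile <- c(0L, e_tile[-length(e_tile)])
    data.frame(chrom = ch,
               start = s_tile * track$tile_width,
               end = pmin(e_tile * track$tile_width, len),
               score = r$values)
  })
  df <- do.call(rbind, rows)
  df <- df[df$score != 0, , drop = FALSE]    # sparse convention
  writeLines(do.call(paste, c(df, sep = "\t")), path)
  invisible(path)
}

## ---- insertion-call tables -------------------------------------------------

#' Read / write insertion-call tables
#'
#' Calls travel as a TSV with columns chrom, start, end (1-based closed
#' span of the insertion point or TSD), orientation, tsd_len, tsd_seq,
#' n_discordant, n_junction5, n_junction3, status.
#'
#' @param path File path.
#' @return A data.frame of insertion calls.
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "orientation", "tsd_len", "tsd_seq",
            "n_discordant", "n_junction5", "n_junction3", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("call table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_calls
#' @param calls A data.frame of insertion calls.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
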