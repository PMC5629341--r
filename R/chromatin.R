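## Euchromatin / heterochromatin partition from H3K9me2 tile enrichment:
## moving-average smoothing, thresholding of the smoothed signal, and
## rounding of the resulting domain bounds to a coarse grid.

#' Smooth a tile track with a centered moving average
#'
#' Each tile gets the mean of the raw values over a centered window of
#' `window_tiles` tiles, truncated at chromosome ends (mean over the
#' available tiles); a window larger than the chromosome degenerates to
#' the global mean.
#'
#' @param track A `TileTrack`.
#' @param window_tiles Window size in tiles (default 100).
#' @return A smoothed `TileTrack`.
#' @export
smooth_track <- function(track, window_tiles = 100) {
  stopifnot(window_tiles >= 1)
  half_l <- (window_tiles - 1L) %/% 2L
  half_r <- window_tiles - 1L - half_l
  values <- lapply(track$values, function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(1L, seq_len(n) - half_l)
    hi <- pmin(n, seq_len(n) + half_r)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  tile_track(values, track$tile_width, track$chrom_lengths)
}

round_to_grid <- function(x, grid) floor(x / grid + 0.5) * grid

#' Partition a smoothed track into heterochromatin and euchromatin
#'
#' Maximal runs of tiles with smoothed value strictly above `threshold`
#' become heterochromatin intervals; interval bounds are rounded half-up
#' to the nearest multiple of `round_to` (chromosome ends exempt),
#' intervals that collapse are dropped, overlapping rounded intervals are
#' merged, and the per-chromosome complement is euchromatin.
#'
#' @param smoothed A smoothed `TileTrack` (see [smooth_track()]).
#' @param threshold Enrichment threshold on the smoothed signal
#'   (default 1.5).
#' @param round_to Rounding granularity in bp (default 100 kb).
#' @return A list of class `ChromatinPartition`: `het` and `eu` (GRanges),
#'   `sizes_mbp`, and `provenance`.
#' @export
partition_track <- function(smoothed, threshold = 1.5, round_to = 1e5) {
  tw <- smoothed$tile_width
  het_list <- list()
  eu_list <- list()
  for (ch in names(smoothed$values)) {
    v <- smoothed$values[[ch]]
    len <- smoothed$chrom_lengths[[ch]]
    r <- rle(v > threshold)
    e_tile <- cumsum(r$lengths)
    s_tile <- c(0L, e_tile[-length(e_tile)]) + 1L
    iv <- cbind(s_tile[r$values], e_tile[r$values])
    rows <- NULL
    if (nrow(iv)) {
      s0 <- (iv[, 1] - 1L) * tw                   # 0-based bounds
      e0 <- pmin(iv[, 2] * tw, len)
      rs <- pmin(pmax(round_to_grid(s0, round_to), 0), len)
      re <- pmin(pmax(round_to_grid(e0, round_to), 0), len)
      keep <- re > rs
      if (any(keep))
        rows <- GenomicRanges::reduce(GenomicRanges::GRanges(
          ch, IRanges::IRanges(rs[keep] + 1L, re[keep])))
    }
    if (is.null(rows)) rows <- GenomicRanges::GRanges()
    het_list[[ch]] <- rows
    whole <- GenomicRanges::GRanges(ch, IRanges::IRanges(1L, len))
    eu_list[[ch]] <- GenomicRanges::setdiff(whole, rows)
  }
  het <- suppressWarnings(
    do.call(c, c(unname(het_list), list(GenomicRanges::GRanges()))))
  eu <- suppressWarnings(
    do.call(c, c(unname(eu_list), list(GenomicRanges::GRanges()))))
  part <- list(het = het, eu = eu,
               sizes_mbp = c(eu = sum(GenomicRanges::width(eu)) / 1e6,
                             het = sum(GenomicRanges::width(het)) / 1e6),
               provenance = list(tile_width = tw,
                                 threshold = threshold,
                                 round_to = round_to),
               chrom_lengths = smoothed$chrom_lengths)
  class(part) <- "ChromatinPartition"
  part
}

#' One-step chromatin partition from a raw tile track
#'
#' Smooths with [smooth_track()] and thresholds with [partition_track()].
#' `mode = "absolute"` (default) calls heterochromatin where the smoothed
#' signal exceeds `threshold`; `mode = "ratio"` calls it where the raw
#' signal exceeds `threshold` times the smoothed trend (the alternative
#' reading of an above-trend filter).
#'
#' @inheritParams smooth_track
#' @inheritParams partition_track
#' @param mode `"absolute"` or `"ratio"`.
#' @return A `ChromatinPartition`.
#' @export
chromatin_partition <- function(track, window_tiles = 100, threshold = 1.5,
                                round_to = 1e5,
                                mode = c("absolute", "ratio")) {
  mode <- match.arg(mode)
  sm <- smooth_track(track, window_tiles)
  if (mode == "absolute") return(partition_track(sm, threshold, round_to))
  ratio <- tile_track(
    mapply(function(raw, trend) ifelse(trend > 0, raw / trend, 0),
           track$values, sm$values, SIMPLIFY = FALSE),
    track$tile_width, track$chrom_lengths)
  partition_track(ratio, threshold, round_to)
}

#' Class sizes of a chromatin partition
#'
#' @param partition A `ChromatinPartition`.
#' @return Named numeric vector `c(eu = , het = )` in Mbp.
#' @export
class_sizes <- function(partition) partition$sizes_mbp

#' Write a chromatin partition as BED
#'
#' @param partition A `ChromatinPartition`.
#' @param path Output path.
#' @export
write_partition_bed <- function(partition, path) {
  row <- function(gr, cls)
    if (length(gr)) data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,    # BED 0-based
      end = GenomicRanges::end(gr), name = cls) else NULL
  df <- rbind(row(partition$het, "heterochromatin"),
              row(partition$eu, "euchromatin"))
  df <- df[order(df$chrom, df$start), ]
  writeLines(do.call(paste, c(df, sep = "\t")), path)
  invisible(path)
}
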