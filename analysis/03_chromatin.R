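#!/usr/bin/env Rscript
# Partition the simulated genome into euchromatin and heterochromatin
# from the H3K9me2 tile track (100-tile moving average, threshold 1.5 on
# the smoothed signal) and compare with the generator's truth blocks.
# Bound rounding is scaled to the toy genome: 10 kb on a 250-kb
# chromosome plays the role the 100-kb grid plays at megabase scale.

suppressMessages(library(onsenscan))
dir.create("results", showWarnings = FALSE)
st <- readRDS("scratch/sim/state.rds")

trk <- read_bedgraph_tiles("scratch/sim/h3k9me2.bedgraph", 60,
                           chrom_lengths = chrom_lengths(st$gen$genome))
part <- chromatin_partition(trk, window_tiles = 100, threshold = 1.5,
                            round_to = 1e4)
write_partition_bed(part, "results/partition.bed")
saveRDS(part, "scratch/sim/partition.rds")

cat("class sizes (Mbp): euchromatin", round(class_sizes(part)["eu"], 3),
    "heterochromatin", round(class_sizes(part)["het"], 3), "\n")
for (i in seq_along(st$gen$het)) {
  ch <- as.character(GenomicRanges::seqnames(st$gen$het))[i]
  got <- part$het[as.character(GenomicRanges::seqnames(part$het)) == ch]
  cat(ch, "truth", GenomicRanges::start(st$gen$het)[i], "-",
      GenomicRanges::end(st$gen$het)[i], "recovered",
      if (length(got)) paste(GenomicRanges::start(got), "-",
                             GenomicRanges::end(got)) else "none", "\n")
}
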