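#!/usr/bin/env Rscript
# Run the two-step detector (discordant pairs + junction reads) on the
# simulated alignments and score the calls against the planted truth.

suppressMessages(library(onsenscan))
dir.create("results", showWarnings = FALSE)
st <- readRDS("scratch/sim/state.rds")

calls <- detect_insertions(st$aln, st$gen$genome, st$te, st$gen$te_copies)
write_calls(calls, "results/calls.tsv")

novel <- calls[calls$status == "novel", ]
truth <- st$pl$truth
hit <- vapply(seq_len(nrow(truth)), function(i)
  any(novel$chrom == truth$chrom[i] &
        abs(novel$start - (truth$point[i] + 1L)) <= 20), NA)
cat(nrow(calls), "calls:", nrow(novel), "novel,",
    sum(calls$status == "preexisting"), "preexisting,",
    sum(calls$status == "low_support"), "low-support\n")
cat("recall:", sum(hit), "/", nrow(truth),
    "; exact TSD:", sum(novel$tsd_len == truth$tsd_len[1], na.rm = TRUE),
    "/", sum(!is.na(novel$tsd_len)), "\n")

## confirm a sample of novel calls by in-silico PCR across the element
pick <- novel[seq_len(min(21, nrow(novel))), ]
conf <- vapply(seq_len(nrow(pick)), function(i)
  isTRUE(insilico_pcr_confirm(pick[i, ], st$gen$genome, st$pl$genome,
                              st$te)), NA)
cat("in-silico PCR confirmed:", sum(conf), "/", nrow(pick), "\n")
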