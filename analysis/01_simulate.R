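#!/usr/bin/env Rscript
# Build the synthetic study: a toy genome with pericentromeric
# heterochromatin, an Onsen-like LTR element, pre-existing copies, 30
# planted insertions with 5-bp TSDs, 30x paired-end alignments against
# the TE-masked reference, an H3K9me2-like tile track, and an RNA-seq
# count table with insertion-linked heat activation. Everything is
# written under scratch/sim/ for the later stages.

suppressMessages(library(onsenscan))
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
set.seed(42)

cfg <- sim_config(n_chrom = 2, chrom_len = 250e3, n_te_copies = 3,
                  n_insertions = 30)
te <- build_te_consensus(cfg$element_len, cfg$ltr_len)
gen <- build_toy_genome(cfg, te)
pl <- plant_insertions(gen$genome, gen$annot, te, cfg)
masked <- mask_te_copies(gen$genome, gen$te_copies)
aln <- simulate_alignments(pl$genome, masked, te, cfg, pl$truth,
                           gen$te_copies)
trk <- simulate_h3k9me2_track(gen$het, gen$genome)
ct <- simulate_count_table(gen$annot, pl$truth)

write_fasta(gen$genome, "scratch/sim/reference.fa")
write_fasta(pl$genome, "scratch/sim/mutated.fa")
write_fasta(stats::setNames(Biostrings::DNAStringSet(te$seq), te$id),
            "scratch/sim/te_consensus.fa")
write_gff3(gen$annot, "scratch/sim/annotation.gff3")
write_sam(aln, "scratch/sim/case.sam")
write_bedgraph_tiles(trk, "scratch/sim/h3k9me2.bedgraph")
utils::write.table(pl$truth, "scratch/sim/truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cbind(gene_id = rownames(ct$counts), ct$counts),
                   "scratch/sim/counts.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(ct$effects, "scratch/sim/planted_effects.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(cfg = cfg, te = te, gen = gen, pl = pl, aln = aln, trk = trk,
             ct = ct), "scratch/sim/state.rds")

cat("Simulated", cfg$n_chrom, "chromosomes x", cfg$chrom_len / 1e3, "kb;",
    nrow(pl$truth), "planted insertions (",
    sum(pl$truth$genic), "genic );", nrow(aln), "reads;",
    sum(!aln$mapped), "unmapped\n")
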