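---
title: "Detecting LTR retrotransposon neo-insertions and characterizing their chromosomal landscape"
author: "onsenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting LTR retrotransposon neo-insertions and characterizing their chromosomal landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Onsen (ATCOPIA78) is a heat-stress-activated Ty1/copia LTR retrotransposon
of *Arabidopsis thaliana*. In small-RNA-deficient backgrounds such as
*nrpd1*, heat stress mobilizes it, and progeny of stressed plants carry
new chromosomal copies ("neo-insertions") absent from the parental
genome. `onsenscan` implements the computational side of such a study as
one reusable, tested pipeline:

1. **Detection** of neo-insertions from paired-end whole-genome
   sequencing, using two evidence classes against a TE-masked reference:
   *discordant pairs* (one mate uniquely anchored on a chromosome, the
   other derived from the element's LTR) and *junction reads* (reads
   spanning the host/element boundary, trimmed of the element part and
   remapped to localize the breakpoint and resolve the target-site
   duplication, TSD).
2. **Landscape statistics**: an H3K9me2-based euchromatin /
   heterochromatin partition, insertion densities per Mbp, an eight-way
   genic category table, Fisher and hypergeometric enrichment tests, a
   matched-random-locus permutation test of window-count variance with a
   gamma tail fit, Kolmogorov-Smirnov distance comparisons, and a
   gene-length-corrected chi-squared test.
3. **Expression impact**: counts-per-million presence calling,
   activation classification from a differential-expression table, and
   orientation/distance mapping of insertions to target and adjacent
   genes with aggregate fractions.
4. A **synthetic-data generator** that produces toy genomes, planted
   insertions with known TSDs, read alignments, chromatin tracks, and
   negative-binomial count tables, so every stage has a ground truth.

## Coordinate conventions

Internally everything is 1-based with closed intervals, the native
convention of GenomicRanges/IRanges/Biostrings on which the package
stands. Each file format keeps its own convention (SAM and GFF3 1-based
closed; BED and bedGraph 0-based half-open); `rtracklayer` performs those
shifts on import/export. Interval lengths are therefore identical in
every frame.

One package-specific convention matters downstream: for an insertion
whose target site began at reference base `p + 1` with TSD length `t`,
the mutated chromosome is `ref[1..p+t] + element + ref[p+1..L]`, the two
junction sides remap to reference positions `p + t` (element-left side)
and `p` (element-right side), and the emitted call spans
`[p + 1, p + t]` — exactly the duplicated target site, so the call width
*is* the TSD length. TSD length is always inferred from the junction
offset, never assumed.

## The detector and its thresholds

The original procedure left final calls to manual assessment, so all
numeric thresholds here are explicit parameters (`detection_params()`):

| parameter | default | role |
|---|---|---|
| `min_ltr_match` | 25 bp | minimum ungapped match of a read to the LTR |
| `min_ltr_identity` | 0.90 | identity over the matched span |
| `min_fragment_len` | 20 bp | minimum trimmed genomic fragment |
| `cluster_window` | 390 bp | single-linkage clustering window (insert mean + 3 sd) |
| `min_discordant` | 2 | discordant pairs needed for a confident call |
| `min_junction` | 1 | junction reads needed |
| `max_tsd` | 20 bp | largest credible TSD before a cluster is split |

LTR matching is seed-and-verify: exact 13-mers fix a diagonal, and the
full clipped overlap on that diagonal is compared base by base. Because
the overlap is clipped at the LTR's ends, a junction read's genomic part
never dilutes the identity of its element part. Junction trimming
requires the match to reach the LTR's *outer* end (LTR start for the
element's 5' extremity, LTR end for the 3' extremity) — that is what
distinguishes a genuine element boundary from element-internal sequence.
Trimmed fragments are remapped by exact full-length search on both
strands; only unique hits become evidence, and fragments with 0 or
multiple hits are counted and dropped. Exact search (rather than scored
local alignment) is sufficient at this scale because junction fragments
carrying a sequencing error simply fail to place and the remaining
error-free fragments carry the same junction point; it also makes the
junction coordinates deterministic.

Element orientation falls out of the evidence geometry: the strand on
which a trimmed fragment remaps equals the element's orientation, and a
discordant pair votes `+` exactly when its anchor strand differs from the
working strand of the mate's LTR match. Calls take the majority vote.

Status assignment codifies the background subtraction: a cluster within
`cluster_window` of a known element copy is `preexisting` (masking is the
mechanism by which pre-existing copies exist, so their flanks always
accumulate evidence); a cluster within the window of a control-genotype
call is `control_shared`; support below `min_discordant`/`min_junction`
is `low_support`; the rest are `novel`.

## The synthetic generator

`sim_config()` defaults describe the sequencing design the pipeline
targets: 75-bp paired-end reads, 300 ± 30 bp inserts, 30x coverage,
per-base substitution error 0.005, TSD length 5 bp (canonical for
Ty1/copia integration), an Onsen-like element of 4.9 kb with 400-bp
LTRs, ~90% genic targeting, and chromosomes with one central
heterochromatin block (fraction 0.15) whose euchromatic arms are tiled
with multi-exon genes (one per 4 kb, about the Arabidopsis spacing;
each gene is 5'UTR + three exons + two introns + 3'UTR, random strand).

The simulator emits alignments directly instead of FASTQ plus an
external aligner, so tests need no third-party binaries (`write_fastq()`
exists for users who want a real aligner). The mapping rule is: a mate
is reported mapped iff its error-free sequence lies entirely within
reference-derived, unmasked sequence — which at these genome sizes
equals "has a unique full-length exact match in the masked reference"
(asserted against a search oracle in the tests). Reads spanning an
insertion junction, inside the inserted element, or inside a masked copy
are reported unmapped with their sequence, which is the detector's
input. Substitution errors are applied after the mapping decision, so
mapping reflects the error-free placement; there are no indel errors, no
base-quality model and no PCR duplicates.

Planted sites keep a minimum spacing (default 5 kb) from each other,
from chromosome ends, *and from pre-existing element copies*: a site
within the clustering window of a masked copy is labeled `preexisting`
by background subtraction — correctly so — which would make planted
truth there undetectable as novel by construction.

What passing tests on this generator do show: the evidence logic, TSD
arithmetic, clustering, background subtraction and every statistic
downstream are correct on data with exactly the structure the method
assumes. What they do not show: robustness to indels, mapping-quality
artifacts, segmental duplications near breakpoints, or non-uniform
coverage in real libraries.

## Chromatin partition

Tile enrichment (60-bp tiles) is smoothed with a centered 100-tile
moving average, truncated at chromosome ends (a window larger than the
chromosome degenerates to the global mean). Centering avoids the
systematic boundary shift a trailing window would introduce. "Above the
trend line of 1.5" is read as *smoothed value > 1.5* (an absolute
threshold on the smoothed signal); the alternative reading — raw signal
above 1.5 x the smoothed trend — is available as `mode = "ratio"` in
`chromatin_partition()` but is not the default, because a ratio filter
flags noise spikes in low-signal regions rather than broad enriched
domains. Run bounds are rounded half-up to the nearest 100 kb,
collapsed intervals dropped, overlaps merged, and the complement is
euchromatin. On megabase-scale chromosomes the partition recovers
simulated two-level tracks (high 3.0 / low 0.5, sd 0.3) to within one
rounding unit per boundary; toy-scale analyses scale the grid
accordingly (the bundled drivers use 10 kb on 250-kb chromosomes).

## Landscape statistics

*Categories.* Each call point maps to exactly one of eight categories
with precedence TE feature > exon > 5'UTR > 3'UTR > intron > promoter
(< 500 bp, then 500–1000 bp upstream of the nearest TSS on that gene's
strand) > intergenic. The precedence had to be decided here (overlap
cases are not otherwise specified); it is configurable through the
annotation model, and category counts always sum to the number of calls.

*Enrichment.* The euchromatin test feeds insertion counts against class
sizes in whole Mbp into a two-sided Fisher exact test — the same
quantities a summary table prints — via `stats::fisher.test`, which the
test suite checks against full hypergeometric enumeration for every 2x2
table with N <= 40. Genic enrichment is an upper-tail hypergeometric
probability over a base-pair population at 1-bp resolution.

*Permutation test.* For each observed call a random locus of the same
length is drawn uniformly from the euchromatin of the same chromosome
(never crossing a class boundary). Per-window counts use 1-Mbp sliding
windows at a 100-kb step restricted to euchromatin; the step is not
otherwise specified, and 100 kb (10 windows per span) is the package's
default, with step = window giving disjoint windows. The *population*
variance of the count vector is the statistic (the estimator choice
cancels, as observed and permuted samples use the same one). A gamma
distribution is fitted to the permuted variances by moment matching
(shape = mean^2/var, scale = var/mean) and the reported p is its upper
tail at the observed variance; the empirical tail proportion is always
reported alongside, and is the fallback when the permuted variances are
degenerate. When window and step align with the euchromatin grid the
permutation engine bins loci at step resolution and computes window
counts as moving sums — an exact shortcut asserted against the generic
counter in the tests — which is what makes 1000-permutation runs
instantaneous and calibration over hundreds of replicates affordable.
Calibration (uniform calls give a ~5% false-positive rate at alpha =
0.05) and power (calls confined to 5% of euchromatin give p < 0.01)
are checked over 200 and 100 replicates respectively on a three-
chromosome 12-Mb partition with 100 calls per replicate.

*Distances and length correction.* The distance comparison between
altered and unaltered adjacent genes is a two-sample KS test (asymptotic
p). The gene-length correction compares observed class counts among
targeted genes against expectation proportional to the summed gene
length per class — the construction is one defensible reading of
"corrected for gene length" and is flagged as such here.

## Expression impact

Genes are deemed expressed with strictly more than 5 CPM in at least 2
samples. Differential-expression status uses log2FC >= 1 and BH-FDR
< 0.05 (boundary semantics: >= on the fold change, < on the FDR). The
module consumes a DE table; a deliberately simple fallback (pooled
exact binomial test per gene + BH) is included only so self-contained
simulations need no external engine — it models no dispersion and is
not equivalent to a negative-binomial DE fit, but recovers planted
eight-fold activations at >= 90% under the generator's defaults
(baseline mean 500, dispersion 0.05). The target gene of an insertion
is the one whose span extended 500 bp upstream contains the point;
adjacent genes are others within 12 kb, the largest influence distance
observed in practice. All fractions are reported with numerator and
denominator, and empty denominators yield NA with count 0.

## Problem sizes and numerical choices

The validation suite uses: two 250-kb chromosomes, 30 planted
insertions, 30x coverage and 10 seeds for detection recall/precision
(plus 10 insertion-free seeds for precision); 20 seeds at 20x for the
evidence-guarantee property; a 12-Mb euchromatin partition with 100
calls per replicate for permutation calibration/power; 1e5 draws for
gamma moment-matching recovery; and five 2-Mb chromosomes for partition
recovery. These sizes were chosen so the full suite runs on a laptop
while every property keeps its statistical meaning; all scale linearly
if increased.

Ties and degenerate inputs: coverage 0 yields an empty (not erroneous)
alignment set; a zero margin in the Fisher table gives p = 1 by
convention; observed variance 0 sits at the gamma's lower support bound
(p = 1); clusters whose junction spread exceeds `max_tsd` are split
into single-sided candidates rather than reporting an implausible TSD;
orientation ties break toward `+`.

## Known limitations

- The detector targets one element family per run and does not genotype
  zygosity (in the motivating study zygosity was resolved genetically).
- Exact-match remapping will under-call junction evidence in genomes
  with near-identical segmental duplications at breakpoints; the
  mismatch-tolerant LTR matcher does not extend to fragment placement.
- The naive DE fallback must not be used for real differential
  expression; supply a proper DE table.
- The simulator's genomes are uniform-random sequence: mappability is
  optimistic relative to real repeat-rich genomes.
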