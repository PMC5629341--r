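## Self-contained benchmark experiments over the synthetic generator:
## detection recall/precision against planted truth, and calibration/power
## of the permutation variance test. These back the package's validation
## suite and the reproduction script.

#' Detection benchmark against planted truth
#'
#' For each seed: build a toy genome, plant insertions, simulate
#' alignments against the TE-masked reference, run the full detector, and
#' score novel calls against the truth table. A truth insertion at point p
#' is recovered when a novel call starts within `tol` bp of p + 1; a
#' novel call matching no truth record is a false positive.
#'
#' @param seeds Integer vector of RNG seeds, one replicate each.
#' @param config [sim_config()] for the replicates; the default scales the
#'   genome to two 250-kb chromosomes so a replicate (30 insertions, 30x)
#'   simulates and detects in seconds while keeping every evidence class.
#' @param tol Matching tolerance in bp (default the detector's `max_tsd`).
#' @param params [detection_params()].
#' @param keep_last Keep the final replicate's objects (genomes, truth,
#'   calls) for downstream inspection.
#' @return A list: `per_seed` data.frame (n_truth, n_novel, recovered,
#'   false_pos, tsd_exact, tsd_called), aggregate `recall`, `precision`,
#'   `tsd_exact_fraction`, and optionally `last`.
#' @export
detection_benchmark <- function(seeds,
                                config = sim_config(n_chrom = 2,
                                                    chrom_len = 250e3,
                                                    n_te_copies = 3),
                                tol = NULL,
                                params = detection_params(),
                                keep_last = FALSE) {
  if (is.null(tol)) tol <- params$max_tsd
  rows <- vector("list", length(seeds))
  last <- NULL
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    te <- build_te_consensus(config$element_len, config$ltr_len)
    gen <- build_toy_genome(config, te)
    pl <- plant_insertions(gen$genome, gen$annot, te, config)
    masked <- mask_te_copies(gen$genome, gen$te_copies)
    aln <- simulate_alignments(pl$genome, masked, te, config, pl$truth,
                               gen$te_copies)
    calls <- detect_insertions(aln, gen$genome, te, gen$te_copies,
                               params = params)
    novel <- calls[calls$status == "novel", , drop = FALSE]
    matched_truth <- logical(nrow(pl$truth))
    matched_call <- logical(nrow(novel))
    tsd_exact <- 0L
    tsd_called <- 0L
    for (i in seq_len(nrow(pl$truth))) {
      cand <- which(novel$chrom == pl$truth$chrom[i] &
                      abs(novel$start - (pl$truth$point[i] + 1L)) <= tol)
      if (length(cand)) {
        matched_truth[i] <- TRUE
        matched_call[cand] <- TRUE
        tl <- novel$tsd_len[cand[1]]
        if (!is.na(tl)) {
          tsd_called <- tsd_called + 1L
          if (tl == pl$truth$tsd_len[i]) tsd_exact <- tsd_exact + 1L
        }
      }
    }
    rows[[si]] <- data.frame(seed = seeds[si], n_truth = nrow(pl$truth),
                             n_novel = nrow(novel),
                             recovered = sum(matched_truth),
                             false_pos = sum(!matched_call),
                             tsd_called = tsd_called,
                             tsd_exact = tsd_exact)
    if (keep_last && si == length(seeds))
      last <- list(te = te, gen = gen, plant = pl, aln = aln, calls = calls)
  }
  per_seed <- do.call(rbind, rows)
  out <- list(
    per_seed = per_seed,
    recall = sum(per_seed$recovered) / max(1L, sum(per_seed$n_truth)),
    precision = if (sum(per_seed$n_novel) > 0)
      1 - sum(per_seed$false_pos) / sum(per_seed$n_novel) else NA_real_,
    tsd_exact_fraction = if (sum(per_seed$tsd_called) > 0)
      sum(per_seed$tsd_exact) / sum(per_seed$tsd_called) else NA_real_)
  if (keep_last) out$last <- last
  out
}

#' Calibration and power of the permutation variance test
#'
#' `permutation_pvalues()` draws `n_rep` replicate call sets and returns
#' the gamma-tail p-value of each. Under `scenario = "uniform"` the calls
#' are themselves uniform matched loci, so p should be approximately
#' uniform (false-positive rate alpha at threshold alpha). Under
#' `scenario = "clustered"` the calls are confined to the leading
#' `cluster_frac` of euchromatin, and p should be small.
#'
#' @param n_rep Number of replicate datasets.
#' @param n_calls Calls per replicate.
#' @param euchromatin `GRanges` euchromatin partition.
#' @param scenario `"uniform"` or `"clustered"`.
#' @param cluster_frac Euchromatin fraction holding clustered calls.
#' @param n_perm,window,step Passed to [permutation_variance_test()].
#' @return Numeric vector of p-values, length `n_rep`.
#' @export
permutation_pvalues <- function(n_rep, n_calls, euchromatin,
                                scenario = c("uniform", "clustered"),
                                cluster_frac = 0.05, n_perm = 1000,
                                window = 1e6, step = 1e5) {
  scenario <- match.arg(scenario)
  chroms <- as.character(GenomicRanges::seqnames(euchromatin))
  sub <- euchromatin
  if (scenario == "clustered") {
    ## leading intervals (clipped) holding cluster_frac of euchromatin bp
    target <- cluster_frac * sum(GenomicRanges::width(euchromatin))
    w <- GenomicRanges::width(euchromatin)
    cum <- cumsum(w)
    k <- which(cum >= target)[1]
    sub <- euchromatin[seq_len(k)]
    excess <- cum[k] - target
    GenomicRanges::end(sub)[k] <- GenomicRanges::end(sub)[k] - round(excess)
  }
  sub_chr <- as.character(GenomicRanges::seqnames(sub))
  vapply(seq_len(n_rep), function(r) {
    skel <- data.frame(chrom = sample(sub_chr, n_calls, replace = TRUE,
                                      prob = GenomicRanges::width(sub)),
                       start = 1L, end = 1L)
    calls <- sample_matched_loci(skel, sub)
    permutation_variance_test(calls, euchromatin, n_perm = n_perm,
                              window = window, step = step)$p
  }, 0)
}
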