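## Local transcriptional influence of new insertions: counts-per-million
## presence calling, activation classification from a differential-
## expression table, orientation/distance mapping of insertions to target
## and adjacent genes, and the aggregate impact fractions.

#' Counts per million
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @return Matrix of the same shape; each column sums to 1e6 (for
#'   non-empty libraries).
#' @export
cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("empty library")
  t(t(counts) / libsize) * 1e6
}

#' Presence-call filter
#'
#' A gene is deemed expressed when strictly more than `min_cpm`
#' counts-per-million are seen in at least `min_reps` samples.
#'
#' @param cpm_matrix Output of [cpm()].
#' @param min_cpm CPM threshold (default 5, strict inequality).
#' @param min_reps Minimum qualifying samples (default 2).
#' @return Character vector of expressed gene ids.
#' @export
presence_filter <- function(cpm_matrix, min_cpm = 5, min_reps = 2) {
  keep <- rowSums(cpm_matrix > min_cpm) >= min_reps
  rownames(cpm_matrix)[keep]
}

#' Classify differential-expression records
#'
#' Activated: log2FC >= `lfc_min` and FDR < `fdr_max`; downregulated:
#' log2FC <= -`lfc_min` and FDR < `fdr_max`; unchanged otherwise.
#'
#' @param de Data.frame with `gene_id`, `log2fc`, `fdr`.
#' @param lfc_min,fdr_max Thresholds (defaults 1 and 0.05).
#' @return Data.frame `gene_id`, `status`.
#' @export
classify_de <- function(de, lfc_min = 1, fdr_max = 0.05) {
  status <- ifelse(de$log2fc >= lfc_min & de$fdr < fdr_max, "activated",
                   ifelse(de$log2fc <= -lfc_min & de$fdr < fdr_max,
                          "downregulated", "unchanged"))
  data.frame(gene_id = de$gene_id, status = status,
             stringsAsFactors = FALSE)
}

#' Naive per-gene differential-expression fallback
#'
#' A self-contained exact binomial test on pooled replicate counts (heat
#' vs control, conditioned on library sizes) with Benjamini-Hochberg
#' correction. It is deliberately simple and not equivalent to a
#' dispersion-modelling engine; use it only where a proper DE table is
#' unavailable, e.g. in self-contained simulations.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Data.frame with `sample` and `condition`
#'   (control/heat), as from [simulate_count_table()].
#' @return DE data.frame (`gene_id`, `log2fc`, `pvalue`, `fdr`).
#' @export
naive_de <- function(counts, samples) {
  heat <- samples$sample[samples$condition == "heat"]
  ctrl <- samples$sample[samples$condition == "control"]
  xh <- rowSums(counts[, heat, drop = FALSE])
  xc <- rowSums(counts[, ctrl, drop = FALSE])
  Lh <- sum(counts[, heat]); Lc <- sum(counts[, ctrl])
  p0 <- Lh / (Lh + Lc)
  pv <- vapply(seq_along(xh), function(i) {
    n <- xh[i] + xc[i]
    if (n == 0) return(1)
    stats::binom.test(xh[i], n, p0)$p.value
  }, 0)
  data.frame(gene_id = rownames(counts),
             log2fc = log2(((xh + 0.5) / Lh) / ((xc + 0.5) / Lc)),
             pvalue = pv, fdr = stats::p.adjust(pv, "BH"),
             stringsAsFactors = FALSE)
}

#' Map insertions to target and adjacent genes
#'
#' The target gene is the one whose span, extended upstream by
#' `promoter` bp, contains the insertion point (distance 0); adjacent
#' genes are the other genes within `adjacent_radius`. Orientation is
#' sense when the element's 5'->3' axis matches the gene's transcription
#' direction.
#'
#' @param calls Calls data.frame with `chrom`, `start`, `orientation`.
#' @param annot `AnnotationModel`.
#' @param adjacent_radius Adjacency radius in bp (default 12 kb, the
#'   largest influence distance seen in practice).
#' @param promoter Upstream extension counted as part of the target span
#'   (bp).
#' @return Impact data.frame: insertion, gene_id, relation
#'   (target/adjacent), orientation (sense/antisense), distance,
#'   in_promoter.
#' @export
map_insertions_to_genes <- function(calls, annot, adjacent_radius = 12000,
                                    promoter = 500) {
  g <- annot$genes
  gchr <- as.character(GenomicRanges::seqnames(g))
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  gstr <- as.character(GenomicRanges::strand(g))
  ext_s <- ifelse(gstr == "+", gs - promoter, gs)
  ext_e <- ifelse(gstr == "+", ge, ge + promoter)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    p <- calls$start[i]
    same <- gchr == calls$chrom[i]
    in_span <- same & p >= ext_s & p <= ext_e
    near <- same & !in_span &
      pmin(abs(p - gs), abs(p - ge)) <= adjacent_radius
    sense <- gstr == calls$orientation[i]
    if (any(in_span)) {
      for (j in which(in_span)) {
        in_prom <- p < gs[j] || p > ge[j]      # in the extension only
        rows[[length(rows) + 1L]] <- data.frame(
          insertion = i, gene_id = g$gene_id[j], relation = "target",
          orientation = if (sense[j]) "sense" else "antisense",
          distance = 0L, in_promoter = in_prom,
          stringsAsFactors = FALSE)
      }
    }
    for (j in which(near)) {
      rows[[length(rows) + 1L]] <- data.frame(
        insertion = i, gene_id = g$gene_id[j], relation = "adjacent",
        orientation = if (sense[j]) "sense" else "antisense",
        distance = min(abs(p - gs[j]), abs(p - ge[j])),
        in_promoter = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(insertion = integer(0), gene_id = character(0),
                      relation = character(0), orientation = character(0),
                      distance = integer(0), in_promoter = logical(0)))
  do.call(rbind, rows)
}

#' Aggregate expression-impact fractions
#'
#' Annotates each impact record with its gene's expression and DE status,
#' then reports: among expressed target genes with sense insertions, the
#' fraction activated; among expressed promoter-insertion targets, the
#' fraction activated; among expressed adjacent genes, the fraction
#' altered (activated or downregulated); and the distance vectors of
#' altered vs unaltered adjacent genes (for [ks_distance_test()]).
#' Fractions over empty denominators are NA with counts 0. Every
#' fraction is reported with its numerator and denominator.
#'
#' @param impact Impact records from [map_insertions_to_genes()].
#' @param de_status Data.frame `gene_id`, `status` from [classify_de()].
#' @param expressed Character vector of expressed gene ids (from
#'   [presence_filter()]).
#' @return A list of class `ImpactSummary`.
#' @export
impact_summary <- function(impact, de_status, expressed) {
  st <- de_status$status[match(impact$gene_id, de_status$gene_id)]
  st[is.na(st)] <- "unchanged"
  expr <- impact$gene_id %in% expressed
  impact$expressed <- expr
  impact$status <- ifelse(expr, st, "not_expressed")
  frac <- function(num, den) {
    list(n = den, k = num,
         fraction = if (den > 0) num / den else NA_real_,
         percent = if (den > 0) round(100 * num / den, 1) else NA_real_)
  }
  tgt <- impact[impact$relation == "target" & impact$expressed, ,
                drop = FALSE]
  tgt <- tgt[!duplicated(tgt$gene_id), , drop = FALSE]
  sense_tgt <- tgt[tgt$orientation == "sense", , drop = FALSE]
  prom_tgt <- tgt[tgt$in_promoter, , drop = FALSE]
  adj <- impact[impact$relation == "adjacent" & impact$expressed, ,
                drop = FALSE]
  adj <- adj[!duplicated(adj$gene_id), , drop = FALSE]
  altered <- adj$status %in% c("activated", "downregulated")
  res <- list(
    sense_target = frac(sum(sense_tgt$status == "activated"),
                        nrow(sense_tgt)),
    promoter_target = frac(sum(prom_tgt$status == "activated"),
                           nrow(prom_tgt)),
    adjacent = frac(sum(altered), nrow(adj)),
    distances_altered = adj$distance[altered],
    distances_unaltered = adj$distance[!altered],
    records = impact)
  class(res) <- "ImpactSummary"
  res
}
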