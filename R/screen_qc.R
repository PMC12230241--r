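#' Pairwise replicate Pearson correlation per (arm, timepoint)
#'
#' @param tensor A [screen_tensor()] with at least two replicates.
#' @return Data frame `arm`, `timepoint`, `replicate_a`, `replicate_b`, `r`,
#'   `undefined` (TRUE when a column is constant).
#' @export
replicate_correlation <- function(tensor) {
  reps <- tensor_replicates(tensor)
  if (length(reps) < 2L) data_error("replicate_correlation needs >= 2 replicates")
  out <- list()
  for (arm in tensor_arms(tensor)) {
    for (tp in tensor_timepoints(tensor)) {
      prs <- combn(reps, 2)
      for (j in seq_len(ncol(prs))) {
        a <- tensor$values[, tensor_cols(tensor, arm, tp, prs[1, j])]
        b <- tensor$values[, tensor_cols(tensor, arm, tp, prs[2, j])]
        undef <- sd(a) == 0 || sd(b) == 0
        out[[length(out) + 1L]] <- data.frame(
          arm = arm, timepoint = tp,
          replicate_a = prs[1, j], replicate_b = prs[2, j],
          r = if (undef) NA_real_ else cor(a, b), undefined = undef,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Precision-recall evaluation against essential / non-essential references
#'
#' Genes are ranked by ascending gene WDC score (strongest dropout first);
#' precision and recall are computed over the ranking treating reference
#' essential genes as positives and non-essential genes as negatives. Genes
#' outside both sets are ignored. `f_max` is the maximum harmonic mean of
#' precision and recall over all rank cutoffs.
#'
#' @param gene_table Data frame with `gene` and `wdc_gene`.
#' @param essential,non_essential Disjoint reference gene sets.
#' @return List with `curve` (rank, precision, recall, f) and `f_max`.
#' @export
evaluate_performance <- function(gene_table, essential, non_essential) {
  if (length(intersect(essential, non_essential)) > 0L)
    config_error("reference sets must be disjoint")
  keep <- gene_table$gene %in% c(essential, non_essential)
  if (!any(keep)) data_error("no overlap between scored genes and references")
  gt <- gene_table[keep, ]
  gt <- gt[order(gt$wdc_gene), ]
  y <- gt$gene %in% essential
  if (!any(y)) data_error("no essential reference genes among scored genes")
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  f <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  list(curve = data.frame(rank = seq_along(y), gene = gt$gene,
                          precision = precision, recall = recall, f = f),
       f_max = max(f))
}

#' Cumulative-signal fold change and KS comparison for a gene set
#'
#' Per arm, the fold change is the ratio of summed linear-scale signal
#' (2^log2, averaged over replicates) of the set's hairpins at T0 over the
#' final timepoint; a two-sample Kolmogorov-Smirnov test compares the T0 and
#' final-timepoint per-hairpin signal distributions.
#'
#' This stage is intended to run on the filtered but un-normalized tensor:
#' quantile normalization forces all samples onto a common distribution and
#' therefore compresses genuine global signal loss, which at desk scale (a
#' few hundred genes, a fifth of them moving) is a large distortion.
#'
#' @param tensor A [screen_tensor()] with T0 and a final timepoint.
#' @param gene_set Character vector of genes defining the hairpin set.
#' @return Data frame `arm`, `fold_change`, `ks_stat`, `ks_p`.
#' @export
cumulative_signal_comparison <- function(tensor, gene_set) {
  sel <- tensor$hairpins$gene %in% gene_set
  if (!any(sel)) data_error("gene set has no retained hairpins")
  tps <- tensor_timepoints(tensor)
  t0 <- tps[1]; tF <- tps[length(tps)]
  out <- lapply(tensor_arms(tensor), function(arm) {
    s0 <- rowMeans(2^tensor$values[sel, tensor_cols(tensor, arm, t0), drop = FALSE])
    s1 <- rowMeans(2^tensor$values[sel, tensor_cols(tensor, arm, tF), drop = FALSE])
    ks <- suppressWarnings(ks.test(s0, s1))
    data.frame(arm = arm, fold_change = sum(s0) / sum(s1),
               ks_stat = unname(ks$statistic), ks_p = ks$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
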