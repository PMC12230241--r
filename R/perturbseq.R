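#' QC and analysis configuration for Perturb-seq triage
#'
#' @param min_umis Minimum UMIs per retained cell (default 5000; a cell with
#'   exactly 5000 is kept).
#' @param guide_umi_min UMI support for a guide to count as detected
#'   (default 3).
#' @param k_clusters Number of k-means clusters (default 10).
#' @param n_pcs Principal components fed to k-means (default 50, capped at
#'   the data dimension).
#' @param anchor Anchor gene (default `"PLK1"`).
#' @param anchor_high_quantile Normalized-expression quantile above which a
#'   cell counts as anchor-high (default 0.9).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for clustering.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_umis = 5000, guide_umi_min = 3, k_clusters = 10,
                      n_pcs = 50, anchor = "PLK1",
                      anchor_high_quantile = 0.9, alpha = 0.05, seed = 1) {
  if (min_umis < 0) config_error("min_umis must be >= 0")
  if (anchor_high_quantile <= 0 || anchor_high_quantile >= 1)
    config_error("anchor_high_quantile must be in (0, 1)")
  structure(as.list(environment()), class = "qc_config")
}

#' Cell quality control: UMI depth and single-guide filters
#'
#' A guide is detected in a cell iff its UMI support is at least
#' `guide_umi_min`. A cell is retained iff its total UMIs are at least
#' `min_umis` and exactly one guide is detected. Removal reasons partition
#' the removed cells: the low-UMI reason takes precedence, then 0-guide,
#' then multi-guide.
#'
#' @param pop A `cell_population` (see [simulate_perturbseq()]).
#' @param cfg A [qc_config()].
#' @return List with `pop` (filtered population, with a `guide` column per
#'   cell) and `report` (counts by removal reason).
#' @export
qc_cells <- function(pop, cfg = qc_config()) {
  if (is.null(pop$guides)) data_error("qc_cells: guide table absent")
  tot <- Matrix::rowSums(pop$umi)
  det <- pop$guides[pop$guides$umis >= cfg$guide_umi_min, ]
  n_det <- as.vector(table(factor(det$cell, levels = rownames(pop$umi))))
  low <- tot < cfg$min_umis
  zero <- !low & n_det == 0L
  multi <- !low & n_det >= 2L
  keep <- !low & n_det == 1L
  g1 <- det$guide[match(rownames(pop$umi)[keep], det$cell)]
  out <- pop
  out$umi <- pop$umi[keep, , drop = FALSE]
  out$guides <- det[det$cell %in% rownames(out$umi), ]
  out$cell_guide <- setNames(g1, rownames(out$umi))
  if (!is.null(pop$truth)) out$truth <- pop$truth[keep, , drop = FALSE]
  report <- list(n_input = length(tot), n_retained = sum(keep),
                 removed = c(low_umi = sum(low), no_guide = sum(zero),
                             multi_guide = sum(multi)))
  list(pop = out, report = report)
}

#' Depth-normalize a cell population
#'
#' Counts are scaled to a common per-cell total (the median raw total) and
#' log2(1 + x) transformed, so per-cell scaled totals are equal and the
#' transform is monotone within a cell.
#'
#' @param pop A QC-filtered `cell_population`.
#' @return `pop` with a dense `norm` matrix (cell x gene) added.
#' @export
normalize_cells <- function(pop) {
  tot <- Matrix::rowSums(pop$umi)
  if (any(tot == 0)) data_error("normalize_cells: zero-UMI cell present; run qc_cells")
  target <- median(tot)
  norm <- as.matrix(pop$umi) / tot * target
  pop$norm <- log2(1 + norm)
  pop
}

## per-cell knockout label (targeted gene) from the single detected guide
cell_knockout <- function(pop) {
  if (is.null(pop$cell_guide)) data_error("run qc_cells first")
  g2gene <- setNames(pop$target_map$gene, pop$target_map$guide)
  setNames(unname(g2gene[pop$cell_guide]), names(pop$cell_guide))
}

#' Knockout-efficiency check against non-targeting controls
#'
#' For each target, a one-sided Wilcoxon rank-sum test that the target
#' gene's normalized expression is lower in its knockout cells than in
#' non-targeting control cells. Targets that fail are flagged for exclusion
#' from composition analyses.
#'
#' @param pop A normalized `cell_population`.
#' @param cfg A [qc_config()].
#' @return Data frame `gene`, `n_ko_cells`, `mean_ko`, `mean_control`, `p`,
#'   `pass`, `not_testable`.
#' @export
ko_efficiency <- function(pop, cfg = qc_config()) {
  if (is.null(pop$norm)) pop <- normalize_cells(pop)
  ko <- cell_knockout(pop)
  ctrl_cells <- names(ko)[ko == "non_targeting"]
  if (!length(ctrl_cells)) data_error("no non-targeting control cells")
  t_genes <- setdiff(unique(pop$target_map$gene), "non_targeting")
  rows <- lapply(t_genes, function(g) {
    cells <- names(ko)[ko == g]
    if (!g %in% colnames(pop$norm) || length(cells) == 0L)
      return(data.frame(gene = g, n_ko_cells = length(cells),
                        mean_ko = NA_real_, mean_control = NA_real_,
                        p = NA_real_, pass = FALSE, not_testable = TRUE))
    x <- pop$norm[cells, g]
    y <- pop$norm[ctrl_cells, g]
    p <- suppressWarnings(wilcox.test(x, y, alternative = "less")$p.value)
    data.frame(gene = g, n_ko_cells = length(cells), mean_ko = mean(x),
               mean_control = mean(y), p = p, pass = !is.na(p) && p < cfg$alpha,
               not_testable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster cells by PCA + k-means
#'
#' Deterministic given the config seed: PCA on the normalized matrix
#' (centered), k-means on the leading components with a fixed seed.
#'
#' @param pop A normalized `cell_population`.
#' @param cfg A [qc_config()].
#' @return `pop` with integer `clusters` (named by cell) added.
#' @export
cluster_cells <- function(pop, cfg = qc_config()) {
  if (is.null(pop$norm)) pop <- normalize_cells(pop)
  if (cfg$k_clusters > nrow(pop$norm))
    data_error("k_clusters exceeds the number of cells")
  npc <- min(cfg$n_pcs, ncol(pop$norm) - 1L, nrow(pop$norm) - 1L)
  pc <- prcomp(pop$norm, center = TRUE, scale. = FALSE, rank. = npc)
  cl <- with_seed(derive_seed(cfg$seed, "kmeans"),
                  kmeans(pc$x, centers = cfg$k_clusters, nstart = 10,
                         iter.max = 100))
  pop$clusters <- setNames(cl$cluster, rownames(pop$norm))
  pop
}

#' Knockout percentage per cluster
#'
#' Entry (g, c) is 100 x (cells with knockout g in cluster c) / (cells with
#' knockout g); rows sum to 100 and are ordered by average-linkage
#' hierarchical clustering with distance 1 - Pearson correlation.
#'
#' @param pop A clustered `cell_population`.
#' @return List with `composition` (knockout x cluster percentage matrix,
#'   rows in dendrogram order) and `hclust` (the row clustering, NULL when
#'   fewer than 3 knockouts).
#' @export
ko_cluster_composition <- function(pop) {
  if (is.null(pop$clusters)) data_error("clusters absent; run cluster_cells")
  ko <- cell_knockout(pop)
  empty <- setdiff(unique(pop$target_map$gene), unique(ko))
  if (length(empty))
    warning(sprintf("knockout(s) with zero cells omitted: %s",
                    paste(empty, collapse = ", ")))
  tab <- table(ko, pop$clusters[names(ko)])
  comp <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  hc <- NULL
  if (nrow(comp) >= 3) {
    cr <- suppressWarnings(cor(t(comp)))
    cr[is.na(cr)] <- 0
    hc <- hclust(as.dist(1 - cr), method = "average")
    comp <- comp[hc$order, , drop = FALSE]
  }
  list(composition = comp, hclust = hc)
}

#' Trace anchor-high cells across knockouts
#'
#' An anchor-high cell has normalized anchor expression above the
#' `anchor_high_quantile` across retained cells (or belongs to `cluster`
#' when one is designated). Knockouts are ranked by ascending fraction of
#' anchor-high cells, so the strongest SDL candidates come first.
#'
#' @param pop A normalized `cell_population`.
#' @param cfg A [qc_config()].
#' @param cluster Optional cluster id defining the anchor-high set instead
#'   of the expression quantile.
#' @return Data frame `knockout`, `n_cells`, `n_anchor_high`,
#'   `frac_anchor_high`, `rank`, ordered by depletion.
#' @export
trace_anchor_high <- function(pop, cfg = qc_config(), cluster = NULL) {
  if (is.null(pop$norm)) pop <- normalize_cells(pop)
  if (!cfg$anchor %in% colnames(pop$norm))
    data_error(sprintf("anchor gene '%s' absent from matrix", cfg$anchor))
  if (is.null(cluster)) {
    a <- pop$norm[, cfg$anchor]
    high <- a > quantile(a, cfg$anchor_high_quantile)
  } else {
    if (is.null(pop$clusters)) data_error("cluster mode requires cluster_cells")
    high <- pop$clusters == cluster
  }
  if (!any(high)) data_error("no anchor-high cells")
  ko <- cell_knockout(pop)
  d <- data.frame(knockout = names(table(ko)),
                  n_cells = as.vector(table(ko)),
                  n_anchor_high = as.vector(tapply(high[names(ko)], ko, sum)),
                  stringsAsFactors = FALSE)
  d$frac_anchor_high <- d$n_anchor_high / d$n_cells
  d <- d[order(d$frac_anchor_high, d$knockout), ]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Per-knockout summary of one gene's normalized expression
#'
#' Flags knockouts whose median expression of `gene` is below the
#' non-targeting median with a rank-sum p below `alpha`.
#'
#' @param pop A normalized `cell_population`.
#' @param gene Gene to summarize (e.g. the anchor).
#' @param cfg A [qc_config()].
#' @return Data frame `knockout`, `n_cells`, `mean`, `median`, `q25`, `q75`,
#'   `p_vs_control`, `flagged`.
#' @export
target_expression_summary <- function(pop, gene, cfg = qc_config()) {
  if (is.null(pop$norm)) pop <- normalize_cells(pop)
  if (!gene %in% colnames(pop$norm))
    data_error(sprintf("gene '%s' absent from matrix", gene))
  ko <- cell_knockout(pop)
  ctrl <- pop$norm[names(ko)[ko == "non_targeting"], gene]
  rows <- lapply(unique(ko), function(k) {
    x <- pop$norm[names(ko)[ko == k], gene]
    p <- if (k == "non_targeting") 1 else
      suppressWarnings(wilcox.test(x, ctrl, alternative = "less")$p.value)
    data.frame(knockout = k, n_cells = length(x), mean = mean(x),
               median = median(x), q25 = unname(quantile(x, 0.25)),
               q75 = unname(quantile(x, 0.75)), p_vs_control = p,
               flagged = k != "non_targeting" && !is.na(p) &&
                 median(x) < median(ctrl) && p < cfg$alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$median), ]
}
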