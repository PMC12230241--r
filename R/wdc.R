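#' Configuration for WDC scoring and hit calling
#'
#' @param epsilon Weight constant in (0, 1]. Interval t -> t+1 receives
#'   weight `epsilon^(t+1)`, so with `epsilon < 1` drops at earlier
#'   timepoints are ranked before drops at later timepoints. Default 0.5.
#' @param k_aggregate Number of most-negative hairpins averaged into the
#'   gene score (default 2).
#' @param n_permutations Permutations for the gene-level null (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param fold_threshold_log2 Hit threshold, log2 units, default -1 (a
#'   2-fold decrease).
#' @param fold_mode How the 2-fold criterion is interpreted: `"wdc"` applies
#'   `fold_threshold_log2` to the gene WDC score; `"signal_ratio"` applies it
#'   to the gene's raw induced-arm log2 fold change from T0 to the final
#'   timepoint (requires an `induced_log2fc` column, see
#'   [gene_induced_log2fc()]).
#' @param p_combination `"both"` requires the permutation and t-test p values
#'   to pass `alpha`; `"perm"`/`"ttest"` use one of them only.
#' @param seed Integer seed for the permutation null (default 1).
#' @return A `wdc_config` list.
#' @export
wdc_config <- function(epsilon = 0.5, k_aggregate = 2, n_permutations = 1000,
                       alpha = 0.05, fold_threshold_log2 = -1.0,
                       fold_mode = c("wdc", "signal_ratio"),
                       p_combination = c("both", "perm", "ttest"),
                       seed = 1) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon > 1)
    config_error("epsilon must be in (0, 1]")
  assert_count(k_aggregate, "k_aggregate")
  assert_count(n_permutations, "n_permutations", min = 100)
  assert_prob(alpha, "alpha")
  structure(list(epsilon = epsilon, k_aggregate = as.integer(k_aggregate),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 fold_threshold_log2 = fold_threshold_log2,
                 fold_mode = match.arg(fold_mode),
                 p_combination = match.arg(p_combination),
                 seed = as.integer(seed)),
            class = "wdc_config")
}

#' Quantile-normalize a screen tensor
#'
#' Every column is mapped onto the common distribution of row-rank means, so
#' all columns share identical sorted values. Ties receive the mean of the
#' implicated row means.
#'
#' @param tensor A [screen_tensor()] with no missing values.
#' @return A quantile-normalized `screen_tensor`.
#' @export
quantile_normalize <- function(tensor) {
  X <- tensor$values
  if (anyNA(X)) data_error("quantile_normalize: missing values in tensor")
  mu <- rowMeans(apply(X, 2, sort))
  Q <- apply(X, 2, function(col) {
    r <- rank(col, ties.method = "average")
    ## non-integer mean ranks (ties) interpolate between adjacent row means
    approx(seq_along(mu), mu, xout = r)$y
  })
  dimnames(Q) <- dimnames(X)
  out <- tensor
  out$values <- Q
  out
}

#' Remove hairpins below background
#'
#' A hairpin is removed iff any T0 value is below `t0_floor` (log2 background
#' floor) or any later-timepoint value is below `later_floor`.
#'
#' @param tensor A [screen_tensor()] containing timepoint 0.
#' @param t0_floor Log2 background floor at T0 (default 8).
#' @param later_floor Log2 floor at later timepoints (default 0).
#' @return List with `tensor` (retained rows) and `dropped` (data frame
#'   `hairpin`, `gene`, `reason`).
#' @export
filter_hairpins <- function(tensor, t0_floor = 8, later_floor = 0) {
  tps <- tensor_timepoints(tensor)
  if (tps[1] != min(tps) || !(tps[1] %in% tensor$samples$timepoint))
    data_error("filter_hairpins: timepoint 0 absent")
  t0_cols <- tensor$samples$sample[tensor$samples$timepoint == tps[1]]
  later_cols <- tensor$samples$sample[tensor$samples$timepoint != tps[1]]
  X <- tensor$values
  low_t0 <- apply(X[, t0_cols, drop = FALSE] < t0_floor, 1, any)
  low_later <- apply(X[, later_cols, drop = FALSE] < later_floor, 1, any)
  drop <- low_t0 | low_later
  reason <- ifelse(low_t0, "T0 below background", "later timepoint below floor")
  dropped <- data.frame(tensor$hairpins[drop, , drop = FALSE],
                        reason = reason[drop], stringsAsFactors = FALSE)
  kept <- tensor
  kept$values <- X[!drop, , drop = FALSE]
  kept$hairpins <- tensor$hairpins[!drop, , drop = FALSE]
  list(tensor = kept, dropped = dropped)
}

## per-(hairpin, replicate) weighted cumulative change for one arm:
## W_{h,r} = sum_{t=0}^{T-1} eps^{t+1} (x_{t+1,r} - x_{t,r})
arm_cumulative_change <- function(tensor, arm, epsilon) {
  tps <- tensor_timepoints(tensor)
  reps <- tensor_replicates(tensor)
  W <- matrix(0, nrow(tensor$values), length(reps),
              dimnames = list(tensor$hairpins$hairpin, paste0("R", reps)))
  for (ri in seq_along(reps)) {
    for (t in seq_len(length(tps) - 1L)) {
      c_hi <- tensor_cols(tensor, arm, tps[t + 1L], reps[ri])
      c_lo <- tensor_cols(tensor, arm, tps[t], reps[ri])
      if (length(c_hi) != 1L || length(c_lo) != 1L)
        data_error(sprintf("arm '%s' missing samples", arm))
      W[, ri] <- W[, ri] + epsilon^t *
        (tensor$values[, c_hi] - tensor$values[, c_lo])
    }
  }
  W
}

#' Hairpin-level weighted differential cumulative change
#'
#' For each replicate r the component is the epsilon-weighted sum of
#' consecutive log2-signal changes in the induced arm minus the same sum in
#' the uninduced arm; `wdc_h` is the mean of the per-replicate components.
#'
#' @param tensor A filtered, normalized [screen_tensor()] with both arms.
#' @param config A [wdc_config()].
#' @return Data frame `hairpin`, `gene`, `component_R*`, `wdc_h`, with the
#'   per-arm cumulative-change matrices attached as attribute
#'   `"arm_components"` (used by [ttest_pvalues()]).
#' @export
wdc_hairpin <- function(tensor, config = wdc_config()) {
  arms <- tensor_arms(tensor)
  if (!all(c("induced", "uninduced") %in% arms))
    data_error("wdc_hairpin: both 'induced' and 'uninduced' arms are required")
  W_in <- arm_cumulative_change(tensor, "induced", config$epsilon)
  W_un <- arm_cumulative_change(tensor, "uninduced", config$epsilon)
  comp <- W_in - W_un
  out <- data.frame(hairpin = tensor$hairpins$hairpin,
                    gene = tensor$hairpins$gene,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(comp))) out[[paste0("component_", colnames(comp)[j])]] <- comp[, j]
  out$wdc_h <- rowMeans(comp)
  attr(out, "arm_components") <- list(induced = W_in, uninduced = W_un)
  out
}

## k-most-negative aggregation; stable tie-break by position (hairpin order)
agg_k_most_negative <- function(x, k) {
  o <- order(x)                      # stable: ties keep original order
  mean(x[o[seq_len(min(k, length(x)))]])
}

#' Gene-level WDC score
#'
#' The gene score is the mean of the `k_aggregate` most negative hairpin
#' scores among the gene's unfiltered hairpins; genes with fewer hairpins use
#' all available and are flagged `underpowered`.
#'
#' @param scores Output of [wdc_hairpin()].
#' @param config A [wdc_config()].
#' @return Data frame `gene`, `wdc_gene`, `n_hairpins_used`, `underpowered`.
#' @export
wdc_gene <- function(scores, config = wdc_config()) {
  k <- config$k_aggregate
  sp <- split(scores$wdc_h, scores$gene)
  genes <- names(sp)
  data.frame(gene = genes,
             wdc_gene = vapply(sp, agg_k_most_negative, 0, k = k),
             n_hairpins_used = pmin(lengths(sp), k),
             underpowered = lengths(sp) < k,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation p values for gene WDC scores
#'
#' The null for a gene with m unfiltered hairpins is built by drawing, for
#' each permutation, m hairpin scores without replacement from the global
#' unfiltered pool and aggregating with the same k-most-negative rule. The
#' reported p uses the add-one rule `(1 + #\{null <= observed\}) / (1 + B)`.
#'
#' @param scores Output of [wdc_hairpin()].
#' @param config A [wdc_config()].
#' @return Data frame `gene`, `wdc_gene`, `p_perm`.
#' @export
permutation_pvalues <- function(scores, config = wdc_config()) {
  pool <- scores$wdc_h
  k <- config$k_aggregate
  B <- config$n_permutations
  gt <- wdc_gene(scores, config)
  m_per <- lengths(split(scores$wdc_h, scores$gene))[gt$gene]
  if (any(m_per > length(pool)))
    data_error("permutation_pvalues: pool smaller than a gene's hairpin count")
  with_seed(derive_seed(config$seed, "perm"), {
    gt$p_perm <- vapply(seq_len(nrow(gt)), function(i) {
      m <- m_per[[i]]
      nullv <- vapply(seq_len(B), function(b)
        agg_k_most_negative(pool[sample.int(length(pool), m)], k), 0)
      (1 + sum(nullv <= gt$wdc_gene[i])) / (1 + B)
    }, 0)
  })
  gt[, c("gene", "wdc_gene", "p_perm")]
}

#' Gene-level t test between arms
#'
#' Two-sample two-sided Student t test comparing the gene's per-(hairpin,
#' replicate) weighted cumulative changes in the induced arm against the
#' uninduced arm.
#'
#' @param tensor The tensor passed to [wdc_hairpin()] (unused when the
#'   components attribute is present, kept for the documented signature).
#' @param scores Output of [wdc_hairpin()].
#' @return Data frame `gene`, `p_ttest`, `not_computable`.
#' @export
ttest_pvalues <- function(tensor, scores) {
  comps <- attr(scores, "arm_components")
  if (is.null(comps)) data_error("scores lack arm components; rerun wdc_hairpin")
  genes <- unique(scores$gene)
  idx <- split(seq_len(nrow(scores)), scores$gene)[genes]
  res <- vapply(idx, function(i) {
    x <- as.vector(comps$induced[i, , drop = FALSE])
    y <- as.vector(comps$uninduced[i, , drop = FALSE])
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }, 0)
  data.frame(gene = genes, p_ttest = unname(res),
             not_computable = is.na(res), stringsAsFactors = FALSE)
}

#' Mean induced-arm log2 fold change per gene
#'
#' Raw (unweighted) log2 change from T0 to the final timepoint in the induced
#' arm, averaged over replicates and over the gene's retained hairpins. Used
#' by the `"signal_ratio"` interpretation of the 2-fold hit criterion.
#'
#' @param tensor A filtered [screen_tensor()].
#' @return Data frame `gene`, `induced_log2fc`.
#' @export
gene_induced_log2fc <- function(tensor) {
  tps <- tensor_timepoints(tensor)
  c0 <- tensor_cols(tensor, "induced", tps[1])
  c1 <- tensor_cols(tensor, "induced", tps[length(tps)])
  lfc <- rowMeans(tensor$values[, c1, drop = FALSE]) -
    rowMeans(tensor$values[, c0, drop = FALSE])
  agg <- tapply(lfc, tensor$hairpins$gene, mean)
  data.frame(gene = names(agg), induced_log2fc = as.vector(agg),
             stringsAsFactors = FALSE)
}

#' Call screen hits
#'
#' A gene is a hit iff its fold criterion passes (see `fold_mode` in
#' [wdc_config()]) and the configured combination of permutation and t-test
#' p values passes `alpha`. Genes with non-computable p values are never
#' hits. A Benjamini-Hochberg FDR column is added for reference but does not
#' enter the default hit rule.
#'
#' @param gene_table Data frame with `gene`, `wdc_gene`, `p_perm`, `p_ttest`
#'   (and `induced_log2fc` when `fold_mode = "signal_ratio"`).
#' @param config A [wdc_config()].
#' @return `gene_table` with logical `hit` and `fdr_perm` columns.
#' @export
call_hits <- function(gene_table, config = wdc_config()) {
  fold_ok <- switch(config$fold_mode,
    wdc = gene_table$wdc_gene <= config$fold_threshold_log2,
    signal_ratio = {
      if (is.null(gene_table$induced_log2fc))
        data_error("fold_mode 'signal_ratio' needs an induced_log2fc column")
      gene_table$induced_log2fc <= config$fold_threshold_log2
    })
  pp <- gene_table$p_perm
  pt <- gene_table$p_ttest
  p_ok <- switch(config$p_combination,
                 both = pp < config$alpha & pt < config$alpha,
                 perm = pp < config$alpha,
                 ttest = pt < config$alpha)
  gene_table$hit <- !is.na(fold_ok) & fold_ok & !is.na(p_ok) & p_ok
  gene_table$fdr_perm <- stats::p.adjust(pp, "BH")
  gene_table
}

#' Score a two-arm screen end to end
#'
#' Convenience wrapper: quantile normalization, background filtering,
#' hairpin and gene WDC, permutation and t-test p values, hit calls.
#'
#' @param tensor A raw [screen_tensor()].
#' @param config A [wdc_config()].
#' @param normalize Apply quantile normalization first (default TRUE).
#' @return List with `gene_table`, `hairpin_table`, `tensor` (filtered,
#'   normalized) and `dropped`.
#' @export
score_screen <- function(tensor, config = wdc_config(), normalize = TRUE) {
  if (normalize) tensor <- quantile_normalize(tensor)
  flt <- filter_hairpins(tensor)
  hp <- wdc_hairpin(flt$tensor, config)
  gt <- permutation_pvalues(hp, config)
  tt <- ttest_pvalues(flt$tensor, hp)
  gt <- merge(gt, tt, by = "gene", sort = FALSE)
  gt <- merge(gt, wdc_gene(hp, config)[, c("gene", "n_hairpins_used", "underpowered")],
              by = "gene", sort = FALSE)
  gt <- merge(gt, gene_induced_log2fc(flt$tensor), by = "gene", sort = FALSE)
  gt <- call_hits(gt, config)
  list(gene_table = gt[order(gt$wdc_gene), ], hairpin_table = hp,
       tensor = flt$tensor, dropped = flt$dropped)
}
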