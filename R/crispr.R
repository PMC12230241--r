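#' Count sgRNA spacers in reads
#'
#' A read is assigned to a guide iff some window of the read matches the
#' guide's spacer with at most `max_mismatch` substitutions and the best
#' match (fewest mismatches) is unique. Reads matching two or more guides
#' equally well are counted as ambiguous; reads matching none as unmatched.
#' `assigned + ambiguous + unmatched = total` always holds.
#'
#' @param reads A [Biostrings::DNAStringSet] (see [read_fastq()]).
#' @param library A [guide_library()].
#' @param max_mismatch 0 or 1 substitutions tolerated.
#' @return List with `counts` (named integer vector over all library
#'   guides), `assigned`, `ambiguous`, `unmatched`, `unmapped`
#'   (= ambiguous + unmatched) and `total`.
#' @export
count_guides <- function(reads, library, max_mismatch = 0) {
  stopifnot(inherits(library, "guide_library"), max_mismatch %in% c(0, 1))
  n <- length(reads)
  hit_mat <- function(mm) {
    m <- vapply(library$spacer, function(sp)
      Biostrings::vcountPattern(sp, reads, max.mismatch = mm) > 0L,
      logical(n))
    matrix(m, nrow = n)
  }
  assign_id <- rep(NA_integer_, n)
  ambiguous <- logical(n)
  if (n > 0) {
    E <- hit_mat(0)
    nE <- rowSums(E)
    assign_id[nE == 1L] <- max.col(E, "first")[nE == 1L]
    ambiguous[nE > 1L] <- TRUE
    if (max_mismatch >= 1) {
      open <- which(nE == 0L)
      if (length(open) > 0) {
        M <- vapply(library$spacer, function(sp)
          Biostrings::vcountPattern(sp, reads[open], max.mismatch = 1L) > 0L,
          logical(length(open)))
        M <- matrix(M, nrow = length(open))
        nM <- rowSums(M)
        assign_id[open[nM == 1L]] <- max.col(M, "first")[nM == 1L]
        ambiguous[open[nM > 1L]] <- TRUE
      }
    }
  }
  counts <- tabulate(assign_id, nbins = nrow(library))
  names(counts) <- library$guide
  n_assigned <- sum(!is.na(assign_id))
  n_amb <- sum(ambiguous)
  list(counts = counts, assigned = n_assigned, ambiguous = n_amb,
       unmatched = n - n_assigned - n_amb,
       unmapped = n - n_assigned, total = n)
}

#' Score a pooled endpoint CRISPR dropout screen
#'
#' Counts are normalized to log2(CPM + pseudocount). Because only endpoint
#' tumors are sequenced, the no-Cas9 arm mean serves as the shared T0
#' baseline, so the two-timepoint WDC reduces to
#' `epsilon * (cas9 - baseline) - epsilon * (no_cas9 - baseline)` averaged
#' over samples. Gene aggregation, permutation p values, the t test and the
#' hit rule reuse the shRNA machinery with `k_aggregate` capped at the
#' number of guides per gene.
#'
#' @param counts Guide x sample integer matrix.
#' @param library A [guide_library()] mapping guides to genes.
#' @param config A [wdc_config()].
#' @param pseudocount Added to CPM before log2 (default 1).
#' @param samples Data frame `sample`, `arm` (`cas9` / `no_cas9`); inferred
#'   from column-name prefixes when omitted.
#' @return List with `gene_table` (gene, wdc_gene, p_perm, p_ttest, hit)
#'   and `guide_table` (per-guide scores).
#' @export
score_invivo <- function(counts, library, config = wdc_config(),
                         pseudocount = 1, samples = NULL) {
  stopifnot(inherits(library, "guide_library"))
  if (is.null(samples)) {
    arm <- ifelse(grepl("^no_cas9", colnames(counts)), "no_cas9",
                  ifelse(grepl("^cas9", colnames(counts)), "cas9", NA))
    if (anyNA(arm)) data_error("cannot infer arms from count column names")
    samples <- data.frame(sample = colnames(counts), arm = arm,
                          stringsAsFactors = FALSE)
  }
  if (!all(c("cas9", "no_cas9") %in% samples$arm))
    data_error("score_invivo: both cas9 and no_cas9 arms are required")
  tot <- colSums(counts)
  if (any(tot == 0)) data_error("sample with zero total counts")
  lg <- log2(t(t(counts) / tot * 1e6) + pseudocount)
  cas9_cols <- samples$sample[samples$arm == "cas9"]
  ctrl_cols <- samples$sample[samples$arm == "no_cas9"]
  baseline <- rowMeans(lg[, ctrl_cols, drop = FALSE])
  comp_cas9 <- config$epsilon * (lg[, cas9_cols, drop = FALSE] - baseline)
  comp_ctrl <- config$epsilon * (lg[, ctrl_cols, drop = FALSE] - baseline)
  guide_score <- rowMeans(comp_cas9) - rowMeans(comp_ctrl)
  scores <- data.frame(hairpin = library$guide, gene = library$gene,
                       wdc_h = unname(guide_score[library$guide]),
                       stringsAsFactors = FALSE)
  attr(scores, "arm_components") <-
    list(induced = comp_cas9[library$guide, , drop = FALSE],
         uninduced = comp_ctrl[library$guide, , drop = FALSE])
  ## genes with fewer guides than k_aggregate use all available (see wdc_gene)
  gt <- permutation_pvalues(scores, config)
  gt <- merge(gt, ttest_pvalues(NULL, scores), by = "gene", sort = FALSE)
  gt <- call_hits(gt, config)
  list(gene_table = gt[order(gt$wdc_gene), ],
       guide_table = data.frame(guide = scores$hairpin, gene = scores$gene,
                                score = scores$wdc_h, stringsAsFactors = FALSE))
}

#' Arrayed confluency screen: growth-reduction hit calling
#'
#' Per well, growth is confluency at `final_day` over confluency at
#' `baseline_day`. Per gene, the reduction is
#' `1 - mean(growth_cas9) / mean(growth_no_cas9)`; growth values are compared
#' between arms by a two-sample t test. A gene is a hit iff reduction >= 0.40
#' and p < 0.05.
#'
#' @param table Data frame `well`, `gene`, `arm`, `day`, `confluency`,
#'   `replicate`.
#' @param baseline_day,final_day Days compared (defaults 2 and 6).
#' @param reduction_min Hit threshold on reduction (default 0.40).
#' @param alpha Significance level (default 0.05).
#' @return Data frame `gene`, `reduction`, `p`, `hit`, `n_wells_cas9`,
#'   `n_wells_no_cas9`.
#' @export
arrayed_growth_reduction <- function(table, baseline_day = 2, final_day = 6,
                                     reduction_min = 0.40, alpha = 0.05) {
  need <- c("well", "gene", "arm", "day", "confluency")
  if (!all(need %in% names(table)))
    data_error(sprintf("arrayed table must have columns: %s",
                       paste(need, collapse = ", ")))
  if (!all(c(baseline_day, final_day) %in% table$day))
    data_error("baseline or final day absent from arrayed table")
  b <- table[table$day == baseline_day, ]
  f <- table[table$day == final_day, ]
  m <- merge(b[, c("well", "gene", "arm", "confluency")],
             f[, c("well", "confluency")], by = "well",
             suffixes = c("_base", "_final"))
  zero <- m$confluency_base == 0
  if (any(zero)) {
    warning(sprintf("%d well(s) with zero baseline confluency excluded", sum(zero)))
    m <- m[!zero, ]
  }
  m$growth <- m$confluency_final / m$confluency_base
  out <- lapply(split(m, m$gene), function(d) {
    g_cas <- d$growth[d$arm == "cas9"]
    g_ctl <- d$growth[d$arm == "no_cas9"]
    red <- 1 - mean(g_cas) / mean(g_ctl)
    p <- tryCatch(t.test(g_cas, g_ctl)$p.value, error = function(e) NA_real_)
    data.frame(gene = d$gene[1], reduction = red, p = p,
               hit = !is.na(p) && red >= reduction_min && p < alpha,
               n_wells_cas9 = length(g_cas), n_wells_no_cas9 = length(g_ctl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-out$reduction), ]
}

#' Intersect validation screens
#'
#' Set algebra over two hit sets with per-gene provenance flags.
#'
#' @param hits_arrayed,hits_invivo Character vectors of hit genes.
#' @return List with `union`, `intersection`, and a `provenance` data frame
#'   (`gene`, `arrayed`, `invivo`).
#' @export
intersect_screens <- function(hits_arrayed, hits_invivo) {
  u <- union(hits_arrayed, hits_invivo)
  list(union = u,
       intersection = intersect(hits_arrayed, hits_invivo),
       provenance = data.frame(gene = u,
                               arrayed = u %in% hits_arrayed,
                               invivo = u %in% hits_invivo,
                               stringsAsFactors = FALSE))
}
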