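#' Co-expression screen across cohorts
#'
#' Spearman correlation between the anchor gene and each candidate in every
#' cohort; a candidate is selected iff r >= `r_min` in more than
#' `majority_rule` of the cohorts. Candidates with undefined correlation in a
#' cohort (constant expression) fail the cutoff there. The returned r matrix
#' is row-ordered by complete-linkage clustering on Euclidean distance of
#' the per-cohort correlation vectors.
#'
#' @param cohorts Named list of patient x gene expression matrices / data
#'   frames (log2 scale), each containing the anchor.
#' @param anchor Anchor gene name.
#' @param candidates Candidate genes to test.
#' @param r_min Correlation cutoff (default 0.4).
#' @param majority_rule Fraction of cohorts that must pass (strictly
#'   exceeded; default 0.5).
#' @return List with `selected` (genes), `r_matrix` (candidate x cohort,
#'   clustered order) and `n_pass` per candidate.
#' @export
coexpression_screen <- function(cohorts, anchor, candidates,
                                r_min = 0.4, majority_rule = 0.5) {
  if (!length(cohorts)) config_error("at least one cohort is required")
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  R <- vapply(cohorts, function(m) {
    m <- as.matrix(as.data.frame(m)[, sapply(as.data.frame(m), is.numeric)])
    if (!anchor %in% colnames(m)) config_error("anchor absent from a cohort")
    vapply(candidates, function(g) {
      if (!g %in% colnames(m)) return(NA_real_)
      suppressWarnings(cor(m[, anchor], m[, g], method = "spearman"))
    }, 0)
  }, numeric(length(candidates)))
  R <- matrix(R, nrow = length(candidates),
              dimnames = list(candidates, names(cohorts)))
  pass <- !is.na(R) & R >= r_min
  n_pass <- rowSums(pass)
  selected <- candidates[n_pass > majority_rule * length(cohorts)]
  ord <- seq_len(nrow(R))
  if (nrow(R) >= 3) {
    Rd <- R; Rd[is.na(Rd)] <- 0
    ord <- hclust(dist(Rd), method = "complete")$order
  }
  list(selected = selected, r_matrix = R[ord, , drop = FALSE], n_pass = n_pass)
}

#' Expression filter for a designated cell line
#'
#' A gene is retained iff its log2 expression in `line` is at least
#' `threshold_log2` (the boundary value is kept).
#'
#' @param cell_line_expr Cell line x gene log2 expression matrix.
#' @param line Cell line of interest (e.g. `"HCT116"`).
#' @param threshold_log2 Cutoff (default 5).
#' @return Character vector of retained genes.
#' @export
expression_filter <- function(cell_line_expr, line, threshold_log2 = 5.0) {
  if (!line %in% rownames(cell_line_expr))
    data_error(sprintf("line '%s' absent from expression matrix", line))
  v <- cell_line_expr[line, ]
  colnames(cell_line_expr)[!is.na(v) & v >= threshold_log2]
}

#' Remove reference-essential genes from a candidate set
#'
#' @param candidates Candidate gene set.
#' @param essential_reference Reference essential genes.
#' @return `setdiff(candidates, essential_reference)`.
#' @export
essential_gene_filter <- function(candidates, essential_reference) {
  setdiff(candidates, essential_reference)
}

#' Differential essentiality between anchor-high and anchor-low lines
#'
#' Cell lines are ranked by anchor expression; the top and bottom fractions
#' form the comparison groups. Per candidate, a two-sided Mann-Whitney U
#' test on the essentiality scores; selected iff p < alpha and the median
#' score is more negative (more essential) in the anchor-high group.
#'
#' @param essentiality Cell line x gene essentiality score matrix (more
#'   negative = more essential).
#' @param expression Cell line x gene expression matrix sharing line ids
#'   (used for the anchor ranking).
#' @param anchor Anchor gene.
#' @param candidates Genes to test (default: all scored genes).
#' @param top_frac,bottom_frac Group fractions (defaults 0.25; the text of
#'   record also mentions 10% grouping, exposed here but not defaulted).
#' @param alpha Significance level (default 0.05).
#' @return Data frame `gene`, `p`, `median_high`, `median_low`, `selected`,
#'   `not_testable`.
#' @export
differential_essentiality <- function(essentiality, expression, anchor,
                                      candidates = colnames(essentiality),
                                      top_frac = 0.25, bottom_frac = 0.25,
                                      alpha = 0.05) {
  lines <- intersect(rownames(essentiality), rownames(expression))
  if (!length(lines)) data_error("no shared cell lines")
  a <- expression[lines, anchor]
  o <- order(a, decreasing = TRUE)
  n_top <- max(1L, floor(top_frac * length(lines)))
  n_bot <- max(1L, floor(bottom_frac * length(lines)))
  hi <- lines[o[seq_len(n_top)]]
  lo <- lines[rev(o)[seq_len(n_bot)]]
  rows <- lapply(candidates, function(g) {
    if (!g %in% colnames(essentiality) || length(hi) < 3L || length(lo) < 3L)
      return(data.frame(gene = g, p = NA_real_, median_high = NA_real_,
                        median_low = NA_real_, selected = FALSE,
                        not_testable = TRUE))
    x <- essentiality[hi, g]; y <- essentiality[lo, g]
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    data.frame(gene = g, p = p, median_high = median(x), median_low = median(y),
               selected = !is.na(p) && p < alpha && median(x) < median(y),
               not_testable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## restricted mean survival time of a survfit stratum up to tau
rmst_by_group <- function(time, event, group, tau) {
  vapply(split(seq_along(time), group), function(i) {
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    tt <- c(0, fit$time[fit$time <= tau], tau)
    ss <- c(1, fit$surv[fit$time <= tau], NA)
    sum(diff(tt) * head(ss, -1))
  }, 0)
}

#' Natural-SDL survival comparison
#'
#' Patients are dichotomized at the median for the anchor and the partner
#' (values equal to the median go to the high group). The natural-SDL group
#' is anchor-high and partner-low; the comparison group is anchor-high and
#' partner-high. Kaplan-Meier curves are compared by the log-rank test;
#' selected iff p < alpha and the natural-SDL group has the better survival
#' (higher restricted-mean survival time).
#'
#' @param expression Data frame with `patient`, anchor and partner columns
#'   (log2 expression).
#' @param surv Data frame `patient`, `time`, `event`.
#' @param anchor,partner Gene names.
#' @param alpha Significance level (default 0.05).
#' @return List with `p` (log-rank), `selected`, `not_testable`, `rmst`
#'   (per group), `fit` (the `survfit` object) and group sizes.
#' @export
natural_sdl_survival <- function(expression, surv, anchor, partner,
                                 alpha = 0.05) {
  d <- merge(expression[, c("patient", anchor, partner)], surv, by = "patient")
  a_high <- d[[anchor]] >= median(d[[anchor]])
  p_high <- d[[partner]] >= median(d[[partner]])
  grp <- ifelse(a_high & !p_high, "natural_sdl",
                ifelse(a_high & p_high, "both_high", NA))
  keep <- !is.na(grp)
  d <- d[keep, ]; grp <- grp[keep]
  sizes <- table(factor(grp, levels = c("natural_sdl", "both_high")))
  if (any(sizes == 0L) || sum(d$event) == 0L)
    return(list(p = NA_real_, selected = FALSE, not_testable = TRUE,
                rmst = NULL, fit = NULL, n = as.list(sizes)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  tau <- min(tapply(d$time, grp, max))
  rmst <- rmst_by_group(d$time, d$event, grp, tau)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = d)
  list(p = p, selected = p < alpha && rmst[["natural_sdl"]] > rmst[["both_high"]],
       not_testable = FALSE, rmst = rmst, fit = fit, n = as.list(sizes))
}

#' Drug-sensitivity differential between anchor-expression tails
#'
#' Cell lines in the top and bottom `tail_frac` of anchor expression
#' (rounded up to at least 3 lines per tail) are compared per drug by a
#' Mann-Whitney U test on log IC50; a drug is selected iff p < alpha and
#' the median IC50 is lower in the anchor-high lines.
#'
#' @param ic50 Drug x cell line IC50 matrix (linear scale; log is taken
#'   internally).
#' @param expression Cell line x gene expression matrix.
#' @param anchor Anchor gene.
#' @param tail_frac Tail fraction (default 0.01).
#' @param alpha Significance level (default 0.05).
#' @return Data frame `drug`, `p`, `median_high`, `median_low`, `selected`,
#'   `skipped`.
#' @export
drug_sensitivity_differential <- function(ic50, expression, anchor,
                                          tail_frac = 0.01, alpha = 0.05) {
  lines <- intersect(colnames(ic50), rownames(expression))
  if (!length(lines)) data_error("no shared cell lines")
  a <- expression[lines, anchor]
  o <- order(a, decreasing = TRUE)
  n_tail <- max(3L, ceiling(tail_frac * length(lines)))
  hi <- lines[o[seq_len(n_tail)]]
  lo <- lines[rev(o)[seq_len(n_tail)]]
  rows <- lapply(rownames(ic50), function(dr) {
    x <- log(ic50[dr, hi]); y <- log(ic50[dr, lo])
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (!length(x) || !length(y)) {
      warning(sprintf("drug '%s' skipped: missing IC50", dr))
      return(data.frame(drug = dr, p = NA_real_, median_high = NA_real_,
                        median_low = NA_real_, selected = FALSE, skipped = TRUE))
    }
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    data.frame(drug = dr, p = p, median_high = median(x), median_low = median(y),
               selected = !is.na(p) && p < alpha && median(x) < median(y),
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the candidate ledger
#'
#' Union of the strategy outputs and fixed lists with per-strategy
#' provenance flags; clone failures are marked excluded. A gene is active
#' iff it carries at least one flag and is not excluded.
#'
#' @param strategy_outputs Named list of gene sets from the data-driven
#'   strategies (e.g. `coexpression`, `essentiality_marcotte`,
#'   `essentiality_achilles`, `survival`).
#' @param fixed_lists Named list of externally supplied gene lists (e.g.
#'   `locus_19p13`, `toppgene`, `surfaceome`).
#' @param clone_failures Genes that failed cloning.
#' @return A `candidate_ledger` data frame: `gene`, one logical column per
#'   strategy / list, `excluded_reason` (NA or `"clone_failure"`), `active`;
#'   attribute `"counts"` holds `n_union`, `n_excluded`, `n_active`.
#' @export
build_ledger <- function(strategy_outputs, fixed_lists = list(),
                         clone_failures = character(0)) {
  all_lists <- c(strategy_outputs, fixed_lists)
  if (is.null(names(all_lists)) || any(names(all_lists) == ""))
    config_error("all strategy outputs and fixed lists must be named")
  u <- unique(unlist(all_lists, use.names = FALSE))
  led <- data.frame(gene = u, stringsAsFactors = FALSE)
  for (nm in names(all_lists)) led[[nm]] <- u %in% all_lists[[nm]]
  led$excluded_reason <- ifelse(u %in% clone_failures, "clone_failure", NA)
  led$active <- is.na(led$excluded_reason)
  attr(led, "counts") <- c(n_union = length(u),
                           n_excluded = sum(!led$active),
                           n_active = sum(led$active))
  class(led) <- c("candidate_ledger", "data.frame")
  led
}
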