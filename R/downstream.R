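#' Tumor volume from caliper diameters
#'
#' `(A * B^2) / 2` with A the long and B the short diameter (mm). Swapped
#' inputs are corrected with a warning.
#'
#' @param A,B Long and short diameters, mm (vectorized).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(A, B) {
  if (any(A <= 0 | B <= 0)) data_error("diameters must be positive")
  sw <- A < B
  if (any(sw)) {
    warning(sprintf("%d measurement(s) with A < B: diameters swapped", sum(sw)))
    tmp <- A[sw]; A[sw] <- B[sw]; B[sw] <- tmp
  }
  A * B^2 / 2
}

#' Tumor growth kinetics from a volume time series
#'
#' Least-squares fit of log2(volume) against time, so the slope is in
#' doublings per day and the doubling time is its reciprocal. Non-positive
#' slopes give an undefined (NA) doubling time with a flag.
#'
#' @param day Measurement days.
#' @param volume Volumes (mm^3), positive; at least 3 timepoints.
#' @return List `slope` (log2 volume / day), `doubling_time` (days),
#'   `doubling_undefined`, `r_squared`.
#' @export
growth_kinetics <- function(day, volume) {
  keep <- !is.na(volume) & volume > 0
  if (sum(keep) < 3L) data_error("growth_kinetics needs >= 3 positive volumes")
  fit <- lm(log2(volume[keep]) ~ day[keep])
  slope <- unname(coef(fit)[2])
  undef <- slope <= 0
  list(slope = slope,
       doubling_time = if (undef) NA_real_ else 1 / slope,
       doubling_undefined = undef,
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Group PDX models by anchor / partner FPKM and compare kinetics
#'
#' A model is `sdl_like` iff anchor FPKM > `high_fpkm` and partner FPKM <
#' `low_fpkm`; `both_high` iff both exceed `high_fpkm`. Models whose partner
#' FPKM falls in the dead zone between the thresholds (or whose anchor is
#' not high) are `unassigned`. Welch two-sample t tests compare slope and
#' doubling time between the two groups.
#'
#' @param table Data frame `model`, `anchor_fpkm`, `partner_fpkm`, `slope`,
#'   `doubling_time`.
#' @param low_fpkm,high_fpkm Expression thresholds (defaults 20 and 30).
#' @return List with `table` (plus `group` column) and `tests` (data frame
#'   `metric`, `p`, `mean_sdl_like`, `mean_both_high`, `not_computable`).
#' @export
pdx_group_compare <- function(table, low_fpkm = 20, high_fpkm = 30) {
  need <- c("model", "anchor_fpkm", "partner_fpkm", "slope", "doubling_time")
  if (!all(need %in% names(table)))
    data_error(sprintf("pdx table must have columns: %s", paste(need, collapse = ", ")))
  grp <- with(table, ifelse(anchor_fpkm > high_fpkm & partner_fpkm < low_fpkm,
                            "sdl_like",
                            ifelse(anchor_fpkm > high_fpkm & partner_fpkm > high_fpkm,
                                   "both_high", "unassigned")))
  table$group <- grp
  tests <- lapply(c("slope", "doubling_time"), function(metric) {
    x <- table[[metric]][grp == "sdl_like"]
    y <- table[[metric]][grp == "both_high"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 3L || length(y) < 3L)
      return(data.frame(metric = metric, p = NA_real_,
                        mean_sdl_like = mean(x), mean_both_high = mean(y),
                        not_computable = TRUE))
    ht <- t.test(x, y)  # Welch by default
    data.frame(metric = metric, p = ht$p.value, mean_sdl_like = mean(x),
               mean_both_high = mean(y), not_computable = FALSE)
  })
  list(table = table, tests = do.call(rbind, tests))
}

#' Mitochondrial stress-test metrics from an OCR trace
#'
#' Standard mito-stress derivations from the four phases of a Seahorse-style
#' assay (oligomycin, FCCP, rotenone/antimycin A):
#' non-mitochondrial = mean(post rot/AA); basal = last(basal) - non-mito;
#' ATP-linked = last(basal) - min(post oligomycin); proton leak =
#' min(post oligomycin) - non-mito; maximal = max(post FCCP) - non-mito;
#' spare capacity = maximal - basal. The identity
#' `atp_linked + proton_leak = basal_resp` holds exactly.
#'
#' @param basal,post_oligomycin,post_fccp,post_rot_aa Numeric OCR vectors
#'   (pmol O2/min), each with at least one value.
#' @return List of the six metrics plus `spare_negative` flag.
#' @export
mito_metrics <- function(basal, post_oligomycin, post_fccp, post_rot_aa) {
  phases <- list(basal = basal, post_oligomycin = post_oligomycin,
                 post_fccp = post_fccp, post_rot_aa = post_rot_aa)
  if (any(vapply(phases, length, 0L) == 0L))
    data_error("all four measurement phases are required")
  non_mito <- mean(post_rot_aa)
  basal_resp <- basal[length(basal)] - non_mito
  atp_linked <- basal[length(basal)] - min(post_oligomycin)
  proton_leak <- min(post_oligomycin) - non_mito
  maximal_resp <- max(post_fccp) - non_mito
  spare_capacity <- maximal_resp - basal_resp
  list(non_mito = non_mito, basal_resp = basal_resp, atp_linked = atp_linked,
       proton_leak = proton_leak, maximal_resp = maximal_resp,
       spare_capacity = spare_capacity, spare_negative = spare_capacity < 0)
}

#' Count RNA motifs in sequences
#'
#' Sliding-window count of each motif in each sequence; overlapping
#' occurrences count, T is treated as U, N never matches.
#'
#' @param sequences Named character vector (or list) of sequences over
#'   A/C/G/U/T/N.
#' @param motifs Motifs to count (default `c("UGGA", "AGGU")`).
#' @return List with `per_sequence` (sequence x motif count matrix) and
#'   `totals` (named vector).
#' @export
count_motifs <- function(sequences, motifs = c("UGGA", "AGGU")) {
  sequences <- unlist(sequences)
  bad <- grepl("[^ACGUTNacgutn]", sequences)
  if (any(bad)) data_error("sequences must be over the A/C/G/U/T/N alphabet")
  m <- vapply(motifs, function(mo)
    vapply(sequences, function(s) length(scan_motif_starts(s, mo)), 0L),
    integer(length(sequences)))
  m <- matrix(m, nrow = length(sequences),
              dimnames = list(names(sequences) %||% seq_along(sequences), motifs))
  list(per_sequence = m, totals = colSums(m))
}
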