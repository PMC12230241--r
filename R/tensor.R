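#' Screen tensor: hairpin x (arm, timepoint, replicate) log2 signal
#'
#' The central container for two-arm time-course dropout screens. Rows are
#' hairpins (or guides), columns are samples named `<arm>_T<t>_R<r>` where
#' `arm` is `"induced"` or `"uninduced"`, `t` is the timepoint label and `r`
#' the replicate index. Every (arm, timepoint, replicate) combination must be
#' present for every retained hairpin.
#'
#' @param values Numeric matrix of log2 signal, hairpins in rows.
#' @param hairpins Data frame with columns `hairpin`, `gene` (one row per
#'   matrix row).
#' @param samples Data frame with columns `sample`, `arm`, `timepoint`,
#'   `replicate` (one row per matrix column). If omitted it is parsed from
#'   the column names of `values`.
#' @return An object of class `screen_tensor`.
#' @export
screen_tensor <- function(values, hairpins, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- parse_sample_names(colnames(values))
  hairpins <- as.data.frame(hairpins, stringsAsFactors = FALSE)
  stopifnot(nrow(hairpins) == nrow(values), nrow(samples) == ncol(values),
            all(c("hairpin", "gene") %in% names(hairpins)))
  rownames(values) <- hairpins$hairpin
  colnames(values) <- samples$sample
  tps <- sort(unique(samples$timepoint))
  if (length(tps) < 2L) data_error("screen tensor needs at least 2 timepoints")
  full <- expand.grid(arm = unique(samples$arm), timepoint = tps,
                      replicate = sort(unique(samples$replicate)))
  got <- with(samples, paste(arm, timepoint, replicate))
  if (!all(with(full, paste(arm, timepoint, replicate)) %in% got))
    data_error("screen tensor is missing (arm, timepoint, replicate) cells")
  structure(list(values = values, hairpins = hairpins, samples = samples),
            class = "screen_tensor")
}

parse_sample_names <- function(nms) {
  if (is.null(nms)) data_error("sample annotation absent and columns unnamed")
  m <- regmatches(nms, regexec("^(.+)_T([0-9]+)_R([0-9]+)$", nms))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    data_error(sprintf("cannot parse sample name(s): %s",
                       paste(nms[bad], collapse = ", ")))
  data.frame(sample = nms,
             arm = vapply(m, `[`, "", 2L),
             timepoint = as.integer(vapply(m, `[`, "", 3L)),
             replicate = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' @export
print.screen_tensor <- function(x, ...) {
  cat(sprintf("screen_tensor: %d hairpins x %d samples (%d genes)\n",
              nrow(x$values), ncol(x$values), length(unique(x$hairpins$gene))))
  cat(sprintf("  arms: %s; timepoints: %s; replicates: %s\n",
              paste(unique(x$samples$arm), collapse = ", "),
              paste(sort(unique(x$samples$timepoint)), collapse = ", "),
              paste(sort(unique(x$samples$replicate)), collapse = ", ")))
  invisible(x)
}

## column names for a given (arm, timepoint); all replicates, ordered
tensor_cols <- function(tensor, arm, timepoint = NULL, replicate = NULL) {
  s <- tensor$samples
  i <- s$arm == arm
  if (!is.null(timepoint)) i <- i & s$timepoint == timepoint
  if (!is.null(replicate)) i <- i & s$replicate == replicate
  s$sample[i]
}

tensor_timepoints <- function(tensor) sort(unique(tensor$samples$timepoint))
tensor_arms <- function(tensor) unique(tensor$samples$arm)
tensor_replicates <- function(tensor) sort(unique(tensor$samples$replicate))

#' Read / write a screen intensity table
#'
#' The interchange format is a TSV with columns `hairpin`, `gene`, then one
#' numeric column per sample named `<arm>_T<t>_R<r>`.
#'
#' @param tensor A [screen_tensor()].
#' @param path File path.
#' @return `read_intensity_tsv` returns a `screen_tensor`;
#'   `write_intensity_tsv` returns `path` invisibly.
#' @export
write_intensity_tsv <- function(tensor, path) {
  df <- data.frame(tensor$hairpins[, c("hairpin", "gene")],
                   as.data.frame(tensor$values), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("hairpin", "gene")
  if (!all(need %in% names(df)))
    data_error(sprintf("intensity table must have columns: %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  if (!is.numeric(vals)) data_error("intensity columns must be numeric")
  screen_tensor(vals, df[, need])
}
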