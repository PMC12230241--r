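#' Generate a random sgRNA library
#'
#' Spacers are random unique 20-mers (configurable length), `guides_per_gene`
#' guides for each gene.
#'
#' @param genes Character vector of gene ids.
#' @param guides_per_gene Guides per gene (default 2).
#' @param spacer_length Spacer length in nt (default 20).
#' @param seed Integer seed.
#' @return A `guide_library` data frame: `guide`, `gene`, `spacer`.
#' @export
make_guide_library <- function(genes, guides_per_gene = 2, spacer_length = 20,
                               seed = 1) {
  assert_count(guides_per_gene, "guides_per_gene")
  with_seed(derive_seed(seed, "library"), {
    n <- length(genes) * guides_per_gene
    spacers <- character(0)
    while (length(spacers) < n) {
      more <- vapply(seq_len(n - length(spacers)), function(i)
        paste(sample(c("A", "C", "G", "T"), spacer_length, replace = TRUE),
              collapse = ""), "")
      spacers <- unique(c(spacers, more))
    }
    guide_library(data.frame(
      guide = sprintf("%s_sg%d", rep(genes, each = guides_per_gene),
                      rep(seq_len(guides_per_gene), length(genes))),
      gene = rep(genes, each = guides_per_gene),
      spacer = spacers[seq_len(n)], stringsAsFactors = FALSE))
  })
}

#' Validate a guide library table
#'
#' @param df Data frame with columns `guide`, `gene`, `spacer` (uppercase
#'   ACGT, unique, equal length).
#' @return The validated data frame with class `guide_library`.
#' @export
guide_library <- function(df) {
  stopifnot(all(c("guide", "gene", "spacer") %in% names(df)))
  if (anyDuplicated(df$spacer)) sdl_stop("duplicate spacer sequences", "sdl_library_error")
  if (anyDuplicated(df$guide)) sdl_stop("duplicate guide ids", "sdl_library_error")
  if (length(unique(nchar(df$spacer))) != 1L)
    sdl_stop("spacers must have equal length", "sdl_library_error")
  if (any(grepl("[^ACGT]", df$spacer)))
    sdl_stop("spacers must be uppercase ACGT", "sdl_library_error")
  class(df) <- c("guide_library", "data.frame")
  df
}

#' Simulate negative-binomial sgRNA counts for a two-arm pooled screen
#'
#' Guides are assigned a lognormal library-composition abundance around
#' `mean_coverage`; counts are negative binomial with the given dispersion.
#' Guides of a class with a non-zero `dropout_log2fc` entry are depleted (or
#' enriched) in the `cas9` arm only.
#'
#' @param library A [guide_library()].
#' @param gene_classes Named character vector mapping gene -> class.
#' @param n_samples_per_arm Samples (tumors/replicates) per arm (default 7).
#' @param mean_coverage Expected reads per guide (default 500).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   default 0.1.
#' @param dropout_log2fc Named numeric map class -> log2 fold change applied
#'   in the cas9 arm (classes absent from the map get 0).
#' @param abundance_log2_sd Lognormal spread of guide abundances (default 0.2).
#' @param seed Integer seed.
#' @return List with `counts` (guide x sample integer matrix), `samples`
#'   (data frame `sample`, `arm`), `library`, and `truth` (per-guide class
#'   and applied log2 fold change).
#' @export
simulate_sgrna_counts <- function(library, gene_classes,
                                  n_samples_per_arm = 7,
                                  mean_coverage = 500,
                                  dispersion = 0.1,
                                  dropout_log2fc = c(sdl = -2, essential = -2),
                                  abundance_log2_sd = 0.2,
                                  seed = 1) {
  if (mean_coverage <= 0) config_error("mean_coverage must be positive")
  stopifnot(inherits(library, "guide_library"))
  with_seed(derive_seed(seed, "sgrna"), {
    G <- nrow(library)
    cls <- unname(gene_classes[library$gene])
    lfc <- ifelse(cls %in% names(dropout_log2fc), dropout_log2fc[cls], 0)
    lfc[is.na(lfc)] <- 0
    base <- mean_coverage * 2^rnorm(G, 0, abundance_log2_sd)
    samples <- data.frame(
      sample = c(sprintf("cas9_S%d", seq_len(n_samples_per_arm)),
                 sprintf("no_cas9_S%d", seq_len(n_samples_per_arm))),
      arm = rep(c("cas9", "no_cas9"), each = n_samples_per_arm),
      stringsAsFactors = FALSE)
    counts <- matrix(0L, G, nrow(samples),
                     dimnames = list(library$guide, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- if (samples$arm[j] == "cas9") base * 2^lfc else base
      counts[, j] <- as.integer(if (dispersion <= 0) rpois(G, mu)
                                else rnbinom(G, mu = mu, size = 1 / dispersion))
    }
    list(counts = counts, samples = samples, library = library,
         truth = data.frame(guide = library$guide, gene = library$gene,
                            class = cls, log2fc_cas9 = lfc,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate amplicon reads for one screen sample
#'
#' Each guide's spacer is emitted `count` times embedded between the vector
#' flanks, with independent per-base substitution errors.
#'
#' @param counts Named integer vector guide -> read count.
#' @param library A [guide_library()].
#' @param flank5,flank3 Vector flank sequences around the spacer.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] of reads (named `read<i>_<guide>`).
#' @export
simulate_reads <- function(counts, library, flank5 = "ACCG", flank3 = "GTTT",
                           error_rate = 0, seed = 1) {
  stopifnot(inherits(library, "guide_library"))
  counts <- counts[counts > 0]
  if (!all(names(counts) %in% library$guide))
    sdl_stop("counts refer to guides absent from the library", "sdl_library_error")
  spacer <- setNames(library$spacer, library$guide)
  gid <- rep(names(counts), counts)
  seqs <- paste0(flank5, spacer[gid], flank3)
  with_seed(derive_seed(seed, "reads"), {
    if (error_rate > 0 && length(seqs) > 0) {
      len <- nchar(seqs[1])
      chars <- matrix(unlist(strsplit(seqs, "")), nrow = len)
      hit <- which(matrix(runif(length(chars)) < error_rate, nrow = len))
      if (length(hit) > 0) {
        bases <- c("A", "C", "G", "T")
        chars[hit] <- vapply(chars[hit], function(b)
          sample(setdiff(bases, b), 1L), "")
        seqs <- apply(chars, 2, paste, collapse = "")
      }
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("read%d_%s", seq_along(gid), gid)
    reads
  })
}

#' Write / read FASTQ (4-line, Phred+33, fixed quality)
#'
#' @param reads A [Biostrings::DNAStringSet].
#' @param path File path (`.gz` transparently compressed on read).
#' @return `read_fastq` returns a `DNAStringSet`.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w)
      paste(rep("I", w), collapse = ""), ""))
  qs <- Biostrings::QualityScaledDNAStringSet(reads, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) Biostrings::readDNAStringSet(path, format = "fastq")

#' Write / read a count matrix TSV (first column `guide`, optional `gene`)
#'
#' @param counts Guide x sample integer matrix.
#' @param path File path.
#' @param genes Optional named vector guide -> gene to include.
#' @return `read_counts_tsv` returns a list `counts`, `genes`.
#' @export
write_counts_tsv <- function(counts, path, genes = NULL) {
  df <- data.frame(guide = rownames(counts), stringsAsFactors = FALSE)
  if (!is.null(genes)) df$gene <- unname(genes[rownames(counts)])
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"guide" %in% names(df)) data_error("count table must have a 'guide' column")
  genes <- if ("gene" %in% names(df)) setNames(df$gene, df$guide) else NULL
  m <- as.matrix(df[, setdiff(names(df), c("guide", "gene")), drop = FALSE])
  rownames(m) <- df$guide
  list(counts = m, genes = genes)
}
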