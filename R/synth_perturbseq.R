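#' Simulate a direct-capture Perturb-seq experiment
#'
#' Cells carry 0, 1 or >= 2 guides in configured fractions. Single-guide
#' cells express their target gene at `knockdown_factor` times the control
#' mean. A latent anchor-high subpopulation (defined at generation time, not
#' by post hoc thresholding) expresses the anchor gene at a higher mean, and
#' within it cells carrying sdl-class guides are depleted by
#' `sdl_depletion_in_anchor_high`.
#'
#' @param n_cells Number of cells before QC.
#' @param targets Named character vector gene -> class, classes among
#'   `"sdl"`, `"other"`, `"positive_control"`. Non-targeting control guides
#'   are added automatically.
#' @param knockdown_factor Residual target expression in knockout cells
#'   (default 0.2; 1 = no knockdown).
#' @param anchor_high_fraction Fraction of cells in the latent anchor-high
#'   state (default 0.15).
#' @param sdl_depletion_in_anchor_high Depletion of sdl-guide cells inside
#'   the anchor-high subpopulation (1 = complete; default 0.8).
#' @param frac_multi_guide,frac_no_guide Fractions of cells with >= 2 or 0
#'   guides (defaults 0.10 and 0.05).
#' @param umi_mean Mean UMIs per cell (default 12000).
#' @param anchor Anchor gene name (default `"PLK1"`).
#' @param n_ntc Number of non-targeting guides (default 5).
#' @param n_background_genes Extra untargeted genes (default 20).
#' @param seed Integer seed.
#' @return A `cell_population` list: `umi` (cell x gene sparse matrix),
#'   `guides` (`cell`, `guide`, `umis`), `target_map` (`guide`, `gene`,
#'   `class`), `clusters` (NULL until [cluster_cells()]), and `truth`
#'   (`cell`, `anchor_high`, `n_guides`, `guide`).
#' @export
simulate_perturbseq <- function(n_cells, targets,
                                knockdown_factor = 0.2,
                                anchor_high_fraction = 0.15,
                                sdl_depletion_in_anchor_high = 0.8,
                                frac_multi_guide = 0.10,
                                frac_no_guide = 0.05,
                                umi_mean = 12000,
                                anchor = "PLK1",
                                n_ntc = 5,
                                n_background_genes = 20,
                                seed = 1) {
  assert_prob(c(knockdown_factor, anchor_high_fraction,
                sdl_depletion_in_anchor_high, frac_multi_guide, frac_no_guide),
              "perturb-seq fractions")
  if (frac_multi_guide + frac_no_guide > 1)
    config_error("guide fractions exceed 1")
  with_seed(derive_seed(seed, "perturbseq"), {
    t_genes <- names(targets)
    bg <- sprintf("BG%02d", seq_len(n_background_genes))
    genes <- unique(c(anchor, t_genes, bg))
    target_map <- data.frame(
      guide = c(sprintf("g_%s", t_genes), sprintf("NTC%d", seq_len(n_ntc))),
      gene = c(t_genes, rep("non_targeting", n_ntc)),
      class = c(unname(targets), rep("non_targeting", n_ntc)),
      stringsAsFactors = FALSE)

    base_mean <- setNames(2^runif(length(genes), 1, 5), genes)
    base_mean[anchor] <- 24

    cells <- sprintf("cell%05d", seq_len(n_cells))
    anchor_high <- runif(n_cells) < anchor_high_fraction
    cat_draw <- runif(n_cells)
    n_guides <- ifelse(cat_draw < frac_no_guide, 0L,
                       ifelse(cat_draw < frac_no_guide + frac_multi_guide, 2L, 1L))

    g_sdl <- target_map$class == "sdl"
    pick_guides <- function(high, k) {
      w <- rep(1, nrow(target_map))
      if (high) w[g_sdl] <- w[g_sdl] * (1 - sdl_depletion_in_anchor_high)
      if (all(w == 0)) w <- rep(1, nrow(target_map))
      sample(target_map$guide, k, prob = w / sum(w))
    }
    guide_rows <- list()
    cell_guides <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      if (n_guides[i] == 0L) next
      gs <- pick_guides(anchor_high[i], n_guides[i])
      cell_guides[[i]] <- gs
      guide_rows[[length(guide_rows) + 1L]] <- data.frame(
        cell = cells[i], guide = gs, umis = rpois(length(gs), 15) + 3L,
        stringsAsFactors = FALSE)
    }
    guides <- if (length(guide_rows)) do.call(rbind, guide_rows) else
      data.frame(cell = character(0), guide = character(0), umis = integer(0))

    mu <- matrix(base_mean, n_cells, length(genes), byrow = TRUE,
                 dimnames = list(cells, genes))
    mu[anchor_high, anchor] <- mu[anchor_high, anchor] * 4
    g2gene <- setNames(target_map$gene, target_map$guide)
    for (i in seq_len(n_cells)) {
      for (g in cell_guides[[i]]) {
        tg <- g2gene[[g]]
        if (tg %in% genes) mu[i, tg] <- mu[i, tg] * knockdown_factor
      }
    }
    size <- exp(rnorm(n_cells, 0, 0.45))
    mu <- mu * (size * umi_mean / sum(base_mean))
    counts <- matrix(rpois(length(mu), mu), n_cells, length(genes),
                     dimnames = dimnames(mu))
    structure(list(
      umi = Matrix::Matrix(counts, sparse = TRUE),
      guides = guides, target_map = target_map, clusters = NULL,
      truth = data.frame(cell = cells, anchor_high = anchor_high,
                         n_guides = n_guides,
                         guide = vapply(cell_guides, function(g)
                           if (is.null(g)) NA_character_ else g[1], ""),
                         stringsAsFactors = FALSE)),
      class = "cell_population")
  })
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("cell_population: %d cells x %d genes; %d guide assignments%s\n",
              nrow(x$umi), ncol(x$umi), nrow(x$guides),
              if (is.null(x$clusters)) "" else sprintf("; %d clusters",
                                                       length(unique(x$clusters)))))
  invisible(x)
}

#' Write / read a UMI matrix as MTX triplet plus features / barcodes TSV
#'
#' Files follow the 10x convention: `matrix.mtx` is gene x cell,
#' `features.tsv` lists genes, `barcodes.tsv` lists cells.
#'
#' @param umi Cell x gene matrix ([Matrix::sparseMatrix()] or dense).
#' @param dir Output directory (created if needed).
#' @return `read_mtx` returns a cell x gene sparse matrix.
#' @export
write_mtx <- function(umi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(methods::as(umi, "CsparseMatrix")), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(umi), file.path(dir, "features.tsv"))
  writeLines(rownames(umi), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  m <- Matrix::t(m)
  dimnames(m) <- list(cells, feats)
  methods::as(m, "CsparseMatrix")
}
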