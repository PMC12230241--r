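## Shared fixtures, all built in code at test time.

## Build a small screen_tensor from per-arm trajectory matrices
## (hairpin x timepoint), replicated identically unless noise is added.
make_tensor <- function(induced, uninduced, timepoints = NULL, reps = 1,
                        genes = NULL, noise_sd = 0, seed = 1) {
  induced <- as.matrix(induced); uninduced <- as.matrix(uninduced)
  H <- nrow(induced); Tn <- ncol(induced)
  if (is.null(timepoints)) timepoints <- seq_len(Tn) - 1L
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(H))
  set.seed(seed)
  cols <- list()
  for (arm in c("induced", "uninduced")) {
    m <- if (arm == "induced") induced else uninduced
    for (t in seq_len(Tn)) for (r in seq_len(reps)) {
      cols[[sprintf("%s_T%d_R%d", arm, timepoints[t], r)]] <-
        m[, t] + rnorm(H, 0, noise_sd)
    }
  }
  vals <- do.call(cbind, cols)
  screen_tensor(vals, data.frame(hairpin = sprintf("hp%02d", seq_len(H)),
                                 gene = genes, stringsAsFactors = FALSE))
}

## The canonical default synthetic screen, generated and scored once per run
## and shared between the module and acceptance tests.
.screen_cache <- new.env(parent = emptyenv())
scored_default_screen <- function() {
  if (is.null(.screen_cache$res)) {
    .screen_cache$sim <- simulate_shrna_screen()
    .screen_cache$res <- score_screen(.screen_cache$sim$tensor, wdc_config(seed = 1))
  }
  list(sim = .screen_cache$sim, res = .screen_cache$res)
}

truth_classes <- function(sim) setNames(sim$truth$class, sim$truth$gene)

## adjusted Rand index for clustering tests
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(n) n * (n - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ <- sa * sb / n
  (sij - exp_) / ((sa + sb) / 2 - exp_)
}

## brute-force motif count oracle: explicit window scan
brute_motif_count <- function(seq, motif) {
  s <- chartr("T", "U", toupper(seq))
  w <- nchar(motif)
  if (nchar(s) < w) return(0L)
  sum(vapply(seq_len(nchar(s) - w + 1L),
             function(i) substr(s, i, i + w - 1L) == motif, TRUE))
}

## small perturb-seq population shared across perturbseq tests
.pp_cache <- new.env(parent = emptyenv())
default_perturb_pop <- function() {
  if (is.null(.pp_cache$pop)) {
    targets <- setNames(rep(c("sdl", "other", "positive_control"), c(3, 5, 2)),
                        c("TJP3", "IGF2BP2", "CRB3", paste0("T", 1:5),
                          "RPL3", "RPL11"))
    .pp_cache$raw <- simulate_perturbseq(1500, targets, seed = 11)
    q <- qc_cells(.pp_cache$raw, qc_config())
    .pp_cache$report <- q$report
    .pp_cache$pop <- normalize_cells(q$pop)
  }
  list(raw = .pp_cache$raw, pop = .pp_cache$pop, report = .pp_cache$report)
}
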