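#' Configuration for the synthetic two-arm shRNA dropout screen
#'
#' The generator emulates a genome-wide pooled shRNA screen read out on
#' microarrays: an induced arm (anchor-gene overexpression switched on) and an
#' isogenic uninduced arm, sampled at three timepoints with replicates. Each
#' gene belongs to one of four classes with class- and arm-specific linear
#' log2-signal decay per timepoint step:
#'
#' * `non_essential`: no decay in either arm;
#' * `essential`: strong decay in both arms, slightly stronger under
#'   induction (loss of an essential gene is aggravated by the proliferative
#'   and chromosomal-instability stress of anchor overexpression);
#' * `sdl`: decay in the induced arm only, calibrated so that the summed
#'   linear-scale hairpin signal falls about 2.2-fold from T0 to T16 when
#'   induced and about 1.3-fold uninduced;
#' * `enriched`: signal gain in the induced arm.
#'
#' @param n_genes Number of genes (default 200).
#' @param class_fractions Named proportions over
#'   `c(non_essential, essential, sdl, enriched)`; must sum to 1.
#' @param hairpins_per_gene Hairpins per gene (default 5).
#' @param timepoints Ordered integer timepoint labels (default `c(0, 8, 16)`).
#' @param n_replicates Replicates per arm (default 2).
#' @param baseline_log2_mean,baseline_log2_sd Log2-intensity baseline
#'   distribution across hairpins (defaults 11 and 1.5).
#' @param decay_per_timestep Named list mapping class to
#'   `c(induced_rate, uninduced_rate)` in log2 units per timepoint step.
#' @param noise_sd Per-measurement Gaussian noise, log2 units (default 0.08).
#' @param frac_below_background Fraction of hairpins seeded with T0 log2
#'   signal below the background floor of 8 (default 0.02).
#' @param seed Integer seed (default 7).
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 200,
                              class_fractions = c(non_essential = 0.80,
                                                  essential = 0.05,
                                                  sdl = 0.10,
                                                  enriched = 0.05),
                              hairpins_per_gene = 5,
                              timepoints = c(0L, 8L, 16L),
                              n_replicates = 2,
                              baseline_log2_mean = 11,
                              baseline_log2_sd = 1.5,
                              decay_per_timestep = list(
                                non_essential = c(0, 0),
                                essential = c(-1.0, -0.75),
                                sdl = c(-log2(2.2) / 2, -log2(1.3) / 2),
                                enriched = c(0.4, 0)),
                              noise_sd = 0.08,
                              frac_below_background = 0.02,
                              seed = 7) {
  classes <- c("non_essential", "essential", "sdl", "enriched")
  if (!setequal(names(class_fractions), classes))
    config_error("class_fractions must be named over the four gene classes")
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    config_error("class_fractions must sum to 1")
  if (!setequal(names(decay_per_timestep), classes) ||
      !all(vapply(decay_per_timestep, length, 0L) == 2L))
    config_error("decay_per_timestep must map each class to (induced, uninduced) rates")
  sdl_rates <- decay_per_timestep[["sdl"]]
  if (!(sdl_rates[1] < sdl_rates[2]))
    config_error("sdl class requires induced_rate < uninduced_rate")
  assert_count(n_genes, "n_genes")
  assert_count(hairpins_per_gene, "hairpins_per_gene")
  assert_count(n_replicates, "n_replicates")
  if (length(timepoints) < 2L || is.unsorted(timepoints, strictly = TRUE))
    config_error("timepoints must be >= 2 strictly increasing labels")
  assert_prob(frac_below_background, "frac_below_background")
  structure(list(n_genes = as.integer(n_genes),
                 class_fractions = class_fractions,
                 hairpins_per_gene = as.integer(hairpins_per_gene),
                 timepoints = as.integer(timepoints),
                 n_replicates = as.integer(n_replicates),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 decay_per_timestep = decay_per_timestep,
                 noise_sd = noise_sd,
                 frac_below_background = frac_below_background,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate a two-arm time-course shRNA dropout screen
#'
#' Log2 signal for hairpin h at timepoint step s (s = 0, 1, ...) in arm a is
#' `baseline_h + rate(class_h, a) * s + N(0, noise_sd)`. A configured fraction
#' of hairpins is seeded with T0 signal below the background floor so the
#' background filter has work to do; their ids are recorded as
#' `dropped_truth`.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `simulated_screen` with elements `tensor`
#'   ([screen_tensor()]), `truth` (data frame gene, class) and
#'   `dropped_truth` (hairpin ids seeded below background).
#' @export
simulate_shrna_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(derive_seed(config$seed, "shrna"), {
    n_per <- round(config$class_fractions * config$n_genes)
    ## rounding can drift off n_genes; pad/trim the largest class
    n_per[which.max(n_per)] <- n_per[which.max(n_per)] + config$n_genes - sum(n_per)
    cls <- rep(names(n_per), n_per)
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    hpg <- config$hairpins_per_gene
    hp_gene <- rep(genes, each = hpg)
    hp_cls <- rep(cls, each = hpg)
    H <- length(hp_gene)
    hp_id <- sprintf("%s_hp%d", hp_gene, rep(seq_len(hpg), times = config$n_genes))
    baseline <- rnorm(H, config$baseline_log2_mean, config$baseline_log2_sd)

    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        timepoint = config$timepoints,
                        arm = c("induced", "uninduced"),
                        stringsAsFactors = FALSE)
    step <- match(grid$timepoint, config$timepoints) - 1L
    X <- matrix(NA_real_, H, nrow(grid))
    rate_ind <- vapply(config$decay_per_timestep, `[`, 0, 1L)[hp_cls]
    rate_un  <- vapply(config$decay_per_timestep, `[`, 0, 2L)[hp_cls]
    for (j in seq_len(nrow(grid))) {
      rate <- if (grid$arm[j] == "induced") rate_ind else rate_un
      X[, j] <- baseline + rate * step[j] + rnorm(H, 0, config$noise_sd)
    }
    colnames(X) <- sprintf("%s_T%d_R%d", grid$arm, grid$timepoint, grid$replicate)

    n_low <- round(config$frac_below_background * H)
    dropped <- character(0)
    if (n_low > 0) {
      low <- sample.int(H, n_low)
      X[low, step == 0L] <- runif(n_low * sum(step == 0L), 5, 7.9)
      dropped <- hp_id[low]
    }
    tensor <- screen_tensor(X, data.frame(hairpin = hp_id, gene = hp_gene,
                                          stringsAsFactors = FALSE))
    structure(list(tensor = tensor,
                   truth = data.frame(gene = genes, class = cls,
                                      stringsAsFactors = FALSE),
                   dropped_truth = dropped,
                   config = config),
              class = "simulated_screen")
  })
}
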