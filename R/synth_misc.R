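#' Configuration for the synthetic patient cohort
#'
#' Emulates an expression + survival cohort for natural-SDL analysis: anchor
#' and partner expression are drawn from a Gaussian copula hitting a target
#' Spearman correlation, and survival is exponential with the hazard
#' multiplied by `hazard_ratio_sdl` for patients NOT in the natural-SDL
#' expression state (anchor-high and partner-low), so the natural-SDL group
#' survives longer.
#'
#' @param n_patients Cohort size (default 500).
#' @param anchor_gene Anchor gene name (default `"PLK1"`).
#' @param partner_gene Partner (screen hit) gene name (default `"PARTNER"`).
#' @param hazard_ratio_sdl Hazard multiplier for non-SDL-state patients
#'   (default 3; 1 gives a null cohort).
#' @param censoring_rate Expected fraction censored (default 0.2).
#' @param expression_corr Target Spearman correlation between anchor and
#'   partner (default 0.6).
#' @param n_noise_genes Additional genes uncorrelated with the anchor
#'   (default 10).
#' @param baseline_hazard Events per day (default 1/1000).
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 500, anchor_gene = "PLK1",
                              partner_gene = "PARTNER",
                              hazard_ratio_sdl = 3, censoring_rate = 0.2,
                              expression_corr = 0.6, n_noise_genes = 10,
                              baseline_hazard = 1 / 1000, seed = 1) {
  if (hazard_ratio_sdl <= 0) config_error("hazard_ratio_sdl must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    config_error("censoring_rate must be in [0, 1)")
  assert_count(n_patients, "n_patients")
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate an expression + survival cohort
#'
#' @param config A [cohort_sim_config()].
#' @return List with `expression` (patient x gene log2 matrix as data frame,
#'   first column `patient`), `survival` (`patient`, `time`, `event`) and
#'   `truth` (per-patient `sdl_state`, plus the config).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_patients
    ## Gaussian copula: Pearson rho on normal scores giving the target
    ## Spearman r_s is rho = 2 sin(pi * r_s / 6)
    rho <- 2 * sin(pi * config$expression_corr / 6)
    za <- rnorm(n)
    zp <- rho * za + sqrt(1 - rho^2) * rnorm(n)
    expr <- data.frame(patient = sprintf("P%04d", seq_len(n)))
    expr[[config$anchor_gene]] <- 8 + 2 * za
    expr[[config$partner_gene]] <- 8 + 2 * zp
    for (g in seq_len(config$n_noise_genes))
      expr[[sprintf("NOISE%02d", g)]] <- 8 + 2 * rnorm(n)
    a_high <- expr[[config$anchor_gene]] >= median(expr[[config$anchor_gene]])
    p_low <- expr[[config$partner_gene]] < median(expr[[config$partner_gene]])
    sdl_state <- a_high & p_low
    hz <- config$baseline_hazard * ifelse(sdl_state, 1, config$hazard_ratio_sdl)
    t_event <- rexp(n, hz)
    ## independent exponential censoring tuned to the marginal censoring rate
    if (config$censoring_rate > 0) {
      cr <- config$censoring_rate
      t_cens <- rexp(n, mean(hz) * cr / (1 - cr))
    } else t_cens <- rep(Inf, n)
    surv <- data.frame(patient = expr$patient,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens))
    list(expression = expr, survival = surv,
         truth = list(sdl_state = sdl_state, config = config))
  })
}

#' Simulate exponential tumor growth with caliper read-out
#'
#' Volumes follow `V0 * 2^(t / doubling_time)` with multiplicative lognormal
#' noise; caliper diameters A and B are back-computed with a fixed 1.5
#' aspect ratio so that `(A * B^2) / 2` reproduces the volume.
#'
#' @param n_models Number of models/animals.
#' @param doubling_times Days per doubling, recycled over models.
#' @param measurement_days Days at which calipers are read.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param v0 Initial volume, mm^3 (default 100).
#' @param seed Integer seed.
#' @return Data frame `model`, `day`, `A`, `B`, `volume`, plus the true
#'   doubling time per model as attribute `"truth"`.
#' @export
simulate_growth <- function(n_models, doubling_times,
                            measurement_days = seq(0, 21, by = 3.5),
                            noise_cv = 0.1, v0 = 100, seed = 1) {
  if (any(doubling_times <= 0)) config_error("doubling_times must be positive")
  dt <- rep_len(doubling_times, n_models)
  with_seed(derive_seed(seed, "growth"), {
    rows <- lapply(seq_len(n_models), function(i) {
      mu <- v0 * 2^(measurement_days / dt[i])
      vol <- mu * exp(rnorm(length(mu), 0, noise_cv))
      if (noise_cv == 0) vol <- mu
      B <- (2 * vol / 1.5)^(1 / 3)
      data.frame(model = sprintf("M%03d", i), day = measurement_days,
                 A = 1.5 * B, B = B, volume = vol, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(model = sprintf("M%03d", seq_len(n_models)),
                                     doubling_time = dt, stringsAsFactors = FALSE)
    out
  })
}

## all overlapping occurrences of motif (RNA, T treated as U) in one sequence
scan_motif_starts <- function(seq, motif) {
  s <- chartr("Tt", "Uu", toupper(seq))
  m <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Simulate transcripts with planted RNA motifs
#'
#' Generates random RNA-alphabet sequences and plants an exact number of
#' occurrences of each motif per sequence. With `guarantee = TRUE` (default)
#' the background is repaired so no spurious occurrences exist, hence the
#' truth equals the observed count; otherwise truth counts are a lower bound.
#'
#' @param n_seqs Number of sequences.
#' @param length Sequence length, nt.
#' @param planted Named integer vector motif -> occurrences per sequence
#'   (RNA alphabet, e.g. `c(UGGA = 3)`).
#' @param guarantee Repair background so observed == planted (default TRUE).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and `truth`
#'   (matrix sequence x motif of planted counts).
#' @export
simulate_transcripts <- function(n_seqs, length, planted = c(UGGA = 0, AGGU = 0),
                                 guarantee = TRUE, seed = 1) {
  motifs <- names(planted)
  if (is.null(motifs) || any(grepl("[^ACGU]", motifs)))
    config_error("planted motifs must be named and over the RNA alphabet")
  w <- nchar(motifs)
  if (sum(planted * w) > length)
    config_error("planted motifs do not fit in the sequence length")
  alph <- c("A", "C", "G", "U")
  with_seed(derive_seed(seed, "transcripts"), {
    seqs <- character(n_seqs)
    for (i in seq_len(n_seqs)) {
      x <- sample(alph, length, replace = TRUE)
      ## choose non-overlapping windows for all planted copies
      want <- rep(motifs, planted)
      slots <- list()
      taken <- logical(length)
      for (m in want) {
        wl <- nchar(m)
        ok <- which(vapply(seq_len(length - wl + 1L), function(p)
          !any(taken[p:(p + wl - 1L)]), TRUE))
        if (!length(ok)) config_error("cannot place planted motifs without overlap")
        p <- if (length(ok) == 1L) ok else sample(ok, 1L)
        x[p:(p + wl - 1L)] <- strsplit(m, "")[[1]]
        taken[p:(p + wl - 1L)] <- TRUE
        slots[[base::length(slots) + 1L]] <- c(p, p + wl - 1L, match(m, motifs))
      }
      if (guarantee) {
        planted_starts <- vapply(slots, `[`, 0, 1L)
        planted_motif <- vapply(slots, `[`, 0L, 3L)
        for (iter in seq_len(200L)) {
          dirty <- FALSE
          for (mi in seq_along(motifs)) {
            st <- scan_motif_starts(paste(x, collapse = ""), motifs[mi])
            spur <- setdiff(st, planted_starts[planted_motif == mi])
            for (p in spur) {
              span <- p:(p + nchar(motifs[mi]) - 1L)
              free <- span[!taken[span]]
              if (!base::length(free)) next  # fully inside planted windows: impossible spur
              j <- free[1]
              x[j] <- sample(setdiff(alph, x[j]), 1L)
              dirty <- TRUE
            }
          }
          if (!dirty) break
        }
      }
      seqs[i] <- paste(x, collapse = "")
    }
    names(seqs) <- sprintf("tx%04d", seq_len(n_seqs))
    truth <- matrix(rep(planted, each = n_seqs), nrow = n_seqs,
                    dimnames = list(names(seqs), motifs))
    list(sequences = seqs, truth = truth)
  })
}

#' Simulate an arrayed confluency screen table
#'
#' Wells grow exponentially in confluency (capped at 1); genes with a
#' non-zero entry in `reduction` grow more slowly in the cas9 arm so that
#' the expected final/baseline growth ratio between arms equals
#' `1 - reduction`.
#'
#' @param genes Character vector of genes (one gene per well group).
#' @param reduction Named numeric vector gene -> target growth reduction in
#'   the cas9 arm (absent genes get 0).
#' @param days Imaging days (default `c(0, 2, 4, 6)`).
#' @param n_wells Wells per gene per arm (default 3).
#' @param growth_per_day Control-arm confluency fold change per day
#'   (default 1.45).
#' @param noise_cv Lognormal noise on confluency (default 0.05).
#' @param conf0 Confluency at day 0 (default 0.05).
#' @param seed Integer seed.
#' @return An arrayed-screen data frame: `well`, `gene`, `arm`, `day`,
#'   `confluency`, `replicate`.
#' @export
simulate_arrayed_confluency <- function(genes, reduction = c(),
                                        days = c(0, 2, 4, 6), n_wells = 3,
                                        growth_per_day = 1.45,
                                        noise_cv = 0.05, conf0 = 0.05,
                                        seed = 1) {
  ## reduction is calibrated to the default day-2 -> day-6 scoring window
  with_seed(derive_seed(seed, "arrayed"), {
    rows <- list()
    for (g in genes) {
      r <- if (g %in% names(reduction)) reduction[[g]] else 0
      for (arm in c("cas9", "no_cas9")) {
        rate <- if (arm == "cas9") growth_per_day * (1 - r)^(1 / 4) else growth_per_day
        for (wl in seq_len(n_wells)) {
          conf <- pmin(1, conf0 * rate^days *
                         exp(rnorm(base::length(days), 0, noise_cv)))
          rows[[base::length(rows) + 1L]] <- data.frame(
            well = sprintf("%s_%s_W%d", g, arm, wl), gene = g, arm = arm,
            day = days, confluency = conf, replicate = wl,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write sequences to wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth Any list of labels / parameters.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
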