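zero_decay <- list(non_essential = c(0, 0), essential = c(0, 0),
                   sdl = c(-1e-12, 0), enriched = c(0, 0))

test_that("shRNA screen generator: zero-rate case, determinism, config validation", {
  cfg <- screen_sim_config(n_genes = 20, decay_per_timestep = zero_decay,
                           noise_sd = 0, frac_below_background = 0, seed = 3)
  sim <- simulate_shrna_screen(cfg)
  v <- sim$tensor$values
  ## constant across timepoints within (arm, replicate)
  for (arm in c("induced", "uninduced")) for (r in 1:2) {
    cols <- sprintf("%s_T%d_R%d", arm, c(0, 8, 16), r)
    expect_equal(v[, cols[1]], v[, cols[2]], tolerance = 1e-9)
    expect_equal(v[, cols[1]], v[, cols[3]], tolerance = 1e-9)
  }
  ## determinism contract
  expect_identical(simulate_shrna_screen(cfg)$tensor$values, v)
  cfg2 <- cfg; cfg2$seed <- 4L
  expect_false(identical(simulate_shrna_screen(cfg2)$tensor$values, v))

  expect_error(screen_sim_config(class_fractions = c(non_essential = 0.5,
    essential = 0.2, sdl = 0.2, enriched = 0.2)), class = "sdl_config_error")
  expect_error(screen_sim_config(decay_per_timestep = modifyList(zero_decay,
    list(sdl = c(0.5, 0)))), class = "sdl_config_error")
})

test_that("default screen hits the calibrated SDL fold changes (pre-normalization)", {
  s <- scored_default_screen()
  truth <- truth_classes(s$sim)
  flt <- filter_hairpins(s$sim$tensor)
  cs <- cumulative_signal_comparison(flt$tensor, names(truth)[truth == "sdl"])
  expect_equal(cs$fold_change[cs$arm == "induced"], 2.2, tolerance = 0.15)
  expect_equal(cs$fold_change[cs$arm == "uninduced"], 1.3, tolerance = 0.15)
  ## the generator's replicate noise keeps screen QC above the r > 0.9 bar
  expect_gt(min(replicate_correlation(s$sim$tensor)$r), 0.9)
})

test_that("sgRNA count generator: null arms, Poisson limit, column totals", {
  lib <- make_guide_library(sprintf("G%02d", 1:30), 2, seed = 2)
  cls <- setNames(rep(c("sdl", "other"), c(5, 25)), sprintf("G%02d", 1:30))

  ## all-zero dropout: arm-wise guide means equal within sampling error
  nullsim <- simulate_sgrna_counts(lib, cls, n_samples_per_arm = 10,
                                   mean_coverage = 400, dispersion = 0.05,
                                   dropout_log2fc = c(), seed = 5)
  m_cas <- rowMeans(nullsim$counts[, nullsim$samples$arm == "cas9"])
  m_ctl <- rowMeans(nullsim$counts[, nullsim$samples$arm == "no_cas9"])
  expect_equal(mean(log2(m_cas / m_ctl)), 0, tolerance = 0.1)

  ## dispersion -> 0 limit: variance/mean about 1 on non-depleted guides
  ps <- simulate_sgrna_counts(lib, cls, n_samples_per_arm = 50,
                              mean_coverage = 300, dispersion = 0,
                              dropout_log2fc = c(), seed = 6)
  vm <- apply(ps$counts, 1, var) / rowMeans(ps$counts)
  expect_equal(mean(vm), 1, tolerance = 0.1)

  ## column sums near library_size * mean_coverage (within 3 empirical sd)
  cs <- colSums(nullsim$counts)
  expect_true(all(abs(cs - nrow(lib) * 400) <= 3 * sd(cs) + 3 * sqrt(nrow(lib) * 400)))

  expect_error(simulate_sgrna_counts(lib, cls, mean_coverage = 0),
               class = "sdl_config_error")
  expect_error(guide_library(data.frame(guide = c("a", "b"), gene = "g",
                                        spacer = c("ACGT", "ACGT"))),
               class = "sdl_library_error")
})

test_that("read simulator: emission counts, round trip, error-rate recovery bound", {
  lib <- make_guide_library(c("gA", "gB"), 1, seed = 9)
  reads <- simulate_reads(c(gA_sg1 = 3, gB_sg1 = 0), lib, error_rate = 0)
  expect_length(reads, 3)
  sp <- lib$spacer[lib$guide == "gA_sg1"]
  expect_true(all(grepl(sp, as.character(reads), fixed = TRUE)))

  ## round-trip identity at zero error rate
  lib2 <- make_guide_library(sprintf("G%02d", 1:25), 2, seed = 10)
  cls <- setNames(rep("other", 25), sprintf("G%02d", 1:25))
  sg <- simulate_sgrna_counts(lib2, cls, n_samples_per_arm = 1,
                              mean_coverage = 60, dropout_log2fc = c(), seed = 11)
  truth <- sg$counts[, 1]
  rr <- simulate_reads(truth, lib2, error_rate = 0, seed = 12)
  cg <- count_guides(rr, lib2, max_mismatch = 0)
  expect_equal(cg$counts[names(truth)], truth)
  expect_equal(cg$unmapped, 0)

  ## error_rate 0.01, 1-mismatch matching: recovery above the analytic
  ## binomial bound P(<2 errors in a 20-nt spacer) = 98.3% > 95%
  lib3 <- make_guide_library(sprintf("H%02d", 1:10), 1, seed = 13)
  cnt <- setNames(rep(1000L, 10), lib3$guide)
  re <- simulate_reads(cnt, lib3, error_rate = 0.01, seed = 14)
  ce <- count_guides(re, lib3, max_mismatch = 1)
  expect_gte(ce$assigned / ce$total, 0.95)
})

test_that("perturb-seq generator respects guide-category fractions and depletion", {
  targets <- setNames(rep(c("sdl", "other"), c(2, 4)), paste0("T", 1:6))
  pp <- simulate_perturbseq(1000, targets, frac_multi_guide = 0.1,
                            frac_no_guide = 0.05, seed = 20)
  q <- qc_cells(pp, qc_config(min_umis = 0))
  removed_guides <- sum(q$report$removed[c("no_guide", "multi_guide")])
  ## expectation 150, binomial sd about 11; allow 4 sd
  expect_lt(abs(removed_guides - 150), 45)
  ## determinism
  pp2 <- simulate_perturbseq(1000, targets, frac_multi_guide = 0.1,
                             frac_no_guide = 0.05, seed = 20)
  expect_identical(as.matrix(pp$umi), as.matrix(pp2$umi))

  ## full depletion: no sdl-guide cells inside the latent anchor-high set
  pf <- simulate_perturbseq(800, targets, sdl_depletion_in_anchor_high = 1,
                            seed = 21)
  sdl_guides <- pf$target_map$guide[pf$target_map$class == "sdl"]
  high_cells <- pf$truth$cell[pf$truth$anchor_high]
  expect_equal(sum(pf$guides$guide %in% sdl_guides &
                     pf$guides$cell %in% high_cells), 0)
})

test_that("cohort generator: correlation target, survival effect and null calibration", {
  co <- simulate_cohort(cohort_sim_config(expression_corr = 0.6, seed = 30))
  r <- cor(co$expression$PLK1, co$expression$PARTNER, method = "spearman")
  expect_equal(r, 0.6, tolerance = 0.1)

  ## hazard_ratio 3, n = 500: the survival selector rejects (power check is
  ## repeated in the acceptance suite; a couple of draws here)
  hits <- vapply(1:3, function(i) {
    ci <- simulate_cohort(cohort_sim_config(hazard_ratio_sdl = 3, seed = 30 + i))
    natural_sdl_survival(ci$expression, ci$survival, "PLK1", "PARTNER")$selected
  }, TRUE)
  expect_gte(mean(hits), 2 / 3)

  ## null: log-rank p roughly uniform over repeated simulation
  ps <- vapply(1:40, function(i) {
    cn <- simulate_cohort(cohort_sim_config(n_patients = 200,
                                            hazard_ratio_sdl = 1, seed = 100 + i))
    natural_sdl_survival(cn$expression, cn$survival, "PLK1", "PARTNER")$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("growth generator: exact and noisy recovery, degenerate series", {
  g0 <- simulate_growth(1, 7, noise_cv = 0, seed = 1)
  k0 <- growth_kinetics(g0$day, g0$volume)
  expect_equal(k0$slope, 1 / 7, tolerance = 1e-12)
  expect_equal(k0$doubling_time, 7, tolerance = 1e-12)
  ## caliper identity (A x B^2)/2 reproduces the volume
  expect_equal(tumor_volume(g0$A, g0$B), g0$volume, tolerance = 1e-9)

  ## noisy recovery within 15% (Monte-Carlo over models)
  gn <- simulate_growth(40, 10, measurement_days = seq(0, 28, 3.5),
                        noise_cv = 0.1, seed = 2)
  dts <- vapply(split(gn, gn$model), function(d)
    growth_kinetics(d$day, d$volume)$doubling_time, 0)
  rel_err <- abs(dts - 10) / 10
  expect_lt(mean(rel_err), 0.15)
  expect_lt(unname(quantile(rel_err, 0.9)), 0.15)

  ## constant series: slope 0, undefined doubling flag
  kf <- growth_kinetics(c(0, 3, 6, 9), rep(100, 4))
  expect_equal(kf$slope, 0)
  expect_true(kf$doubling_undefined)
})

test_that("transcript generator plants exactly the requested motifs", {
  tx <- simulate_transcripts(10, 300, c(UGGA = 3, AGGU = 0), seed = 40)
  cm <- count_motifs(tx$sequences)
  expect_equal(unname(cm$per_sequence[, "UGGA"]), rep(3, 10))
  expect_equal(unname(cm$per_sequence[, "AGGU"]), rep(0, 10))
  tx0 <- simulate_transcripts(5, 200, c(UGGA = 0, AGGU = 0), seed = 41)
  expect_equal(sum(count_motifs(tx0$sequences)$totals), 0)
  expect_error(simulate_transcripts(1, 10, c(UGGA = 5)),
               class = "sdl_config_error")
})

test_that("simulators are seed-deterministic across the board", {
  lib <- make_guide_library(c("a", "b"), 2, seed = 50)
  expect_identical(lib, make_guide_library(c("a", "b"), 2, seed = 50))
  cls <- c(a = "other", b = "other")
  expect_identical(simulate_sgrna_counts(lib, cls, seed = 51)$counts,
                   simulate_sgrna_counts(lib, cls, seed = 51)$counts)
  expect_identical(
    as.character(simulate_reads(c(a_sg1 = 5), lib, error_rate = 0.1, seed = 52)),
    as.character(simulate_reads(c(a_sg1 = 5), lib, error_rate = 0.1, seed = 52)))
  expect_identical(simulate_cohort(cohort_sim_config(seed = 53)),
                   simulate_cohort(cohort_sim_config(seed = 53)))
  expect_identical(simulate_growth(2, 7, seed = 54),
                   simulate_growth(2, 7, seed = 54))
  expect_identical(simulate_transcripts(2, 100, c(UGGA = 1), seed = 55),
                   simulate_transcripts(2, 100, c(UGGA = 1), seed = 55))
})
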