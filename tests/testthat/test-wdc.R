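test_that("quantile normalization matches the sorted-mean rule and its invariant", {
  ## direct evaluation: columns [1,2,3] and [4,5,6] -> both [2.5,3.5,4.5]
  tn <- make_tensor(induced = cbind(c(1, 2, 3), c(4, 5, 6)),
                    uninduced = cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(tn)
  expect_equal(unname(qn$values[, "induced_T0_R1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, "induced_T1_R1"]), c(2.5, 3.5, 4.5))

  ## identical columns are unchanged
  tn2 <- make_tensor(cbind(c(9, 10, 11), c(9, 10, 11)),
                     cbind(c(9, 10, 11), c(9, 10, 11)))
  expect_equal(quantile_normalize(tn2)$values, tn2$values)

  ## definitional invariant + independent oracle (limma) on random input
  set.seed(42)
  tn3 <- make_tensor(matrix(rnorm(60, 10), 20), matrix(rnorm(60, 10), 20),
                     reps = 2)
  q3 <- quantile_normalize(tn3)
  srt <- apply(q3$values, 2, sort)
  expect_true(all(abs(srt - srt[, 1]) < 1e-12))
  expect_equal(unname(q3$values),
               unname(limma::normalizeQuantiles(tn3$values)),
               tolerance = 1e-12)
  expect_error(quantile_normalize(make_tensor(cbind(c(NA, 1), c(1, 1)),
                                              cbind(c(1, 1), c(1, 1)))),
               class = "sdl_data_error")
})

test_that("hairpin background filter applies both rules, matching a row-wise oracle", {
  tn <- make_tensor(
    induced   = rbind(c(7.9, 9, 9), c(9, 9, 9), c(9, -1, 9), c(12, 11, 10)),
    uninduced = rbind(c(9.1, 9, 9), c(9, 9, 9), c(9, 9, 9), c(12, 11, 10)))
  fl <- filter_hairpins(tn)
  expect_setequal(fl$dropped$hairpin, c("hp01", "hp03"))
  expect_equal(fl$dropped$reason[fl$dropped$hairpin == "hp01"],
               "T0 below background")
  expect_true("hp04" %in% fl$tensor$hairpins$hairpin)

  set.seed(7)
  rt <- make_tensor(matrix(rnorm(90, 9, 3), 30), matrix(rnorm(90, 9, 3), 30))
  fr <- filter_hairpins(rt)
  oracle_keep <- vapply(seq_len(30), function(i) {
    t0 <- rt$values[i, grepl("_T0_", colnames(rt$values))]
    later <- rt$values[i, !grepl("_T0_", colnames(rt$values))]
    all(t0 >= 8) && all(later >= 0)
  }, TRUE)
  expect_setequal(fr$tensor$hairpins$hairpin,
                  rt$hairpins$hairpin[oracle_keep])
})

test_that("wdc_hairpin evaluates the printed formula (oracle to 1e-12) with its symmetries", {
  ## direct evaluation: eps=0.5, induced [10,8,6], uninduced flat
  tn <- make_tensor(rbind(c(10, 8, 6)), rbind(c(10, 10, 10)))
  hp <- wdc_hairpin(tn, wdc_config(epsilon = 0.5))
  expect_equal(hp$wdc_h, -1.5)

  ## identical trajectories -> 0; increasing induced -> positive
  tn0 <- make_tensor(rbind(c(10, 8, 6)), rbind(c(10, 8, 6)))
  expect_equal(wdc_hairpin(tn0, wdc_config())$wdc_h, 0)
  tnp <- make_tensor(rbind(c(10, 11, 12)), rbind(c(10, 10, 10)))
  expect_gt(wdc_hairpin(tnp, wdc_config())$wdc_h, 0)

  ## naive double-loop oracle on random tensors, several epsilons
  set.seed(11)
  for (eps in c(0.3, 0.5, 1)) {
    ind <- matrix(rnorm(40, 10), 10); un <- matrix(rnorm(40, 10), 10)
    tr <- make_tensor(ind, un, reps = 2, noise_sd = 0.2, seed = eps * 100)
    got <- wdc_hairpin(tr, wdc_config(epsilon = eps))$wdc_h
    oracle <- vapply(seq_len(10), function(h) {
      per_rep <- vapply(1:2, function(r) {
        s <- 0
        for (t in 0:2) {
          xi1 <- tr$values[h, sprintf("induced_T%d_R%d", t + 1, r)]
          xi0 <- tr$values[h, sprintf("induced_T%d_R%d", t, r)]
          xu1 <- tr$values[h, sprintf("uninduced_T%d_R%d", t + 1, r)]
          xu0 <- tr$values[h, sprintf("uninduced_T%d_R%d", t, r)]
          s <- s + eps^(t + 1) * (xi1 - xi0) - eps^(t + 1) * (xu1 - xu0)
        }
        s
      }, 0)
      mean(per_rep)
    }, 0)
    expect_equal(got, oracle, tolerance = 1e-12)

    ## linearity: scaling increments by c scales wdc_h by c
    tr2 <- tr; t0v <- tr2$values[, grepl("_T0_", colnames(tr2$values))]
    for (cn in colnames(tr2$values))
      tr2$values[, cn] <- 3 * tr2$values[, cn] - 2 * rowMeans(t0v)
    expect_equal(wdc_hairpin(tr2, wdc_config(epsilon = eps))$wdc_h, 3 * got,
                 tolerance = 1e-10)

    ## arm-swap antisymmetry
    swapped <- tr
    cn <- colnames(swapped$values)
    newn <- sub("^induced", "XX", cn)
    newn <- sub("^uninduced", "induced", newn)
    newn <- sub("^XX", "uninduced", newn)
    colnames(swapped$values) <- newn
    swapped <- screen_tensor(swapped$values, swapped$hairpins)
    expect_equal(wdc_hairpin(swapped, wdc_config(epsilon = eps))$wdc_h, -got,
                 tolerance = 1e-12)
  }
  one_arm <- screen_tensor(tn$values[, 1:3, drop = FALSE], tn$hairpins)
  expect_error(wdc_hairpin(one_arm, wdc_config()), class = "sdl_data_error")
})

test_that("gene aggregation averages the k most negative hairpins", {
  sc <- data.frame(hairpin = paste0("h", 1:8),
                   gene = c(rep("A", 5), "B", rep("C", 2)),
                   wdc_h = c(-3, -1, -5, 0, 2, -2, 1, 3))
  gt <- wdc_gene(sc, wdc_config(k_aggregate = 2))
  expect_equal(gt$wdc_gene[gt$gene == "A"], -4)        # (-5 + -3)/2
  expect_equal(gt$wdc_gene[gt$gene == "B"], -2)        # single hairpin
  expect_true(gt$underpowered[gt$gene == "B"])
  expect_equal(gt$wdc_gene[gt$gene == "C"], 2)         # all positive: (1+3)/2
  expect_false(any(gt$underpowered[gt$gene %in% c("A", "C")]))
})

test_that("permutation p values follow the add-one rule and match exhaustive enumeration", {
  ## add-one floor: p can never be 0 and is near 1/(B+1) when the observed
  ## score undercuts the rest of the pool (its own hairpin is in the pool,
  ## so an occasional tie draw keeps p slightly above the floor)
  set.seed(4)
  sc <- data.frame(hairpin = paste0("h", 1:1000),
                   gene = c("A", rep("P", 999)),
                   wdc_h = c(-100, rnorm(999)))
  pp <- permutation_pvalues(sc, wdc_config(n_permutations = 999, k_aggregate = 1,
                                           seed = 4))
  expect_gte(pp$p_perm[pp$gene == "A"], 1 / 1000)
  expect_lte(pp$p_perm[pp$gene == "A"], 6 / 1000)

  ## m = 1, k = 1, observed at the pool median: p about 0.5
  scm <- data.frame(hairpin = paste0("h", 1:101),
                    gene = c("A", rep("P", 100)),
                    wdc_h = c(0, seq(-1, 1, length.out = 100)))
  ppm <- permutation_pvalues(scm, wdc_config(n_permutations = 2000,
                                             k_aggregate = 1, seed = 5))
  expect_equal(ppm$p_perm[ppm$gene == "A"], 0.5, tolerance = 0.06)

  ## exhaustive C(5,2) oracle: pool of 5, m = 2, k = 2
  pool <- c(-2.0, -0.7, 0.1, 0.9, 1.6)
  sc5 <- data.frame(hairpin = paste0("h", 1:7),
                    gene = c("A", "A", paste0("P", 1:5)),
                    wdc_h = c(-0.8, 0.5, pool))
  ## the sampling pool is all 7 unfiltered scores
  full_pool <- sc5$wdc_h
  obs <- mean(sort(c(-0.8, 0.5))[1:2])
  subs <- combn(full_pool, 2)
  exact_p <- mean(colMeans(subs) <= obs)
  pp5 <- permutation_pvalues(sc5, wdc_config(n_permutations = 10000, seed = 6))
  expect_equal(pp5$p_perm[pp5$gene == "A"], exact_p, tolerance = 0.02)
})

test_that("gene-level t test behaves at the edges and with real separation", {
  ## identical arms: zero components in both -> degenerate, flagged not crash
  tn <- make_tensor(matrix(10, 4, 3), matrix(10, 4, 3), reps = 2,
                    genes = rep("A", 4))
  hp <- wdc_hairpin(tn, wdc_config())
  tt <- ttest_pvalues(tn, hp)
  expect_true(tt$not_computable[tt$gene == "A"])

  ## identical arms with noise: p near 1 on average (no separation)
  set.seed(3)
  ps <- replicate(20, {
    tnn <- make_tensor(matrix(10, 5, 3), matrix(10, 5, 3), reps = 2,
                       genes = rep("A", 5), noise_sd = 0.3,
                       seed = sample.int(1e6, 1))
    hpn <- wdc_hairpin(tnn, wdc_config())
    ttest_pvalues(tnn, hpn)$p_ttest
  })
  expect_gt(mean(ps), 0.3)  # uniform p has mean 0.5

  ## strong separation, n = 10 per arm -> p < 0.001 (textbook two-sample t)
  ind <- matrix(rep(c(10, 8, 6), each = 5), 5)
  un <- matrix(10, 5, 3)
  tns <- make_tensor(ind, un, reps = 2, genes = rep("A", 5),
                     noise_sd = 0.1, seed = 8)
  hps <- wdc_hairpin(tns, wdc_config())
  tts <- ttest_pvalues(tns, hps)
  expect_lt(tts$p_ttest, 1e-3)
  x <- as.vector(attr(hps, "arm_components")$induced)
  y <- as.vector(attr(hps, "arm_components")$uninduced)
  expect_equal(tts$p_ttest, t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("hit calling conjoins the fold and significance rules", {
  gt <- data.frame(gene = c("a", "b", "c", "d"),
                   wdc_gene = c(-2.5, -2.5, -0.5, -1.5),
                   p_perm = c(0.01, 0.2, 0.001, 0.04),
                   p_ttest = c(0.02, 0.01, 0.001, NA))
  res <- call_hits(gt, wdc_config(fold_threshold_log2 = -1.0))
  expect_equal(res$hit, c(TRUE, FALSE, FALSE, FALSE))
  ## signal-ratio mode uses the raw induced-arm fold column
  gt$induced_log2fc <- c(-2, -2, -2, -0.5)
  res2 <- call_hits(gt, wdc_config(fold_mode = "signal_ratio"))
  expect_equal(res2$hit, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(call_hits(gt[, 1:4], wdc_config(fold_mode = "signal_ratio")),
               class = "sdl_data_error")
})

test_that("replicate correlation handles duplicated, negated and constant columns", {
  set.seed(9)
  base <- matrix(rnorm(30, 10), 10, 3)
  tn <- make_tensor(base, base, reps = 2)  # replicates identical by build
  rc <- replicate_correlation(tn)
  expect_equal(rc$r, rep(1, nrow(rc)))
  ## negate a centered replicate: r = -1
  v <- tn$values
  v[, "induced_T0_R2"] <- 2 * mean(v[, "induced_T0_R1"]) - v[, "induced_T0_R1"]
  tn2 <- screen_tensor(v, tn$hairpins)
  rc2 <- replicate_correlation(tn2)
  expect_equal(rc2$r[rc2$arm == "induced" & rc2$timepoint == 0], -1)
  ## constant column flagged
  v[, "induced_T1_R1"] <- 5
  rc3 <- replicate_correlation(screen_tensor(v, tn$hairpins))
  expect_true(rc3$undefined[rc3$arm == "induced" & rc3$timepoint == 1])
})

test_that("precision-recall evaluation: perfect separation, label-free ranking, errors", {
  gt <- data.frame(gene = paste0("g", 1:40),
                   wdc_gene = c(seq(-5, -3, length.out = 20),
                                seq(-0.5, 1, length.out = 20)))
  ess <- paste0("g", 1:20); non <- paste0("g", 21:40)
  expect_equal(evaluate_performance(gt, ess, non)$f_max, 1)

  ## ranking independent of labels, balanced classes: F_max -> 2/3 at full recall
  set.seed(10)
  gt2 <- data.frame(gene = paste0("g", 1:400), wdc_gene = rnorm(400))
  f2 <- evaluate_performance(gt2, paste0("g", 1:200), paste0("g", 201:400))$f_max
  expect_equal(f2, 2 / 3, tolerance = 0.05)

  expect_error(evaluate_performance(gt, "absent1", "absent2"),
               class = "sdl_data_error")
  expect_error(evaluate_performance(gt, c("g1"), c("g1", "g2")),
               class = "sdl_config_error")
})

test_that("cumulative signal comparison recovers exact fold changes", {
  ## constant tensor: fold 1, KS p about 1
  tn <- make_tensor(matrix(10, 20, 3), matrix(10, 20, 3))
  cs <- cumulative_signal_comparison(tn, unique(tn$hairpins$gene))
  expect_equal(cs$fold_change, c(1, 1))
  expect_true(all(cs$ks_p > 0.9))
  ## halved linear signal at the final timepoint: fold exactly 2
  set.seed(12)
  base <- rnorm(20, 10)
  ind <- cbind(base, base, base - 1)  # log2 - 1 = halved
  tn2 <- make_tensor(ind, cbind(base, base, base))
  cs2 <- cumulative_signal_comparison(tn2, unique(tn2$hairpins$gene))
  expect_equal(cs2$fold_change[cs2$arm == "induced"], 2, tolerance = 1e-12)
  expect_equal(cs2$fold_change[cs2$arm == "uninduced"], 1, tolerance = 1e-12)
  expect_error(cumulative_signal_comparison(tn, "no_such_gene"),
               class = "sdl_data_error")
})
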