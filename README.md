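# sdlscreen

Scoring and candidate triage for **synthetic dosage lethality (SDL)**
screens. SDL is the genetic interaction in which overexpression of one gene
(an anchor such as the mitotic kinase PLK1, whose overexpression drives
chromosomal instability) makes loss of a second, otherwise non-essential
gene lethal. Pooled dropout screens find such partners by comparing hairpin
or guide abundance over time between an anchor-*induced* arm and an isogenic
*uninduced* arm.

The package is aimed at functional-genomics analysts who have screen
read-outs in tabular form and want a tested, deterministic pipeline from raw
signal to a prioritized candidate list.

## What it computes

The core fitness statistic is the **weighted differential cumulative change
(WDC)**. For hairpin *h* with log2 signal x<sub>t,r</sub> at timepoint index
t and replicate r:

    WDC_h = mean_r [ sum_{t=0}^{T-1} eps^(t+1) (x_IN[t+1,r] - x_IN[t,r])
                   - sum_{t=0}^{T-1} eps^(t+1) (x_UN[t+1,r] - x_UN[t,r]) ]

with weight constant eps in (0, 1] (default 0.5) ranking early dropouts
ahead of late ones. The gene score averages the two most negative hairpins;
significance combines a permutation test (null drawn from the global hairpin
pool, aggregated with the same rule) with a two-sample t test between arms.

Around this core the package provides:

* `synthdata` generators for every input, with recorded ground truth
  (`simulate_shrna_screen()`, `simulate_sgrna_counts()`, `simulate_reads()`,
  `simulate_perturbseq()`, `simulate_cohort()`, `simulate_growth()`,
  `simulate_transcripts()`, `simulate_arrayed_confluency()`);
* screen scoring and QC (`quantile_normalize()`, `filter_hairpins()`,
  `wdc_hairpin()`, `wdc_gene()`, `permutation_pvalues()`, `ttest_pvalues()`,
  `call_hits()`, `replicate_correlation()`, `evaluate_performance()`,
  `cumulative_signal_comparison()`, wrapper `score_screen()`);
* secondary CRISPR screens (`count_guides()`, `score_invivo()`,
  `arrayed_growth_reduction()`, `intersect_screens()`);
* prioritization (`coexpression_screen()`, `expression_filter()`,
  `essential_gene_filter()`, `differential_essentiality()`,
  `natural_sdl_survival()`, `drug_sensitivity_differential()`,
  `build_ledger()`);
* Perturb-seq triage (`qc_cells()`, `normalize_cells()`, `ko_efficiency()`,
  `cluster_cells()`, `ko_cluster_composition()`, `trace_anchor_high()`,
  `target_expression_summary()`);
* downstream analyses (`tumor_volume()`, `growth_kinetics()`,
  `pdx_group_compare()`, `mito_metrics()`, `count_motifs()`).

## Worked example

Generate the default labeled synthetic screen (200 genes, 5 hairpins each,
T0/T8/T16, two replicates per arm) and score it:

```r
library(sdlscreen)

sim <- simulate_shrna_screen()             # default config, seed 7
res <- score_screen(sim$tensor, wdc_config(seed = 1))
head(res$gene_table[, c("gene", "wdc_gene", "p_perm", "p_ttest",
                        "induced_log2fc")], 5)
#>      gene wdc_gene  p_perm  p_ttest induced_log2fc
#> 184 G0184   -0.338 0.00300 5.35e-09          -1.03
#> 190 G0190   -0.331 0.00400 1.90e-09          -1.02
#> 185 G0185   -0.331 0.00400 1.33e-07          -1.03
#> 171 G0171   -0.328 0.00300 4.65e-12          -1.09
#> 180 G0180   -0.323 0.00599 8.96e-06          -1.04
```

All five top-ranked genes are planted SDL genes: strongly negative WDC, both
p values far below 0.05, and an induced-arm log2 fold change of about −1
(the calibrated ~2-fold induced drop). Benchmarking the ranking against the
simulated essential / non-essential labels and recovering the planted
cumulative-signal fold changes:

```r
truth <- setNames(sim$truth$class, sim$truth$gene)
evaluate_performance(res$gene_table,
                     names(truth)[truth == "essential"],
                     names(truth)[truth == "non_essential"])$f_max
#> [1] 1

flt <- filter_hairpins(sim$tensor)
cumulative_signal_comparison(flt$tensor, names(truth)[truth == "sdl"])
#>         arm fold_change ks_stat      ks_p
#> 1   induced       2.227  0.4211 6.248e-08
#> 2 uninduced       1.314  0.2105 2.941e-02
```

The SDL hairpin pool loses 2.23x of its summed signal in the induced arm and
1.31x in the uninduced arm between T0 and T16 — the fold changes the
generator is calibrated to.

## Command line

```sh
Rscript -e 'sdlscreen::sdl_main()' simulate-shrna --seed 7 --out-dir sim/
Rscript -e 'sdlscreen::sdl_main()' shrna-score --input sim/intensity.tsv \
    --epsilon 0.5 --n-perm 1000 --alpha 0.05 --fold-threshold -1.0 \
    --seed 7 --out-dir scored/
```

(or use the installed shim `inst/cli/sdl`). Further subcommands:
`crispr-count`, `crispr-score`, `arrayed`, `motifs`, `growth`,
`pdx-compare`, `mito`. Every run writes a `provenance.json` with the parsed
configuration.

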