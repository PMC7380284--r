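# evotiss

Tissue-anchored analysis of protein sequence evolution from multi-tissue
transcriptomes.

## The problem

Why do proteins evolve at such different rates? Expression level has long
been the strongest known correlate of the evolutionary rate ω = dN/dS (the
ratio of nonsynonymous to synonymous substitution rates), but in a
multicellular organism expression is a tissue-by-tissue phenomenon.
evotiss is for researchers in molecular evolution and statistical genetics
who want to ask, from a gene-by-sample expression matrix and a per-gene
substitution-rate table:

- How does each tissue's expression level and inter-individual expression
  variance correlate with dN, dS and ω?
- Is the tissue in which a gene is *most variable* across individuals — its
  **MaxTissue**, with that variance its **MaxVariance** — informative about
  the gene's evolutionary rate? The **tissue-anchored model** holds that the
  variance in ω *across* MaxTissues exceeds the variance within them, i.e.
  the physiological context of peak expression variability constrains
  protein evolution. It is tested with a Kruskal–Wallis statistic and a
  gene-count-preserving permutation test, and summarized per tissue by the
  median ω of anchored genes with the dispersion metric
  MaxTissue-δ = 3.14 (v75 − v25)/√n.
- Do determinants have *independent* effects once a correlated covariate is
  controlled, when that covariate is measured with noise? (EPRCA —
  Empirical Partial Rank Correlation Analysis — with an adjusted coefficient
  θ̂ = √(r² − E(M₀)²) that subtracts the spurious component estimated by a
  permutation null.)
- How much of the variation in ω do all features jointly explain?
  (Gradient-boosted regression trees; relative-importance spectra over a
  grid of tree counts and interaction depths; out-of-sample adjusted R².)
- What does it imply for gene discovery? (Statistical power of
  transcriptome-wide association tests as a function of expression
  imputation accuracy, via the noncentral chi-square with
  λ = N · R² · φ².)

All inputs are plain TSV (expression matrix + sample→tissue map,
gene/dN/dS table, edge list, gene sets); a synthetic-data generator with
the same statistical structure (lognormal multi-tissue expression with a
mean–variance relation, a tau breadth spectrum, tissue-anchored median-ω
shifts, co-expression blocks, a heavy-tailed network, imputation R² coupled
to ω) makes every stage testable without external data. See the methods
vignette (`vignettes/evotiss-methods.Rmd`) for the models, parameter
meanings and design choices.

## Worked example

```r
library(evotiss)

sim <- simulate_dataset(sim_config(n_genes = 2000, n_tissues = 12,
                                   samples_per_tissue = 40, seed = 7))
features <- build_feature_table(sim$expression, network = sim$network,
                                branch = sim$branch,
                                imputation_r2 = sim$imputation_r2)
omega <- setNames(sim$rates$omega, sim$rates$gene)[features$gene]

anchor_test(features$max_tissue, omega, n_perm = 1000, seed = 7)
#> <anchor_test_result> H = 84.204 (df = 11), analytic p = 2.26e-13, empirical p = 0 (1000 permutations)
```

The Kruskal–Wallis H of 84.2 on 11 degrees of freedom says ω differs
strongly between MaxTissue groups; no random tissue reassignment among
1000 (preserving the per-tissue gene counts) reached the observed H, so
the empirical p is 0 at resolution 1/1000 — the tissue-anchored signal the
generator planted (per-tissue anchor shifts of sd 0.3 on log ω) is
recovered. The per-tissue signature ranks tissues by the median ω of their
anchored genes with MaxTissue-δ as its dispersion:

```r
head(anchor_test(features$max_tissue, omega, n_perm = 1000, seed = 7)$signature, 3)
#>      tissue   n median_omega      delta
#> 7  tissue07 164    0.1041234 0.02809667
#> 11 tissue11 123    0.1256484 0.03976489
#> 9  tissue09 112    0.1294999 0.03522834

eprca(log2(features$max_level + 1), omega, features$tau,
      n_perm = 1000, seed = 7)
#> <eprca_result> r_obs = -0.3140, null mean = -0.1772 (sd 0.0099), empirical p = 0, theta = 0.2592 [proxy_swap, 1000 permutations]
```

Expression level correlates with ω at −0.31 after conditioning on the tau
breadth statistic; the permutation null (which preserves the level–tau
correlation) shows −0.18 of that would arise spuriously, leaving an
adjusted independent-effect magnitude θ̂ = 0.26, significant at the 1/1000
resolution.

```r
fit <- fit_boosted(features, omega,
                   boost_config(n_trees = 1000, interaction_depth = 4, seed = 7))
round(sort(fit$importance, decreasing = TRUE), 1)
#>  max_variance           tau     max_level imputation_r2        branch
#>          39.8          29.7          11.9           7.9           3.7
#>  median_level    mean_level        degree
#>           3.3           2.2           1.5
```

MaxVariance tops the importance spectrum (scores sum to 100), ahead of
expression breadth and maximum expression level — the joint-model ranking
that motivates anchoring genes to their tissue of maximal variance.

```r
twas_power(sim$imputation_r2, gwas_n = 1000, phi2 = 0.01, omega = omega,
           conserved_max = quantile(omega, 0.25),
           fast_min = quantile(omega, 0.75))
#> <power_result> N = 1000, alpha = 0.05, phi2 = 0.01: median power 0.270
#>   conserved 0.189 vs fast-evolving 0.379 (Mann-Whitney p = 3.21e-42)
```

Because imputation R² rises with ω, conserved genes (bottom ω quartile)
have about half the TWAS power of fast-evolving genes at N = 1000 — the
methodological warning that expression-based gene discovery is biased
against exactly the genes under the strongest purifying selection.

`run_pipeline()` chains simulate → features → correlate → anchor → EPRCA /
GLS → boost → power through files in these formats, with a manifest of
outputs, checksums and a seed-stamped log, so any stage can also be run
standalone on user data.

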