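---
title: "Methods: tissue-anchored analysis of protein evolutionary rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-anchored analysis of protein evolutionary rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

evotiss relates multi-tissue gene expression features to the rate of protein
sequence evolution, measured per gene as omega = dN/dS — the ratio of
nonsynonymous to synonymous substitution rates between two species' orthologs.
omega well below 1 indicates purifying selection; dS serves as a proxy for the
neutral mutation rate, so omega is undefined (reported as missing, never 0 or
infinity) when dS = 0.

The package implements four layers of analysis:

1. **Expression features.** Per-tissue mean, median, variance (denominator
   n − 1) and variance-to-mean ratio of RPKM-scale expression; the tau
   expression-breadth statistic
   \(\tau = \sum_i (1 - \hat x_i)/(n-1)\), \(\hat x_i = x_i / \max_j x_j\),
   computed on per-tissue mean expression (0 = identical expression
   everywhere, 1 = single-tissue expression); and each gene's **MaxTissue**,
   the tissue where it attains its maximum inter-individual expression
   variance (**MaxVariance**).
2. **The tissue-anchored model.** The hypothesis that variance in omega
   *across* MaxTissues exceeds the variance within them — i.e. the
   developmental or physiological context in which a gene is most variably
   expressed constrains its protein evolution. It is tested by a
   Kruskal–Wallis test of omega across MaxTissue groups, backed by a
   permutation test that reassigns genes to tissues while preserving the
   observed per-tissue gene counts. Each tissue's evolutionary signature is
   the median omega of its anchored genes, with the dispersion metric
   MaxTissue-delta = 3.14 (v75 − v25)/sqrt(n) (v75, v25 the 75th/25th
   percentiles of omega, linear interpolation between order statistics). The
   constant is implemented literally as 3.14, as the metric is defined with
   that coefficient; the difference from pi is below 0.06%.
3. **Robust association machinery.** EPRCA (below), generalized least
   squares regression of expression on dN with a known co-expression
   covariance \( \mathrm{var}(\varepsilon) = \sigma^2 \Delta \)
   (\(\hat\pi = (dN^T\Delta^{-1}dN)^{-1} dN^T\Delta^{-1} G\), solved by
   Cholesky factorization, never an explicit inverse), resampling tests of
   gene-set enrichment, and permutation nulls that preserve phylogenetic
   branch assignment or network degree.
4. **Joint modeling and power.** Gradient-boosted regression trees with
   squared-error loss over the grid of 100–10000 trees and interaction
   depths 1/4/5 at shrinkage 0.01, reporting a relative-importance spectrum
   (gain normalized to sum to 100) and out-of-sample adjusted R² from
   repeated 70/30 splits; and the statistical power of TWAS gene tests as a
   function of expression-imputation accuracy.

# EPRCA: partial rank correlation under a noisy covariate

The question "does a determinant D affect omega (K) beyond a covariate X?"
is usually answered with a first-order partial Spearman correlation
\(r_{DK|X}\). When only a noisy measurement X' of X is available, the
conditioning is incomplete: both D and K retain shared X signal that X'
cannot remove, and the naive partial correlation is spuriously nonzero even
under conditional independence. `partial_spearman_test()` exposes the naive
analytic test precisely so that its failure mode can be demonstrated.

`eprca()` calibrates the test empirically. The observed statistic is
\(r_{DK|X'}\); a permutation null M0 re-shuffles D and X' together and
recomputes the partial correlation; the empirical p-value is the proportion
of null draws at least as large in magnitude; and the adjusted coefficient
\(\hat\theta = \sqrt{\max(r_{obs}^2 - \overline{M_0}^2, 0)}\) subtracts the
spurious component in quadrature (truncated at zero, where the unadjusted
formula would be imaginary).

Two null schemes are provided because "shuffling D and X' together" can be
operationalized in two ways with complementary properties, and no single
scheme has both:

- **`proxy_swap`** (default) exchanges the *values* \(D_i \leftrightarrow
  X'_i\) within a random subset of genes. When D and X' are two noisy
  measurements centered on the same latent X — exactly the regime in which
  the spurious correlation arises — the data distribution is invariant under
  these swaps when D contributes nothing beyond X, so this is a
  randomization test in the strict sense: the null mean reproduces the
  spurious correlation level (it *quantifies* it), and the type-I error
  stays at its nominal level no matter how noisy X' is. Our simulations
  (equal unit noise on D, K and X', n = 500) show the naive analytic test
  rejecting essentially always while the proxy-swap test holds 5%.
- **`joint_shuffle`** applies one random row permutation jointly to
  (D, X'), preserving Spearman(D, X') exactly in every replicate. Its null
  is centered at zero, so it tests whether the (D, X') pair is associated
  with K at all; with a noise-free conditioning variable this is the scheme
  under which \(\hat\theta\) consistently recovers the true partial
  correlation (we verify recovery within ±0.05 for true values 0.1–0.3).

The practical guidance is: use `proxy_swap` to *test* an independent effect
when the conditioning variable is a noisy proxy of the same construct the
determinant measures; use `joint_shuffle` to *estimate* the effect magnitude
when the conditioning variable is trusted.

# The synthetic-data generator

`simulate_dataset()` produces a coherent dataset — expression, substitution
rates, a protein-interaction-style network, branch (gene age) labels, an
affected-tissue annotation, and per-gene imputation R² — with the couplings
the analysis is designed to detect. Defaults describe a reference
multi-tissue panel: 5000 genes, 44 tissues, 70 samples per tissue.

Expression is generated on the natural-log scale and exponentiated, giving
lognormal margins and the mean–variance relation RPKM data exhibit. Each
gene has an overall abundance (log-normal, spanning roughly four orders of
magnitude), a tissue profile placing it in a broad / intermediate /
tissue-specific class (25/50/25 by default, giving a realized tau spectrum
with median near 0.8), a gene-specific within-tissue noisiness, and one
tissue — the tissue where it is most expressed — in which its
inter-individual variance is further inflated by a gene-specific factor.
The population-variance argmax defines the gene's latent anchor tissue;
because inflation acts where expression peaks, the realized MaxTissue
recovers the anchor for ~94% of genes at 70 samples per tissue.

Log omega is a linear combination of *population* summaries of that
structure: a standardized blend of overall abundance and the mean-adjusted
maximum variance (the lognormal identity log var − 2 log mean =
log(e^{sigma^2} − 1) at the anchor), a small tissue-specificity term, a
per-tissue anchor shift (`anchor_effect_sd`, the tissue-anchored effect),
and independent noise. Three properties follow by construction:

- **Calibration.** With `anchor_effect_sd = 0`, omega carries no
  tissue-identity information (tissue-wide offsets are partialled out of
  the signal), so the anchored permutation test is exactly null — a
  property we verify by the uniformity of its empirical p over replicate
  simulations.
- **Coupling targets.** The blend weight is solved internally (1-D root
  finding on population rank correlations) so that the realized per-tissue
  Spearman correlation between mean expression and omega matches
  `target_rho_level` (default −0.3, the order of magnitude seen in
  mammalian divergence data); the per-tissue variance coupling rides on the
  mean–variance relation and is aimed at the midpoint, so both land within
  about ±0.05 of target when the two targets are equal (the default). With
  unequal targets the variance coupling is only approximate.
- **Explainable variance.** `explainable_variance` (default 0.6) fixes the
  share of omega variance (on the omega scale, via the lognormal
  variance identity) attributable to the population signal. Realized
  feature-based models recover somewhat less — sample variances of
  lognormal data are noisy even at 70 samples — so boosted-model
  out-of-sample adjusted R² concentrates near 0.5–0.55 rather than 0.6.

Auxiliary outputs couple to the same conservation axis: network degree by
rank-matching with a configurable re-shuffle fraction (the marginal degree
law — a truncated power law with exponent 2.5 — is exact for any coupling);
branch labels as age quartiles of a noisy copy of the signal; imputation R²
as a logistic transform of the signal plus noise (positively coupled to
omega: conserved genes are harder to impute); and the affected tissue
equals the anchor with probability `p_match` (default 0.5) else uniform.

**What the generator does not emulate:** library-size normalization and
zero inflation; correlated brain sub-regions (tissues are exchangeable, so
tau needs no exclusion list on synthetic data); realistic linkage between
dS and local mutation context (dS is independent log-normal by design, so
omega and dN carry the signal); genotypes (imputation R² is simulated
directly). Passing tests therefore demonstrate that the statistical
machinery recovers known structure of this kind — not that real data meet
the generator's assumptions.

# Numerical and design choices

- **Moment scale.** Per-tissue moments default to the raw RPKM scale, with
  log2(x + 1) available via `scale = "log2p1"` (pseudocount 1, bounded at
  zero). Correlation profiles are computed from whichever scale the feature
  table was built on; tree-based models are invariant to per-feature
  monotone transforms, so the choice matters mainly for the profile layer.
- **Ties and determinism.** Spearman correlations use average ranks;
  MaxTissue ties break lexicographically by tissue label; Kruskal–Wallis
  uses the standard tie correction (validated against `kruskal.test`).
  Every randomized operation takes an explicit integer seed and restores
  the caller's RNG state.
- **Empirical p-values** are reported exactly as count/n_perm (the
  proportion of null draws that matched or exceeded the observed statistic)
  and may be 0; the resolution bound 1/n_perm is carried in the result.
  EPRCA's p is two-sided on |r|, since partial correlations can take either
  sign.
- **Mann–Whitney comparisons** use the exact distribution only for small
  tie-free samples and the tie-corrected normal approximation otherwise.
- **Tissue clustering** uses Euclidean distance on correlation-profile rows
  with average linkage — a display-ordering choice, not an inferential one.
- **Affected-tissue overlap** tests independence on the full contingency
  table; the accompanying match odds ratio combines per-tissue 2×2 strata
  (MaxTissue = t vs not) × (affected = t vs not) by the Mantel–Haenszel
  common odds ratio. This is one defensible 2×2 construction among several;
  when no discordant pairs exist the ratio is infinite and is reported at a
  continuity-corrected finite bound with a flag.
- **Degree-preserving nulls** default to shuffling omega within log2-spaced
  degree strata, because statistics that are functions of (degree,
  attribute) pairs are *invariant* under edge rewiring, which would make
  that null vacuous; double-edge-swap rewiring (10 swaps per edge per
  replicate, degree sequence asserted identical) is provided for
  topology-dependent statistics.
- **Boosting** delegates tree induction to xgboost with squared-error loss,
  `eta` = shrinkage, `max_depth` = interaction depth, and subsampling
  disabled, making fits deterministic given the seed; importance is gain
  rescaled to sum to 100. Branch enters as an ordered integer code (oldest
  first); missing feature values are routed natively by the trees. The
  default feature set is the cross-tissue set — maximum expression level,
  MaxVariance, tau, mean and median expression level — plus degree, branch
  and imputation R²; per-tissue expansions or other summaries can be
  requested via `feature_cols`.
- **TWAS power** uses the noncentral chi-square form: the association
  statistic for a gene with imputation accuracy R² in a GWAS of N samples
  has noncentrality lambda = N · R² · phi², where phi² (default 0.01, a
  required and logged parameter) is the fraction of trait variance mediated
  by the gene's expression; power is the noncentral tail beyond the central
  chi-square(1) critical value, so R² = 0 gives power exactly alpha.
- **Residualization** removes leading SVD factors of the centered
  sample-by-gene log2 matrix per tissue (plus known covariates) — a simple
  factor-analysis stand-in for PEER-style correction, not an implementation
  of it.

# Problem sizes used by the test suite

The suite validates calibration and power on simulation sizes chosen to
make the checks statistically meaningful on a single CPU: 200 replicate
simulations of 2000 genes × 10 tissues × 25 samples (permutation n = 200)
for the anchored-test calibration; 500 null simulations at n = 500 with 200
permutations for EPRCA's size, and 200 simulations at n = 1000 with 500
permutations per true effect for theta recovery; 20 seeded runs of the full
5000-gene default dataset for the importance-spectrum structure recovery,
with the out-of-sample adjusted R² distribution collected over 70/30 splits
of the first replicates; 500 simulations of block-correlated residuals for
the GLS efficiency comparison; and 100 tissue-subset replicates at sizes 10
and 30 of 44 for tau downsampling.

# Known limitations

- The generator ties all couplings to a single latent conservation axis;
  real determinants of evolutionary rate are only partly collinear.
- The variance-coupling target is exact only when equal to the level
  target; strongly diverging targets are not representable under one latent
  axis with a lognormal mean-variance relation.
- theta recovery in EPRCA assumes the spurious and direct components
  combine in quadrature; with a strong direct effect *and* a noisy
  covariate, theta is an index of effect magnitude, not a consistent
  estimator.
- GLS treats the co-expression covariance as known; estimating it from the
  same expression data would add uncertainty the variance formula ignores.
- Degree-sequence graph construction uses stub pairing with removal of
  self-loops and multi-edges, so hub degrees are approximate at the far
  tail.
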