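# The tissue-anchored model of evolutionary rate: association of MaxTissue
# with omega, gene-count-preserving permutation, the MaxTissue-delta
# dispersion metric, tissue evolutionary signatures, and the affected-tissue
# overlap test.

# Kruskal-Wallis H with tie correction from pre-computed ranks; the fast path
# used inside permutation loops (validated against stats::kruskal.test).
.kw_from_ranks <- function(r, group_idx, tie_corr, N) {
  s <- vapply(group_idx, function(ii) sum(r[ii]), 0)
  n <- lengths(group_idx)
  H <- 12 / (N * (N + 1)) * sum(s^2 / n) - 3 * (N + 1)
  H / tie_corr
}

.kw_prep <- function(labels, omega) {
  ok <- is.finite(omega) & !is.na(labels)
  labels <- as.character(labels[ok]); omega <- omega[ok]
  if (length(unique(labels)) < 2L)
    stop_("need at least 2 tissues with genes (got %d)",
          length(unique(labels)))
  r <- rank(omega)
  N <- length(r)
  ties <- table(omega)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr == 0) tie_corr <- 1  # all values identical; H is 0 anyway
  list(labels = labels, omega = omega, r = r, N = N, tie_corr = tie_corr,
       group_idx = split(seq_len(N), labels))
}

#' Kruskal-Wallis test of MaxTissue against evolutionary rate
#'
#' Tests whether omega differs between genes grouped by the tissue in which
#' each attains its maximum inter-individual expression variance. Rejection
#' supports the tissue-anchored model: variance in evolutionary rate across
#' MaxTissues exceeding the variance within them.
#'
#' @param max_tissue Character vector of MaxTissue labels, one per gene.
#' @param omega Evolutionary rates (dN/dS); pairs with a missing value are
#'   dropped.
#' @return List with `H` (tie-corrected statistic), `df`, `p_analytic`
#'   (chi-square tail), and `n` (genes used). All omega identical gives
#'   H = 0, p = 1.
#' @export
max_tissue_association <- function(max_tissue, omega) {
  pr <- .kw_prep(max_tissue, omega)
  H <- .kw_from_ranks(pr$r, pr$group_idx, pr$tie_corr, pr$N)
  df <- length(pr$group_idx) - 1L
  list(H = H, df = df,
       p_analytic = stats::pchisq(H, df, lower.tail = FALSE), n = pr$N)
}

#' Gene-count-preserving permutation test of the MaxTissue association
#'
#' Each permutation randomly reassigns genes to tissues while preserving the
#' per-tissue gene counts of the observed MaxTissue configuration, and
#' recomputes the Kruskal-Wallis H. The empirical p-value is the proportion
#' of permutations whose H matched or exceeded the observed statistic.
#'
#' @inheritParams max_tissue_association
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A [permutation_result()] (one-sided, `H >= observed`).
#' @export
max_tissue_permutation <- function(max_tissue, omega, n_perm = 1000L,
                                   seed = 1L) {
  if (!is_count(n_perm)) stop_("n_perm must be a positive integer")
  pr <- .kw_prep(max_tissue, omega)
  counts <- lengths(pr$group_idx)
  H_obs <- .kw_from_ranks(pr$r, pr$group_idx, pr$tie_corr, pr$N)
  H_null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    rp <- sample(pr$r)   # random reassignment; group sizes are fixed
    stopifnot(identical(lengths(pr$group_idx), counts))
    .kw_from_ranks(rp, pr$group_idx, pr$tie_corr, pr$N)
  }, 0))
  permutation_result(H_obs, H_null, seed = seed, alternative = "greater")
}

#' MaxTissue-delta dispersion metric
#'
#' delta = 3.14 (v75 - v25) / sqrt(n), where v75 and v25 are the 75th and
#' 25th percentiles (linear interpolation) of the omega values of the n genes
#' anchored in one tissue - an uncertainty-style measure for the tissue's
#' evolutionary-rate signature. The constant is used literally as 3.14.
#'
#' @param omega Omega values of the genes whose MaxTissue is the tissue of
#'   interest.
#' @return delta (nonnegative scalar).
#' @export
max_tissue_delta <- function(omega) {
  omega <- omega[is.finite(omega)]
  if (!length(omega)) stop_("empty group")
  q <- stats::quantile(omega, c(0.25, 0.75), names = FALSE, type = 7)
  3.14 * (q[2L] - q[1L]) / sqrt(length(omega))
}

#' Evolutionary-rate signature of each tissue
#'
#' The "evolutionary rate of a tissue" is the median omega of the genes for
#' which the tissue is the MaxTissue; MaxTissue-delta accompanies it as a
#' dispersion measure. Optionally drops one tissue (and its genes) first, for
#' leave-one-tissue-out robustness checks of the association.
#'
#' @inheritParams max_tissue_association
#' @param drop_tissue Optional tissue label removed before summarizing.
#' @return Data frame (tissue, n, median_omega, delta) sorted by increasing
#'   median omega.
#' @export
tissue_signature <- function(max_tissue, omega, drop_tissue = NULL) {
  ok <- is.finite(omega) & !is.na(max_tissue)
  max_tissue <- as.character(max_tissue[ok]); omega <- omega[ok]
  if (!is.null(drop_tissue)) {
    keep <- max_tissue != drop_tissue
    max_tissue <- max_tissue[keep]; omega <- omega[keep]
  }
  groups <- split(omega, max_tissue)
  out <- data.frame(
    tissue = names(groups),
    n = lengths(groups),
    median_omega = vapply(groups, stats::median, 0),
    delta = vapply(groups, max_tissue_delta, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$median_omega), , drop = FALSE]
}

#' Full tissue-anchored test
#'
#' Convenience wrapper combining [max_tissue_association()],
#' [max_tissue_permutation()] and [tissue_signature()].
#'
#' @inheritParams max_tissue_permutation
#' @param drop_tissue Optional tissue excluded (with its genes) from the
#'   whole analysis, for leave-one-tissue-out checks.
#' @return Object of class `anchor_test_result`: list with `H`, `df`,
#'   `p_analytic`, `perm` ([permutation_result()]), and `signature` (data
#'   frame).
#' @export
anchor_test <- function(max_tissue, omega, n_perm = 1000L, seed = 1L,
                        drop_tissue = NULL) {
  if (!is.null(drop_tissue)) {
    keep <- !is.na(max_tissue) & max_tissue != drop_tissue
    max_tissue <- max_tissue[keep]; omega <- omega[keep]
  }
  assoc <- max_tissue_association(max_tissue, omega)
  perm <- max_tissue_permutation(max_tissue, omega, n_perm = n_perm,
                                 seed = seed)
  structure(c(assoc, list(perm = perm,
                          signature = tissue_signature(max_tissue, omega))),
            class = "anchor_test_result")
}

#' @export
print.anchor_test_result <- function(x, ...) {
  cat(sprintf(paste0("<anchor_test_result> H = %.3f (df = %d), analytic p =",
                     " %.3g, empirical p = %.3g (%d permutations)\n"),
              x$H, x$df, x$p_analytic, x$perm$empirical_p, x$perm$n_perm))
  invisible(x)
}

#' Overlap of MaxTissue with the primary affected tissue
#'
#' Tests, over genes annotated with the primary organ affected in an
#' associated developmental disorder, whether MaxTissue and affected tissue
#' are independent (chi-square test on the full contingency table). A
#' per-tissue match odds ratio is also reported: each tissue contributes a
#' 2x2 stratum (MaxTissue = t vs not) x (affected = t vs not), combined by
#' the Mantel-Haenszel common odds ratio.
#'
#' @param max_tissue Named character vector gene -> MaxTissue.
#' @param affected_tissue Named character vector gene -> primary affected
#'   tissue. Only genes present in both vectors are used; genes whose
#'   MaxTissue label has no counterpart in the affected-tissue vocabulary are
#'   dropped with a message.
#' @return List with `chi2`, `df`, `p`, `match_odds_ratio`,
#'   `or_upper_bounded` (TRUE when the odds ratio is infinite and reported at
#'   its finite lower bound), `n`, and the contingency `table`.
#' @export
affected_tissue_overlap <- function(max_tissue, affected_tissue) {
  shared <- intersect(names(max_tissue), names(affected_tissue))
  if (!length(shared)) stop_("no shared genes")
  mt <- as.character(max_tissue[shared])
  at <- as.character(affected_tissue[shared])
  vocab <- unique(at)
  drop <- !(mt %in% vocab)
  if (any(drop)) {
    message(sprintf(
      "dropped %d gene(s) whose MaxTissue is absent from the affected-tissue vocabulary",
      sum(drop)))
    mt <- mt[!drop]; at <- at[!drop]
  }
  if (length(unique(mt)) < 2L || length(unique(at)) < 2L)
    stop_("degenerate contingency table (a single row or column)")
  tab <- table(MaxTissue = mt, Affected = at)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  num <- den <- 0
  n <- length(mt)
  for (t in vocab) {
    a <- sum(mt == t & at == t); b <- sum(mt == t & at != t)
    cc <- sum(mt != t & at == t); d <- sum(mt != t & at != t)
    num <- num + a * d / n
    den <- den + b * cc / n
  }
  upper_bounded <- den == 0
  or <- if (upper_bounded) {
    # continuity-style finite bound when no discordant pairs exist
    (num + 0.5) / 0.5
  } else num / den
  list(chi2 = unname(chi$statistic), df = unname(chi$parameter),
       p = chi$p.value, match_odds_ratio = or,
       or_upper_bounded = upper_bounded, n = n, table = tab)
}
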