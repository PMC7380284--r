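# Feature-rate correlation profiles, tissue clustering, highly-variable-gene
# comparisons, and tau downsampling stability.

#' Spearman correlation with two-sided p-value
#'
#' Thin, validated wrapper around [stats::cor.test()] with
#' `method = "spearman"`: average ranks for ties, two-sided p (asymptotic via
#' the t approximation in the presence of ties or large n). Pairs with a
#' missing value in either vector are dropped first.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p`, and `n` (pairs used).
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_("need at least 3 complete pairs (got %d)",
                            length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("zero variance in input; Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-tissue correlation profile of expression features with rates
#'
#' For every tissue and every combination of expression feature (per-tissue
#' mean, variance, variance-to-mean) and rate type (dN, dS, omega), computes
#' the Spearman correlation over genes shared between the feature table and
#' the rate table, with pairwise-complete deletion per cell.
#'
#' @param features A [build_feature_table()] result (its attached per-tissue
#'   moment matrices are used).
#' @param rates An [evol_rates()] table.
#' @return Object of class `correlation_profile`: list with matrices `rho`
#'   and `p` (rows = tissues, columns = `<feature>.<rate>`), and `n` of pairs
#'   used per cell.
#' @export
correlation_profile <- function(features, rates) {
  mom <- attr(features, "moments")
  if (is.null(mom)) stop_("feature table lacks per-tissue moments")
  shared <- intersect(features$gene, rates$gene)
  if (length(shared) < 3L) stop_("fewer than 3 genes shared with rates")
  ri <- match(shared, rates$gene)
  gi <- match(shared, features$gene)
  tis <- rownames(mom$mean)  # gene ids
  feats <- c(mean = "mean", variance = "variance",
             var_to_mean = "var_to_mean")
  rts <- c("dN", "dS", "omega")
  tlabs <- colnames(mom$mean)
  cn <- as.vector(outer(names(feats), rts, paste, sep = "."))
  rho <- p <- n <- matrix(NA_real_, length(tlabs), length(cn),
                          dimnames = list(tlabs, cn))
  for (t in tlabs) for (f in names(feats)) for (r in rts) {
    cell <- paste(f, r, sep = ".")
    fx <- mom[[feats[[f]]]][gi, t]
    rx <- rates[[r]][ri]
    ok <- is.finite(fx) & is.finite(rx)
    if (sum(ok) >= 3L && stats::sd(fx[ok]) > 0 && stats::sd(rx[ok]) > 0) {
      s <- spearman_cor(fx, rx)
      rho[t, cell] <- s$rho; p[t, cell] <- s$p; n[t, cell] <- s$n
    }
  }
  structure(list(rho = rho, p = p, n = n), class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> %d tissues x %d feature-rate cells\n",
              nrow(x$rho), ncol(x$rho)))
  invisible(x)
}

#' Cluster tissues by their correlation profiles
#'
#' Hierarchical agglomerative clustering (Euclidean distance on the rho rows,
#' average linkage), giving a deterministic tissue ordering for heatmap-style
#' displays.
#'
#' @param profile A [correlation_profile()].
#' @param impute_missing Replace missing cells by their row mean before
#'   clustering (otherwise missing cells are an error).
#' @return List with `order` (tissue labels in dendrogram order) and `hclust`
#'   (the [stats::hclust()] object), or a trivial ordering for a single
#'   tissue.
#' @export
cluster_tissues <- function(profile, impute_missing = FALSE) {
  m <- profile$rho
  if (nrow(m) < 2L) return(list(order = rownames(m), hclust = NULL))
  if (anyNA(m)) {
    if (!impute_missing)
      stop_("missing profile cells; set impute_missing = TRUE to impute")
    for (i in seq_len(nrow(m)))
      m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
  }
  hc <- stats::hclust(stats::dist(m), method = "average")
  list(order = rownames(m)[hc$order], hclust = hc)
}

#' Compare evolutionary rates of highly variable genes between two tissues
#'
#' Takes the `top_n` genes by within-tissue expression variance in each of two
#' tissues and compares the omega values of the two gene sets with a
#' two-sided Mann-Whitney U test (exact when both sets are small and tie-free,
#' normal approximation with tie correction otherwise). Genes appearing in
#' both top sets are retained in both.
#'
#' @param tissue_a,tissue_b Tissue labels.
#' @param features A [build_feature_table()] result.
#' @param rates An [evol_rates()] table.
#' @param top_n Number of top-variance genes per tissue (default 1000).
#' @return List with `statistic` (U), `p`, and the median omega of each set.
#' @export
compare_top_variable <- function(tissue_a, tissue_b, features, rates,
                                 top_n = 1000L) {
  mom <- attr(features, "moments")
  if (is.null(mom)) stop_("feature table lacks per-tissue moments")
  omega <- stats::setNames(rates$omega, rates$gene)
  pick <- function(t) {
    if (!t %in% colnames(mom$variance)) stop_("unknown tissue '%s'", t)
    v <- mom$variance[, t]
    w <- omega[rownames(mom$variance)]
    ok <- is.finite(v) & is.finite(w)
    if (sum(ok) < top_n)
      stop_("tissue '%s' has only %d genes with variance and omega (need %d)",
            t, sum(ok), top_n)
    idx <- order(v, decreasing = TRUE)
    idx <- idx[ok[idx]][seq_len(top_n)]
    w[idx]
  }
  wa <- pick(tissue_a); wb <- pick(tissue_b)
  exact <- (top_n < 20L) && !anyDuplicated(c(wa, wb))
  wt <- suppressWarnings(stats::wilcox.test(wa, wb, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_a = stats::median(wa), median_b = stats::median(wb))
}

#' Stability of tau under tissue downsampling
#'
#' Repeatedly recomputes tau on random tissue subsets (sampled without
#' replacement) and summarizes, per gene, the standard deviation of tau
#' across replicates, together with the Spearman correlation of that
#' standard deviation with the full-catalog tau. A positive correlation means
#' the tissue-specificity estimate of tissue-specific genes is the least
#' stable under partial tissue catalogs.
#'
#' @param x An [expression_dataset()].
#' @param subset_sizes Integer vector of tissue-subset sizes (each >= 2 and
#'   <= the number of tissues).
#' @param n_reps Replicates per subset size (default 100).
#' @param seed Integer seed.
#' @param exclude_tissues Tissues excluded from tau throughout.
#' @return List with `sd_tau` (gene x subset-size matrix), `tau_full`, and
#'   `correlation` (per subset size: Spearman rho and p of sd_tau vs
#'   tau_full).
#' @export
tau_downsampling <- function(x, subset_sizes, n_reps = 100L, seed = 1L,
                             exclude_tissues = NULL) {
  mom_mean <- per_tissue_moments(x, scale = "raw")$mean
  if (length(exclude_tissues))
    mom_mean <- mom_mean[, !(colnames(mom_mean) %in% exclude_tissues),
                         drop = FALSE]
  T_ <- ncol(mom_mean)
  if (any(subset_sizes < 2L)) stop_("subset sizes must be >= 2")
  if (any(subset_sizes > T_))
    stop_("subset size exceeds the %d available tissues", T_)
  tau_mat <- function(mm) {
    mx <- apply(mm, 1L, max)
    ifelse(mx == 0, NA_real_,
           rowSums(1 - mm / mx) / (ncol(mm) - 1L))
  }
  tau_full <- tau_mat(mom_mean)
  sd_tau <- matrix(NA_real_, nrow(mom_mean), length(subset_sizes),
                   dimnames = list(rownames(mom_mean),
                                   as.character(subset_sizes)))
  with_seed(seed, {
    for (j in seq_along(subset_sizes)) {
      k <- subset_sizes[j]
      taus <- matrix(NA_real_, nrow(mom_mean), n_reps)
      for (r in seq_len(n_reps)) {
        sel <- sample.int(T_, k)
        taus[, r] <- tau_mat(mom_mean[, sel, drop = FALSE])
      }
      sd_tau[, j] <- apply(taus, 1L, stats::sd, na.rm = TRUE)
    }
  })
  correlation <- lapply(seq_along(subset_sizes), function(j) {
    s <- tryCatch(spearman_cor(sd_tau[, j], tau_full),
                  error = function(e) list(rho = NA_real_, p = NA_real_))
    list(subset_size = subset_sizes[j], rho = s$rho, p = s$p)
  })
  list(sd_tau = sd_tau, tau_full = tau_full, correlation = correlation)
}
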