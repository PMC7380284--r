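# Per-tissue expression features: moments, tau expression breadth,
# MaxTissue/MaxVariance, latent-factor residualization, and assembly of the
# per-gene feature table.

#' Per-gene, per-tissue expression moments
#'
#' For each gene and tissue, computes the mean, median, sample variance
#' (denominator n - 1) and variance-to-mean ratio of expression across the
#' tissue's samples. Moments can be taken on the raw RPKM scale (default) or
#' on log2(x + 1); inter-individual variability is quantified by the variance
#' and by the variance-to-mean ratio, which is reported as missing when the
#' mean is 0 and as 0 when the variance is 0 with a positive mean.
#'
#' @param x An [expression_dataset()].
#' @param scale `"raw"` or `"log2p1"`.
#' @return List of four gene-by-tissue matrices: `mean`, `median`, `variance`,
#'   `var_to_mean`. Tissues with fewer than 2 samples get `NA` variance with a
#'   warning.
#' @export
per_tissue_moments <- function(x, scale = c("raw", "log2p1")) {
  scale <- match.arg(scale)
  v <- x$values
  if (scale == "log2p1") v <- log2(v + 1)
  tis <- tissues(x)
  G <- nrow(v)
  mk <- function() matrix(NA_real_, G, length(tis),
                          dimnames = list(rownames(v), tis))
  out <- list(mean = mk(), median = mk(), variance = mk(), var_to_mean = mk())
  small <- character(0)
  for (t in tis) {
    sub <- v[, x$tissue_of == t, drop = FALSE]
    mu <- rowMeans(sub)
    out$mean[, t] <- mu
    out$median[, t] <- row_medians(sub)
    if (ncol(sub) >= 2L) {
      va <- row_vars(sub)
      # guard tiny negative values from the sum-of-squares identity
      va[va < 0] <- 0
      out$variance[, t] <- va
      out$var_to_mean[, t] <- ifelse(mu == 0, NA_real_, va / mu)
    } else {
      small <- c(small, t)
    }
  }
  if (length(small))
    warn_("variance undefined for tissue(s) with < 2 samples: %s",
          paste(small, collapse = ", "))
  out
}

#' Tau expression-breadth statistic
#'
#' tau = sum_i (1 - x_i / max_j x_j) / (n - 1) over the n per-tissue summary
#' values of one gene. tau is 0 for identical expression in every tissue and 1
#' for expression confined to a single tissue; it is invariant to rescaling of
#' the expression values.
#'
#' @param x Nonnegative per-tissue summary values (typically per-tissue mean
#'   expression), named by tissue if `exclude` is used.
#' @param exclude Tissue labels to drop before computing tau (e.g. redundant
#'   brain sub-regions whose correlated profiles would otherwise bias the
#'   estimate).
#' @return tau in \[0, 1\], or `NA` if the maximum is 0.
#' @export
compute_tau <- function(x, exclude = NULL) {
  if (length(exclude)) {
    if (is.null(names(x))) stop_("`x` must be named to use `exclude`")
    x <- x[!(names(x) %in% exclude)]
  }
  if (length(x) < 2L) stop_("tau needs at least 2 tissues")
  if (any(!is.finite(x) | x < 0)) stop_("tau inputs must be finite and >= 0")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1L)
}

#' MaxTissue and MaxVariance of one gene
#'
#' Returns the tissue in which the gene attains its maximum inter-individual
#' expression variance, together with that variance. Ties are broken
#' lexicographically by tissue label so the result is deterministic.
#'
#' @param v Named vector of per-tissue variances for one gene (`NA` allowed).
#' @return List with `max_tissue` (character) and `max_variance` (numeric).
#' @export
identify_max_tissue <- function(v) {
  if (is.null(names(v))) stop_("per-tissue variances must be named by tissue")
  v <- v[!is.na(v)]
  if (!length(v)) stop_("all per-tissue variances are missing")
  v <- v[order(names(v))]
  i <- which.max(v)
  list(max_tissue = names(v)[i], max_variance = unname(v[i]))
}

#' Residualize expression on latent factors and known covariates
#'
#' Within each tissue, removes the leading `k_factors` latent factors of the
#' centered sample-by-gene matrix of log2(x + 1) expression (estimated by
#' singular value decomposition) together with any known covariates, returning
#' per-gene residuals. This is a simple factor-analysis style correction for
#' hidden technical structure (batches, population structure) in the spirit of
#' PEER-type residualization.
#'
#' @param x An [expression_dataset()].
#' @param k_factors Number of leading latent factors to remove (0 = centering
#'   only).
#' @param covariates Optional numeric matrix of known per-sample covariates
#'   (rownames = sample ids).
#' @return An `expression_dataset` of residuals on the centered log2 scale
#'   (values may be negative; flagged via its `residual` field).
#' @export
residualize <- function(x, k_factors = 0L, covariates = NULL) {
  stopifnot(is_count(k_factors, min = 0L))
  lv <- log2(x$values + 1)
  out <- lv
  for (t in tissues(x)) {
    idx <- which(x$tissue_of == t)
    if (k_factors >= length(idx))
      stop_("k_factors (%d) must be < samples in tissue '%s' (%d)",
            k_factors, t, length(idx))
    m <- t(lv[, idx, drop = FALSE])          # samples x genes
    m <- scale(m, center = TRUE, scale = FALSE)
    design <- NULL
    if (!is.null(covariates)) {
      cv <- covariates[rownames(m), , drop = FALSE]
      design <- scale(cv, center = TRUE, scale = FALSE)
    }
    if (k_factors > 0L) {
      sv <- svd(m, nu = k_factors, nv = 0L)
      design <- cbind(design, sv$u[, seq_len(k_factors), drop = FALSE])
    }
    if (!is.null(design) && ncol(design) > 0L) {
      qr_d <- qr(design)
      m <- m - qr.fitted(qr_d, m)
    }
    out[, idx] <- t(m)
  }
  expression_dataset(out, x$tissue_of, residual = TRUE)
}

#' Assemble the per-gene feature table
#'
#' Derives, for every gene, the cross-tissue features used throughout the
#' analysis: tau expression breadth (from per-tissue mean expression),
#' MaxTissue and MaxVariance, maximum per-tissue mean expression (`max_level`),
#' cross-tissue summaries of the per-tissue moments, and - where the
#' corresponding inputs are supplied - network degree, phylogenetic branch,
#' imputation R-squared, and gene-set membership flags.
#'
#' @param x An [expression_dataset()].
#' @param scale Moment scale passed to [per_tissue_moments()].
#' @param exclude_tissues Tissues excluded from the tau computation only.
#' @param network Optional [gene_network()]; genes absent from it get `NA`
#'   degree.
#' @param branch Optional named character vector gene -> branch label.
#' @param imputation_r2 Optional named numeric vector gene -> imputation
#'   R-squared in \[0, 1\].
#' @param gene_sets Optional named list of character vectors; each becomes a
#'   logical membership column (conventionally `essential`, `mendelian`,
#'   `lof_tolerant`).
#' @return A data frame of class `gene_feature_table`, one row per gene, with
#'   the per-tissue moment matrices attached as attribute `moments`.
#' @export
build_feature_table <- function(x, scale = c("raw", "log2p1"),
                                exclude_tissues = NULL, network = NULL,
                                branch = NULL, imputation_r2 = NULL,
                                gene_sets = NULL) {
  scale <- match.arg(scale)
  mom <- per_tissue_moments(x, scale = scale)
  genes <- rownames(x$values)
  tau <- apply(mom$mean, 1L, compute_tau, exclude = exclude_tissues)
  mt <- lapply(seq_along(genes),
               function(i) identify_max_tissue(mom$variance[i, ]))
  ft <- data.frame(
    gene = genes,
    tau = tau,
    max_variance = vapply(mt, `[[`, 0, "max_variance"),
    max_tissue = vapply(mt, `[[`, "", "max_tissue"),
    max_level = apply(mom$mean, 1L, max),
    mean_level = rowMeans(mom$mean),
    median_level = apply(mom$mean, 1L, stats::median),
    mean_variance = rowMeans(mom$variance),
    mean_var_to_mean = rowMeans(mom$var_to_mean, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  ft$degree <- if (is.null(network)) NA_integer_ else {
    d <- network_degree(network)
    unname(ifelse(genes %in% names(d), d[genes], NA_integer_))
  }
  ft$branch <- if (is.null(branch)) NA_character_ else
    unname(branch[genes])
  ft$imputation_r2 <- if (is.null(imputation_r2)) NA_real_ else {
    r2 <- unname(imputation_r2[genes])
    if (any(r2 < 0 | r2 > 1, na.rm = TRUE))
      stop_("imputation_r2 must lie in [0, 1]")
    r2
  }
  for (nm in names(gene_sets)) ft[[nm]] <- genes %in% gene_sets[[nm]]
  rownames(ft) <- NULL
  attr(ft, "moments") <- mom
  attr(ft, "scale") <- scale
  class(ft) <- c("gene_feature_table", "data.frame")
  ft
}
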